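## Synthetic inputs: canonical angle maps, striped test images, a
## structure-tensor orientation estimator, and particle rendering.

#' Canonical synthetic angle maps
#'
#' Samples one of the reference orientation fields onto an [angle_grid()]:
#' \describe{
#'   \item{`parallel`}{constant angle `theta0`;}
#'   \item{`single_core` / `single_delta`}{quadratic-differential field of one
#'     singular point at `zeta`;}
#'   \item{`core_plus_delta`}{composite field with a core at `zeta` and a
#'     delta at `zeta2` (defaults `(0.5, 0.55)` and `(0.5, 0.45)`: a compact
#'     loop whose far field is nearly constant, which keeps the non-periodic
#'     analytic field close to seam-compatible on the torus);}
#'   \item{`two_region`}{angle `theta0` on the left half of the square,
#'     `theta1` on the right -- deliberately discontinuous.}
#' }
#'
#' @param kind one of `"parallel"`, `"single_core"`, `"single_delta"`,
#'   `"core_plus_delta"`, `"two_region"`
#' @param resolution cells per side (>= 16)
#' @param theta0,theta1 angles for `parallel` / `two_region`
#' @param zeta,zeta2 singular-point positions
#' @return an [angle_grid()]
#' @export
make_angle_map <- function(kind = c("parallel", "single_core", "single_delta",
                                    "core_plus_delta", "two_region"),
                           resolution = 64, theta0 = pi / 2, theta1 = 0,
                           zeta = c(0.5, 0.5),
                           zeta2 = c(0.5, 0.45)) {
  kind <- match.arg(kind)
  stopifnot(resolution >= 16)
  centers <- (seq_len(resolution) - 0.5) / resolution
  xy <- cbind(rep(centers, times = resolution),   # x varies fastest
              rep(centers, each = resolution))    # y constant per block
  th <- switch(kind,
    parallel = rep(norm_angle(theta0), resolution^2),
    single_core = core_orientation(xy, zeta),
    single_delta = delta_orientation(xy, zeta),
    core_plus_delta = {
      core_pos <- if (missing(zeta)) c(0.5, 0.55) else zeta
      composite_orientation(xy, list(singular_point(core_pos, "core"),
                                     singular_point(zeta2, "delta")))
    },
    two_region = ifelse(xy[, 1] < 0.5, norm_angle(theta0), norm_angle(theta1)))
  # xy rows are (x const-y blocks); angles[i, j] has y = row i, x = col j
  angle_grid(matrix(th, nrow = resolution, ncol = resolution, byrow = TRUE))
}

#' Synthetic stripe image
#'
#' A cosine grating on the unit square:
#' `pixels = (1 + cos(2 pi (p . n) / wavelength)) / 2` with `n` the unit
#' normal to the stripe direction. Pixel `[i, j]` is centred at
#' `x = (j - 1/2)/res`, `y = (i - 1/2)/res`. Rotating the orientation by pi
#' leaves the image unchanged (stripes are lines, not vectors).
#'
#' @param wavelength stripe period in domain units, in `(0, 0.5]`
#' @param orientation stripe direction (radians)
#' @param resolution pixels per side
#' @return list with `pixels` (matrix in `[0,1]`), `wavelength`, `orientation`
#' @export
stripe_image <- function(wavelength, orientation, resolution = 128) {
  stopifnot(wavelength > 0, wavelength <= 0.5)
  centers <- (seq_len(resolution) - 0.5) / resolution
  nvec <- c(-sin(orientation), cos(orientation))
  # phase[i, j] = x_j * n1 + y_i * n2
  phase <- outer(centers * nvec[2], centers * nvec[1], "+")
  list(pixels = (1 + cos(2 * pi * phase / wavelength)) / 2,
       wavelength = wavelength, orientation = norm_angle(orientation))
}

#' Structure-tensor ridge-orientation estimator
#'
#' A simplified gradient-based estimator: central-difference gradients, a
#' per-pixel gradient outer product smoothed with an isotropic Gaussian
#' (circular boundary, matching the torus), and the ridge orientation taken
#' as the eigenvector of the *smaller* eigenvalue of the smoothed structure
#' tensor -- perpendicular to the dominant gradient -- returned mod pi.
#' Pixels whose smoothed tensor trace is below `mask_rel_tol` times the
#' maximum trace (no local contrast, e.g. a constant image) are masked out.
#'
#' @param pixels grayscale matrix (at least 16x16), values in `[0, 1]`
#' @param smoothing_sigma Gaussian smoothing scale in pixels (default 2)
#' @param mask_rel_tol relative tensor-trace masking threshold (default 1e-6)
#' @return an [angle_grid()] with mask
#' @export
estimate_orientation <- function(pixels, smoothing_sigma = 2,
                                 mask_rel_tol = 1e-6) {
  if (is.list(pixels) && !is.null(pixels$pixels)) pixels <- pixels$pixels
  pixels <- as.matrix(pixels)
  stopifnot(nrow(pixels) >= 16, ncol(pixels) >= 16)
  nr <- nrow(pixels); nc <- ncol(pixels)
  up <- c(nr, 1:(nr - 1)); dn <- c(2:nr, 1)
  lf <- c(nc, 1:(nc - 1)); rt <- c(2:nc, 1)
  gy <- (pixels[dn, ] - pixels[up, ]) / 2  # d/dy: rows index y
  gx <- (pixels[, rt] - pixels[, lf]) / 2  # d/dx
  jxx <- EBImage::gblur(gx * gx, sigma = smoothing_sigma, boundary = "circular")
  jyy <- EBImage::gblur(gy * gy, sigma = smoothing_sigma, boundary = "circular")
  jxy <- EBImage::gblur(gx * gy, sigma = smoothing_sigma, boundary = "circular")
  tr <- jxx + jyy
  mask <- tr > mask_rel_tol * max(tr)
  # dominant gradient orientation, then + pi/2 for the ridge direction
  grad_theta <- atan2(2 * jxy, jxx - jyy) / 2
  angle_grid(norm_angle(grad_theta + pi / 2), mask)
}

#' Render particles to a grayscale torus image
#'
#' Deposits a Gaussian splat per particle (via binning to the pixel grid and
#' convolution with a circular-boundary Gaussian, so mass wraps across the
#' periodic seam) and normalizes the result to `[0, 1]`.
#'
#' @param state a [particle_state()]
#' @param resolution pixels per side (default 256)
#' @param splat_radius Gaussian sigma in domain units (default 0.004)
#' @return matrix in `[0, 1]` (all zeros for an empty accumulation)
#' @export
render_particles <- function(state, resolution = 256, splat_radius = 0.004) {
  stopifnot(splat_radius > 0)
  pos <- state$positions
  img <- matrix(0, resolution, resolution)
  if (nrow(pos) > 0) {
    i <- pmin(floor(pos[, 2] * resolution) + 1, resolution)  # row = y
    j <- pmin(floor(pos[, 1] * resolution) + 1, resolution)  # col = x
    for (k in seq_along(i)) img[i[k], j[k]] <- img[i[k], j[k]] + 1
    img <- EBImage::gblur(img, sigma = splat_radius * resolution,
                          boundary = "circular")
    if (max(img) > 0) img <- img / max(img)
  }
  img
}
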