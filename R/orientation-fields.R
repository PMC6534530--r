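## Orientation fields: the direction s(x) of smallest stress (a line field,
## defined mod pi), its perpendicular l(x), and the anisotropy tensor
## T(x) = chi s(x) (x) s(x) + l(x) (x) l(x).

norm_angle <- function(theta) {
  th <- theta %% pi
  # half-open [0, pi): pi itself (possible from %% rounding) maps to 0
  th[th >= pi] <- 0
  th
}

#' A singular point of an orientation field
#'
#' Cores and deltas are the two singular-point types of fingerprint
#' orientation fields: a core is the endpoint of a single ridge line, a delta
#' the junction of three lines. In the quadratic-differential representation
#' a delta contributes a simple zero and a core a simple pole.
#'
#' @param position length-2 numeric in the unit square
#' @param kind `"core"` or `"delta"`
#' @return an object of class `singular_point`
#' @export
singular_point <- function(position, kind = c("core", "delta")) {
  kind <- match.arg(kind)
  stopifnot(length(position) == 2, all(position >= 0), all(position <= 1))
  structure(list(position = as.numeric(position), kind = kind),
            class = "singular_point")
}

#' Orientation angle of a single delta
#'
#' The line field of a delta at `zeta` solves \eqn{z\, dz^2 > 0}, giving
#' \eqn{dz = \pm \exp(-i\,\arg(z)/2)}: the angle at `x` is
#' \eqn{-\arg(x - \zeta)/2} reduced mod \eqn{\pi}. The three straight ridges
#' of the delta meet at equal \eqn{2\pi/3} angles around the singular point.
#'
#' @param x query point(s): length-2 vector or n-by-2 matrix
#' @param zeta delta position (length-2)
#' @return angle(s) in `[0, pi)`
#' @export
delta_orientation <- function(x, zeta) {
  x <- rbind2col(x)
  dx <- x[, 1] - zeta[1]; dy <- x[, 2] - zeta[2]
  if (any(dx == 0 & dy == 0))
    stop("orientation undefined at the singular point itself")
  norm_angle(-atan2(dy, dx) / 2)
}

#' Orientation angle of a single core
#'
#' The core field solves \eqn{dz^2 / z > 0}, i.e.
#' \eqn{dz = \pm \exp(+i\,\arg(z)/2)}: the angle at `x` is
#' \eqn{+\arg(x - \zeta)/2} mod \eqn{\pi}. Exactly one straight ridge
#' terminates at the singular point.
#'
#' @inheritParams delta_orientation
#' @param zeta core position (length-2)
#' @return angle(s) in `[0, pi)`
#' @export
core_orientation <- function(x, zeta) {
  x <- rbind2col(x)
  dx <- x[, 1] - zeta[1]; dy <- x[, 2] - zeta[2]
  if (any(dx == 0 & dy == 0))
    stop("orientation undefined at the singular point itself")
  norm_angle(atan2(dy, dx) / 2)
}

#' Orientation angle of a combined core/delta field
#'
#' Represents the global field by the quadratic differential
#' \eqn{\phi(z) = \prod_i (z - \zeta_i^{delta}) / \prod_j (z - \zeta_j^{core})}
#' and solves \eqn{\phi\, dz^2 > 0}, which yields the additive argument rule
#' \deqn{\theta(x) = \tfrac12\Big(\sum_{cores} \arg(x - \zeta_j)
#'   - \sum_{deltas} \arg(x - \zeta_i)\Big) \bmod \pi.}
#' For a single point this reduces exactly to [delta_orientation()] /
#' [core_orientation()].
#'
#' @inheritParams delta_orientation
#' @param points list of [singular_point()] objects
#' @return angle(s) in `[0, pi)`
#' @export
composite_orientation <- function(x, points) {
  stopifnot(length(points) >= 1)
  x <- rbind2col(x)
  acc <- numeric(nrow(x))
  for (p in points) {
    dx <- x[, 1] - p$position[1]; dy <- x[, 2] - p$position[2]
    if (any(dx == 0 & dy == 0))
      stop("orientation undefined at the singular point itself")
    a <- atan2(dy, dx)
    acc <- acc + if (p$kind == "core") a else -a
  }
  norm_angle(acc / 2)
}

# coerce a point or matrix of points to n x 2
rbind2col <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 2)
    matrix(x, ncol = 2)
  } else {
    stopifnot(ncol(x) == 2)
    as.matrix(x)
  }
}

#' A sampled grid of orientation angles
#'
#' Angles in `[0, pi)` sampled on a uniform grid over the unit square.
#' Entry `angles[i, j]` belongs to the cell centred at
#' `x = (j - 1/2)/ncol`, `y = (i - 1/2)/nrow`. The optional logical `mask`
#' marks valid cells.
#'
#' @param angles numeric matrix of angles (radians); normalized mod pi on
#'   ingest
#' @param mask optional logical matrix of the same shape (`TRUE` = valid)
#' @return an object of class `angle_grid`
#' @export
angle_grid <- function(angles, mask = NULL) {
  angles <- as.matrix(angles)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(angles), ncol(angles))
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  stopifnot(all(dim(mask) == dim(angles)))
  angles[mask] <- norm_angle(angles[mask])
  structure(list(angles = angles, mask = mask), class = "angle_grid")
}

#' Look up an angle in a sampled grid
#'
#' `mode = "nearest"` returns the angle of the closest valid cell (searching
#' outward if the containing cell is masked). `mode = "bilinear"` bilinearly
#' interpolates the doubled-angle embedding `(cos 2theta, sin 2theta)`
#' component-wise and halves the recovered argument, so averaging is correct
#' across the `pi` wraparound (two adjacent cells at `0.01` and `pi - 0.01`
#' average to `~0`, not `pi/2`). Interpolation wraps periodically (torus).
#' Cells under the mask fall back to nearest-valid lookup.
#'
#' @param grid an [angle_grid()]
#' @param x query point(s) in `[0,1)^2`: length-2 vector or n-by-2 matrix
#' @param mode `"bilinear"` (default) or `"nearest"`
#' @return angle(s) in `[0, pi)`
#' @export
grid_lookup <- function(grid, x, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "angle_grid"))
  if (!any(grid$mask)) stop("angle grid has no valid cells")
  x <- rbind2col(x)
  nr <- nrow(grid$angles); nc <- ncol(grid$angles)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  nearest_one <- function(px, py) {
    i0 <- wrap(floor(py * nr - 0.5 + 0.5) + 1, nr)  # nearest cell index
    j0 <- wrap(floor(px * nc - 0.5 + 0.5) + 1, nc)
    if (grid$mask[i0, j0]) return(grid$angles[i0, j0])
    # expanding ring search over valid cells (torus metric)
    for (rad in 1:max(nr, nc)) {
      ii <- wrap(i0 + (-rad:rad), nr); jj <- wrap(j0 + (-rad:rad), nc)
      sub <- grid$mask[ii, jj, drop = FALSE]
      if (any(sub)) {
        cand <- which(sub, arr.ind = TRUE)
        # pick the candidate closest in torus distance
        cy <- (ii[cand[, 1]] - 0.5) / nr; cx <- (jj[cand[, 2]] - 0.5) / nc
        d2 <- torus_delta(cx - px)^2 + torus_delta(cy - py)^2
        k <- which.min(d2)
        return(grid$angles[ii[cand[k, 1]], jj[cand[k, 2]]])
      }
    }
    stop("no valid cell found")  # unreachable: mask has at least one TRUE
  }
  if (mode == "nearest")
    return(vapply(seq_len(nrow(x)), function(k) nearest_one(x[k, 1], x[k, 2]),
                  numeric(1)))
  # bilinear on the doubled-angle embedding
  gi <- x[, 2] * nr - 0.5; gj <- x[, 1] * nc - 0.5  # continuous 0-based index
  i0 <- floor(gi); j0 <- floor(gj)
  fi <- gi - i0; fj <- gj - j0
  i1 <- wrap(i0 + 1, nr); i2 <- wrap(i0 + 2, nr)
  j1 <- wrap(j0 + 1, nc); j2 <- wrap(j0 + 2, nc)
  idx <- function(ii, jj) cbind(ii, jj)
  corners <- list(idx(i1, j1), idx(i1, j2), idx(i2, j1), idx(i2, j2))
  w <- list((1 - fi) * (1 - fj), (1 - fi) * fj, fi * (1 - fj), fi * fj)
  all_valid <- grid$mask[corners[[1]]] & grid$mask[corners[[2]]] &
    grid$mask[corners[[3]]] & grid$mask[corners[[4]]]
  c2 <- s2 <- numeric(nrow(x))
  for (k in 1:4) {
    a <- grid$angles[corners[[k]]]
    c2 <- c2 + w[[k]] * cos(2 * a)
    s2 <- s2 + w[[k]] * sin(2 * a)
  }
  out <- norm_angle(atan2(s2, c2) / 2)
  degen <- !all_valid | (c2^2 + s2^2 < 1e-24)
  if (any(degen))
    out[degen] <- vapply(which(degen),
                         function(k) nearest_one(x[k, 1], x[k, 2]), numeric(1))
  out
}

# shortest signed representative of a coordinate difference on the unit circle
torus_delta <- function(d) d - floor(d + 0.5)

#' Fill masked cells of an angle grid by harmonic extension
#'
#' Replaces invalid cells with a discrete Laplace (Jacobi) smoothing of the
#' doubled-angle embedding `(cos 2theta, sin 2theta)`, holding valid cells
#' fixed as boundary data; neighbourhoods wrap periodically. Valid cells are
#' returned unchanged. This is a deliberately simple stand-in for
#' image-based orientation extrapolation: a constant valid region extends to
#' the exact same constant.
#'
#' @param grid an [angle_grid()] with at least one valid cell
#' @param sweeps number of Jacobi sweeps (default 50)
#' @return a fully valid [angle_grid()]
#' @export
fill_missing_orientations <- function(grid, sweeps = 50) {
  stopifnot(inherits(grid, "angle_grid"))
  if (!any(grid$mask)) stop("angle grid has no valid cells")
  if (all(grid$mask)) return(grid)
  a <- grid$angles; m <- grid$mask
  cs <- cos(2 * a) * m; sn <- sin(2 * a) * m  # masked cells start at (0, 0)
  nr <- nrow(a); nc <- ncol(a)
  up <- c(nr, 1:(nr - 1)); dn <- c(2:nr, 1)
  lf <- c(nc, 1:(nc - 1)); rt <- c(2:nc, 1)
  for (it in seq_len(sweeps)) {
    cs_new <- (cs[up, ] + cs[dn, ] + cs[, lf] + cs[, rt]) / 4
    sn_new <- (sn[up, ] + sn[dn, ] + sn[, lf] + sn[, rt]) / 4
    cs[!m] <- cs_new[!m]
    sn[!m] <- sn_new[!m]
  }
  filled <- a
  filled[!m] <- norm_angle(atan2(sn[!m], cs[!m]) / 2)
  angle_grid(filled)
}

#' Construct an orientation field
#'
#' An orientation field maps every point of the unit square to the unit
#' direction `s(x)` of smallest stress (defined up to sign -- a line field),
#' the perpendicular `l(x)`, and the anisotropy tensor
#' \eqn{T(x) = \chi\, s s^T + l l^T}. Four representations are supported:
#'
#' * `homogeneous_field(theta0)`: constant angle;
#' * `singular_field(points)`: quadratic-differential field of cores/deltas;
#' * `piecewise_field(regions)`: axis-aligned rectangles with constant angle,
#'   first match wins; `regions` is a data.frame with columns
#'   `xmin, xmax, ymin, ymax, theta` (the last row should cover the rest of
#'   the square);
#' * `sampled_field(grid)`: an [angle_grid()], looked up per [grid_lookup()].
#'
#' @param theta0 constant angle (radians)
#' @param chi anisotropy parameter in `[0, 1]` carried by the tensor
#' @return an object of class `orientation_field`
#' @export
homogeneous_field <- function(theta0, chi = 0.2) {
  new_field("homogeneous", chi, theta0 = norm_angle(theta0))
}

#' @rdname homogeneous_field
#' @param points list of [singular_point()] objects
#' @export
singular_field <- function(points, chi = 0.2) {
  stopifnot(all(vapply(points, inherits, logical(1), "singular_point")))
  new_field("singular", chi, points = points)
}

#' @rdname homogeneous_field
#' @param regions data.frame with columns `xmin, xmax, ymin, ymax, theta`
#' @export
piecewise_field <- function(regions, chi = 0.2) {
  stopifnot(is.data.frame(regions),
            all(c("xmin", "xmax", "ymin", "ymax", "theta") %in% names(regions)))
  new_field("piecewise", chi, regions = regions)
}

#' @rdname homogeneous_field
#' @param grid an [angle_grid()]
#' @param mode lookup mode for sampled fields, see [grid_lookup()]
#' @export
sampled_field <- function(grid, chi = 0.2, mode = "bilinear") {
  stopifnot(inherits(grid, "angle_grid"))
  new_field("sampled", chi, grid = grid, mode = mode)
}

new_field <- function(kind, chi, ...) {
  stopifnot(chi >= 0, chi <= 1)
  structure(c(list(kind = kind, chi = chi), list(...)),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat("<orientation_field>", x$kind, " chi:", x$chi, "\n")
  invisible(x)
}

#' Orientation angle(s) of a field
#'
#' Vectorized evaluation of the field angle `theta(x)` in `[0, pi)`.
#'
#' @param field an `orientation_field`
#' @param x query point(s): length-2 vector or n-by-2 matrix in `[0,1)^2`
#' @return numeric vector of angles
#' @export
field_angle <- function(field, x) {
  stopifnot(inherits(field, "orientation_field"))
  x <- rbind2col(x)
  switch(field$kind,
    homogeneous = rep(field$theta0, nrow(x)),
    singular = composite_orientation(x, field$points),
    piecewise = {
      th <- rep(NA_real_, nrow(x))
      for (k in seq_len(nrow(field$regions))) {
        rg <- field$regions[k, ]
        hit <- is.na(th) & x[, 1] >= rg$xmin & x[, 1] < rg$xmax &
          x[, 2] >= rg$ymin & x[, 2] < rg$ymax
        th[hit] <- rg$theta
      }
      if (anyNA(th)) stop("point outside all piecewise regions")
      norm_angle(th)
    },
    sampled = grid_lookup(field$grid, x, field$mode),
    stop("unknown field kind")
  )
}

#' Local stress frame
#'
#' Reconstructs the unit direction of smallest stress
#' `s = (cos theta, sin theta)` and its perpendicular `l = (-sin theta,
#' cos theta)` at a single point.
#'
#' @param field an `orientation_field`
#' @param x length-2 point
#' @return list with unit 2-vectors `s` and `l`
#' @export
frame_at <- function(field, x) {
  th <- field_angle(field, x)
  list(s = c(cos(th), sin(th)), l = c(-sin(th), cos(th)))
}

# vectorized frames for all particle positions: list(S = n x 2, L = n x 2)
field_frames <- function(field, pos) {
  th <- field_angle(field, pos)
  list(S = cbind(cos(th), sin(th)), L = cbind(-sin(th), cos(th)))
}

#' Anisotropy tensor at a point
#'
#' \eqn{T(x) = \chi\, s(x) s(x)^T + l(x) l(x)^T}: a symmetric 2x2 matrix with
#' eigenvalues `chi` (eigenvector `s`) and `1` (eigenvector `l`). Invariant
#' under the sign flip `s -> -s`, as any quantity derived from a line field
#' must be.
#'
#' @inheritParams frame_at
#' @return 2x2 symmetric matrix
#' @export
tensor_at <- function(field, x) {
  fr <- frame_at(field, x)
  field$chi * tcrossprod(fr$s) + tcrossprod(fr$l)
}
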