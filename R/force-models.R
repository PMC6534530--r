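#' Parameters of the Kuecken--Champod force coefficients
#'
#' Bundles the constants of the quadratic-times-exponential repulsion
#' coefficient \eqn{f_R(r) = (\alpha r^2 + \beta) e^{-e_R r}} and the
#' attraction coefficient \eqn{f_A(r) = -\gamma r e^{-e_A r}}, together with
#' the anisotropy parameter \eqn{\chi \in [0,1]} of the stress tensor and an
#' optional multiplicative factor `delta_scale` on the attraction force
#' (the \eqn{\delta} of the attraction-strength sweep; `1` recovers the
#' unmodified force).
#'
#' @param alpha repulsion quadratic amplitude (dimensionless, >= 0)
#' @param beta repulsion offset (>= 0); equals \eqn{f_R(0)}
#' @param gamma attraction amplitude (>= 0)
#' @param e_A attraction decay rate (1/length, >= 0)
#' @param e_R repulsion decay rate (1/length, >= 0)
#' @param chi anisotropy parameter in \eqn{[0, 1]}
#' @param delta_scale multiplicative factor on the attraction force in
#'   \eqn{[0, 1]}; default 1
#' @return an object of class `kc_params`
#' @seealso [force_preset()] for the canonical parameter sets
#' @export
kc_params <- function(alpha, beta, gamma, e_A, e_R, chi, delta_scale = 1.0) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, e_A >= 0, e_R >= 0,
            chi >= 0, chi <= 1, delta_scale >= 0, delta_scale <= 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 e_A = e_A, e_R = e_R, chi = chi, delta_scale = delta_scale),
            class = "kc_params")
}

#' Parameters of the damped-harmonic-oscillator force coefficients
#'
#' The oscillator ansatz models both coefficient functions as damped
#' oscillations: \eqn{f_s(r) = c e^{e_{s1} r} + c_s \sin(\pi r / a_s) e^{e_{s2} r}}
#' and \eqn{f_l(r) = c \cos(\pi r / a_l) e^{e_{l1} r} + c_l \sin(\pi r / a_l)
#' e^{e_{l2} r}}. All decay rates must be negative; `c` dominates the
#' oscillatory amplitudes so that `f_s` stays repulsive.
#'
#' @param c leading amplitude (> 0)
#' @param c_s,c_l oscillation amplitudes, `abs(c) > abs(c_s)`, `abs(c) > abs(c_l)`
#' @param e_s1,e_s2,e_l1,e_l2 decay rates (all < 0)
#' @param a_s,a_l oscillation half-periods (length, > 0)
#' @return an object of class `oscillator_params`
#' @export
oscillator_params <- function(c, c_s, c_l, e_s1, e_s2, e_l1, e_l2, a_s, a_l) {
  stopifnot(c > 0, abs(c) > abs(c_s), abs(c) > abs(c_l),
            e_s1 < 0, e_s2 < 0, e_l1 < 0, e_l2 < 0, a_s > 0, a_l > 0)
  structure(list(c = c, c_s = c_s, c_l = c_l, e_s1 = e_s1, e_s2 = e_s2,
                 e_l1 = e_l1, e_l2 = e_l2, a_s = a_s, a_l = a_l),
            class = "oscillator_params")
}

#' Parameters of the piecewise (sign-flipped tail) force coefficients
#'
#' Wraps a [kc_params()] base with two cutoffs `c1 < c2`. Writing
#' \eqn{f(r, \chi) = \chi f_A(r) + f_R(r)}, the l-coefficient equals
#' \eqn{f(r, 1)} below `c1`, its negation above `c2`, and the linear
#' interpolation between \eqn{f(c_1, 1)} and \eqn{-f(c_2, 1)} in between;
#' the s-coefficient is \eqn{f(r, \chi)} everywhere. The flipped tail turns
#' the long-range repulsion of \eqn{f(r,1)} into a weak attraction so the
#' model remains usable under range rescaling with \eqn{\eta > 1}.
#'
#' @param base a [kc_params()] object
#' @param c1,c2 inner and outer interpolation cutoffs, `0 < c1 < c2`
#' @return an object of class `piecewise_params`
#' @export
piecewise_params <- function(base, c1 = 0.06, c2 = 0.07) {
  stopifnot(inherits(base, "kc_params"), c1 > 0, c1 < c2)
  structure(list(base = base, c1 = c1, c2 = c2), class = "piecewise_params")
}

#' Assemble a force model
#'
#' A force model names one of the five interaction families, carries the
#' matching parameter record, the hard cutoff radius beyond which the pair
#' force vanishes identically, and the range-rescaling factor \eqn{\eta}
#' (the force is evaluated as \eqn{F(\eta d, T)}, so \eqn{\eta > 1} shrinks
#' the effective interaction range and the stationary ridge spacing, while
#' \eqn{\eta < 1} enlarges both).
#'
#' @param family one of `"kc_original"`, `"kc_adapted"`, `"kc_reparam"`,
#'   `"piecewise"`, `"oscillator"`
#' @param params parameter record matching the family ([kc_params()] for the
#'   three kc variants, [piecewise_params()], [oscillator_params()])
#' @param cutoff_radius hard cutoff in `(0, 0.5]`; default 0.5, the largest
#'   separation possible on the unit torus
#' @param eta rescaling factor (> 0); default 1
#' @return an object of class `force_model`
#' @export
force_model <- function(family, params, cutoff_radius = 0.5, eta = 1.0) {
  family <- match.arg(family, c("kc_original", "kc_adapted", "kc_reparam",
                                "piecewise", "oscillator"))
  need <- switch(family,
                 piecewise  = "piecewise_params",
                 oscillator = "oscillator_params",
                 "kc_params")
  if (!inherits(params, need))
    stop("family '", family, "' requires params of class '", need, "'")
  stopifnot(cutoff_radius > 0, cutoff_radius <= 0.5, eta > 0)
  if (family == "piecewise" && params$c2 >= cutoff_radius)
    stop("piecewise cutoffs must satisfy c1 < c2 < cutoff_radius")
  structure(list(family = family, params = params,
                 cutoff_radius = cutoff_radius, eta = eta),
            class = "force_model")
}

#' @export
print.force_model <- function(x, ...) {
  cat("<force_model> family:", x$family,
      " cutoff:", x$cutoff_radius, " eta:", x$eta, "\n")
  str(unclass(x$params), give.attr = FALSE)
  invisible(x)
}

#' Canonical force-model presets
#'
#' Named parameter presets addressable from configuration files and the
#' command line:
#' \describe{
#'   \item{`"kc2012"`}{Kuecken--Champod style coefficients with
#'     \eqn{\alpha=270, \beta=0.1, \gamma=35, e_A=95, e_R=100, \chi=0.2}.}
#'   \item{`"kc-adapted"`}{same constants, but the attraction along the lines
#'     of largest stress is damped to \eqn{0.3 f_A} (family `kc_adapted`).}
#'   \item{`"kc-reparam"`}{the equivalent reparameterization folding the 0.3
#'     into the attraction amplitude: \eqn{\gamma = 0.3 \times 35 = 10.5},
#'     family `kc_original`.}
#'   \item{`"piecewise"`}{kc2012 constants with the sign-flipped attraction
#'     tail, interpolation cutoffs \eqn{c_1 = 0.06}, \eqn{c_2 = 0.07}.}
#'   \item{`"oscillator2014"`}{damped-oscillator coefficients with
#'     \eqn{c=0.1, c_s=-0.05, e_{s1}=-65, e_{s2}=-100, a_s=0.03,
#'     c_l=0.005, e_{l1}=-160, e_{l2}=-40, a_l=0.022}.}
#' }
#'
#' @param name preset identifier (see Details)
#' @param cutoff_radius,eta forwarded to [force_model()]
#' @return a [force_model()] object
#' @export
force_preset <- function(name, cutoff_radius = 0.5, eta = 1.0) {
  name <- match.arg(name, c("kc2012", "kc-adapted", "kc-reparam",
                            "piecewise", "oscillator2014"))
  kc12 <- kc_params(alpha = 270, beta = 0.1, gamma = 35,
                    e_A = 95, e_R = 100, chi = 0.2)
  switch(name,
    "kc2012"    = force_model("kc_original", kc12, cutoff_radius, eta),
    "kc-adapted" = force_model("kc_adapted", kc12, cutoff_radius, eta),
    "kc-reparam" = force_model("kc_original",
                               kc_params(alpha = 270, beta = 0.1, gamma = 10.5,
                                         e_A = 95, e_R = 100, chi = 0.2),
                               cutoff_radius, eta),
    "piecewise" = force_model("piecewise", piecewise_params(kc12, 0.06, 0.07),
                              cutoff_radius, eta),
    "oscillator2014" = force_model("oscillator",
                                   oscillator_params(c = 0.1, c_s = -0.05,
                                                     c_l = 0.005,
                                                     e_s1 = -65, e_s2 = -100,
                                                     e_l1 = -160, e_l2 = -40,
                                                     a_s = 0.03, a_l = 0.022),
                                   cutoff_radius, eta))
}

#' Repulsion force coefficient
#'
#' \eqn{f_R(r) = (\alpha r^2 + \beta) e^{-e_R r}}; strictly positive for
#' \eqn{\beta > 0} and exponentially decaying.
#'
#' @param r nonnegative distance(s)
#' @param p a [kc_params()] object
#' @return numeric vector of the same length as `r`
#' @export
repulsion_coefficient <- function(r, p) {
  stopifnot(inherits(p, "kc_params"))
  if (any(r < 0)) stop("distance r must be nonnegative")
  (p$alpha * r^2 + p$beta) * exp(-p$e_R * r)
}

#' Attraction force coefficient
#'
#' \eqn{f_A(r) = -\gamma r e^{-e_A r}}; nonpositive everywhere, zero at the
#' origin, with a single minimum at \eqn{r = 1/e_A}.
#'
#' @inheritParams repulsion_coefficient
#' @return numeric vector of the same length as `r`
#' @export
attraction_coefficient <- function(r, p) {
  stopifnot(inherits(p, "kc_params"))
  if (any(r < 0)) stop("distance r must be nonnegative")
  -p$gamma * r * exp(-p$e_A * r)
}

#' Damped-oscillator force coefficients
#'
#' Evaluates both oscillator coefficient functions (see
#' [oscillator_params()]) at the given distances. No cutoff is applied here;
#' see [axis_coefficients()] for the assembled, truncated pair.
#'
#' @param r nonnegative distance(s)
#' @param p an [oscillator_params()] object
#' @return list with components `f_s` and `f_l`
#' @export
oscillator_coefficients <- function(r, p) {
  stopifnot(inherits(p, "oscillator_params"))
  if (any(r < 0)) stop("distance r must be nonnegative")
  list(
    f_s = p$c * exp(p$e_s1 * r) + p$c_s * sin(pi * r / p$a_s) * exp(p$e_s2 * r),
    f_l = p$c * cos(pi * r / p$a_l) * exp(p$e_l1 * r) +
      p$c_l * sin(pi * r / p$a_l) * exp(p$e_l2 * r)
  )
}

#' Piecewise force coefficients with sign-flipped attraction tail
#'
#' Evaluates \eqn{\bar f_s(r) = f(r, \chi)} and the continuous piecewise
#' l-coefficient (see [piecewise_params()]).
#'
#' @param r nonnegative distance(s)
#' @param p a [piecewise_params()] object
#' @return list with components `f_s` and `f_l`
#' @export
piecewise_coefficients <- function(r, p) {
  stopifnot(inherits(p, "piecewise_params"))
  if (any(r < 0)) stop("distance r must be nonnegative")
  b <- p$base
  f <- function(r, chi) {
    chi * b$delta_scale * attraction_coefficient(r, b) +
      repulsion_coefficient(r, b)
  }
  f1 <- f(r, 1)
  fl <- ifelse(r < p$c1, f1,
               ifelse(r > p$c2, -f1,
                      f(p$c1, 1) + (r - p$c1) / (p$c2 - p$c1) *
                        (-f(p$c2, 1) - f(p$c1, 1))))
  list(f_s = f(r, b$chi), f_l = fl)
}

#' Axis force coefficients of a force model
#'
#' Unified dispatch to the coefficient pair \eqn{(f_s, f_l)} acting along the
#' lines of smallest and largest stress:
#' * `kc_original` / `kc_reparam`: \eqn{(\chi \delta f_A + f_R,\ \delta f_A + f_R)}
#'   with \eqn{\delta} = `delta_scale` (so \eqn{\delta < 1} with \eqn{\chi = 1}
#'   realizes the radially symmetric attraction-strength sweep
#'   \eqn{F = \delta F_A + F_R});
#' * `kc_adapted`: \eqn{(\chi f_A + f_R,\ 0.3 f_A + f_R)};
#' * `piecewise`, `oscillator`: their own coefficient pairs.
#'
#' The hard cutoff is applied last: both components are exactly zero for
#' `r >= cutoff_radius` (closed at the cutoff).
#'
#' @param model a [force_model()]
#' @param r nonnegative distance(s), already rescaled by \eqn{\eta} if
#'   applicable (callers pass \eqn{\eta |d|})
#' @return list with components `f_s` and `f_l`
#' @export
axis_coefficients <- function(model, r) {
  stopifnot(inherits(model, "force_model"))
  if (any(r < 0)) stop("distance r must be nonnegative")
  p <- model$params
  co <- switch(model$family,
    kc_original = {
      fA <- attraction_coefficient(r, p)
      fR <- repulsion_coefficient(r, p)
      list(f_s = p$chi * p$delta_scale * fA + fR,
           f_l = p$delta_scale * fA + fR)
    },
    kc_adapted = {
      fA <- attraction_coefficient(r, p)
      fR <- repulsion_coefficient(r, p)
      list(f_s = p$chi * p$delta_scale * fA + fR,
           f_l = 0.3 * p$delta_scale * fA + fR)
    },
    kc_reparam = {
      fA <- attraction_coefficient(r, p)
      fR <- repulsion_coefficient(r, p)
      list(f_s = p$chi * p$delta_scale * fA + fR,
           f_l = p$delta_scale * fA + fR)
    },
    piecewise = piecewise_coefficients(r, p),
    oscillator = oscillator_coefficients(r, p),
    stop("unknown force family: ", model$family)
  )
  keep <- (r < model$cutoff_radius)  # preserves dim for matrix input
  list(f_s = co$f_s * keep, f_l = co$f_l * keep)
}

#' Anisotropic pair force
#'
#' Force exerted on a particle with displacement `d` from its interaction
#' partner, resolved in the local orthonormal stress frame `(s_vec, l_vec)`:
#' \deqn{F(\eta d, T) = f_s(\eta|d|)\,(s \cdot \eta d)\, s +
#'   f_l(\eta|d|)\,(l \cdot \eta d)\, l,}
#' i.e. the rescaling factor \eqn{\eta} enters both the coefficient argument
#' and the projections. The force is identically zero whenever
#' \eqn{\eta |d| \ge} `cutoff_radius`, and satisfies \eqn{F(d) = -F(-d)}.
#'
#' @param d displacement 2-vector (minimum-image convention on the torus)
#' @param s_vec,l_vec orthonormal frame: unit direction of smallest stress and
#'   its perpendicular
#' @param model a [force_model()]
#' @return force 2-vector
#' @export
pair_force <- function(d, s_vec, l_vec, model) {
  stopifnot(inherits(model, "force_model"), length(d) == 2)
  if (abs(sum(s_vec^2) - 1) > 1e-8 || abs(sum(l_vec^2) - 1) > 1e-8 ||
      abs(sum(s_vec * l_vec)) > 1e-8)
    stop("(s_vec, l_vec) must be an orthonormal frame")
  ed <- model$eta * d
  r <- sqrt(sum(ed^2))
  co <- axis_coefficients(model, r)
  co$f_s * sum(s_vec * ed) * s_vec + co$f_l * sum(l_vec * ed) * l_vec
}
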