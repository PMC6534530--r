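## Time integration of the N-particle system on the unit torus.

#' Particle state on the unit torus
#'
#' @param positions n-by-2 matrix of positions; wrapped into `[0,1)^2`.
#'   An empty (0-row) matrix is allowed for plumbing such as rendering.
#' @param time nonnegative simulation time
#' @return an object of class `particle_state`
#' @export
particle_state <- function(positions, time = 0) {
  positions <- rbind2col(positions)
  stopifnot(time >= 0)
  structure(list(positions = wrap_torus(positions), time = time),
            class = "particle_state")
}

#' @export
print.particle_state <- function(x, ...) {
  cat("<particle_state> N =", nrow(x$positions), " t =", x$time, "\n")
  invisible(x)
}

# wrap coordinates into the half-open unit square
wrap_torus <- function(p) p - floor(p)

#' Simulation configuration
#'
#' @param dt time step (default 0.2)
#' @param n_steps maximum number of steps
#' @param integrator `"euler"` (default) or `"rk_dopri"` (fixed-step
#'   Dormand--Prince 5(4))
#' @param seed RNG seed recorded with the run (initial data generators take
#'   their own seed; this one is echoed into manifests)
#' @param snapshot_every store a snapshot every this many steps (0 = none)
#' @param converge_tol optional threshold on the per-step displacement
#'   statistic tau; integration stops early once `tau < converge_tol`
#' @return an object of class `sim_config`
#' @export
sim_config <- function(dt = 0.2, n_steps = 2000,
                       integrator = c("euler", "rk_dopri"), seed = 1L,
                       snapshot_every = 0, converge_tol = NULL) {
  integrator <- match.arg(integrator)
  stopifnot(dt > 0, n_steps >= 0)
  structure(list(dt = dt, n_steps = n_steps, integrator = integrator,
                 seed = as.integer(seed), snapshot_every = snapshot_every,
                 converge_tol = converge_tol),
            class = "sim_config")
}

#' Minimum-image displacement on the unit torus
#'
#' Returns `a - b` with each component shifted by an integer into
#' `[-0.5, 0.5)`: the shortest periodic representative. Consequently no two
#' points of the torus are separated by more than 0.5 per coordinate, which
#' is what justifies the 0.5 force cutoff.
#'
#' @param a,b points (length-2 vectors or n-by-2 matrices)
#' @return displacement(s), same shape as the inputs
#' @export
min_image_displacement <- function(a, b) {
  a <- rbind2col(wrap_torus(a)); b <- rbind2col(wrap_torus(b))
  d <- torus_delta(a - b)
  if (nrow(d) == 1) drop(d) else d
}

#' Per-particle velocities (brute-force reference)
#'
#' The right-hand side of the particle model:
#' \deqn{v_j = \frac1N \sum_{k \ne j} F(x_j - x_k, T(x_j)),}
#' with minimum-image displacements and the local frame evaluated at
#' \eqn{x_j}. This is the vectorized O(N^2) reference implementation; the
#' cell-list path [rhs_velocities_celllist()] must agree with it to
#' near machine precision.
#'
#' @param state a [particle_state()]
#' @param field an `orientation_field`
#' @param model a [force_model()]
#' @return n-by-2 matrix of velocities
#' @export
rhs_velocities <- function(state, field, model) {
  pos <- state$positions
  n <- nrow(pos)
  fr <- field_frames(field, pos)
  dx <- torus_delta(outer(pos[, 1], pos[, 1], "-"))  # dx[j,k] = x_j - x_k
  dy <- torus_delta(outer(pos[, 2], pos[, 2], "-"))
  edx <- model$eta * dx; edy <- model$eta * dy
  r <- sqrt(edx^2 + edy^2)
  co <- axis_coefficients(model, r)  # cutoff already applied at eta|d|
  # projections of eta*d on the row-particle's frame (recycled down columns)
  ps <- edx * fr$S[, 1] + edy * fr$S[, 2]
  pl <- edx * fr$L[, 1] + edy * fr$L[, 2]
  as <- co$f_s * ps; al <- co$f_l * pl
  diag(as) <- 0; diag(al) <- 0
  vx <- (rowSums(as) * fr$S[, 1] + rowSums(al) * fr$L[, 1]) / n
  vy <- (rowSums(as) * fr$S[, 2] + rowSums(al) * fr$L[, 2]) / n
  cbind(vx, vy, deparse.level = 0)
}

#' Per-particle velocities via cell-list neighbour search
#'
#' Identical contract to [rhs_velocities()], computed in compiled code with
#' spatial hashing: the domain is divided into `cells_per_side^2` square
#' cells whose edge must be at least the effective interaction range
#' `cutoff_radius / eta`, so only the 3x3 cell neighbourhood (with periodic
#' wrapping) needs to be searched. With fewer than 3 cells per side the
#' neighbourhood covers the torus and the search degenerates to the direct
#' sum over all pairs.
#'
#' @inheritParams rhs_velocities
#' @param cells_per_side number of cells per side; `NULL` (default) picks the
#'   largest valid value `floor(eta / cutoff_radius)`, at least 1
#' @return n-by-2 matrix of velocities
#' @export
rhs_velocities_celllist <- function(state, field, model, cells_per_side = NULL) {
  pos <- state$positions
  range_eff <- model$cutoff_radius / model$eta
  if (is.null(cells_per_side)) cells_per_side <- max(1L, floor(1 / range_eff))
  cells_per_side <- as.integer(cells_per_side)
  if (1 / cells_per_side < range_eff - 1e-12)
    stop("cell edge 1/", cells_per_side,
         " is smaller than the effective cutoff ", range_eff)
  fr <- field_frames(field, pos)
  enc <- encode_model(model)
  velocities_cpp(pos, fr$S, enc$family, enc$params,
                 model$cutoff_radius, model$eta, cells_per_side)
}

# encode a force_model for the C++ kernel
encode_model <- function(model) {
  p <- model$params
  switch(model$family,
    kc_original = ,
    kc_reparam = list(family = 1L,
                      params = c(p$alpha, p$beta, p$gamma, p$e_A, p$e_R,
                                 p$chi * p$delta_scale, p$delta_scale)),
    kc_adapted = list(family = 1L,
                      params = c(p$alpha, p$beta, p$gamma, p$e_A, p$e_R,
                                 p$chi * p$delta_scale, 0.3 * p$delta_scale)),
    piecewise = {
      b <- p$base
      list(family = 2L,
           params = c(b$alpha, b$beta, b$gamma, b$e_A, b$e_R,
                      b$chi * b$delta_scale, b$delta_scale, p$c1, p$c2))
    },
    oscillator = list(family = 3L,
                      params = c(p$c, p$c_s, p$c_l, p$e_s1, p$e_s2,
                                 p$e_l1, p$e_l2, p$a_s, p$a_l)))
}

# Dormand-Prince 5(4) tableau (5th-order solution weights, fixed step)
.dp_a <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
.dp_b <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)

#' Advance the particle system by one time step
#'
#' Explicit Euler (`x <- wrap(x + dt v)`) or a fixed-step Dormand--Prince
#' 5(4) stage evaluation on the same right-hand side (no step-size
#' adaptivity, keeping trajectories deterministic and directly comparable to
#' Euler). Positions are wrapped back into the unit square after the step.
#'
#' @inheritParams rhs_velocities
#' @param cfg a [sim_config()]
#' @param rhs velocity function `(state, field, model) -> n x 2`; defaults to
#'   the cell-list path
#' @return the advanced [particle_state()]
#' @export
step_particles <- function(state, field, model, cfg,
                           rhs = rhs_velocities_celllist) {
  dt <- cfg$dt
  pos <- state$positions
  if (cfg$integrator == "euler") {
    v <- rhs(state, field, model)
    return(particle_state(pos + dt * v, state$time + dt))
  }
  # fixed-step Dormand-Prince: 7 stages, 5th-order combination
  k <- vector("list", 7)
  k[[1]] <- rhs(state, field, model)
  for (s in 1:6) {
    inc <- Reduce(`+`, Map(`*`, k[seq_along(.dp_a[[s]])], .dp_a[[s]]))
    st <- particle_state(pos + dt * inc, state$time)
    k[[s + 1]] <- rhs(st, field, model)
  }
  inc <- Reduce(`+`, Map(`*`, k, .dp_b))
  particle_state(pos + dt * inc, state$time + dt)
}

#' Convergence statistic tau between consecutive snapshots
#'
#' \eqn{\tau = \sum_j \lVert x_j(t + \Delta t) - x_j(t) \rVert_{L^1}},
#' with displacements taken in the minimum-image sense so that particles
#' crossing the periodic seam do not spuriously inflate the statistic
#' (a move from 0.999 to 0.001 counts as 0.002).
#'
#' @param prev,next_ two [particle_state()]s with the same particle count
#' @return nonnegative scalar
#' @export
tau_metric <- function(prev, next_) {
  if (nrow(prev$positions) != nrow(next_$positions))
    stop("particle counts differ")
  d <- torus_delta(next_$positions - prev$positions)
  sum(abs(d))
}

#' Integrate the particle system to (near) stationarity
#'
#' Runs up to `cfg$n_steps` steps, optionally stopping early when the
#' per-step displacement `tau` falls below `cfg$converge_tol`. Snapshots are
#' recorded every `cfg$snapshot_every` steps (plus the final state).
#' Deterministic given the initial state and configuration.
#'
#' @inheritParams step_particles
#' @param init initial [particle_state()]
#' @param verbose log tau to stderr every 100 steps
#' @return list with `final` ([particle_state()]), `snapshots` (list),
#'   `tau_trace` (numeric, one entry per step), `steps_run`
#' @export
integrate_particles <- function(init, field, model, cfg,
                                rhs = rhs_velocities_celllist,
                                verbose = FALSE) {
  state <- init
  snaps <- list()
  taus <- numeric(0)
  steps <- 0L
  if (cfg$n_steps >= 1) {
    for (i in seq_len(cfg$n_steps)) {
      nxt <- step_particles(state, field, model, cfg, rhs)
      tau <- tau_metric(state, nxt)
      taus[i] <- tau
      state <- nxt
      steps <- i
      if (cfg$snapshot_every > 0 && i %% cfg$snapshot_every == 0)
        snaps[[length(snaps) + 1]] <- state
      if (verbose && i %% 100 == 0)
        message(sprintf("step %d  t = %.1f  tau = %.3e", i, state$time, tau))
      if (!is.null(cfg$converge_tol) && tau < cfg$converge_tol) break
    }
  }
  list(final = state, snapshots = snaps, tau_trace = taus, steps_run = steps)
}

#' Mean per-particle displacement implied by a total tau
#'
#' The stationarity statistic tau sums L1 displacements over all particles;
#' dividing by the particle count gives the average per-particle motion per
#' time step, the number quoted when calling a pattern "stationary".
#'
#' @param tau_total total tau over one step
#' @param n particle count
#' @return scalar displacement per particle
#' @export
per_particle_displacement <- function(tau_total, n) tau_total / n

#' Uniform random initial data
#'
#' N independent uniform points on the unit torus, reproducible from `seed`.
#'
#' @param n particle count
#' @param seed RNG seed
#' @return a [particle_state()] at time 0
#' @export
uniform_random_init <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  particle_state(matrix(stats::runif(2 * n), ncol = 2))
}

#' Equiangular circle initial data
#'
#' Particle `j` sits at `center + radius (cos(2 pi j / n), sin(2 pi j / n))`,
#' wrapped onto the torus. Radially symmetric initial data for the
#' attraction-strength sweep.
#'
#' @param n particle count
#' @param center circle centre (default `(0.5, 0.5)`)
#' @param radius circle radius (default 0.005)
#' @return a [particle_state()] at time 0
#' @export
circle_init <- function(n, center = c(0.5, 0.5), radius = 0.005) {
  stopifnot(n >= 1)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  particle_state(cbind(center[1] + radius * cos(ang),
                       center[2] + radius * sin(ang)))
}
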