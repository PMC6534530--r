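## Configuration, snapshots, angle-grid files, manifests.

#' Load and validate a full run configuration
#'
#' Reads a JSON (canonical) or YAML configuration with sections `force`,
#' `field` and `sim`, applies defaults (`dt = 0.2`, `cutoff_radius = 0.5`,
#' `eta = 1`), resolves force presets, and rejects unknown keys. Supplying
#' both a preset and explicit parameters in the `force` section is an error.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file
#' @return list with components `force` (a [force_model()]), `field` (an
#'   `orientation_field` or `NULL`), and `sim` (a [sim_config()])
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known_top <- c("force", "field", "sim")
  bad <- setdiff(names(raw), known_top)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  list(force = parse_force_config(raw$force),
       field = if (is.null(raw$field)) NULL else parse_field_config(raw$field),
       sim = parse_sim_config(raw$sim))
}

parse_force_config <- function(fc) {
  if (is.null(fc)) fc <- list()
  known <- c("family", "preset", "params", "cutoff_radius", "eta")
  bad <- setdiff(names(fc), known)
  if (length(bad)) stop("unknown 'force' key(s): ", paste(bad, collapse = ", "))
  cutoff <- fc$cutoff_radius %||% 0.5
  eta <- fc$eta %||% 1.0
  if (!is.null(fc$preset)) {
    if (!is.null(fc$params))
      stop("supply either 'preset' or explicit 'params', not both")
    return(force_preset(fc$preset, cutoff_radius = cutoff, eta = eta))
  }
  if (is.null(fc$family)) return(force_preset("kc2012", cutoff, eta))
  p <- fc$params
  params <- switch(fc$family,
    oscillator = do.call(oscillator_params, p),
    piecewise = {
      extra <- p[c("c1", "c2")]
      base <- do.call(kc_params, p[setdiff(names(p), c("c1", "c2"))])
      piecewise_params(base, extra$c1 %||% 0.06, extra$c2 %||% 0.07)
    },
    do.call(kc_params, p))
  force_model(fc$family, params, cutoff_radius = cutoff, eta = eta)
}

parse_field_config <- function(fd) {
  known <- c("kind", "theta0", "theta1", "chi", "points", "angles_csv",
             "mask_csv", "regions")
  bad <- setdiff(names(fd), known)
  if (length(bad)) stop("unknown 'field' key(s): ", paste(bad, collapse = ", "))
  chi <- fd$chi %||% 0.2
  switch(fd$kind %||% "homogeneous",
    homogeneous = homogeneous_field(fd$theta0 %||% (pi / 2), chi),
    singular = {
      pts <- lapply(seq_len(nrow(fd$points)), function(i)
        singular_point(c(fd$points$x[i], fd$points$y[i]), fd$points$kind[i]))
      singular_field(pts, chi)
    },
    piecewise = piecewise_field(as.data.frame(fd$regions), chi),
    sampled = {
      grid <- read_angle_grid(fd$angles_csv, fd$mask_csv)
      sampled_field(grid, chi)
    },
    stop("unknown field kind: ", fd$kind))
}

parse_sim_config <- function(sc) {
  if (is.null(sc)) sc <- list()
  known <- c("dt", "n_steps", "integrator", "seed", "snapshot_every",
             "converge_tol", "N", "init")
  bad <- setdiff(names(sc), known)
  if (length(bad)) stop("unknown 'sim' key(s): ", paste(bad, collapse = ", "))
  cfg <- sim_config(dt = sc$dt %||% 0.2, n_steps = sc$n_steps %||% 2000,
                    integrator = sc$integrator %||% "euler",
                    seed = sc$seed %||% 1L,
                    snapshot_every = sc$snapshot_every %||% 0,
                    converge_tol = sc$converge_tol)
  cfg$N <- sc$N %||% 600
  cfg$init <- sc$init %||% "uniform"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read particle snapshots as CSV
#'
#' Columns `time, particle_id, x, y`; coordinates are printed with 17
#' significant digits so a read-back reproduces the positions exactly.
#' Coordinates outside `[0, 1)` on read are wrapped with a warning.
#'
#' @param state a [particle_state()]
#' @param path output file
#' @return `write_snapshot` returns `path` invisibly; `read_snapshot` a
#'   [particle_state()]
#' @export
write_snapshot <- function(state, path) {
  df <- data.frame(time = rep(state$time, nrow(state$positions)),
                   particle_id = seq_len(nrow(state$positions)),
                   x = state$positions[, 1], y = state$positions[, 2])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,particle_id,x,y", con)
  writeLines(sprintf("%.17g,%d,%.17g,%.17g", df$time, df$particle_id,
                     df$x, df$y), con)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, colClasses = c("numeric", "integer",
                                         "numeric", "numeric")),
    error = function(e) stop("malformed snapshot file '", path, "': ",
                             conditionMessage(e)))
  need <- c("time", "particle_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("snapshot must have columns: ", paste(need, collapse = ", "))
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop("malformed snapshot row(s) at line(s): ",
         paste(bad + 1, collapse = ", "))
  pos <- cbind(df$x, df$y)
  if (any(pos < 0 | pos >= 1)) {
    warning("coordinates outside [0,1) wrapped onto the torus")
    pos <- wrap_torus(pos)
  }
  particle_state(pos[order(df$particle_id), , drop = FALSE], time = df$time[1])
}

#' Write / read an angle grid as CSV
#'
#' The angle matrix is stored as a headerless CSV of radians; an optional
#' companion mask CSV holds 0/1 validity flags. Masked cells are written
#' as `NA`.
#'
#' @param grid an [angle_grid()]
#' @param path angle CSV path
#' @param mask_path optional mask CSV path
#' @return `write_angle_grid` returns `path` invisibly; `read_angle_grid` an
#'   [angle_grid()]
#' @export
write_angle_grid <- function(grid, path, mask_path = NULL) {
  a <- grid$angles
  a[!grid$mask] <- NA
  utils::write.table(format(a, digits = 17, trim = TRUE), path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(mask_path))
    utils::write.table(grid$mask * 1L, mask_path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_angle_grid
#' @export
read_angle_grid <- function(path, mask_path = NULL) {
  a <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(a) <- NULL
  mask <- if (!is.null(mask_path)) {
    m <- as.matrix(utils::read.table(mask_path, sep = ",", header = FALSE))
    dimnames(m) <- NULL
    m > 0
  } else {
    !is.na(a)
  }
  a[is.na(a)] <- 0
  angle_grid(a, mask & !is.na(a))
}

#' Write a run manifest
#'
#' Records the full configuration (force family and parameters, field
#' specification, particle count, time step, steps run, cutoff, eta, seed,
#' integrator), the package version, and the tau trace, as JSON -- enough to
#' reproduce the run bit-for-bit.
#'
#' @param path output JSON path
#' @param model a [force_model()]
#' @param cfg a [sim_config()]
#' @param n particle count
#' @param field_spec description of the field (list or string)
#' @param tau_trace numeric vector of per-step tau values
#' @param extra optional named list of additional entries
#' @return `path`, invisibly
#' @export
write_manifest <- function(path, model, cfg, n, field_spec = NULL,
                           tau_trace = NULL, extra = NULL) {
  man <- list(
    package = "ridgesim",
    version = as.character(utils::packageVersion("ridgesim")),
    force = list(family = model$family, params = unclass_deep(model$params),
                 cutoff_radius = model$cutoff_radius, eta = model$eta),
    field = field_spec,
    sim = list(N = n, dt = cfg$dt, n_steps = cfg$n_steps,
               integrator = cfg$integrator, seed = cfg$seed,
               snapshot_every = cfg$snapshot_every,
               converge_tol = cfg$converge_tol),
    tau_trace = tau_trace)
  if (!is.null(extra)) man <- c(man, extra)
  # digits = I(17): full double precision so a re-run from the manifest is
  # bit-identical
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
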