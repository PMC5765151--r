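#' Default run configuration
#'
#' All knobs of a simulation/analysis run with their documented defaults:
#'
#' * `k_m = 0.5` — mineralisation rate constant (per unit time).
#' * `k_b = 0` — outer-to-inner transition rate (per unit time);
#'   0 = non-replenishing inner zone.
#' * `k_b_I = 1` — inner-zone biotic decay rate (per unit time).
#' * `k_b_II = 0.2` — outer-layer biotic growth rate (per unit time).
#' * `c = 1` — biofilm/microbe volume scale factor (dimensionless).
#' * `c_I = 0`, `c_II = 1` — threshold and background nutrient
#'   concentrations.
#' * `D = 1` — nutrient diffusivity (length^2/time).
#' * `k = 1` — nutrient consumption rate (concentration/time).
#' * `rtol = 1e-10`, `atol = 1e-12` — ODE solver tolerances.
#' * `seed = 1` — RNG seed for anything stochastic.
#' * `verbose = FALSE` — chatty logging.
#' * `out = NA` — default output path (subcommand-specific).
#'
#' The kinetic defaults sit in the size-limited regime with a finite upper
#' bound (`c*k_b_I - k_m = 0.5 > c*k_b_II = 0.2`).
#'
#' @return A named list of class `"run_config"`.
#' @export
default_config <- function() {
  structure(list(
    k_m = 0.5, k_b = 0, k_b_I = 1, k_b_II = 0.2, c = 1,
    c_I = 0, c_II = 1, D = 1, k = 1,
    rtol = 1e-10, atol = 1e-12,
    seed = 1L, verbose = FALSE, out = NA_character_
  ), class = "run_config")
}

#' Load a run configuration from file with overrides
#'
#' Reads a flat key/value configuration (YAML; flat JSON objects parse
#' identically) and applies overrides on top — file values replace
#' defaults, override values replace file values. Unknown keys are rejected
#' with the offending key named alongside the nearest valid key, so typos
#' like `km` point at `k_m`.
#'
#' @param path Path to a config file, or `NULL` for defaults only. An
#'   empty file yields all defaults.
#' @param overrides Named list applied after the file (e.g. parsed CLI
#'   flags).
#' @return A validated `"run_config"` list.
#' @examples
#' cfg <- load_config(overrides = list(k_m = 0.7))
#' cfg$k_m
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  valid <- names(cfg)

  apply_kv <- function(cfg, kv, origin) {
    if (length(kv) == 0L) return(cfg)
    if (is.null(names(kv)) || any(names(kv) == ""))
      stop("config entries from ", origin, " must be named", call. = FALSE)
    for (key in names(kv)) {
      if (!key %in% valid) {
        near <- valid[which.min(utils::adist(key, valid))]
        stop("unknown config key '", key, "' in ", origin,
             "; did you mean '", near, "'?", call. = FALSE)
      }
      cfg[[key]] <- kv[[key]]
    }
    cfg
  }

  if (!is.null(path)) {
    if (!file.exists(path))
      stop("config file not found: ", path, call. = FALSE)
    vals <- tryCatch(yaml::read_yaml(path),
                     error = function(e) stop("config parse failure in ",
                                              path, ": ", conditionMessage(e),
                                              call. = FALSE))
    if (!is.null(vals)) cfg <- apply_kv(cfg, vals, path)
  }
  cfg <- apply_kv(cfg, overrides, "overrides")

  num_keys <- c("k_m", "k_b", "k_b_I", "k_b_II", "c", "c_I", "c_II",
                "D", "k", "rtol", "atol")
  for (key in num_keys) {
    v <- suppressWarnings(as.numeric(cfg[[key]]))
    if (length(v) != 1L || is.na(v))
      stop("config key '", key, "' must be numeric (got '",
           cfg[[key]], "')", call. = FALSE)
    cfg[[key]] <- v
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$verbose <- isTRUE(as.logical(cfg$verbose))
  # constructor validation surfaces invariant violations with the key named
  model_params_from(cfg)
  nutrient_params_from(cfg)
  class(cfg) <- "run_config"
  if (cfg$verbose)
    message("resolved config: ",
            paste(names(cfg), unlist(lapply(cfg, format)),
                  sep = "=", collapse = " "))
  cfg
}

#' Extract parameter objects from a run configuration
#'
#' @param cfg A `"run_config"` list (see [default_config()]).
#' @return [model_params_from()] returns the [model_params()] slice;
#'   [nutrient_params_from()] the [nutrient_params()] slice.
#' @export
model_params_from <- function(cfg) {
  model_params(k_m = cfg$k_m, k_b = cfg$k_b, k_b_I = cfg$k_b_I,
               k_b_II = cfg$k_b_II, c = cfg$c)
}

#' @rdname model_params_from
#' @export
nutrient_params_from <- function(cfg) {
  nutrient_params(c_I = cfg$c_I, c_II = cfg$c_II, D = cfg$D, k = cfg$k)
}

fmt_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE,
                               trim = TRUE), character(1))
}

#' Write and read trajectory CSV files
#'
#' Serialises an integrated trajectory with header
#' `t,V_m,V_b_I,V_b_II,V_total`, one row per time point, 15 significant
#' digits so that round-trips preserve oracle-grade precision.
#'
#' @param traj An `"ooid_trajectory"` (or any data frame with those
#'   columns).
#' @param path Output CSV path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a data frame.
#' @export
write_trajectory_csv <- function(traj, path) {
  cols <- c("t", "V_m", "V_b_I", "V_b_II", "V_total")
  stopifnot(all(cols %in% names(traj)))
  out <- as.data.frame(lapply(traj[cols], fmt_num))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t", "V_m", "V_b_I", "V_b_II", "V_total") %in% names(df)))
  df
}

#' Write and read lamination-ring CSV files
#'
#' Ring CSVs have header `j,radius`, one ring per row. On reading, a
#' single-column file (header `radius`, or headerless numbers) is also
#' accepted, with `j` taken as positional.
#'
#' @param radii Numeric vector of ring radii (or a
#'   [lamination_pattern()] / [ring_observations()] object).
#' @param path CSV path.
#' @param j Optional integer ring indices (default `1:length(radii)`).
#' @return `write_rings_csv()` returns `path` invisibly;
#'   `read_rings_csv()` returns a [ring_observations()] object.
#' @export
write_rings_csv <- function(radii, path, j = NULL) {
  if (inherits(radii, "lamination_pattern") ||
      inherits(radii, "ring_observations"))
    radii <- radii$radii
  if (is.null(j)) j <- seq_along(radii)
  df <- data.frame(j = j, radius = fmt_num(radii))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rings_csv
#' @export
read_rings_csv <- function(path) {
  if (!file.exists(path))
    stop("ring CSV not found: ", path, call. = FALSE)
  head1 <- readLines(path, n = 1L)
  has_header <- grepl("radius", head1, fixed = TRUE)
  df <- utils::read.csv(path, header = has_header)
  radii <- if (has_header) df$radius else df[[ncol(df)]]
  ring_observations(as.numeric(radii))
}

#' Write a ring-fit report as JSON
#'
#' Keys: `scale`, `dt`, `alpha`, `j0`, `rmse`, `per_ring_residuals`,
#' `converged`. Numbers are written at full precision.
#'
#' @param fit A `"ring_fit"` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "ring_fit"))
  jsonlite::write_json(
    list(scale = fit$scale, dt = fit$dt, alpha = fit$alpha, j0 = fit$j0,
         rmse = fit$rmse, per_ring_residuals = fit$per_ring_residuals,
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a limiting-size report as JSON
#'
#' Keys: `R`, `lower`, `upper`, `unbounded_upper`, `w`, `A`, `B`, `C`.
#' An unbounded upper bound is serialised as `null` with
#' `unbounded_upper = true`, never as an infinity literal.
#'
#' @param lim A `"limiting_size"` object from [limiting_radius()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_limit_json <- function(lim, path) {
  stopifnot(inherits(lim, "limiting_size"))
  jsonlite::write_json(
    list(R = lim$R, lower = lim$lower,
         upper = if (lim$unbounded_upper) NULL else lim$upper,
         unbounded_upper = lim$unbounded_upper,
         w = lim$w, A = lim$A, B = lim$B, C = lim$C),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
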