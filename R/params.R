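#' Kinetic and volumetric parameters of the biofilm growth model
#'
#' Bundles the five constants that drive the three-compartment volume model:
#' the mineralisation rate in the inner zone, the outer-to-inner transition
#' rate, the inner-zone biotic decay rate, the outer-layer biotic growth rate
#' and the dimensionless scale factor relating biofilm volume to microbial
#' volume.
#'
#' @param k_m Mineralisation rate constant (per unit time): rate at which
#'   inner-zone biotic volume is converted to mineral.
#' @param k_b Transition rate (per unit time) at which outer-layer microbes
#'   move into the inner zone. Zero means a non-replenishing inner zone.
#' @param k_b_I Inner-zone biotic decay rate (per unit time).
#' @param k_b_II Outer-layer biotic growth rate (per unit time).
#' @param c Dimensionless scale factor relating biofilm volume to the volume
#'   of microbes it contains; must be positive.
#'
#' @return An object of class `"model_params"`: a named list of the five
#'   constants.
#'
#' @details All rate constants must be non-negative. Two derived regime
#'   predicates matter for the limiting-size analysis:
#'   [is_size_limited()] tests `c*k_b_I - k_m > 0` (the stationarity cubic
#'   has a positive leading coefficient, hence a unique positive root), and
#'   [has_finite_upper_bound()] additionally requires
#'   `c*k_b_I - k_m - c*k_b_II > 0` so that the upper bound on the limiting
#'   radius is finite.
#'
#' @examples
#' p <- model_params(k_m = 0.5, k_b = 0, k_b_I = 1, k_b_II = 0.2, c = 1)
#' is_size_limited(p)
#' @export
model_params <- function(k_m, k_b = 0, k_b_I = 1, k_b_II = 0, c = 1) {
  for (nm in c("k_m", "k_b", "k_b_I", "k_b_II", "c")) {
    v <- get(nm, inherits = FALSE)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be >= 0 (got ", v, ")", call. = FALSE)
  }
  if (c <= 0)
    stop("scale factor 'c' must be > 0 (got ", c, ")", call. = FALSE)
  structure(
    list(k_m = k_m, k_b = k_b, k_b_I = k_b_I, k_b_II = k_b_II, c = c),
    class = "model_params"
  )
}

#' @rdname model_params
#' @param params A `"model_params"` object.
#' @export
is_size_limited <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$c * params$k_b_I - params$k_m > 0
}

#' @rdname model_params
#' @export
has_finite_upper_bound <- function(params) {
  stopifnot(inherits(params, "model_params"))
  is_size_limited(params) &&
    params$c * params$k_b_I - params$k_m - params$c * params$k_b_II > 0
}

#' @export
print.model_params <- function(x, ...) {
  cat("Biofilm growth model parameters\n")
  cat(sprintf("  k_m    = %g  (mineralisation rate, inner zone)\n", x$k_m))
  cat(sprintf("  k_b    = %g  (outer -> inner transition rate)\n", x$k_b))
  cat(sprintf("  k_b_I  = %g  (inner-zone biotic decay rate)\n", x$k_b_I))
  cat(sprintf("  k_b_II = %g  (outer-layer biotic growth rate)\n", x$k_b_II))
  cat(sprintf("  c      = %g  (biofilm/microbe volume scale factor)\n", x$c))
  cat(sprintf("  size-limited regime: %s; finite upper bound: %s\n",
              is_size_limited(x), has_finite_upper_bound(x)))
  invisible(x)
}

#' Nutrient transport and consumption parameters
#'
#' The quantities controlling the width of the nutrient-supplied active rim
#' of the biofilm: the threshold concentration microbes need to survive, the
#' background concentration in the surrounding medium, the nutrient
#' diffusivity and the volumetric consumption rate.
#'
#' @param c_I Threshold nutrient concentration below which microbes cannot
#'   grow (concentration units).
#' @param c_II Background nutrient concentration at the outer surface (same
#'   units); must satisfy `c_II >= c_I`.
#' @param D Nutrient diffusivity (length^2 / time); must be positive.
#' @param k Nutrient consumption rate per unit volume (concentration / time);
#'   must be positive.
#'
#' @return An object of class `"nutrient_params"`.
#' @seealso [outer_width()] for the thin-shell rim width
#'   `sqrt(2 * (c_II - c_I) * D / k)`, [shell_width_exact()] for the exact
#'   spherical-shell solution.
#' @examples
#' nutrient_params(c_I = 0.2, c_II = 1, D = 1, k = 1)
#' @export
nutrient_params <- function(c_I = 0, c_II = 1, D = 1, k = 1) {
  for (nm in c("c_I", "c_II", "D", "k")) {
    v <- get(nm, inherits = FALSE)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (c_I < 0) stop("'c_I' must be >= 0", call. = FALSE)
  if (c_II < c_I)
    stop("background concentration 'c_II' must be >= threshold 'c_I'",
         call. = FALSE)
  if (D <= 0) stop("'D' must be > 0", call. = FALSE)
  if (k <= 0) stop("'k' must be > 0", call. = FALSE)
  structure(list(c_I = c_I, c_II = c_II, D = D, k = k),
            class = "nutrient_params")
}

#' @export
print.nutrient_params <- function(x, ...) {
  cat("Nutrient parameters\n")
  cat(sprintf("  c_I  = %g (threshold), c_II = %g (background)\n",
              x$c_I, x$c_II))
  cat(sprintf("  D    = %g (diffusivity), k = %g (consumption rate)\n",
              x$D, x$k))
  cat(sprintf("  thin-shell rim width w = %g\n", outer_width(x)))
  invisible(x)
}
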