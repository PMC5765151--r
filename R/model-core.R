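#' Compartment state of the mineralising biofilm
#'
#' A snapshot of the three volume compartments at one time: mineralised
#' volume `V_m`, inner-zone biotic volume `V_b_I` and outer-layer biotic
#' volume `V_b_II`. All volumes must be non-negative.
#'
#' @param t Time of the snapshot.
#' @param V_m Mineralised volume (>= 0).
#' @param V_b_I Inner-zone biotic volume (>= 0).
#' @param V_b_II Outer-layer biotic volume (>= 0).
#' @return An object of class `"biofilm_state"`.
#' @examples
#' biofilm_state(t = 0, V_m = 0, V_b_I = 4 * pi / 3, V_b_II = 0)
#' @export
biofilm_state <- function(t = 0, V_m = 0, V_b_I = 0, V_b_II = 0) {
  for (nm in c("t", "V_m", "V_b_I", "V_b_II")) {
    v <- get(nm, inherits = FALSE)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (V_m < 0 || V_b_I < 0 || V_b_II < 0)
    stop("compartment volumes must be >= 0", call. = FALSE)
  structure(list(t = t, V_m = V_m, V_b_I = V_b_I, V_b_II = V_b_II),
            class = "biofilm_state")
}

#' Integrate the three-compartment growth equations
#'
#' Solves the linear compartment system
#' \deqn{dV_m/dt = k_m V_b^I}
#' \deqn{dV_b^I/dt = -k_b^I V_b^I + k_b V_b^{II}}
#' \deqn{dV_b^{II}/dt = (k_b^{II} - k_b) V_b^{II}}
#' from the initial state to `t_end` on a regular time grid. Mineral is
#' deposited in proportion to the inner-zone biotic volume; the inner zone
#' decays while being fed by the outer layer; the outer layer grows
#' exponentially net of the transition loss.
#'
#' The system is linear and non-stiff; it is integrated with `deSolve`'s
#' `lsoda` at tight tolerances (default relative 1e-10, absolute 1e-12) so
#' that trajectories can be compared against closed-form solutions. Volumes
#' are never clipped: the linear system preserves non-negativity
#' analytically, and any volume falling below `-10 * atol` aborts the run as
#' evidence of solver misuse.
#'
#' @param params A [model_params()] object.
#' @param init A [biofilm_state()] giving the initial condition.
#' @param t_end Final time; must exceed `init$t`.
#' @param n_steps Number of grid intervals (>= 2); the output has
#'   `n_steps + 1` rows.
#' @param rtol,atol Solver relative and absolute tolerances.
#' @param tau Onset time recorded as trajectory metadata (defaults to
#'   `init$t`); purely informational.
#'
#' @return An object of class `"ooid_trajectory"`: a data frame with columns
#'   `t`, `V_m`, `V_b_I`, `V_b_II`, `V_total` (the last from
#'   [total_volume()]), carrying the parameters, tolerances and onset time
#'   as attributes.
#' @examples
#' p <- model_params(k_m = 1, k_b = 0, k_b_I = 1, k_b_II = 0, c = 1)
#' s0 <- biofilm_state(V_b_I = 4 * pi / 3)
#' tr <- integrate_model(p, s0, t_end = 5)
#' tail(tr, 2)
#' @export
integrate_model <- function(params, init, t_end, n_steps = 200L,
                            rtol = 1e-10, atol = 1e-12, tau = init$t) {
  stopifnot(inherits(params, "model_params"), inherits(init, "biofilm_state"))
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) ||
      t_end <= init$t)
    stop("'t_end' must be a finite number greater than init$t", call. = FALSE)
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 2L)
    stop("'n_steps' must be an integer >= 2", call. = FALSE)

  times <- seq(init$t, t_end, length.out = n_steps + 1L)
  y0 <- c(V_m = init$V_m, V_b_I = init$V_b_I, V_b_II = init$V_b_II)
  rhs <- function(t, y, p) {
    list(c(p$k_m * y[2L],
           -p$k_b_I * y[2L] + p$k_b * y[3L],
           (p$k_b_II - p$k_b) * y[3L]))
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = params,
                      method = "lsoda", rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)
  names(sol)[1L] <- "t"

  bad <- !is.finite(as.matrix(sol[-1L]))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value of %s at t = %g during integration",
                 names(sol[-1L])[ij[2L]], sol$t[ij[1L]]), call. = FALSE)
  }
  low <- as.matrix(sol[-1L]) < -10 * atol
  if (any(low)) {
    ij <- which(low, arr.ind = TRUE)[1L, ]
    stop(sprintf("volume %s fell below -10*atol at t = %g; tighten tolerances",
                 names(sol[-1L])[ij[2L]], sol$t[ij[1L]]), call. = FALSE)
  }

  sol$V_total <- sol$V_m + params$c * sol$V_b_I + params$c * sol$V_b_II
  structure(sol,
            class = c("ooid_trajectory", "data.frame"),
            params = params, rtol = rtol, atol = atol, tau = tau)
}

#' Total ooid volume of a compartment state
#'
#' The volume of the entire ooid is the mineral volume plus the biofilm
#' volumes of both zones, each biotic volume inflated by the scale factor
#' `c`: `V = V_m + c*V_b_I + c*V_b_II`.
#'
#' @param state A [biofilm_state()], or a data frame / list with columns
#'   `V_m`, `V_b_I`, `V_b_II` (vectorised).
#' @param c Positive scale factor relating biofilm volume to microbial
#'   volume.
#' @return Total volume (same length as the state columns).
#' @examples
#' total_volume(biofilm_state(V_m = 1, V_b_I = 2, V_b_II = 3), c = 2)  # 11
#' @export
total_volume <- function(state, c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("'c' must be a single positive number", call. = FALSE)
  state$V_m + c * state$V_b_I + c * state$V_b_II
}

#' Instantaneous rate of change of total ooid volume
#'
#' Differentiating the total volume along the compartment equations gives
#' `dV/dt = -(c*k_b_I - k_m) * V_b_I + c*k_b_II * V_b_II`: the inner zone
#' shrinks the ooid when biotic decay outpaces mineral replacement, while
#' the outer layer always adds volume. A stationary total volume (`dV/dt =
#' 0`) is the limiting-size condition.
#'
#' @param state A [biofilm_state()] or data frame with columns `V_b_I`,
#'   `V_b_II` (vectorised).
#' @param params A [model_params()] object.
#' @return Signed volume rate (same length as the state columns).
#' @examples
#' p <- model_params(k_m = 0.5, k_b_I = 1, k_b_II = 0.2, c = 1)
#' volume_rate(biofilm_state(V_b_I = 1, V_b_II = 2.5), p)  # 0: balance point
#' @export
volume_rate <- function(state, params) {
  stopifnot(inherits(params, "model_params"))
  -(params$c * params$k_b_I - params$k_m) * state$V_b_I +
    params$c * params$k_b_II * state$V_b_II
}

#' Dimensionless radius of the mineralisation front
#'
#' In scaled units (inner-zone decay rate and the asymptotic mineral volume
#' both set to one, onset of mineralisation at dimensionless time 1) the
#' mineralisation front sits at
#' \deqn{R_m(t) = (1 + \alpha (t - 1) - e^{-(t-1)})^{1/3}, \quad t \ge 1.}
#' With no replenishment (`alpha = 0`) the front rises from 0 at onset
#' toward the limiting radius 1; with `alpha > 0` the cubed radius gains a
#' linear term and the front grows without bound. Near onset the front
#' scales as `(t - 1)^(1/3)` for every `alpha`, the classic coarsening
#' exponent.
#'
#' @param t Dimensionless time(s), `>= 1` (onset at exactly 1 returns 0).
#' @param alpha Replenishment parameter `>= 0`; see
#'   [replenishment_alpha()].
#' @return Dimensionless front radius, same length as `t`; strictly
#'   increasing in `t` for `t > 1`.
#' @examples
#' mineral_front_radius(2)                   # (1 - exp(-1))^(1/3)
#' mineral_front_radius(c(1, 2, 50), alpha = 0)
#' @export
mineral_front_radius <- function(t, alpha = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0)
    stop("'alpha' must be a single number >= 0", call. = FALSE)
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  if (any(t < 1))
    stop("mineralisation has not begun before dimensionless time 1 ",
         "(got t = ", min(t), ")", call. = FALSE)
  s <- t - 1
  # 1 + alpha*s - exp(-s) written via expm1 to avoid cancellation near onset;
  # at s = 0 this is exactly 0, and for alpha = 0 it reduces bit-for-bit to
  # the no-replenishment law -expm1(-s)
  cubed <- alpha * s - expm1(-s)
  cubed[cubed < 0] <- 0
  cubed^(1 / 3)
}

#' Dimensional radius of the mineralisation front (no replenishment)
#'
#' For a non-replenishing inner zone (`k_b = 0`) that starts mineralising at
#' time `tau` from a biofilm of pre-onset limiting radius `R`, the front is
#' \deqn{R_m(t) = \left(\frac{k_m R^3}{k_b^I c}
#'   (1 - e^{-k_b^I (t - \tau)})\right)^{1/3}.}
#' Setting `k_m R^3 / (k_b_I c) = 1` and `k_b_I = 1` recovers the
#' dimensionless law of [mineral_front_radius()] with `alpha = 0`.
#'
#' @param t Time(s), `>= tau`.
#' @param tau Onset time of mineralisation.
#' @param params A [model_params()] object with `k_b_I > 0`.
#' @param R Pre-onset limiting radius of the biofilm (> 0).
#' @return Front radius in the same length units as `R`.
#' @examples
#' p <- model_params(k_m = 1, k_b_I = 1, c = 1)
#' mineral_front_radius_dimensional(2, tau = 1, params = p, R = 1)
#' @export
mineral_front_radius_dimensional <- function(t, tau, params, R) {
  stopifnot(inherits(params, "model_params"))
  if (params$k_b_I <= 0)
    stop("'k_b_I' must be > 0 for the front solution", call. = FALSE)
  if (!is.numeric(R) || length(R) != 1L || R <= 0)
    stop("'R' must be a single positive radius", call. = FALSE)
  if (any(t < tau))
    stop("mineralisation has not begun before t = tau", call. = FALSE)
  amp <- params$k_m * R^3 / (params$k_b_I * params$c)
  (amp * (1 - exp(-params$k_b_I * (t - tau))))^(1 / 3)
}

#' Replenishment parameter of the generalised front law
#'
#' When the outer layer holds a constant biotic volume `V0` and feeds the
#' inner zone at rate `k_b`, the cubed dimensionless front radius gains a
#' linear term `alpha * (t - 1)`. Solving the inner-zone balance
#' `dV_b_I/dt = -k_b_I V_b_I + k_b V0` in closed form gives
#' \deqn{\alpha = \frac{k_b V_0}{k_b^I V_b^I(\tau) - k_b V_0}.}
#' (A variant with the numerator squared in `k_b` circulates; it does not
#' reproduce the integrated compartment equations, against which this form
#' is validated to solver precision, and is therefore taken to be a
#' misprint.)
#'
#' @param params A [model_params()] object supplying `k_b` and `k_b_I`.
#' @param V_bI_tau Inner-zone biotic volume at the onset of mineralisation
#'   (>= 0).
#' @param V0 Constant outer-layer biotic volume (>= 0).
#' @return The dimensionless replenishment parameter `alpha >= 0`.
#' @examples
#' p <- model_params(k_m = 1, k_b = 0.2, k_b_I = 1, c = 1)
#' replenishment_alpha(p, V_bI_tau = 1, V0 = 1)  # 0.25
#' replenishment_alpha(p, V_bI_tau = 1, V0 = 0)  # 0: no replenishment
#' @export
replenishment_alpha <- function(params, V_bI_tau, V0) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(V_bI_tau) || V_bI_tau < 0 || !is.numeric(V0) || V0 < 0)
    stop("'V_bI_tau' and 'V0' must be >= 0", call. = FALSE)
  den <- params$k_b_I * V_bI_tau - params$k_b * V0
  if (den <= 0)
    stop("no valid replenishment parameter: k_b_I*V_bI_tau - k_b*V0 must be ",
         "positive (got ", den, ")", call. = FALSE)
  params$k_b * V0 / den
}

#' Mineral volume via the volume-replacement rate equation
#'
#' An alternative route to the front law: if the ooid holds a fixed total
#' volume `V_total` and the inner-zone biotic volume is whatever mineral has
#' not yet replaced, the mineral obeys `dV_m/dt = k_m * c * (V_total - V_m)`.
#' Integrating this linear equation reproduces exactly the same
#' dimensionless front as the compartment route with no replenishment.
#'
#' @param V_total Fixed total volume (> 0).
#' @param params A [model_params()] object supplying `k_m` and `c`.
#' @param t_grid Increasing vector of output times; integration starts at
#'   `t_grid[1]`.
#' @param V_m0 Initial mineral volume (default 0; `V_m0 = V_total` is the
#'   fully-mineralised fixed point).
#' @param rtol,atol Solver tolerances.
#' @return A data frame with columns `t` and `V_m`.
#' @examples
#' p <- model_params(k_m = 1, c = 1)
#' out <- mineralisation_ode_alternative(1, p, seq(0, 5, 0.5))
#' all.equal(out$V_m, 1 - exp(-out$t), tolerance = 1e-8)
#' @export
mineralisation_ode_alternative <- function(V_total, params, t_grid,
                                           V_m0 = 0,
                                           rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(V_total) || length(V_total) != 1L || V_total <= 0)
    stop("'V_total' must be a single positive volume", call. = FALSE)
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("'t_grid' must be an increasing vector of length >= 2",
         call. = FALSE)
  rhs <- function(t, y, p) list(p$k_m * p$c * (V_total - y[1L]))
  sol <- deSolve::ode(y = c(V_m = V_m0), times = t_grid, func = rhs,
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  data.frame(t = sol[, 1L], V_m = sol[, "V_m"])
}
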