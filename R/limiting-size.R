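#' Width of the nutrient-supplied active rim (thin-shell limit)
#'
#' Nutrients diffuse in from the surrounding medium and are consumed at a
#' constant volumetric rate inside the biofilm; once the grain is large the
#' actively growing rim settles to the constant width
#' \deqn{w = \sqrt{2 (c_{II} - c_I) D / k},}
#' the classic Greenspan active-layer width for spherical growth.
#'
#' @param nutrients A [nutrient_params()] object.
#' @return Rim width in length units.
#' @examples
#' outer_width(nutrient_params(c_I = 0, c_II = 1, D = 2, k = 1))  # 2
#' @export
outer_width <- function(nutrients) {
  stopifnot(inherits(nutrients, "nutrient_params"))
  sqrt(2 * (nutrients$c_II - nutrients$c_I) * nutrients$D / nutrients$k)
}

#' Limiting ooid radius from the stationarity cubic
#'
#' The ooid stops growing when the volume gained in the nutrient-supplied
#' rim balances the net volume lost in the inner zone. With the rim volume
#' `4*pi*R^2*w` and the inner volume `(4/3)*pi*R^3`, the stationary radius
#' solves
#' \deqn{-\tfrac{4}{3}\pi\,|k_b^I - k_m/c|\,R^3 + 4\pi k_b^{II} w R^2
#'   + |k_b^I - k_m/c|\,V_m = 0,}
#' of the form `-A*R^3 + B*R^2 + C = 0` with one sign change in the
#' coefficients, hence (Descartes) exactly one positive root.
#'
#' The root is located by bracketed bisection (`uniroot` on
#' `(0, B/A + (C/A)^(1/3) + 1)`) followed by Newton polishing; closed-form
#' radicals are avoided for robustness across extreme parameter ratios.
#' With `V_m = 0` the cubic degenerates to a quadratic and the root `B/A`
#' is returned exactly.
#'
#' @param params A [model_params()] object in the size-limited regime
#'   (`c*k_b_I > k_m`; see [is_size_limited()]).
#' @param w Active-rim width (> 0), typically from [outer_width()].
#' @param V_m Mineral volume already locked into the inner zone (>= 0).
#' @return An object of class `"limiting_size"`: a list with the limiting
#'   radius `R`, the analytic bounds `lower` and `upper` (see
#'   [radius_bounds()]), the flag `unbounded_upper`, the rim width `w` and
#'   the cubic coefficients `A`, `B`, `C` as diagnostics.
#' @examples
#' p <- model_params(k_m = 0.5, k_b_I = 1, k_b_II = 0.2, c = 1)
#' limiting_radius(p, w = 1, V_m = 1)
#' @export
limiting_radius <- function(params, w, V_m = 0) {
  stopifnot(inherits(params, "model_params"))
  if (!is_size_limited(params))
    stop("no finite limiting size exists: requires c*k_b_I > k_m ",
         "(inner-zone decay must outpace mineral replacement)",
         call. = FALSE)
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0)
    stop("'w' must be a single positive width", call. = FALSE)
  if (!is.numeric(V_m) || length(V_m) != 1L || !is.finite(V_m) || V_m < 0)
    stop("'V_m' must be a single volume >= 0", call. = FALSE)

  kappa <- abs(params$k_b_I - params$k_m / params$c)
  A <- (4 / 3) * pi * kappa
  B <- 4 * pi * params$k_b_II * w
  C <- kappa * V_m

  f <- function(R) -A * R^3 + B * R^2 + C
  if (C == 0) {
    root <- B / A            # quadratic degeneration: exact
  } else {
    hi <- B / A + (C / A)^(1 / 3) + 1
    root <- stats::uniroot(f, c(0, hi), tol = .Machine$double.eps^0.75)$root
    # Newton polish to drive the residual below 1e-10 of the largest term
    for (i in 1:8) {
      fp <- -3 * A * root^2 + 2 * B * root
      if (fp == 0) break
      step <- f(root) / fp
      root <- root - step
      if (abs(step) < 1e-15 * root) break
    }
  }

  b <- radius_bounds(params, w)
  structure(
    list(R = root, lower = b$lower, upper = b$upper,
         unbounded_upper = b$unbounded_upper, w = w, A = A, B = B, C = C),
    class = "limiting_size"
  )
}

#' @export
print.limiting_size <- function(x, ...) {
  cat("Limiting ooid size\n")
  cat(sprintf("  R     = %.10g\n", x$R))
  cat(sprintf("  lower = %.10g\n", x$lower))
  if (x$unbounded_upper) cat("  upper = unbounded\n")
  else cat(sprintf("  upper = %.10g\n", x$upper))
  cat(sprintf("  rim width w = %g; cubic A = %g, B = %g, C = %g\n",
              x$w, x$A, x$B, x$C))
  invisible(x)
}

#' Analytic bounds on the limiting radius
#'
#' Setting `V_m = 0` in the stationarity cubic gives the lower bound
#' `3*c*k_b_II*w / (c*k_b_I - k_m)`; substituting the largest mineral volume
#' compatible with an active rim of width `w`
#' (`V_m = (4/3)*pi*R^3 - 4*pi*R^2*w + 4*pi*R*w^2`) gives the upper bound
#' `w*(c*k_b_I - k_m) / (c*k_b_I - k_m - c*k_b_II)`, finite only when the
#' denominator is positive. Both bounds are exactly linear in `w`, which is
#' how the limiting size inherits the square-root sensitivity of the rim
#' width to diffusivity and consumption rate.
#'
#' @param params A [model_params()] object in the size-limited regime.
#' @param w Active-rim width (>= 0).
#' @return A list with `lower`, `upper` (``Inf`` when unbounded) and the
#'   logical flag `unbounded_upper`.
#' @examples
#' p <- model_params(k_m = 0.5, k_b_I = 1, k_b_II = 0.2, c = 1)
#' radius_bounds(p, w = 1)
#' @export
radius_bounds <- function(params, w) {
  stopifnot(inherits(params, "model_params"))
  if (!is_size_limited(params))
    stop("no finite limiting size exists: requires c*k_b_I > k_m",
         call. = FALSE)
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w < 0)
    stop("'w' must be a single width >= 0", call. = FALSE)
  net <- params$c * params$k_b_I - params$k_m
  lower <- 3 * params$c * params$k_b_II * w / net
  den <- net - params$c * params$k_b_II
  if (den > 0) {
    list(lower = lower, upper = w * net / den, unbounded_upper = FALSE)
  } else {
    list(lower = lower, upper = Inf, unbounded_upper = TRUE)
  }
}

#' Sensitivity of the limiting size to nutrient transport
#'
#' With no pre-existing mineral volume the limiting radius is exactly
#' proportional to the rim width `w = sqrt(2*(c_II - c_I)*D/k)`, so the
#' limiting size scales as `D^(1/2)` and `k^(-1/2)`: faster diffusion makes
#' larger ooids, faster consumption makes smaller ones. This function
#' measures both exponents empirically as least-squares log-log slopes of
#' the computed limiting radius over a two-decade sweep of each quantity.
#'
#' @param params A [model_params()] object in the size-limited regime.
#' @param nutrients A [nutrient_params()] object giving the sweep midpoint.
#' @param n_points Number of sweep points per exponent (default 25).
#' @param decades Width of the sweep in decades (default 2).
#' @return A list with `exponent_D` and `exponent_k` (contract: +1/2 and
#'   -1/2).
#' @examples
#' p <- model_params(k_m = 0.5, k_b_I = 1, k_b_II = 0.2, c = 1)
#' sensitivity_exponents(p, nutrient_params())
#' @export
sensitivity_exponents <- function(params, nutrients, n_points = 25L,
                                  decades = 2) {
  stopifnot(inherits(params, "model_params"),
            inherits(nutrients, "nutrient_params"))
  factors <- 10^seq(0, decades, length.out = n_points)
  radius_at <- function(nut) limiting_radius(params, outer_width(nut))$R

  slope <- function(x, R) {
    unname(stats::coef(stats::lm(log(R) ~ log(x)))[2L])
  }
  R_D <- vapply(factors, function(f) {
    nut <- nutrients; nut$D <- nutrients$D * f; radius_at(nut)
  }, numeric(1))
  R_k <- vapply(factors, function(f) {
    nut <- nutrients; nut$k <- nutrients$k * f; radius_at(nut)
  }, numeric(1))
  list(exponent_D = slope(nutrients$D * factors, R_D),
       exponent_k = slope(nutrients$k * factors, R_k))
}

#' Exact active-layer width in a spherical shell
#'
#' Solves the steady-state diffusion--consumption balance in a sphere of
#' outer radius `R`: nutrient concentration `c_II` at the surface, constant
#' volumetric consumption `k` in the active shell, and concentration `c_I`
#' with zero flux at the inner interface where microbes stop growing.
#' Radial symmetry reduces the boundary-value problem to the exact relation
#' \deqn{\frac{k}{6D}\left(R^2 - 3 R_i^2 + 2 R_i^3 / R\right) = c_{II} - c_I}
#' whose left side is strictly decreasing in the inner radius `R_i` on
#' `[0, R]`, so the interface is found by bracketed root-finding to machine
#' precision. As `width/R -> 0` the width converges to the thin-shell
#' formula of [outer_width()].
#'
#' If even full penetration (`R_i = 0`) cannot consume the supplied
#' nutrient — i.e. `k*R^2/(6*D) <= c_II - c_I` — nutrients reach the centre
#' and there is no starved inner zone yet (the initial growth stage); this
#' is reported with `full_penetration = TRUE` and `width = R`.
#'
#' @param nutrients A [nutrient_params()] object.
#' @param R Outer radius of the biofilm (> 0).
#' @return An object of class `"shell_width"`: a list with `width`,
#'   `r_inner`, `full_penetration` and `w_thin` (the [outer_width()] value
#'   for reference).
#' @examples
#' nut <- nutrient_params(c_I = 0, c_II = 5e-7, D = 1, k = 1)
#' shell_width_exact(nut, R = 1)  # width close to outer_width(nut) = 1e-3
#' @export
shell_width_exact <- function(nutrients, R) {
  stopifnot(inherits(nutrients, "nutrient_params"))
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("'R' must be a single positive radius", call. = FALSE)
  dc <- nutrients$c_II - nutrients$c_I
  w_thin <- outer_width(nutrients)
  if (dc == 0)
    return(structure(list(width = 0, r_inner = R, full_penetration = FALSE,
                          w_thin = w_thin), class = "shell_width"))
  g <- function(ri) {
    nutrients$k / (6 * nutrients$D) * (R^2 - 3 * ri^2 + 2 * ri^3 / R) - dc
  }
  if (g(0) <= 0) {
    return(structure(list(width = R, r_inner = 0, full_penetration = TRUE,
                          w_thin = w_thin), class = "shell_width"))
  }
  ri <- stats::uniroot(g, c(0, R), tol = .Machine$double.eps^0.75)$root
  structure(list(width = R - ri, r_inner = ri, full_penetration = FALSE,
                 w_thin = w_thin), class = "shell_width")
}

#' @export
print.shell_width <- function(x, ...) {
  if (x$full_penetration)
    cat("Nutrients penetrate the full sphere (no starved inner zone);",
        "width =", x$width, "\n")
  else
    cat(sprintf("Active-layer width %.10g (inner interface at %.10g; thin-shell value %.10g)\n",
                x$width, x$r_inner, x$w_thin))
  invisible(x)
}
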