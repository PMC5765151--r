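# Independent oracles and seeded fixture generators shared across tests.

# Finite-difference boundary-value oracle for the spherical diffusion-
# consumption problem: given an inner interface ri with zero flux, solve
#   D * (c'' + (2/r) c') = k  on [ri, R],  c(R) = c_II,  c'(ri) = 0
# with second-order central differences and return c(ri). Tridiagonal
# system solved by the Thomas algorithm (no dependence on the package's
# algebraic reduction or on deSolve).
fd_shell_inner_conc <- function(ri, R, D, k, c_II, n = 10001L) {
  h <- (R - ri) / (n - 1L)
  r <- ri + h * (0:(n - 1L))
  # unknowns c_1..c_{n-1} (c_n = c_II fixed)
  m <- n - 1L
  lo <- numeric(m); di <- numeric(m); up <- numeric(m); rhs <- numeric(m)
  # Neumann row via ghost node c_0 = c_2: 2*(c_2 - c_1)/h^2 = k/D
  di[1L] <- -2 / h^2; up[1L] <- 2 / h^2; rhs[1L] <- k / D
  for (j in 2:m) {
    lo[j] <- 1 / h^2 - 1 / (r[j] * h)
    di[j] <- -2 / h^2
    up[j] <- 1 / h^2 + 1 / (r[j] * h)
    rhs[j] <- k / D
  }
  rhs[m] <- rhs[m] - up[m] * c_II
  # Thomas forward sweep
  for (j in 2:m) {
    w <- lo[j] / di[j - 1L]
    di[j] <- di[j] - w * up[j - 1L]
    rhs[j] <- rhs[j] - w * rhs[j - 1L]
  }
  cc <- numeric(m)
  cc[m] <- rhs[m] / di[m]
  for (j in (m - 1L):1L) cc[j] <- (rhs[j] - up[j] * cc[j + 1L]) / di[j]
  cc[1L]
}

# Width oracle: bisect the inner radius until the FD solution hits c_I.
fd_shell_width <- function(nut, R, n = 10001L) {
  f <- function(ri) fd_shell_inner_conc(ri, R, nut$D, nut$k, nut$c_II, n) -
    nut$c_I
  ri <- uniroot(f, c(R * 1e-9, R * (1 - 1e-9)), tol = R * 1e-12)$root
  R - ri
}

# Seeded random draws of kinetic parameters inside the size-limited regime
# (optionally with a finite upper bound) plus a rim width and a mineral
# volume strictly inside the admissible range.
draw_regime_cases <- function(n, seed, finite_upper = TRUE) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    c_ <- runif(1, 0.2, 5)
    k_b_I <- runif(1, 0.1, 3)
    net <- c_ * k_b_I
    k_m <- runif(1, 0.01, 0.9) * net
    k_b_II <- if (finite_upper) runif(1, 0.05, 0.9) * (net - k_m) / c_
              else runif(1, 0.05, 3)
    w <- 10^runif(1, -2, 2)
    p <- model_params(k_m = k_m, k_b = 0, k_b_I = k_b_I, k_b_II = k_b_II,
                      c = c_)
    b <- radius_bounds(p, w)
    V_m_max <- if (is.finite(b$upper))
      (4 / 3) * pi * b$upper^3 - 4 * pi * b$upper^2 * w + 4 * pi * b$upper * w^2
    else (4 / 3) * pi * (10 * b$lower + w)^3
    V_m <- runif(1, 0.05, 0.95) * V_m_max
    out[[i]] <- list(params = p, w = w, V_m = V_m)
  }
  out
}

# Count the positive real roots of -A x^3 + B x^2 + C via polyroot
# (independent of the package's bracketed solver).
count_positive_roots <- function(A, B, C) {
  z <- polyroot(c(C, 0, B, -A))
  sum(abs(Im(z)) < 1e-8 * (1 + abs(Re(z))) & Re(z) > 0)
}

# Bracketed bisection on the stationarity cubic, the oracle the cubic
# solver is checked against.
bisect_cubic_root <- function(A, B, C, hi, iter = 200L) {
  f <- function(x) -A * x^3 + B * x^2 + C
  lo <- 0
  stopifnot(f(hi) < 0)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Least-squares slope of log(y) on log(x).
loglog_slope <- function(x, y) unname(coef(lm(log(y) ~ log(x)))[2L])
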