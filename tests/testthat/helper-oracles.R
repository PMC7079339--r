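# Shared fixtures and independent oracles. All expected values used in
# the tests are computed by these oracles (or asserted trivially); the
# oracles never call the code paths they check.

# -- random parameter draws (log-uniform over plausible ranges) --------

draw_base_params <- function() {
  base_params(a = exp(runif(1, log(0.1), log(1))),
              b = exp(runif(1, log(1e-10), log(1e-8))),
              k = exp(runif(1, log(1e-5), log(10))),
              sigma = exp(runif(1, log(1), log(100))),
              d = exp(runif(1, log(1e-3), log(1e-1))),
              m = -exp(runif(1, log(1e-8), log(1e-4))))
}

draw_saturation_params <- function() {
  saturation_params(a = exp(runif(1, log(0.1), log(1))),
                    b = exp(runif(1, log(1e-10), log(1e-8))),
                    k = exp(runif(1, log(1e-5), log(1e-1))),
                    sigma = exp(runif(1, log(1), log(100))),
                    d = exp(runif(1, log(1e-3), log(1e-1))),
                    b_e = runif(1, 0, 1.5),
                    d_e = runif(1, 0, 3),
                    kappa_e = exp(runif(1, log(1e3), log(1e7))),
                    kappa_d = exp(runif(1, log(1e3), log(1e7))))
}

draw_nkctl_params <- function() {
  nkctl_params(a = exp(runif(1, log(0.1), log(1))),
               b = exp(runif(1, log(1e-10), log(1e-8))),
               c = exp(runif(1, log(1e-7), log(1e-2))),
               k = exp(runif(1, log(1e-5), log(1e-1))),
               sigma = exp(runif(1, log(1), log(100))),
               mu = exp(runif(1, log(1e-2), log(1e-1))),
               b_n = runif(1, 0, 1), d_n = runif(1, 0, 2),
               b_e = runif(1, 0, 1), d_e = runif(1, 0, 3),
               d = exp(runif(1, log(1e-3), log(1e-1))),
               kappa_bn = exp(runif(1, log(1e3), log(1e7))),
               kappa_dn = exp(runif(1, log(1e3), log(1e7))),
               kappa_be = exp(runif(1, log(1e3), log(1e7))),
               kappa_de = exp(runif(1, log(1e3), log(1e7))),
               omega = exp(runif(1, log(1e-12), log(1e-8))))
}

# -- term-by-term RHS oracles ------------------------------------------
# written as explicit sums of individually evaluated terms, independent
# of the package's vectorized expressions

base_rhs_oracle <- function(T, E, p) {
  growth <- p$a * T
  crowding <- -(p$a * p$b) * (T * T)
  killing <- -(p$k * T) * E
  supply <- p$sigma
  death <- -(p$d * E)
  modulation <- (p$m * E) * T
  c(growth + crowding + killing, supply + death + modulation)
}

saturation_rhs_oracle <- function(T, E, p) {
  dT <- p$a * T - (p$a * p$b) * T * T - (p$k * T) * E
  prol <- (p$b_e * E) * (T / (p$kappa_e + T))
  exh <- -(p$d_e * E) * (T / (p$kappa_d + T))
  c(dT, p$sigma - p$d * E + prol + exh)
}

nkctl_rhs_oracle <- function(T, N, E, p) {
  dT <- p$a * T - (p$a * p$b) * T * T - (p$c * N) * T - (p$k * E) * T
  dN <- p$sigma - p$mu * N + (p$b_n * N) * (T / (p$kappa_bn + T)) -
    (p$d_n * N) * (T / (p$kappa_dn + T))
  dE <- -p$d * E + (p$b_e * E) * (T / (p$kappa_be + T)) -
    (p$d_e * E) * (T / (p$kappa_de + T)) + (p$omega * N) * T
  c(dT, dN, dE)
}

# -- numeric root oracles ----------------------------------------------

# positive-root count of the base model's interior-equilibrium quadratic,
# assembled from the two nullclines (E = sigma/(d - mT) substituted into
# the tumor equation) and solved by polyroot with Newton polishing and a
# residual acceptance test
quad_positive_roots_oracle <- function(p) {
  c0 <- p$a * p$d - p$k * p$sigma
  c1 <- -p$a * (p$m + p$b * p$d)
  c2 <- p$a * p$b * p$m
  f <- function(x) c0 + c1 * x + c2 * x^2
  fp <- function(x) c1 + 2 * c2 * x
  roots <- c()
  for (z in polyroot(c(c0, c1, c2))) {
    x <- Re(z)
    for (it in 1:100) {
      st <- f(x) / fp(x)
      x <- x - st
      if (!is.finite(x) || abs(st) < 1e-12 * max(1, abs(x))) break
    }
    scale <- abs(c0) + abs(c1 * x) + abs(c2 * x^2)
    if (is.finite(x) && abs(f(x)) <= 1e-8 * scale) roots <- c(roots, x)
  }
  roots <- sort(roots)
  if (length(roots) == 2 && diff(roots) < 1e-9 * max(1, abs(roots[2]))) {
    roots <- roots[2] # double root
  }
  roots[roots > 1e-6]
}

# positive equilibria of the saturation model located directly on the
# assembled nullcline function (sign-change scan + uniroot), independent
# of the cubic coefficients
saturation_roots_scan_oracle <- function(p, n_grid = 4000) {
  G <- function(T) {
    E <- p$a * (1 - p$b * T) / p$k
    p$sigma + E * (-p$d + p$b_e * T / (p$kappa_e + T) -
                     p$d_e * T / (p$kappa_d + T))
  }
  grid <- exp(seq(log(1e-4), log(1 / p$b), length.out = n_grid))
  vals <- vapply(grid, G, numeric(1))
  sgn <- sign(vals)
  idx <- which(sgn[-1] * sgn[-n_grid] < 0)
  vapply(idx, function(i)
    uniroot(G, c(grid[i], grid[i + 1]), tol = 1e-10 * grid[i])$root,
    numeric(1))
}

# attractors reached by long deterministic integration from a lattice of
# initial conditions (used to confirm bi-/multistability structure)
attractors_by_integration <- function(params, inits, t_end = 2000,
                                      merge_rel = 0.05) {
  Ts <- vapply(inits, function(y0) {
    out <- ode_solve(params, y0, times = c(0, t_end / 2, t_end),
                     rtol = 1e-8, atol = 1e-8)
    out[nrow(out), 2] # tumor component
  }, numeric(1))
  Ts <- sort(pmax(Ts, 0))
  Ts[Ts < 1] <- 0 # sub-cell residue counts as the cancer-free attractor
  keep <- c(TRUE, diff(Ts) > merge_rel * pmax(1, Ts[-length(Ts)]))
  Ts[keep]
}

expect_close <- function(x, y, tol = 1e-8) {
  expect_true(all(abs(x - y) <= tol * pmax(1, abs(y))),
              label = sprintf("max rel diff %.3g", max(abs(x - y) /
                                                         pmax(1, abs(y)))))
}
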