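# Parameter containers and deterministic right-hand sides.

test_that("parameter constructors validate and warn appropriately", {
  expect_s3_class(base_params(), "cisi_params")
  expect_error(base_params(a = -1))
  expect_error(base_params(a = c(1, 2)), "scalar")
  expect_error(base_params(d = NaN), "scalar")
  expect_error(saturation_params(kappa_e = 0))
  expect_error(nkctl_params(omega = -1))
  expect_warning(base_params(m = 1e-7), "m >= 0")
  expect_warning(base_params(m = 0), "m >= 0")
})

test_that("presets carry the standard parameterizations", {
  t1 <- param_preset("table1")
  expect_equal(unclass(t1)[c("a", "b", "k", "sigma", "d", "m")],
               list(a = 0.514, b = 1.02e-9, k = 1e-4, sigma = 10,
                    d = 1e-2, m = -1e-6))
  f2 <- param_preset("fig2")
  expect_equal(f2$d, 2e-2)
  expect_equal(unclass(f2)[c("a", "b", "sigma", "m")],
               unclass(t1)[c("a", "b", "sigma", "m")])
})

test_that("update_params copies immutably and rejects unknown names", {
  p <- base_params()
  q <- update_params(p, k = 0.5)
  expect_equal(q$k, 0.5)
  expect_equal(p$k, 1e-4) # original untouched
  expect_error(update_params(p, kappa_e = 1), "unknown parameter")
  expect_error(update_params(p, a = -2)) # revalidated through constructor
})

test_that("RHS evaluates exactly at the trivial fixed points", {
  p <- base_params()
  expect_equal(unname(base_rhs(c(0, p$sigma / p$d), p)), c(0, 0))
  # 1/b is not exactly representable; the logistic term vanishes to
  # rounding error at carrying-capacity scale
  expect_equal(unname(base_rhs(c(1 / p$b, 0), p)), c(0, p$sigma),
               tolerance = 1e-6)
  ps <- saturation_params()
  expect_equal(unname(saturation_rhs(c(0, ps$sigma / ps$d), ps)), c(0, 0))
  pn <- nkctl_params()
  expect_equal(unname(nkctl_rhs(c(0, pn$sigma / pn$mu, 0), pn)), c(0, 0, 0))
})

test_that("NK/CTL CTLs are sourced only through NK-tumor priming", {
  p <- nkctl_params()
  d <- nkctl_rhs(c(T = 1e4, N = 500, E = 0), p)
  expect_equal(unname(d[["E"]]), p$omega * 500 * 1e4)
  expect_gt(d[["E"]], 0)
  # no constant CTL supply: with N = 0 and E = 0, dE/dt = 0
  expect_equal(unname(nkctl_rhs(c(1e4, 0, 0), p)[["E"]]), 0)
})

test_that("RHS matches term-by-term oracle on random states", {
  set.seed(101)
  for (i in 1:200) {
    p <- draw_base_params()
    st <- c(10^runif(1, 0, 9), 10^runif(1, 0, 6))
    expect_close(unname(base_rhs(st, p)), base_rhs_oracle(st[1], st[2], p),
                 tol = 1e-12)
    ps <- draw_saturation_params()
    expect_close(unname(saturation_rhs(st, ps)),
                 saturation_rhs_oracle(st[1], st[2], ps), tol = 1e-12)
    pn <- draw_nkctl_params()
    st3 <- c(st, 10^runif(1, 0, 5))
    expect_close(unname(nkctl_rhs(st3, pn)),
                 nkctl_rhs_oracle(st3[1], st3[2], st3[3], pn), tol = 1e-12)
  }
})

test_that("axes are invariant: no flow out of the nonnegative orthant", {
  set.seed(102)
  for (i in 1:100) {
    p <- draw_base_params()
    E <- 10^runif(1, 0, 6)
    expect_equal(unname(base_rhs(c(0, E), p)[["T"]]), 0)
    expect_gte(base_rhs(c(10^runif(1, 0, 9), 0), p)[["E"]], 0)
    pn <- draw_nkctl_params()
    T <- 10^runif(1, 0, 9)
    expect_equal(unname(nkctl_rhs(c(0, 500, 10), pn)[["T"]]), 0)
    expect_gte(nkctl_rhs(c(T, 0, 10), pn)[["N"]], 0)
    expect_gte(nkctl_rhs(c(T, 500, 0), pn)[["E"]], 0)
  }
})

test_that("base model degenerates to pure logistic growth when k = 0", {
  p <- update_params(base_params(), k = 0)
  set.seed(103)
  for (i in 1:20) {
    T <- 10^runif(1, 0, 9)
    E <- 10^runif(1, 0, 5)
    expect_equal(unname(base_rhs(c(T, E), p)[["T"]]),
                 p$a * T * (1 - p$b * T))
  }
})

test_that("saturation model at large T approaches per-capita rate b_e - d_e - d", {
  p <- saturation_params()
  E <- 1000
  T <- 1e12 # far above both half-saturations
  percap <- (saturation_rhs(c(T, E), p)[["E"]] - p$sigma) / E
  expect_equal(percap, p$b_e - p$d_e - p$d, tolerance = 1e-6)
})

test_that("invalid states are rejected", {
  p <- base_params()
  expect_error(base_rhs(c(NA, 1), p), "non-finite")
  expect_error(base_rhs(c(Inf, 1), p), "non-finite")
  expect_error(base_rhs(c(1, 2, 3), p), "length")
  expect_error(nkctl_rhs(c(1, 2), nkctl_params()), "length")
  expect_error(check_state(c(-1, 5), p, require_nonneg = TRUE),
               "nonnegative")
})

test_that("analytic base Jacobian agrees with finite differences", {
  set.seed(104)
  for (i in 1:20) {
    p <- draw_base_params()
    st <- c(T = 10^runif(1, 0, 9), E = 10^runif(1, 0, 5))
    Jnum <- cisim:::num_jacobian(model_rhs(p), st)
    expect_close(as.vector(base_jacobian(st, p)), as.vector(Jnum),
                 tol = 1e-4)
  }
})
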