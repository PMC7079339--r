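# Fixed points, thresholds, regime classification, and the
# bistability/multistability condition apparatus.

fig2 <- param_preset("fig2")

test_that("cancer-free point is always among the base equilibria", {
  set.seed(201)
  for (i in 1:50) {
    p <- draw_base_params()
    eq <- base_equilibria(p)
    T0 <- which(vapply(eq, function(e) e$state[["T"]] == 0, logical(1)))
    expect_length(T0, 1)
    expect_equal(eq[[T0]]$state[["E"]], p$sigma / p$d)
  }
})

test_that("k thresholds: closed forms, ordering, and regime errors", {
  th <- base_k_thresholds(fig2)
  expect_equal(th[["k_l"]], fig2$a * fig2$d / fig2$sigma)
  expect_equal(th[["k_u"]],
               th[["k_l"]] - (fig2$a * (fig2$m + fig2$b * fig2$d))^2 /
                 (4 * fig2$a * fig2$b * fig2$m) / fig2$sigma)
  expect_gt(th[["k_u"]], th[["k_l"]])
  # both thresholds scale as 1/sigma: large sigma collapses the window
  th_big <- base_k_thresholds(update_params(fig2, sigma = 1e12))
  expect_lt(th_big[["k_l"]], 1e-12)
  expect_lt(th_big[["k_u"]] - th_big[["k_l"]], 13 / 1e11)
  expect_error(base_k_thresholds(suppressWarnings(
    update_params(fig2, m = 1e-9))), "m < 0")
  expect_error(base_k_thresholds(update_params(fig2, m = -1e-12)),
               "m \\+ b\\*d")
})

test_that("bistable window: three equilibria with the expected stability", {
  th <- base_k_thresholds(fig2)
  p <- update_params(fig2, k = sqrt(th[["k_l"]] * th[["k_u"]]))
  eq <- base_equilibria(p)
  expect_length(eq, 3)
  tab <- equilibria_table(eq)
  expect_equal(tab$stability, c("stable", "unstable", "stable"))
  expect_true(all(diff(tab$T_star) > 0))
  # attractor structure confirmed by long forward integration from
  # initial conditions bracketing the interior unstable point; the
  # macroscopic start pairs T with its conditional effector equilibrium
  # (starting it at the cancer-free effector level sigma/d would kill
  # the tumor through the transient before suppression sets in)
  Tmid <- tab$T_star[2]
  att <- attractors_by_integration(
    p, list(c(Tmid / 10, p$sigma / p$d),
            c(Tmid * 10, p$sigma / (p$d - p$m * Tmid * 10))))
  expect_length(att, 2)
  expect_equal(att[1], 0)
  expect_equal(att[2], tab$T_star[3], tolerance = 1e-3)
})

test_that("degenerate closed forms: k = 0 and m = 0 branches", {
  p0 <- update_params(fig2, k = 0)
  tab <- equilibria_table(base_equilibria(p0))
  expect_equal(tab$T_star, c(0, 1 / p0$b), tolerance = 1e-12)
  pm <- suppressWarnings(update_params(fig2, m = 0, k = 1e-4))
  tab <- equilibria_table(base_equilibria(pm))
  expect_equal(tab$T_star[2],
               (1 - pm$k * pm$sigma / (pm$a * pm$d)) / pm$b,
               tolerance = 1e-12)
  expect_equal(tab$E_star, rep(pm$sigma / pm$d, 2))
})

test_that("regime classification follows the threshold cases", {
  th <- base_k_thresholds(fig2)
  expect_equal(classify_base_regime(
    update_params(fig2, k = 10 * th[["k_u"]]))$case_label, "i")
  cl2 <- classify_base_regime(update_params(fig2, k = th[["k_l"]] / 2))
  expect_equal(cl2$case_label, "ii")
  expect_equal(cl2$n_positive_roots, 1L)
  cl3 <- classify_base_regime(
    update_params(fig2, k = (th[["k_l"]] + th[["k_u"]]) / 2))
  expect_equal(cl3$case_label, "iii")
  expect_equal(cl3$n_positive_roots, 2L)
  expect_equal(classify_base_regime(
    update_params(fig2, k = th[["k_l"]]))$case_label, "marginal")
  expect_named(cl3$conditions_satisfied, c("eq5", "eq6", "eq7", "eq8"))
  expect_true(all(cl3$conditions_satisfied))
})

test_that("analytic base roots match the independent quadratic oracle", {
  set.seed(202)
  for (i in 1:300) {
    p <- draw_base_params()
    Ts <- equilibria_table(base_equilibria(p))$T_star
    Ts <- Ts[Ts > 0]
    oracle <- quad_positive_roots_oracle(p)
    expect_equal(length(Ts), length(oracle))
    if (length(Ts)) expect_close(sort(Ts), sort(oracle), tol = 1e-6)
  }
})

test_that("saturation cubic with b_e = d_e = 0 factors to the base m = 0 line", {
  p <- saturation_params(b_e = 0, d_e = 0, k = 2e-4)
  co <- saturation_cubic_coeffs(p)
  cubic <- function(T) co[["A"]] * T^3 + co[["B"]] * T^2 +
    co[["C"]] * T + co[["D"]]
  # the cubic factors as const * (kappa_e + T)(kappa_d + T)(linear term);
  # its only admissible root is the base-model m = 0 equilibrium
  T_base <- (1 - p$k * p$sigma / (p$a * p$d)) / p$b
  expect_equal(cubic(T_base) / max(abs(co)) / T_base^3, 0,
               tolerance = 1e-10)
  expect_equal(cubic(-p$kappa_e) / max(abs(co)), 0, tolerance = 1e-8)
  expect_equal(cubic(-p$kappa_d) / max(abs(co)), 0, tolerance = 1e-8)
})

test_that("sign of cubic leading coefficient A equals sign of ab(b_e - d_e - d)", {
  set.seed(203)
  for (i in 1:100) {
    p <- draw_saturation_params()
    A <- saturation_cubic_coeffs(p)[["A"]]
    expect_equal(sign(A), sign(p$a * p$b * (p$b_e - p$d_e - p$d)))
  }
})

test_that("cubic roots agree with the assembled-nullcline scan oracle", {
  set.seed(204)
  for (i in 1:40) {
    p <- draw_saturation_params()
    roots_pkg <- equilibria_table(saturation_equilibria(p))$T_star
    roots_pkg <- roots_pkg[roots_pkg > 1e-3 & roots_pkg < 1 / p$b]
    roots_scan <- saturation_roots_scan_oracle(p)
    roots_scan <- roots_scan[roots_scan > 1e-3]
    expect_equal(length(roots_pkg), length(roots_scan))
    if (length(roots_pkg)) {
      expect_close(sort(roots_pkg), sort(roots_scan), tol = 1e-4)
    }
  }
})

test_that("bistability conditions match numeric root counts on random draws", {
  set.seed(205)
  n_indet <- 0
  for (i in 1:400) {
    p <- draw_saturation_params()
    sb <- suppressWarnings(saturation_bistability(p))
    sm <- suppressWarnings(saturation_multistability(p))
    if (isTRUE(sb$indeterminate)) {
      n_indet <- n_indet + 1
      expect_equal(sb$bistable, sb$n_positive_roots == 2L) # fallback
      next
    }
    expect_identical(sb$bistable_conditions, sb$n_positive_roots == 2L)
    expect_identical(sm$multistable_conditions, sm$n_positive_roots == 3L)
    # the two labels are mutually exclusive on the same parameters
    expect_false(isTRUE(sb$bistable_conditions) &&
                   isTRUE(sm$multistable_conditions))
  }
  expect_lt(n_indet / 400, 0.05)
})

test_that("exhaustion-dominated regime is predominantly bistable", {
  # d_e > 1 and k > 5e-4 (others at package defaults): bistability in
  # the majority of draws
  set.seed(206)
  hits <- 0
  for (i in 1:100) {
    p <- saturation_params(d_e = runif(1, 1, 3),
                           k = exp(runif(1, log(5e-4), log(5e-2))))
    if (saturation_bistability(p)$bistable) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.5)
})

test_that("no killing means no barrier: k = 0 is never bistable", {
  p <- saturation_params(k = 0)
  co <- saturation_cubic_coeffs(p)
  expect_equal(co[["D"]], p$kappa_d * p$kappa_e * p$a * p$d)
  expect_gt(co[["D"]], 0)
  expect_false(saturation_bistability(p)$bistable)
})

test_that("b_e = 0 never yields multistability", {
  set.seed(207)
  for (i in 1:100) {
    p <- draw_saturation_params()
    p <- update_params(p, b_e = 0)
    expect_false(suppressWarnings(saturation_multistability(p))$multistable)
  }
})

test_that("a concrete multistable instance has three positive roots and dormant attractor", {
  # frozen instance located by random search in the proliferation-then-
  # exhaustion regime (kappa_e << kappa_d)
  p <- saturation_params(k = 4.621726e-4, b_e = 3.635086e-2,
                         kappa_e = 1.748695e3, d_e = 6.472006e-1,
                         kappa_d = 4.595593e4)
  sm <- saturation_multistability(p)
  expect_true(sm$multistable)
  expect_equal(sm$n_positive_roots, 3L)
  tab <- equilibria_table(saturation_equilibria(p))
  expect_equal(nrow(tab), 4L)
  # k < k_l here, so the tumor-free state is unstable; the two stable
  # states are the dormant microscopic tumor and the macroscopic one
  expect_equal(tab$stability,
               c("unstable", "stable", "unstable", "stable"))
})

test_that("NK/CTL plausibility condition: signs and kappa independence", {
  p <- nkctl_params() # b_e < d_e + d and b_n < d_n + mu by default
  expect_lt(p$b_e - p$d_e - p$d, 0)
  expect_lt(p$b_n - p$d_n - p$mu, 0)
  expect_true(nkctl_plausibility(p))
  # sign bookkeeping: no killing/priming and mixed exhaustion signs
  p2 <- update_params(p, k = 0, sigma = 0, omega = 0, b_e = 3) # b_e-d_e-d > 0
  expect_false(nkctl_plausibility(p2))
  set.seed(208)
  for (i in 1:100) {
    pr <- draw_nkctl_params()
    direct <- -pr$a * pr$b * ((pr$b_e - pr$d_e - pr$d) *
                                (pr$b_n - pr$d_n - pr$mu)) -
      pr$k * pr$sigma * pr$omega < 0
    expect_identical(nkctl_plausibility(pr), direct)
    # invariance under perturbation of all four saturation constants
    pk <- update_params(pr,
                        kappa_bn = pr$kappa_bn * 10^runif(1, -2, 2),
                        kappa_dn = pr$kappa_dn * 10^runif(1, -2, 2),
                        kappa_be = pr$kappa_be * 10^runif(1, -2, 2),
                        kappa_de = pr$kappa_de * 10^runif(1, -2, 2))
    expect_identical(nkctl_plausibility(pk), nkctl_plausibility(pr))
  }
})

test_that("NK/CTL equilibria: tumor-free point, count cap, bistable default", {
  set.seed(209)
  for (i in 1:30) {
    p <- draw_nkctl_params()
    eq <- suppressMessages(nkctl_equilibria(p))
    expect_lte(length(eq), 6L)
    tab <- equilibria_table(eq)
    i0 <- which(tab$T_star == 0)
    expect_length(i0, 1)
    expect_equal(tab$N_star[i0], p$sigma / p$mu)
    expect_equal(tab$E_star[i0], 0)
    expect_equal(tab$method[i0], "analytic")
  }
  # default parameterization sits in the bistable exhaustion regime
  p <- nkctl_params()
  tab <- equilibria_table(nkctl_equilibria(p))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$stability, c("stable", "unstable", "stable"))
  # confirmed by integration from states bracketing the barrier
  Tmid <- tab$T_star[2]
  N0 <- p$sigma / p$mu
  att <- attractors_by_integration(
    p, list(c(Tmid / 10, N0, 0), c(Tmid * 10, N0, 0)), t_end = 3000)
  expect_length(att, 2)
  expect_equal(att[2], tab$T_star[3], tolerance = 1e-3)
})

test_that("stability_of matches theory at the cancer-free point", {
  th <- base_k_thresholds(fig2)
  p_ii <- update_params(fig2, k = th[["k_l"]] / 2)
  st <- stability_of(c(0, p_ii$sigma / p_ii$d), p_ii)
  expect_equal(st$stability, "unstable")
  # the unstable direction is tumor growth at rate a - k sigma / d
  expect_equal(max(Re(st$eigenvalues)),
               p_ii$a - p_ii$k * p_ii$sigma / p_ii$d, tolerance = 1e-5)
  p_i <- update_params(fig2, k = 10 * th[["k_u"]])
  expect_equal(stability_of(c(0, p_i$sigma / p_i$d), p_i)$stability,
               "stable")
  expect_error(stability_of(c(1e5, 1e3), p_i), "not an equilibrium")
})
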