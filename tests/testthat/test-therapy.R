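# Treatment schedules, dose bookkeeping, and treated simulations.

table1 <- param_preset("table1")

test_that("schedule validation enforces dose/duration coupling", {
  expect_s3_class(treatment_schedule(), "treatment_schedule")
  expect_error(treatment_schedule(delta_k = 0.1, delta_tau_k = 0),
               "delta_tau_k")
  expect_error(treatment_schedule(delta_E = 10, delta_tau_E = 0),
               "delta_tau_E")
  expect_error(treatment_schedule(delta_k = -1))
})

test_that("killing-efficacy ramp follows the daily increment rule", {
  sched <- treatment_schedule(tau_k = 50, delta_tau_k = 21, delta_k = 0.1)
  kf <- k_of_t(sched, k0 = 1e-4)
  expect_equal(kf(0), 1e-4)
  expect_equal(kf(50), 1e-4)           # no increment before day end
  expect_equal(kf(50 + 10.5), 1e-4 + 10 * (0.1 / 21)) # before the 11th
  expect_equal(kf(71), 0.1001)
  expect_equal(kf(1000), 0.1001)       # permanent alteration
  # increments sum to delta_k with no rounding drift
  vals <- attr(kf, "values")
  expect_length(vals, 21)
  expect_identical(vals[21], 1e-4 + 0.1)
  # null dose: constant function
  kf0 <- k_of_t(treatment_schedule(delta_k = 0), k0 = 2e-4)
  expect_equal(kf0(c(0, 50, 1e3)), rep(2e-4, 3))
  expect_length(attr(kf0, "breakpoints"), 0)
})

test_that("transfer boluses conserve the dose exactly", {
  sched <- treatment_schedule(tau_E = 50, delta_tau_E = 28, delta_E = 1e5)
  ev <- transfer_events(sched)
  expect_equal(nrow(ev), 28L)
  expect_equal(ev$time, 50:77)
  expect_identical(sum(ev$amount), 1e5)
  expect_true(all(ev$amount == round(ev$amount)))
  expect_equal(nrow(transfer_events(treatment_schedule(delta_E = 0))), 0L)
  single <- transfer_events(treatment_schedule(tau_E = 50,
                                               delta_tau_E = 1,
                                               delta_E = 12345))
  expect_equal(single$time, 50)
  expect_equal(single$amount, 12345)
  set.seed(401)
  for (i in 1:50) { # property: conservation for integer doses
    dE <- sample(1:10^6, 1); dtau <- sample(1:60, 1)
    ev <- transfer_events(treatment_schedule(delta_E = dE,
                                             delta_tau_E = dtau))
    expect_identical(sum(ev$amount), as.numeric(dE))
  }
})

test_that("null schedule reproduces the untreated run bit-for-bit", {
  null_sched <- treatment_schedule(delta_k = 0, delta_E = 0)
  tr_treat <- run_treatment(table1, c(T = 100, E = 1000), null_sched,
                            t_max = 30, seed = 5)
  tr_plain <- simulate_tauleap(build_base_reactions(table1),
                               c(T = 100, E = 1000), 30, seed = 5)
  expect_identical(tr_treat$states, tr_plain$states)
})

test_that("treatment causality: pre-treatment prefix identical to untreated", {
  sched <- treatment_schedule(tau_k = 50, delta_tau_k = 21,
                              delta_k = 0.1, tau_E = 50,
                              delta_tau_E = 28, delta_E = 1e5)
  tr_treat <- run_treatment(table1, c(T = 100, E = 1000), sched,
                            t_max = 90, seed = 9)
  tr_plain <- simulate_tauleap(build_base_reactions(table1),
                               c(T = 100, E = 1000), 90, seed = 9)
  common <- intersect(tr_treat$times, tr_plain$times)
  pre <- common[common < 50]
  expect_identical(tr_treat$states[match(pre, tr_treat$times), ],
                   tr_plain$states[match(pre, tr_plain$times), ])
  # and the treated run diverges afterwards
  post <- common[common > 80]
  expect_false(identical(tr_treat$states[match(post, tr_treat$times), ],
                         tr_plain$states[match(post, tr_plain$times), ]))
})

test_that("antibody therapy beyond k_u clears an established tumor", {
  th <- base_k_thresholds(table1)
  sched <- treatment_schedule(tau_k = 50, delta_tau_k = 1,
                              delta_k = th[["k_u"]] * 2, delta_E = 0)
  for (s in 1:2) {
    tr <- run_treatment(table1, established_tumor_state(table1), sched,
                        t_max = 120, seed = s, record_dt = 5)
    expect_equal(unname(tr$states[nrow(tr$states), "T"]), 0)
  }
})

test_that("bistability exploitation: clearance persists after treatment wanes", {
  # raise k into the bistable window (k0 + delta_k in (k_l, k_u)), push
  # T below the interior barrier with transfers, then verify that the
  # cancer-free state persists long after all dosing has stopped
  th <- base_k_thresholds(table1)
  sched <- treatment_schedule(tau_k = 50, delta_tau_k = 5, delta_k = 0.1,
                              tau_E = 55, delta_tau_E = 10, delta_E = 1e5)
  k_final <- table1$k + sched$delta_k
  expect_true(k_final > th[["k_l"]] && k_final < th[["k_u"]])
  tr <- run_treatment(table1, established_tumor_state(table1), sched,
                      t_max = 200, seed = 3, record_dt = 1)
  post <- tr$states[tr$times >= 100, "T"] # >35 days after last bolus
  expect_true(all(post == 0))
})

test_that("dose grid: shapes, seeds, and the untreated corner", {
  gr <- combination_grid(table1, delta_k_grid = c(0, 1),
                         delta_E_grid = c(0, 1e5),
                         n_reps = 2, base_seed = 17)
  expect_equal(dim(gr$median), c(2L, 2L))
  expect_equal(dim(gr$final_T), c(2L, 2L, 2L))
  expect_equal(gr$n_failed, 0L)
  expect_false(anyDuplicated(as.vector(gr$seeds)) > 0)
  # untreated corner stays at carrying capacity (bT ~ 1)
  expect_gt(gr$median[1, 1] * table1$b, 0.97)
  fr <- clearance_frontier(gr)
  expect_equal(fr$delta_k, c(0, 1))
  expect_true(all(fr$min_clearing_delta_E == sort(fr$min_clearing_delta_E,
                                                  decreasing = TRUE)))
})
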