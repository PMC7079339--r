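# Treatment model: two concurrent modalities.
#
# Antibody (checkpoint-blockade) therapy permanently raises the killing
# efficacy: starting at tau_k, k is increased by delta_k/delta_tau_k at
# the end of each of delta_tau_k treatment days, reaching k0 + delta_k
# when the course completes and staying there.
#
# Adoptive effector transfer injects delta_E cells in equal daily boluses
# of round(delta_E/delta_tau_E) at days tau_E, tau_E + 1, ...,
# tau_E + delta_tau_E - 1, the last bolus adjusted so the administered
# total is exactly delta_E.

#' Combination immunotherapy schedule
#'
#' @param tau_k Antibody-therapy start day.
#' @param delta_tau_k Antibody course duration (days, >= 1 whenever
#'   `delta_k > 0`).
#' @param delta_k Total permanent killing-efficacy increase
#'   (cells^-1 day^-1, >= 0).
#' @param tau_E Adoptive-transfer start day.
#' @param delta_tau_E Transfer course duration (days, >= 1 whenever
#'   `delta_E > 0`).
#' @param delta_E Total transferred effector cells (cells, >= 0).
#' @return Object of class `treatment_schedule`.
#' @export
#' @examples
#' # the combination protocol used in the treated-run experiment:
#' treatment_schedule(tau_k = 50, delta_tau_k = 21, delta_k = 1e-1,
#'                    tau_E = 50, delta_tau_E = 28, delta_E = 1e5)
treatment_schedule <- function(tau_k = 50, delta_tau_k = 1, delta_k = 0,
                               tau_E = 50, delta_tau_E = 1, delta_E = 0) {
  stopifnot(tau_k >= 0, tau_E >= 0, delta_k >= 0, delta_E >= 0)
  if (delta_k > 0 && delta_tau_k < 1) {
    stop("delta_tau_k must be >= 1 day when delta_k > 0", call. = FALSE)
  }
  if (delta_E > 0 && delta_tau_E < 1) {
    stop("delta_tau_E must be >= 1 day when delta_E > 0", call. = FALSE)
  }
  stopifnot(delta_tau_k == round(delta_tau_k),
            delta_tau_E == round(delta_tau_E))
  structure(list(tau_k = tau_k, delta_tau_k = as.integer(delta_tau_k),
                 delta_k = delta_k,
                 tau_E = tau_E, delta_tau_E = as.integer(delta_tau_E),
                 delta_E = delta_E),
            class = "treatment_schedule")
}

#' Killing efficacy as a function of time under treatment
#'
#' Piecewise-constant daily ramp: `k(t) = k0` before `tau_k`; `k`
#' increases by `delta_k/delta_tau_k` at the end of each treatment day
#' (i.e. at `tau_k + 1, ..., tau_k + delta_tau_k`); from the end of the
#' course on, `k(t) = k0 + delta_k` exactly and permanently.
#'
#' @param schedule A [treatment_schedule()].
#' @param k0 Baseline killing efficacy (cells^-1 day^-1, >= 0).
#' @return A step function `k(t)` (vectorized in `t`) with attributes
#'   `breakpoints` and `values` consumed by [simulate_tauleap()].
#' @export
#' @examples
#' kf <- k_of_t(treatment_schedule(tau_k = 50, delta_tau_k = 21,
#'                                 delta_k = 0.1), k0 = 1e-4)
#' kf(c(50, 60.5, 71)) # 1e-4, 1e-4 + 10 * 0.1/21, 0.1001
k_of_t <- function(schedule, k0) {
  stopifnot(inherits(schedule, "treatment_schedule"), k0 >= 0)
  if (schedule$delta_k == 0) {
    f <- function(t) rep_len(k0, length(t))
    attr(f, "breakpoints") <- numeric(0)
    attr(f, "values") <- numeric(0)
    return(f)
  }
  n <- schedule$delta_tau_k
  bp <- schedule$tau_k + seq_len(n)
  vals <- k0 + seq_len(n) * (schedule$delta_k / n)
  vals[n] <- k0 + schedule$delta_k # no rounding drift at course end
  f <- function(t) {
    steps <- pmin(n, pmax(0, floor(t - schedule$tau_k)))
    ifelse(steps >= n, k0 + schedule$delta_k,
           k0 + steps * (schedule$delta_k / n))
  }
  attr(f, "breakpoints") <- bp
  attr(f, "values") <- vals
  f
}

#' Adoptive-transfer bolus events
#'
#' Daily boluses of `round(delta_E/delta_tau_E)` cells at days
#' `tau_E, ..., tau_E + delta_tau_E - 1`; the final bolus is adjusted so
#' the administered total is exactly `delta_E` (dose conservation).
#' Boluses are whole cells, so a non-integer `delta_E` is first rounded
#' to the nearest cell.
#'
#' @param schedule A [treatment_schedule()].
#' @return Data frame with columns `time`, `species` (`"E"`), `amount`;
#'   zero rows when `delta_E = 0`.
#' @export
transfer_events <- function(schedule) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  if (schedule$delta_E == 0) {
    return(data.frame(time = numeric(0), species = character(0),
                      amount = numeric(0)))
  }
  n <- schedule$delta_tau_E
  total <- round(schedule$delta_E)
  dose <- round(total / n)
  amounts <- rep(dose, n)
  amounts[n] <- total - dose * (n - 1)
  stopifnot(amounts[n] >= 0)
  data.frame(time = schedule$tau_E + seq_len(n) - 1,
             species = "E", amount = amounts)
}

#' Stochastic simulation under combination immunotherapy
#'
#' Wires the killing-efficacy ramp of [k_of_t()] into the killing
#' propensity and the transfer boluses of [transfer_events()] into the
#' effector count, then runs [simulate_tauleap()]. A null schedule
#' (`delta_k = delta_E = 0`) is exactly equivalent to an untreated run
#' with the same seed.
#'
#' @param params A [base_params()] object; `params$k` is the baseline
#'   efficacy `k0`.
#' @param init Initial integer state `c(T, E)`.
#' @param schedule A [treatment_schedule()].
#' @param t_max Horizon (days).
#' @param seed Integer seed.
#' @param record_dt Recording interval (days).
#' @param eps Tau-leap control parameter.
#' @return A `cisi_trajectory` (with the schedule stored in `$schedule`).
#' @export
run_treatment <- function(params, init, schedule, t_max, seed,
                          record_dt = 1, eps = 0.03) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  kf <- k_of_t(schedule, k0 = params$k)
  sys <- build_base_reactions(params, k_fun = kf)
  tr <- simulate_tauleap(sys, init, t_max, seed = seed,
                         record_dt = record_dt,
                         events = transfer_events(schedule), eps = eps)
  tr$schedule <- schedule
  tr
}

#' Established-tumor initial state
#'
#' The deterministic coexistence state of an untreated macroscopic
#' tumor: `T` at the largest stable equilibrium (carrying capacity up to
#' the small killing correction) and `E` at its conditional equilibrium
#' `sigma / (d - m T)`, rounded to integers. Used as the starting point
#' of dose-grid experiments.
#'
#' @param params A [base_params()] object.
#' @return Integer state `c(T, E)`.
#' @export
established_tumor_state <- function(params) {
  eq <- base_equilibria(params)
  Ts <- vapply(eq, function(e) e$state[["T"]], numeric(1))
  stab <- vapply(eq, function(e) e$stability, character(1))
  big <- which(Ts > 0 & stab == "stable")
  T0 <- if (length(big)) max(Ts[big]) else 1 / params$b
  c(T = round(T0), E = round(params$sigma / (params$d - params$m * T0)))
}

#' Combination-dose grid experiment
#'
#' For every pair on the `delta_k` x `delta_E` axes, runs `n_reps`
#' replicate treatments from an established tumor and records the tumor
#' count at `eval_day`; the cell summary is the median over replicates
#' (robust to the bimodal cleared/persisting outcome). The default
#' template is the single-day combination protocol: the antibody dose is
#' administered during day 50 (killing-efficacy increments take effect
#' at the end of each treatment day, so the raised efficacy holds from
#' day 51) and the transfer bolus lands on day 51 as the ramp completes;
#' the outcome is evaluated at day 120. Administering the bolus under
#' the already-raised efficacy is what makes the two modalities
#' synergistic -- a day-50 bolus would be exhausted by the
#' immunosuppressive tumor hours before the efficacy increase arrives.
#' Individual failed runs are recorded as `NA` and flagged; the grid
#' always completes.
#'
#' @param params A [base_params()] object.
#' @param delta_k_grid,delta_E_grid Nonnegative dose axes (total
#'   killing-efficacy increase; total transferred cells).
#' @param init Initial integer state; default
#'   [established_tumor_state()].
#' @param schedule_template A [treatment_schedule()] supplying timing
#'   (`tau_k`, `delta_tau_k`, `tau_E`, `delta_tau_E`); its dose fields
#'   are overwritten by the grid values.
#' @param eval_day Evaluation day (> treatment start).
#' @param n_reps Replicates per cell.
#' @param base_seed Seed of the first replicate; each grid cell uses an
#'   independent, deterministic seed block.
#' @param record_dt Recording interval passed to the simulator.
#' @param eps Tau-leap control parameter.
#' @return Object of class `grid_result`: list with `delta_k`,
#'   `delta_E`, `median` (matrix delta_k x delta_E of median final tumor
#'   counts), `final_T` (array delta_k x delta_E x rep), `seeds`,
#'   `eval_day`, `n_failed`.
#' @export
combination_grid <- function(params, delta_k_grid, delta_E_grid,
                             init = established_tumor_state(params),
                             schedule_template = treatment_schedule(
                               tau_k = 50, delta_tau_k = 1,
                               tau_E = 51, delta_tau_E = 1),
                             eval_day = 120, n_reps = 5, base_seed = 1,
                             record_dt = 5, eps = 0.03) {
  stopifnot(length(delta_k_grid) >= 1, length(delta_E_grid) >= 1,
            all(delta_k_grid >= 0), all(delta_E_grid >= 0),
            eval_day > min(schedule_template$tau_k,
                           schedule_template$tau_E))
  nk <- length(delta_k_grid); nE <- length(delta_E_grid)
  final_T <- array(NA_real_, dim = c(nk, nE, n_reps))
  seeds <- array(NA_integer_, dim = c(nk, nE, n_reps))
  n_failed <- 0L
  for (i in seq_len(nk)) {
    for (j in seq_len(nE)) {
      sched <- schedule_template
      sched$delta_k <- delta_k_grid[i]
      sched$delta_E <- delta_E_grid[j]
      for (r in seq_len(n_reps)) {
        seed <- base_seed + ((i - 1L) * nE + (j - 1L)) * n_reps + (r - 1L)
        seeds[i, j, r] <- seed
        res <- tryCatch(
          run_treatment(params, init, sched, t_max = eval_day,
                        seed = seed, record_dt = record_dt, eps = eps),
          error = function(e) NULL)
        if (is.null(res)) {
          n_failed <- n_failed + 1L
          warning(sprintf("grid cell (%g, %g) rep %d failed",
                          delta_k_grid[i], delta_E_grid[j], r),
                  call. = FALSE)
        } else {
          final_T[i, j, r] <- res$states[nrow(res$states), "T"]
        }
      }
    }
  }
  med <- apply(final_T, c(1, 2), stats::median, na.rm = TRUE)
  dimnames(med) <- list(delta_k = signif(delta_k_grid, 6),
                        delta_E = signif(delta_E_grid, 6))
  structure(list(delta_k = delta_k_grid, delta_E = delta_E_grid,
                 median = med, final_T = final_T, seeds = seeds,
                 eval_day = eval_day, init = init,
                 schedule_template = schedule_template,
                 n_failed = n_failed),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf(
    "<dose grid> %d x %d cells, %d reps, median tumor count at day %g\n",
    length(x$delta_k), length(x$delta_E), dim(x$final_T)[3], x$eval_day))
  print(x$median)
  invisible(x)
}

#' Clearance frontier of a dose grid
#'
#' For each `delta_k`, the minimal `delta_E` on the grid whose median
#' outcome is full clearance (tumor count 0); `Inf` if no grid dose
#' clears. Along a bistability-exploiting trade-off the frontier is
#' non-increasing in `delta_k`.
#'
#' @param grid A [combination_grid()] result.
#' @return Data frame with columns `delta_k`, `min_clearing_delta_E`.
#' @export
clearance_frontier <- function(grid) {
  stopifnot(inherits(grid, "grid_result"))
  minE <- vapply(seq_along(grid$delta_k), function(i) {
    j <- which(grid$median[i, ] == 0)
    if (!length(j)) Inf else min(grid$delta_E[j])
  }, numeric(1))
  data.frame(delta_k = grid$delta_k, min_clearing_delta_E = minE)
}
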