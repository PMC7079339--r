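#' Stochastic tau-leaping simulation
#'
#' Simulates a [build_base_reactions()] system by adaptive tau-leaping
#' with exact-SSA fallback at low propensity (see `src/tauleap.cpp` for
#' the leap-control details). Counts are integer-valued and can never go
#' negative (leaps that would overshoot are rejected and retried with a
#' halved step). Tumor extinction (`T = 0`) is absorbing because every
#' tumor reaction has zero propensity there; "cleared" in this package
#' always means the integer count 0, not a threshold.
#'
#' Runs are bit-reproducible: the same `(system, init, seed, events)`
#' yields the identical trajectory.
#'
#' @param system A `reaction_system`. A time-varying killing efficacy
#'   must be a step function (as produced by [k_of_t()]); its
#'   breakpoints become in-run coefficient-change events.
#' @param init Nonnegative integer initial counts, in `system$species`
#'   order.
#' @param t_max Simulation horizon (days), > 0.
#' @param seed Integer seed for the run.
#' @param record_dt Recording interval (days); states are recorded at
#'   multiples of `record_dt` plus all event instants.
#' @param events Optional data frame of bolus additions with columns
#'   `time`, `species` (name or index), `amount` (integer cells).
#' @param eps Tau-leap error-control parameter: bound on the expected
#'   relative change of any species per leap (default 0.03; a package
#'   convention, not a quantity with a canonical value).
#' @return Object of class `cisi_trajectory`: list with `times`,
#'   `states` (matrix, one column per species), `seed`, `params`,
#'   `events`, `eps`, `record_dt`.
#' @export
#' @examples
#' sys <- build_base_reactions(base_params())
#' tr <- simulate_tauleap(sys, c(T = 100, E = 1000), t_max = 5, seed = 1)
#' tail(as.data.frame(tr))
simulate_tauleap <- function(system, init, t_max, seed,
                             record_dt = 1, events = NULL, eps = 0.03) {
  stopifnot(inherits(system, "reaction_system"),
            is.numeric(init), length(init) == length(system$species),
            all(init >= 0), all(init == round(init)),
            is.numeric(t_max), t_max > 0, record_dt > 0)
  record_times <- unique(c(seq(0, t_max, by = record_dt), t_max))

  ev_times <- numeric(0); ev_type <- integer(0)
  ev_index <- integer(0); ev_value <- numeric(0)
  if (!is.null(system$k_fun)) {
    bp <- attr(system$k_fun, "breakpoints")
    vals <- attr(system$k_fun, "values")
    if (is.null(bp) || is.null(vals)) {
      stop("time-varying killing efficacy must be a step function with ",
           "'breakpoints'/'values' attributes (see k_of_t())",
           call. = FALSE)
    }
    keep <- bp > 0 & bp <= t_max
    ev_times <- c(ev_times, bp[keep])
    ev_type <- c(ev_type, rep(0L, sum(keep)))
    ev_index <- c(ev_index, rep(system$kill_index - 1L, sum(keep)))
    ev_value <- c(ev_value, vals[keep])
  }
  if (!is.null(events) && nrow(events) > 0) {
    sp <- events$species
    if (is.character(sp)) sp <- match(sp, system$species)
    stopifnot(!anyNA(sp), all(events$amount >= 0),
              all(events$amount == round(events$amount)))
    keep <- events$time > 0 & events$time <= t_max
    ev_times <- c(ev_times, events$time[keep])
    ev_type <- c(ev_type, rep(1L, sum(keep)))
    ev_index <- c(ev_index, sp[keep] - 1L)
    ev_value <- c(ev_value, events$amount[keep])
  }
  ord <- order(ev_times)
  ev_times <- ev_times[ord]; ev_type <- ev_type[ord]
  ev_index <- ev_index[ord]; ev_value <- ev_value[ord]
  record_times <- sort(unique(c(record_times, ev_times)))

  set.seed(seed)
  res <- .tauleap_run(as.numeric(init), system$change, system$coef,
                      system$expo, record_times,
                      ev_times, ev_type, ev_index, ev_value,
                      eps, 10, 100L)
  states <- res$states
  colnames(states) <- system$species
  structure(list(times = res$times, states = states, seed = seed,
                 params = system$params, events = events,
                 eps = eps, record_dt = record_dt),
            class = "cisi_trajectory")
}

#' @export
as.data.frame.cisi_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states)
}

#' @export
print.cisi_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<trajectory> %d records over %.4g days (seed %d)\n",
              n, x$times[n], x$seed))
  cat("  final state:",
      paste(sprintf("%s=%.6g", colnames(x$states), x$states[n, ]),
            collapse = " "), "\n")
  invisible(x)
}

#' First-passage time of a trajectory
#'
#' First recorded time at which a species reaches or exceeds a level
#' (`NA` if never).
#'
#' @param trajectory A `cisi_trajectory`.
#' @param species Species name.
#' @param level Threshold count.
#' @return Time in days, or `NA`.
#' @export
first_passage <- function(trajectory, species, level) {
  i <- which(trajectory$states[, species] >= level)
  if (!length(i)) NA_real_ else trajectory$times[min(i)]
}

#' Replicate mean and standard deviation of stochastic trajectories
#'
#' Runs `n_reps` independent replicates with seeds
#' `base_seed, base_seed + 1, ..., base_seed + n_reps - 1` and returns
#' the per-time mean and standard deviation for every species.
#'
#' @inheritParams simulate_tauleap
#' @param n_reps Number of replicates, >= 2.
#' @param base_seed First replicate seed; subsequent seeds are offset by
#'   one (seed collisions are therefore impossible).
#' @return A data frame with `time` plus `<species>_mean` and
#'   `<species>_sd` columns, with attributes `n_reps` and
#'   `trajectories` (list of the individual runs).
#' @export
mean_trajectory <- function(system, init, t_max, n_reps, base_seed,
                            record_dt = 1, events = NULL, eps = 0.03) {
  stopifnot(n_reps >= 2)
  seeds <- base_seed + seq_len(n_reps) - 1L
  if (anyDuplicated(seeds)) stop("replicate seeds must be distinct",
                                 call. = FALSE)
  runs <- lapply(seeds, function(s)
    simulate_tauleap(system, init, t_max, seed = s,
                     record_dt = record_dt, events = events, eps = eps))
  times <- runs[[1]]$times
  out <- data.frame(time = times)
  for (sp in system$species) {
    mat <- vapply(runs, function(r) r$states[, sp],
                  numeric(length(times)))
    out[[paste0(sp, "_mean")]] <- rowMeans(mat)
    out[[paste0(sp, "_sd")]] <- apply(mat, 1, stats::sd)
  }
  attr(out, "n_reps") <- n_reps
  attr(out, "trajectories") <- runs
  out
}
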