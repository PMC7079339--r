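# End-to-end regeneration of the package's reference experiments. Data
# files are the contract; plotting is left to the caller.

#' Regenerate a reference experiment
#'
#' Runs one of the package's canonical pipelines end to end and writes
#' its data files (CSV plus JSON metadata sidecars, see
#' [write_run_table()]):
#'
#' * `"fig2"`: bifurcation branch table of the base model over a
#'   200-point log grid of killing efficacies spanning
#'   `[k_l/10, 10 k_u]` (bifurcation-diagram preset, `d = 2e-2`), plus
#'   the detected bifurcation intervals.
#' * `"fig3a"`: untreated stochastic growth from `T(0) = 100`,
#'   `E(0) = 1000` (standard preset) to day 120.
#' * `"fig3b"`: the combination protocol -- treatment from day 50,
#'   `delta_k = 0.1` over 21 days, `delta_E = 1e5` over 28 days,
#'   baseline `k = 1e-4` -- to day 120.
#' * `"fig4"`: combination dose grid (single-day treatment at day 50,
#'   evaluation at day 120) over log-spaced dose axes including the
#'   zero-dose edges.
#'
#' @param tag One of `"fig2"`, `"fig3a"`, `"fig3b"`, `"fig4"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Base seed for the stochastic pipelines.
#' @param grid_n,grid_reps Dose-grid resolution and replicates per cell
#'   (`"fig4"` only).
#' @return Character vector of the files written, invisibly.
#' @export
reproduce_figure <- function(tag = c("fig2", "fig3a", "fig3b", "fig4"),
                             out_dir = ".", seed = 1,
                             grid_n = 8, grid_reps = 5) {
  tag <- match.arg(tag)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (tag == "fig2") {
    p <- param_preset("fig2")
    th <- base_k_thresholds(p)
    grid <- k_log_grid(th[["k_l"]] / 10, th[["k_u"]] * 10, 200)
    bt <- sweep_branches(p, "k", grid)
    f1 <- file.path(out_dir, "fig2_branches.csv")
    write_run_table(as.data.frame(bt), f1,
                    meta = list(preset = "fig2", sweep = "k",
                                k_l = th[["k_l"]], k_u = th[["k_u"]]))
    f2 <- file.path(out_dir, "fig2_bifurcations.csv")
    write_run_table(detect_bifurcations(bt), f2,
                    meta = list(preset = "fig2"))
    files <- c(f1, f2)
  } else if (tag %in% c("fig3a", "fig3b")) {
    p <- param_preset("table1")
    init <- c(T = 100, E = 1000)
    tr <- if (tag == "fig3a") {
      sys <- build_base_reactions(p)
      simulate_tauleap(sys, init, t_max = 120, seed = seed,
                       record_dt = 0.5)
    } else {
      sched <- treatment_schedule(tau_k = 50, delta_tau_k = 21,
                                  delta_k = 1e-1,
                                  tau_E = 50, delta_tau_E = 28,
                                  delta_E = 1e5)
      run_treatment(p, init, sched, t_max = 120, seed = seed,
                    record_dt = 0.5)
    }
    f1 <- file.path(out_dir, paste0(tag, "_trajectory.csv"))
    write_run_table(as.data.frame(tr), f1,
                    meta = list(preset = "table1", seed = seed,
                                init = as.list(init),
                                schedule = if (tag == "fig3b")
                                  unclass(tr$schedule) else NULL))
    files <- f1
  } else { # fig4
    p <- param_preset("table1")
    dk <- c(0, k_log_grid(1e-3, 10^1.5, grid_n - 1))
    dE <- c(0, k_log_grid(1e4, 1e9, grid_n - 1))
    gr <- combination_grid(p, dk, dE, n_reps = grid_reps,
                           base_seed = seed)
    long <- expand.grid(rep = seq_len(grid_reps),
                        delta_E = dE, delta_k = dk)
    long <- long[, c("delta_k", "delta_E", "rep")]
    long$final_T <- as.vector(aperm(gr$final_T, c(3, 2, 1)))
    f1 <- file.path(out_dir, "fig4_grid_long.csv")
    write_run_table(long, f1,
                    meta = list(preset = "table1", seed = seed,
                                eval_day = gr$eval_day,
                                init = as.list(gr$init)))
    med <- as.data.frame(as.table(gr$median), stringsAsFactors = FALSE)
    names(med) <- c("delta_k", "delta_E", "median_final_T")
    f2 <- file.path(out_dir, "fig4_grid_median.csv")
    write_run_table(med, f2, meta = list(preset = "table1", seed = seed))
    files <- c(f1, f2)
  }
  invisible(files)
}
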