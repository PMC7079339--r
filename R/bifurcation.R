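# Parameter sweeps and branch tables: the machine-readable form of a
# bifurcation diagram in the killing efficacy (or any other scalar
# parameter).

#' Log-spaced parameter grid
#'
#' @param from,to Positive range endpoints.
#' @param n Number of grid points.
#' @return Strictly increasing numeric vector.
#' @export
k_log_grid <- function(from, to, n = 200) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}

#' Sweep a parameter and assemble the equilibrium branch table
#'
#' For each grid value the swept parameter is replaced (by constructing a
#' modified parameter copy), all equilibria are computed with the
#' model-appropriate routine, and the branches are recorded in long
#' format sorted by `T*` within each grid point. Equilibrium failures at
#' individual grid points are flagged (`ok = FALSE`) and the sweep
#' continues.
#'
#' @param params A `cisi_params` object (any of the three models).
#' @param param_name Name of the swept parameter (default `"k"`).
#' @param grid Strictly increasing vector of parameter values.
#' @return A data frame of class `branch_table` with columns
#'   `param_value`, `T_star`, `bT_star` (tumor size scaled by the
#'   carrying capacity; 1 means the tumor is at capacity), `stability`,
#'   `method`, `ok`; the sweep parameter name and grid are attached as
#'   attributes.
#' @export
#' @examples
#' p <- param_preset("fig2")
#' th <- base_k_thresholds(p)
#' bt <- sweep_branches(p, "k", k_log_grid(th["k_l"] / 10, th["k_u"] * 10, 50))
sweep_branches <- function(params, param_name = "k", grid) {
  stopifnot(inherits(params, "cisi_params"),
            param_name %in% names(params),
            is.numeric(grid), length(grid) >= 1, all(is.finite(grid)),
            !is.unsorted(grid, strictly = TRUE))
  eq_fun <- if (inherits(params, "base_params")) {
    base_equilibria
  } else if (inherits(params, "saturation_params")) {
    saturation_equilibria
  } else {
    nkctl_equilibria
  }
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    rows[[i]] <- tryCatch({
      repl <- stats::setNames(list(grid[i]), param_name)
      pi <- do.call(update_params, c(list(params), repl))
      tab <- equilibria_table(eq_fun(pi))
      data.frame(param_value = grid[i],
                 T_star = tab$T_star,
                 bT_star = pi$b * tab$T_star,
                 stability = tab$stability,
                 method = tab$method,
                 ok = TRUE)
    }, error = function(e) {
      data.frame(param_value = grid[i], T_star = NA_real_,
                 bT_star = NA_real_, stability = NA_character_,
                 method = NA_character_, ok = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  attr(out, "sweep_param") <- param_name
  attr(out, "grid") <- grid
  class(out) <- c("branch_table", class(out))
  out
}

#' Locate bifurcations in a branch table
#'
#' Returns the consecutive grid intervals across which the number of
#' distinct equilibria changes. On a sufficiently fine grid these
#' intervals bracket the true bifurcation points (for the base model,
#' the closed-form thresholds of [base_k_thresholds()]).
#'
#' @param table A `branch_table` from [sweep_branches()].
#' @return Data frame with columns `lower`, `upper` (grid interval) and
#'   `count_before`, `count_after` (equilibrium counts on either side).
#'   Zero rows if the count never changes.
#' @export
detect_bifurcations <- function(table) {
  stopifnot(inherits(table, "branch_table"))
  grid <- attr(table, "grid")
  if (length(grid) < 2) stop("need at least 2 grid points", call. = FALSE)
  counts <- vapply(grid, function(g) {
    sub <- table[table$param_value == g & table$ok, , drop = FALSE]
    nrow(sub)
  }, integer(1))
  chg <- which(diff(counts) != 0)
  data.frame(lower = grid[chg], upper = grid[chg + 1L],
             count_before = counts[chg], count_after = counts[chg + 1L])
}
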