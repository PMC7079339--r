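# Linear stability analysis of fixed points. Tolerances (package-wide
# defaults): residual tolerance 1e-6 relative to the state scale, an
# eigenvalue dead band of 1e-10 day^-1 around zero, and a deduplication
# tolerance of 1e-4 relative. Chosen for double-precision headroom at
# cell counts up to ~1e9; none of these is model-specific.

.tol_resid <- 1e-6
.tol_eig <- 1e-10
.tol_dedup <- 1e-4

# central finite-difference Jacobian, step scaled per component
num_jacobian <- function(f, x, scale = NULL) {
  n <- length(x)
  if (is.null(scale)) scale <- max(abs(x), 1)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- max(abs(x[j]), 1e-6 * scale, 1e-8) * 1e-6
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  dimnames(J) <- list(names(x), names(x))
  J
}

#' Linear stability of a fixed point
#'
#' Verifies that `point` is (numerically) a fixed point of the model,
#' linearizes by central finite differences, and classifies the point by
#' the real parts of the Jacobian eigenvalues: `"stable"` if all real
#' parts are below `-tol_eig`, `"unstable"` if any exceeds `+tol_eig`,
#' otherwise `"marginal"`.
#'
#' @param point State vector at the candidate equilibrium.
#' @param params A `cisi_params` object.
#' @param tol_resid Residual tolerance, relative to `max(1, max(|point|))`.
#' @param tol_eig Eigenvalue dead band (day^-1).
#' @return A list with `stability` (label), `eigenvalues` (complex),
#'   `jacobian`, and `residual` (max abs RHS component).
#' @export
stability_of <- function(point, params, tol_resid = .tol_resid,
                         tol_eig = .tol_eig) {
  point <- check_state(point, params)
  f <- model_rhs(params)
  resid <- max(abs(f(point)))
  scale <- max(1, abs(point))
  if (resid > tol_resid * scale) {
    stop(sprintf(
      "stability_of: point is not an equilibrium (|rhs| = %.3g > %.3g)",
      resid, tol_resid * scale), call. = FALSE)
  }
  J <- num_jacobian(f, point, scale = scale)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  label <- if (all(re < -tol_eig)) {
    "stable"
  } else if (any(re > tol_eig)) {
    "unstable"
  } else {
    "marginal"
  }
  list(stability = label, eigenvalues = ev, jacobian = J, residual = resid)
}

# package a located fixed point with its classification
.make_equilibrium <- function(state, params, method) {
  st <- stability_of(state, params)
  structure(list(state = check_state(state, params),
                 stability = st$stability,
                 method = method,
                 eigenvalues = st$eigenvalues,
                 residual = st$residual),
            class = "cisi_equilibrium")
}

#' @export
print.cisi_equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium [%s, %s]> %s  (max Re eig = %.3g)\n",
              x$stability, x$method,
              paste(sprintf("%s=%.6g", names(x$state), x$state),
                    collapse = " "),
              max(Re(x$eigenvalues))))
  invisible(x)
}

#' Tabulate a list of equilibria
#'
#' @param x A list of `cisi_equilibrium` objects as returned by
#'   [base_equilibria()], [saturation_equilibria()] or [nkctl_equilibria()].
#' @param ... Unused.
#' @return A data frame with one row per equilibrium: the state
#'   components, `stability`, `method` and `eigen_real_max`.
#' @export
equilibria_table <- function(x, ...) {
  stopifnot(is.list(x))
  if (!length(x)) {
    return(data.frame(T_star = numeric(0), stability = character(0),
                      method = character(0), eigen_real_max = numeric(0)))
  }
  states <- do.call(rbind, lapply(x, function(e) e$state))
  colnames(states) <- paste0(colnames(states), "_star")
  data.frame(states,
             stability = vapply(x, function(e) e$stability, character(1)),
             method = vapply(x, function(e) e$method, character(1)),
             eigen_real_max = vapply(x, function(e)
               max(Re(e$eigenvalues)), numeric(1)),
             row.names = NULL)
}

# collapse near-duplicate scalar roots (relative tolerance)
.dedup_roots <- function(x, tol = .tol_dedup) {
  if (!length(x)) return(x)
  x <- sort(x)
  keep <- c(TRUE, diff(x) > tol * pmax(1, abs(x[-length(x)])))
  x[keep]
}
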