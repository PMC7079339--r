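# Adaptive explicit Runge-Kutta integration. No ODE-solver package is
# assumed to be available at run time, so a Dormand-Prince 5(4) pair is
# implemented here. The tumor-immune systems are only mildly stiff (fast
# effector turnover near carrying capacity); step-size control handles
# this at the cost of small steps, which is acceptable for the desk-scale
# horizons used in this package.

# Butcher tableau, Dormand & Prince (1980)
.dp_c <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
.dp_a <- list(
  numeric(0),
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
.dp_b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.dp_b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)

#' Integrate an ODE system with adaptive step size
#'
#' Dormand-Prince 5(4) integrator with proportional step control, used as
#' the deterministic reference for the stochastic simulator and to confirm
#' stability labels by forward integration.
#'
#' @param f Derivative function `f(t, y) -> dy/dt` (numeric vector).
#' @param y0 Initial state.
#' @param times Increasing vector of output times; `times[1]` is the
#'   initial time.
#' @param rtol,atol Relative and absolute local error tolerances.
#' @param hmax Maximum step size (default: span of `times`).
#' @param max_steps Safety cap on accepted + rejected steps.
#' @return A matrix with a `time` column followed by one column per state
#'   component, one row per requested time.
#' @export
#' @examples
#' p <- base_params()
#' f <- function(t, y) base_rhs(y, p)
#' out <- ode_integrate(f, c(T = 100, E = 1000), times = 0:10)
ode_integrate <- function(f, y0, times, rtol = 1e-8, atol = 1e-8,
                          hmax = NULL, max_steps = 1e7) {
  stopifnot(is.numeric(times), length(times) >= 2, all(diff(times) > 0))
  n <- length(y0)
  out <- matrix(NA_real_, nrow = length(times), ncol = n + 1)
  colnames(out) <- c("time", if (!is.null(names(y0))) names(y0) else
    paste0("y", seq_len(n)))
  t <- times[1]
  y <- as.numeric(y0)
  out[1, ] <- c(t, y)
  if (is.null(hmax)) hmax <- diff(range(times))
  h <- min(hmax, (times[2] - times[1]) / 10)
  k <- matrix(0, nrow = 7, ncol = n)
  k[1, ] <- f(t, y)
  next_i <- 2L
  steps <- 0L
  while (next_i <= length(times)) {
    if ((steps <- steps + 1L) > max_steps) {
      stop("ode_integrate: step limit exceeded", call. = FALSE)
    }
    h <- min(h, hmax, times[length(times)] - t)
    for (s in 2:7) {
      ys <- y + h * drop(.dp_a[[s]] %*% k[seq_len(s - 1), , drop = FALSE])
      k[s, ] <- f(t + .dp_c[s] * h, ys)
    }
    y5 <- y + h * drop(.dp_b5 %*% k)
    y4 <- y + h * drop(.dp_b4 %*% k)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (!is.finite(err)) err <- 2 # force rejection on overflow
    if (err <= 1) {
      t_new <- t + h
      # dense-ish output: fill requested times inside (t, t_new] by
      # cubic Hermite interpolation on the accepted step
      while (next_i <= length(times) && times[next_i] <= t_new + 1e-12 * h) {
        th <- (times[next_i] - t) / h
        f0 <- k[1, ]; f1 <- k[7, ] # FSAL: k7 = f(t_new, y5)
        h00 <- (1 + 2 * th) * (1 - th)^2
        h10 <- th * (1 - th)^2
        h01 <- th^2 * (3 - 2 * th)
        h11 <- th^2 * (th - 1)
        out[next_i, ] <- c(times[next_i],
                           h00 * y + h10 * h * f0 + h01 * y5 + h11 * h * f1)
        next_i <- next_i + 1L
      }
      t <- t_new
      y <- y5
      k[1, ] <- k[7, ] # first-same-as-last
      if (t >= times[length(times)]) break
    }
    h <- h * min(5, max(0.2, 0.9 * err^(-1 / 5)))
    if (h < 1e-14 * max(1, abs(t))) {
      stop("ode_integrate: step size underflow", call. = FALSE)
    }
  }
  out
}

#' Solve a model ODE from an initial state
#'
#' Convenience wrapper around [ode_integrate()] for a `cisi_params` model.
#'
#' @param params A `cisi_params` object.
#' @param init Initial state (see [check_state()]).
#' @param times Output times (days).
#' @param ... Passed on to [ode_integrate()].
#' @return Matrix of time and state columns.
#' @export
ode_solve <- function(params, init, times, ...) {
  init <- check_state(init, params, require_nonneg = TRUE)
  f <- model_rhs(params)
  ode_integrate(function(t, y) f(y), init, times, ...)
}
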