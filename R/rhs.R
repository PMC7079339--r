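#' Right-hand side of the base model
#'
#' Evaluates the deterministic rates of change
#' `dT/dt = a T (1 - b T) - k T E` and `dE/dt = sigma - d E + m E T`.
#'
#' @param state Numeric state `c(T, E)` (cells).
#' @param params A [base_params()] object.
#' @return Named derivative vector `c(T=, E=)` in cells day^-1.
#' @export
base_rhs <- function(state, params) {
  stopifnot(inherits(params, "base_params"))
  s <- check_state(state, params)
  T <- s[["T"]]; E <- s[["E"]]
  c(T = params$a * T * (1 - params$b * T) - params$k * T * E,
    E = params$sigma - params$d * E + params$m * E * T)
}

#' Analytic Jacobian of the base model
#'
#' Closed-form 2x2 Jacobian of [base_rhs()], used as an independent check
#' on the finite-difference linearization in [stability_of()].
#'
#' @inheritParams base_rhs
#' @return A 2x2 matrix, rows/columns ordered `(T, E)`.
#' @export
base_jacobian <- function(state, params) {
  s <- check_state(state, params)
  T <- s[["T"]]; E <- s[["E"]]
  matrix(c(params$a * (1 - 2 * params$b * T) - params$k * E, -params$k * T,
           params$m * E, -params$d + params$m * T),
         nrow = 2, byrow = TRUE, dimnames = list(c("T", "E"), c("T", "E")))
}

#' Right-hand side of the saturation model
#'
#' Evaluates `dT/dt = a T (1 - b T) - k T E` and
#' `dE/dt = sigma - d E + b_e T/(kappa_e + T) E - d_e T/(kappa_d + T) E`.
#'
#' @param state Numeric state `c(T, E)` (cells).
#' @param params A [saturation_params()] object.
#' @return Named derivative vector `c(T=, E=)` in cells day^-1.
#' @export
saturation_rhs <- function(state, params) {
  stopifnot(inherits(params, "saturation_params"))
  s <- check_state(state, params)
  T <- s[["T"]]; E <- s[["E"]]
  c(T = params$a * T * (1 - params$b * T) - params$k * T * E,
    E = params$sigma - params$d * E +
      params$b_e * T / (params$kappa_e + T) * E -
      params$d_e * T / (params$kappa_d + T) * E)
}

#' Right-hand side of the NK/CTL model
#'
#' Evaluates the three-compartment model of [nkctl_params()]. CTLs have no
#' constant supply; their only source is priming by NK-tumor encounters at
#' rate `omega * N * T`.
#'
#' @param state Numeric state `c(T, N, E)` (cells).
#' @param params An [nkctl_params()] object.
#' @return Named derivative vector `c(T=, N=, E=)` in cells day^-1.
#' @export
nkctl_rhs <- function(state, params) {
  stopifnot(inherits(params, "nkctl_params"))
  s <- check_state(state, params)
  T <- s[["T"]]; N <- s[["N"]]; E <- s[["E"]]
  c(T = params$a * T * (1 - params$b * T) - params$c * N * T -
        params$k * T * E,
    N = params$sigma - params$mu * N +
        params$b_n * T / (params$kappa_bn + T) * N -
        params$d_n * T / (params$kappa_dn + T) * N,
    E = -params$d * E +
        params$b_e * T / (params$kappa_be + T) * E -
        params$d_e * T / (params$kappa_de + T) * E +
        params$omega * N * T)
}

#' Deterministic right-hand side for a parameter set
#'
#' Dispatches to the appropriate model RHS and returns it as a function of
#' the state alone, convenient for integrators and linearization.
#'
#' @param params A `cisi_params` object.
#' @return A function `f(state) -> derivative`.
#' @export
model_rhs <- function(params) {
  f <- if (inherits(params, "base_params")) {
    base_rhs
  } else if (inherits(params, "saturation_params")) {
    saturation_rhs
  } else if (inherits(params, "nkctl_params")) {
    nkctl_rhs
  } else {
    stop("unsupported parameter class", call. = FALSE)
  }
  function(state) f(state, params)
}
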