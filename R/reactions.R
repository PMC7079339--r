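# Discrete-event representation of the base model. The net logistic
# growth a*T*(1 - b*T) is decomposed into a birth reaction (rate a*T)
# and a crowding death reaction (rate a*b*T^2) -- the simplest
# nonnegative birth-death split whose drift reproduces the ODE exactly.
# Alternative splits can be slotted in by editing this table.

#' Build the stochastic reaction system for the base model
#'
#' Six reactions on species `(T, E)`:
#' tumor birth (rate `a T`, `T + 1`), crowding death (rate `a b T^2`,
#' `T - 1`), immune killing (rate `k(t) T E`, `T - 1`), effector supply
#' (rate `sigma`, `E + 1`), effector death (rate `d E`, `E - 1`), and
#' effector modulation (rate `|m| T E`; `E - 1` for `m < 0`
#' (suppression), `E + 1` for `m > 0`). The summed propensity-weighted
#' state changes equal [base_rhs()] at every state.
#'
#' @param params A [base_params()] object.
#' @param k_fun Optional time-varying killing efficacy: a function
#'   `k(t)`, typically a step function from [k_of_t()]. `NULL` means the
#'   constant `params$k`. The stochastic engine requires piecewise
#'   constant `k(t)` (step functions carry their breakpoints as
#'   attributes); arbitrary functions are accepted for propensity
#'   evaluation only.
#' @return A list of class `reaction_system` with fields `species`,
#'   `change` (reactions x species), `coef`, `expo` (reaction orders per
#'   species), `kill_index`, `k_fun`, and the parameter snapshot.
#' @export
build_base_reactions <- function(params, k_fun = NULL) {
  stopifnot(inherits(params, "base_params"))
  k0 <- if (is.null(k_fun)) params$k else k_fun(0)
  m_change <- if (params$m >= 0) 1L else -1L
  change <- rbind(
    tumor_birth    = c(T = 1L, E = 0L),
    crowding_death = c(T = -1L, E = 0L),
    killing        = c(T = -1L, E = 0L),
    effector_supply = c(T = 0L, E = 1L),
    effector_death = c(T = 0L, E = -1L),
    modulation     = c(T = 0L, E = m_change)
  )
  coef <- c(params$a, params$a * params$b, k0,
            params$sigma, params$d, abs(params$m))
  expo <- rbind(
    tumor_birth    = c(T = 1L, E = 0L),
    crowding_death = c(T = 2L, E = 0L),
    killing        = c(T = 1L, E = 1L),
    effector_supply = c(T = 0L, E = 0L),
    effector_death = c(T = 0L, E = 1L),
    modulation     = c(T = 1L, E = 1L)
  )
  structure(list(species = c("T", "E"),
                 change = change,
                 coef = coef,
                 expo = expo,
                 kill_index = 3L,
                 k_fun = k_fun,
                 params = params),
            class = "reaction_system")
}

#' Reaction propensities at a state
#'
#' @param system A [build_base_reactions()] system.
#' @param state Nonnegative state vector in `system$species` order.
#' @param t Time (days); only relevant when the system carries a
#'   time-varying killing efficacy.
#' @return Named vector of propensities (day^-1), all `>= 0`.
#' @export
propensities <- function(system, state, t = 0) {
  stopifnot(inherits(system, "reaction_system"),
            length(state) == length(system$species), all(state >= 0))
  coef <- system$coef
  if (!is.null(system$k_fun)) coef[system$kill_index] <- system$k_fun(t)
  a <- coef
  for (i in seq_along(system$species)) {
    e <- system$expo[, i]
    a <- a * state[i]^e
  }
  stats::setNames(a, rownames(system$change))
}

#' Expected instantaneous drift of a reaction system
#'
#' The propensity-weighted sum of state-change vectors; for the base
#' system this equals [base_rhs()] identically at every state.
#'
#' @inheritParams propensities
#' @return Named drift vector (cells day^-1).
#' @export
reaction_drift <- function(system, state, t = 0) {
  a <- propensities(system, state, t)
  drop(a %*% system$change)
}
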