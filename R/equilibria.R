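# Fixed points of the three models.
#
# Base model: besides the cancer-free point (0, sigma/d), positive
# equilibria solve a quadratic in T,
#   T* = [a(m + b d) +/- sqrt(Ds)] / (2 a b m),
#   Ds = (a(m + b d))^2 - 4 a b m (a d - k sigma),
# with E* recovered from the tumor nullcline, E* = a(1 - b T*)/k.
#
# Saturation model: positive equilibria are roots of a cubic
# A T^3 + B T^2 + C T + D (coefficients below); bistability and
# multistability are decided by the cubic discriminant plus closed-form
# root-location conditions, cross-checked against numeric root counting.
#
# NK/CTL model: positive equilibria reduce to the roots of a quintic in T
# (no closed form); we assemble its coefficients numerically and use
# polyroot(), then back out N* and E* and filter for positivity.

# --- base model --------------------------------------------------------

#' Killing-efficacy thresholds of the base model
#'
#' In the immunosuppressive regime (`m < 0` and `m + b d < 0`) the base
#' model has two positive equilibria exactly for killing efficacies
#' between
#' \deqn{k_l = a d / \sigma} and
#' \deqn{k_u = k_l - \frac{(a(m+bd))^2}{4abm}\cdot\frac{1}{\sigma},}
#' bracketing the bistable window: below `k_l` a single macroscopic tumor
#' attractor exists, above `k_u` only the cancer-free state survives.
#'
#' @param params A [base_params()] object with `m < 0` and `m + b*d < 0`.
#' @return Named vector `c(k_l =, k_u =)` (cells^-1 day^-1).
#' @export
#' @examples
#' base_k_thresholds(param_preset("fig2"))
base_k_thresholds <- function(params) {
  stopifnot(inherits(params, "base_params"))
  if (params$m >= 0) {
    stop("base_k_thresholds requires m < 0 (immunosuppressive regime)",
         call. = FALSE)
  }
  if (params$m + params$b * params$d >= 0) {
    stop("base_k_thresholds requires m + b*d < 0", call. = FALSE)
  }
  k_l <- params$a * params$d / params$sigma
  k_u <- k_l - (params$a * (params$m + params$b * params$d))^2 /
    (4 * params$a * params$b * params$m) / params$sigma
  c(k_l = k_l, k_u = k_u)
}

#' All fixed points of the base model
#'
#' Returns the cancer-free point `(0, sigma/d)` plus any nonnegative
#' positive-tumor equilibria from the quadratic closed form, each with a
#' finite-difference stability label. Degenerate parameterizations are
#' handled by explicit reduced formulas rather than limits: with `k = 0`
#' the tumor decouples (logistic equilibria `T* = 0, 1/b`); with `m = 0`
#' the effector level is fixed at `sigma/d` and the tumor equation is
#' linear in `T`.
#'
#' @param params A [base_params()] object.
#' @return List of `cisi_equilibrium` objects, sorted by increasing `T*`.
#' @seealso [equilibria_table()] to tabulate the result.
#' @export
base_equilibria <- function(params) {
  stopifnot(inherits(params, "base_params"))
  a <- params$a; b <- params$b; k <- params$k
  sigma <- params$sigma; d <- params$d; m <- params$m
  pts <- list(c(T = 0, E = sigma / d))
  Ts <- if (k == 0) {
    1 / b # pure logistic; E* solved from its own nullcline below
  } else if (m == 0) {
    (1 - k * sigma / (a * d)) / b
  } else {
    Ds <- (a * (m + b * d))^2 - 4 * a * b * m * (a * d - k * sigma)
    if (Ds < 0) numeric(0) else
      (a * (m + b * d) + c(-1, 1) * sqrt(Ds)) / (2 * a * b * m)
  }
  scaleT <- 1 / b
  Ts <- Ts[is.finite(Ts) & Ts > .tol_dedup * scaleT * 1e-6]
  Ts <- .dedup_roots(Ts)
  for (T in Ts) {
    E <- if (k > 0) a * (1 - b * T) / k else sigma / (d - m * T)
    if (T >= 0 && E >= 0) pts <- c(pts, list(c(T = T, E = E)))
  }
  eq <- lapply(pts, .make_equilibrium, params = params, method = "analytic")
  eq[order(vapply(eq, function(e) e$state[["T"]], numeric(1)))]
}

#' Classify the equilibrium regime of the base model
#'
#' Under immunosuppression (`m < 0`, `m + b d < 0`) the sign pattern of
#' the quadratic roots falls into three cases as the killing efficacy
#' crosses the thresholds of [base_k_thresholds()]:
#' case `"i"` (`k > k_u`): only the cancer-free state; case `"ii"`
#' (`k < k_l`): a single macroscopic attractor (no barrier); case
#' `"iii"` (`k_l < k < k_u`): bistability with an interior unstable
#' barrier. Exact threshold hits are labelled `"marginal"`.
#'
#' @param params A [base_params()] object.
#' @return A list of class `regime_classification` with `case_label`,
#'   `n_positive_roots`, and a named logical `conditions` map
#'   (`eq5`: m < 0; `eq6`: m + bd < 0; `eq7`: k > k_l; `eq8`: k < k_u).
#' @export
classify_base_regime <- function(params) {
  th <- base_k_thresholds(params) # errors outside the plausible regime
  k <- params$k
  conditions <- c(eq5 = params$m < 0,
                  eq6 = params$m + params$b * params$d < 0,
                  eq7 = k > th[["k_l"]],
                  eq8 = k < th[["k_u"]])
  case_label <- if (k == th[["k_l"]] || k == th[["k_u"]]) {
    "marginal"
  } else if (k > th[["k_u"]]) {
    "i"
  } else if (k < th[["k_l"]]) {
    "ii"
  } else {
    "iii"
  }
  n_pos <- sum(vapply(base_equilibria(params),
                      function(e) e$state[["T"]] > 0, logical(1)))
  structure(list(case_label = case_label,
                 n_positive_roots = n_pos,
                 conditions_satisfied = conditions,
                 k_thresholds = th),
            class = "regime_classification")
}

#' @export
print.regime_classification <- function(x, ...) {
  cat(sprintf("<regime case %s> positive roots: %d; k_l=%.4g k_u=%.4g\n",
              x$case_label, x$n_positive_roots,
              x$k_thresholds[["k_l"]], x$k_thresholds[["k_u"]]))
  cond <- paste(names(x$conditions_satisfied),
                ifelse(x$conditions_satisfied, "T", "F"), sep = "=")
  cat(" ", paste(cond, collapse = " "), "\n")
  invisible(x)
}

# --- saturation model --------------------------------------------------

#' Equilibrium cubic of the saturation model
#'
#' Coefficients of the cubic `A T^3 + B T^2 + C T + D` whose positive
#' roots are the positive-tumor equilibria of the saturation model:
#' \deqn{A = -ab(d - b_e + d_e)}
#' \deqn{B = ab(b_e\kappa_d - d_e\kappa_e - d(\kappa_d+\kappa_e))
#'           + a(d_e + d - b_e) - \sigma k}
#' \deqn{C = a(d_e\kappa_e - b_e\kappa_d)
#'           + ad(\kappa_d + \kappa_e - b\kappa_d\kappa_e)
#'           - \sigma k(\kappa_d + \kappa_e)}
#' \deqn{D = \kappa_d\kappa_e(ad - \sigma k)}
#'
#' @param params A [saturation_params()] object.
#' @return Named vector `c(A=, B=, C=, D=)`.
#' @export
saturation_cubic_coeffs <- function(params) {
  stopifnot(inherits(params, "saturation_params"))
  a <- params$a; b <- params$b; k <- params$k
  sigma <- params$sigma; d <- params$d
  be <- params$b_e; ke <- params$kappa_e
  de <- params$d_e; kd <- params$kappa_d
  c(A = -a * b * (d - be + de),
    B = a * b * (be * kd - de * ke - d * (kd + ke)) +
      a * (de + d - be) - sigma * k,
    C = a * (de * ke - be * kd) + a * d * (kd + ke - b * kd * ke) -
      sigma * k * (kd + ke),
    D = kd * ke * (a * d - sigma * k))
}

# real roots of A x^3 + B x^2 + C x + D. polyroot supplies the values;
# for a true cubic the sign of the discriminant decides how many are
# real (polyroot alone can attach spurious imaginary parts of relative
# size ~1e-7 when |A| is many orders below |B|, which would miscount)
.cubic_real_roots <- function(co, im_tol = 1e-7) {
  cf <- c(co[["D"]], co[["C"]], co[["B"]], co[["A"]])
  deg <- max(which(cf != 0)) - 1L
  if (deg < 1L) return(numeric(0))
  r <- polyroot(cf[seq_len(deg + 1L)])
  if (deg == 3L) {
    A <- co[["A"]]; B <- co[["B"]]; C <- co[["C"]]; D <- co[["D"]]
    disc <- 18 * A * B * C * D - 4 * B^3 * D + B^2 * C^2 - 4 * A * C^3 -
      27 * A^2 * D^2
    if (disc >= 0) return(sort(Re(r))) # three real roots (counted with
                                       # multiplicity when disc == 0)
    return(Re(r)[which.min(abs(Im(r)))]) # one real root
  }
  sort(Re(r)[abs(Im(r)) <= im_tol * pmax(1, Mod(r))])
}

# positive-root count of the equilibrium cubic (numeric oracle route)
.cubic_n_positive <- function(co, pos_tol = 1e-9) {
  r <- .cubic_real_roots(co)
  sum(r > pos_tol * pmax(1, abs(r)))
}

# closed-form root-location expressions for a cubic with three real
# roots: value 13 is the smallest root, value 14 the middle root
# (trigonometric representation; requires B^2 - 3AC > 0 and a
# well-defined arccos argument)
.cubic_trig_exprs <- function(co, arg_tol = 1e-9) {
  A <- co[["A"]]; B <- co[["B"]]; C <- co[["C"]]; D <- co[["D"]]
  p <- B^2 - 3 * A * C
  if (p <= 0) {
    return(list(indeterminate = TRUE, reason = "B^2 - 3AC <= 0"))
  }
  arg <- (B * (2 * B^2 - 9 * A * C) + 27 * A^2 * D) /
    (6 * A * p) * sqrt(9 * A^2 / p)
  if (abs(arg) > 1 + arg_tol) {
    return(list(indeterminate = TRUE, reason = "arccos argument outside [-1,1]"))
  }
  arg <- max(-1, min(1, arg))
  amp <- 2 * sqrt(p / (9 * A^2))
  list(indeterminate = FALSE,
       expr13 = -amp * cos(acos(arg) / 3) - B / (3 * A),
       expr14 = amp * cos(acos(-arg) / 3 - 2 * pi / 3) - B / (3 * A))
}

.saturation_conditions <- function(params) {
  co <- saturation_cubic_coeffs(params)
  A <- co[["A"]]; B <- co[["B"]]; C <- co[["C"]]; D <- co[["D"]]
  disc <- 18 * A * B * C * D - 4 * B^3 * D + B^2 * C^2 - 4 * A * C^3 -
    27 * A^2 * D^2
  tr <- .cubic_trig_exprs(co)
  n_pos <- .cubic_n_positive(co)
  if (disc <= 0) {
    # fewer than three distinct real roots: the closed-form conditions
    # are determinately false, no trig branch needed
    conds <- c(eq12 = FALSE, eq13 = NA, eq14 = NA)
    list(coeffs = co, discriminant = disc, conditions = conds,
         indeterminate = FALSE,
         bistable_conditions = FALSE,
         multistable_conditions = FALSE,
         n_positive_roots = n_pos)
  } else if (tr$indeterminate) {
    list(coeffs = co, discriminant = disc,
         conditions = c(eq12 = TRUE, eq13 = NA, eq14 = NA),
         indeterminate = TRUE, reason = tr$reason,
         bistable_conditions = NA,
         multistable_conditions = NA,
         n_positive_roots = n_pos)
  } else {
    conds <- c(eq12 = TRUE, eq13 = tr$expr13 < 0, eq14 = tr$expr14 > 0)
    list(coeffs = co, discriminant = disc, conditions = conds,
         indeterminate = FALSE,
         bistable_conditions = unname(conds[["eq13"]] && conds[["eq14"]]),
         multistable_conditions = unname(!conds[["eq13"]] && tr$expr13 > 0),
         n_positive_roots = n_pos)
  }
}

#' Bistability test for the saturation model
#'
#' Bistability (exactly two positive equilibria besides `T = 0`) is
#' decided along two routes: (a) the closed-form conditions -- positive
#' cubic discriminant together with trigonometric root-location
#' inequalities placing the smallest root below zero and the middle root
#' above zero -- and (b) numeric root counting on the same cubic. When
#' the trigonometric branch is indeterminate (non-real roots or an
#' arccos argument outside `[-1, 1]`), the numeric count alone decides.
#' The two routes are expected to agree; a determinate disagreement
#' triggers a warning and the numeric verdict is authoritative.
#'
#' @param params A [saturation_params()] object.
#' @return A list of class `saturation_regime` with `bistable` (final,
#'   numeric-authoritative verdict), `bistable_conditions` (closed-form
#'   verdict, `NA` if indeterminate), `n_positive_roots`, a `conditions`
#'   map (`eq12` discriminant, `eq13`/`eq14` root locations),
#'   `indeterminate` and `agreement` flags, and the cubic `coeffs`.
#' @export
saturation_bistability <- function(params) {
  sc <- .saturation_conditions(params)
  numeric_verdict <- sc$n_positive_roots == 2L
  agreement <- if (isTRUE(sc$indeterminate)) NA else
    identical(sc$bistable_conditions, numeric_verdict)
  if (isFALSE(agreement)) {
    warning("closed-form bistability conditions disagree with numeric ",
            "root count; using the numeric verdict", call. = FALSE)
  }
  structure(c(sc, list(bistable = numeric_verdict, agreement = agreement)),
            class = "saturation_regime")
}

#' Multistability test for the saturation model
#'
#' Multistability here means four equilibria in `T` total: three positive
#' cubic roots plus the tumor-free state -- the regime admitting a
#' microscopic stable tumor (dormancy) alongside the macroscopic one.
#' The closed-form route requires a positive discriminant and the
#' smallest cubic root itself positive; numeric root counting is the
#' authoritative fallback, as in [saturation_bistability()].
#'
#' @inheritParams saturation_bistability
#' @return A list of class `saturation_regime` with `multistable`,
#'   `multistable_conditions`, and the fields of
#'   [saturation_bistability()].
#' @export
saturation_multistability <- function(params) {
  sc <- .saturation_conditions(params)
  numeric_verdict <- sc$n_positive_roots == 3L
  agreement <- if (isTRUE(sc$indeterminate)) NA else
    identical(sc$multistable_conditions, numeric_verdict)
  if (isFALSE(agreement)) {
    warning("closed-form multistability conditions disagree with numeric ",
            "root count; using the numeric verdict", call. = FALSE)
  }
  structure(c(sc, list(multistable = numeric_verdict,
                       agreement = agreement)),
            class = "saturation_regime")
}

#' @export
print.saturation_regime <- function(x, ...) {
  lab <- if (!is.null(x$bistable)) c("bistable", x$bistable) else
    c("multistable", x$multistable)
  cat(sprintf("<saturation regime> %s: %s (positive roots: %d%s)\n",
              lab[1], lab[2], x$n_positive_roots,
              if (isTRUE(x$indeterminate)) "; trig branch indeterminate"
              else ""))
  invisible(x)
}

#' All fixed points of the saturation model
#'
#' The tumor-free point `(0, sigma/d)` plus every positive real root of
#' the equilibrium cubic, with `E*` recovered from the tumor nullcline
#' (`E* = a(1 - bT*)/k` for `k > 0`) and finite-difference stability
#' labels. With `k = 0` the tumor decouples and the reduced logistic
#' forms are used.
#'
#' @param params A [saturation_params()] object.
#' @return List of `cisi_equilibrium` objects, sorted by increasing `T*`.
#' @export
saturation_equilibria <- function(params) {
  stopifnot(inherits(params, "saturation_params"))
  a <- params$a; b <- params$b; k <- params$k
  sigma <- params$sigma; d <- params$d
  E_nullcline <- function(T) {
    den <- d - params$b_e * T / (params$kappa_e + T) +
      params$d_e * T / (params$kappa_d + T)
    if (den <= 0) NA_real_ else sigma / den
  }
  pts <- list(c(T = 0, E = sigma / d))
  if (k == 0) {
    T <- 1 / b
    E <- E_nullcline(T)
    if (is.finite(E) && E >= 0) pts <- c(pts, list(c(T = T, E = E)))
  } else {
    Ts <- .cubic_real_roots(saturation_cubic_coeffs(params))
    Ts <- .dedup_roots(Ts[Ts > 1e-9 * pmax(1, abs(Ts))])
    for (T in Ts) {
      E <- a * (1 - b * T) / k
      if (E >= 0) pts <- c(pts, list(c(T = T, E = E)))
    }
  }
  eq <- lapply(pts, .make_equilibrium, params = params, method = "analytic")
  eq[order(vapply(eq, function(e) e$state[["T"]], numeric(1)))]
}

# --- NK/CTL model ------------------------------------------------------

#' Plausibility condition of the NK/CTL model
#'
#' The analogue of `m < 0` for the two-effector model:
#' \deqn{-ab\big((b_e - d_e - d)(b_n - d_n - \mu)\big) - k\sigma\omega < 0.}
#' It holds in particular when tumor cells exhaust both NK cells and
#' CTLs, i.e. `b_e - d_e - d < 0` and `b_n - d_n - mu < 0`. The condition
#' is independent of the four saturation constants.
#'
#' @param params An [nkctl_params()] object.
#' @return Logical scalar.
#' @export
nkctl_plausibility <- function(params) {
  stopifnot(inherits(params, "nkctl_params"))
  -params$a * params$b *
    ((params$b_e - params$d_e - params$d) *
       (params$b_n - params$d_n - params$mu)) -
    params$k * params$sigma * params$omega < 0
}

# ascending-power polynomial product
.poly_mul <- function(p, q) {
  r <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    idx <- i:(i + length(q) - 1L)
    r[idx] <- r[idx] + p[i] * q
  }
  r
}

#' Quintic equilibrium polynomial of the NK/CTL model
#'
#' Eliminating `N` and `E` through their nullclines reduces the positive
#' fixed points of the NK/CTL model to roots of a fifth-order polynomial
#' in `T` (no general closed form exists). With
#' `Q_N(T) = mu(kbn+T)(kdn+T) - b_n T(kdn+T) + d_n T(kbn+T)` and
#' `Q_E(T)` defined analogously for the CTL rates, the polynomial is
#' \deqn{P(T) = a(1-bT)\,Q_N Q_E - c\sigma(\kappa_{bn}+T)(\kappa_{dn}+T)Q_E
#'   - k\omega\sigma T(\kappa_{bn}+T)(\kappa_{dn}+T)(\kappa_{be}+T)(\kappa_{de}+T),}
#' assembled here by numeric coefficient convolution. Roots at which
#' `Q_N` or `Q_E` vanish are poles of the nullclines, not equilibria,
#' and are filtered out by [nkctl_equilibria()].
#'
#' @param params An [nkctl_params()] object.
#' @return Numeric vector of polynomial coefficients in ascending powers
#'   of `T` (length 6).
#' @export
nkctl_quintic_coeffs <- function(params) {
  stopifnot(inherits(params, "nkctl_params"))
  p <- params
  pbn <- c(p$kappa_bn, 1) # (kappa_bn + T)
  pdn <- c(p$kappa_dn, 1)
  pbe <- c(p$kappa_be, 1)
  pde <- c(p$kappa_de, 1)
  QN <- p$mu * .poly_mul(pbn, pdn) +
    c(0, -p$b_n * p$kappa_dn + p$d_n * p$kappa_bn, -p$b_n + p$d_n)
  QE <- p$d * .poly_mul(pbe, pde) +
    c(0, -p$b_e * p$kappa_de + p$d_e * p$kappa_be, -p$b_e + p$d_e)
  P1 <- .poly_mul(.poly_mul(c(p$a, -p$a * p$b), QN), QE)
  P2 <- .poly_mul(-p$c * p$sigma * .poly_mul(pbn, pdn), QE)
  P3 <- .poly_mul(c(0, -p$k * p$omega * p$sigma),
                  .poly_mul(.poly_mul(pbn, pdn), .poly_mul(pbe, pde)))
  n <- max(length(P1), length(P2), length(P3))
  pad <- function(x) c(x, numeric(n - length(x)))
  pad(P1) + pad(P2) + pad(P3)
}

#' All fixed points of the NK/CTL model
#'
#' The tumor-free point `(0, sigma/mu, 0)` plus every positive real root
#' of the equilibrium quintic lying inside `search_box`, with `N*` and
#' `E*` recovered from the nullclines, positivity and residual checks,
#' deduplication, and finite-difference stability labels. Roots whose
#' recovered state fails the residual check (nullcline poles, spurious
#' polyroot artifacts) are dropped with a message. At most six equilibria
#' can be returned (the quintic admits up to five positive roots).
#'
#' @param params An [nkctl_params()] object.
#' @param search_box Length-2 positive range of tumor sizes searched for
#'   interior equilibria; defaults to `c(1e-6, 2/b)`.
#' @return List of `cisi_equilibrium` objects, sorted by increasing `T*`.
#' @export
nkctl_equilibria <- function(params, search_box = NULL) {
  stopifnot(inherits(params, "nkctl_params"))
  if (is.null(search_box)) search_box <- c(1e-6, 2 / params$b)
  stopifnot(length(search_box) == 2, all(search_box > 0),
            diff(search_box) > 0)
  eq <- list(.make_equilibrium(c(T = 0, N = params$sigma / params$mu, E = 0),
                               params, method = "analytic"))
  co <- nkctl_quintic_coeffs(params)
  deg <- max(which(co != 0)) - 1L
  if (deg >= 1L) {
    r <- polyroot(co[seq_len(deg + 1L)])
    Ts <- Re(r)[abs(Im(r)) <= 1e-7 * pmax(1, Mod(r))]
    Ts <- .dedup_roots(Ts[Ts >= search_box[1] & Ts <= search_box[2]])
    f <- model_rhs(params)
    for (T in Ts) {
      den_N <- params$mu - params$b_n * T / (params$kappa_bn + T) +
        params$d_n * T / (params$kappa_dn + T)
      N <- params$sigma / den_N
      den_E <- params$d - params$b_e * T / (params$kappa_be + T) +
        params$d_e * T / (params$kappa_de + T)
      E <- params$omega * N * T / den_E
      if (!is.finite(N) || !is.finite(E) || N < 0 || E < 0) next
      st <- c(T = T, N = N, E = E)
      res <- tryCatch(.make_equilibrium(st, params, method = "numeric"),
                      error = function(e) NULL)
      if (is.null(res)) {
        message(sprintf(
          "nkctl_equilibria: dropped spurious root at T = %.6g", T))
      } else {
        eq <- c(eq, list(res))
      }
    }
  }
  eq[order(vapply(eq, function(e) e$state[["T"]], numeric(1)))]
}
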