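# Peng-Robinson and Soave-Redlich-Kwong cubic equations of state with
# two-parameter (k_ij, l_ij) van der Waals mixing rules, closed-form fugacity
# coefficients, solid-solubility equilibrium and per-isotherm regression.
#
# Both EoS are the generic two-parameter cubic
#   P = RT/(v - b) - a / [(v + d1 b)(v + d2 b)]
# with (d1, d2) = (1 + sqrt(2), 1 - sqrt(2)) for PR and (1, 0) for SRK.

.cubic_deltas <- function(eos) {
  if (eos == "pr") c(1 + sqrt(2), 1 - sqrt(2)) else c(1, 0)
}

#' Pure-component cubic-EoS parameters
#'
#' PR: a = 0.45724 R^2 Tc^2 / Pc * alpha, b = 0.0778 R Tc / Pc with
#' alpha = (1 + k (1 - sqrt(Tr)))^2, k = 0.37464 + 1.5422 w - 0.26992 w^2.
#' SRK: a = 0.42747 R^2 Tc^2 / Pc * alpha, b = 0.08664 R Tc / Pc with
#' m = 0.480 + 1.574 w - 0.176 w^2.
#'
#' @param eos `"pr"` or `"srk"`.
#' @param Tc critical temperature (K).
#' @param Pc critical pressure (Pa).
#' @param omega acentric factor.
#' @param T temperature (K).
#' @return list of class `cubic_pure_params`: `a` (Pa m6/mol2), `b` (m3/mol),
#'   `eos`, and the alpha-function slope (`k` or `m`).
#' @export
cubic_pure_params <- function(eos = c("pr", "srk"), Tc, Pc, omega, T) {
  eos <- match.arg(eos)
  stopifnot(T > 0, Tc > 0, Pc > 0)
  Tr <- T / Tc
  if (eos == "pr") {
    slope <- 0.37464 + 1.5422 * omega - 0.26992 * omega^2
    a <- 0.45724 * .R_GAS^2 * Tc^2 / Pc * (1 + slope * (1 - sqrt(Tr)))^2
    b <- 0.0778 * .R_GAS * Tc / Pc
  } else {
    slope <- 0.480 + 1.574 * omega - 0.176 * omega^2
    a <- 0.42747 * .R_GAS^2 * Tc^2 / Pc * (1 + slope * (1 - sqrt(Tr)))^2
    b <- 0.08664 * .R_GAS * Tc / Pc
  }
  structure(list(a = a, b = b, eos = eos, alpha_slope = slope),
            class = "cubic_pure_params")
}

#' Mixture a and b under two-parameter van der Waals mixing rules
#'
#' a_m = sum_ij y_i y_j sqrt(a_i a_j)(1 - k_ij),
#' b_m = sum_ij y_i y_j (b_i + b_j)/2 (1 - l_ij), with k_ii = l_ii = 0.
#'
#' @param y composition vector (sums to 1).
#' @param pures list of [cubic_pure_params()], all of the same EoS.
#' @param k_ij,l_ij binary interaction parameters (scalar, applied to every
#'   i != j pair, or full symmetric matrices).
#' @return list with `a_m`, `b_m`, and the pairwise matrices `a_ij`, `b_ij`.
#' @export
cubic_mix_params <- function(y, pures, k_ij = 0, l_ij = 0) {
  n <- length(y)
  if (abs(sum(y) - 1) > 1e-12) stop("composition must sum to 1")
  if (length(unique(vapply(pures, `[[`, "", "eos"))) != 1L)
    stop("all pure parameter sets must use the same EoS")
  a <- vapply(pures, `[[`, 0, "a"); b <- vapply(pures, `[[`, 0, "b")
  K <- if (is.matrix(k_ij)) k_ij else (1 - diag(n)) * k_ij
  L <- if (is.matrix(l_ij)) l_ij else (1 - diag(n)) * l_ij
  a_ij <- sqrt(outer(a, a)) * (1 - K)
  b_ij <- outer(b, b, function(x, z) (x + z) / 2) * (1 - L)
  list(a_m = drop(y %*% a_ij %*% y), b_m = drop(y %*% b_ij %*% y),
       a_ij = a_ij, b_ij = b_ij)
}

# Real roots of z^3 + c2 z^2 + c1 z + c0 (Cardano; deterministic, no polyroot)
.cubic_real_roots <- function(c2, c1, c0) {
  p <- c1 - c2^2 / 3
  q <- 2 * c2^3 / 27 - c2 * c1 / 3 + c0
  disc <- (q / 2)^2 + (p / 3)^3
  sh <- -c2 / 3
  if (disc > 0) {
    u <- -q / 2 + sqrt(disc); v <- -q / 2 - sqrt(disc)
    sh + sign(u) * abs(u)^(1 / 3) + sign(v) * abs(v)^(1 / 3)
  } else if (disc == 0) {
    if (q == 0) rep(sh, 1) else unique(c(sh + 2 * (-q / 2)^(1 / 3),
                                         sh - (-q / 2)^(1 / 3)))
  } else {
    r <- sqrt(-p^3 / 27)
    th <- acos(max(-1, min(1, -q / 2 / r)))
    sh + 2 * sqrt(-p / 3) * cos((th + c(0, 2, 4) * pi) / 3)
  }
}

#' Solve the cubic equation of state for the compressibility factor
#'
#' Dimensionless form with A = a_m P / (RT)^2, B = b_m P / (RT). Among real
#' roots Z > B the root of minimum Gibbs energy is selected (the standard
#' unambiguous criterion: the candidate minimizing
#' Z - 1 - ln(Z - B) - A/(B(d1-d2)) ln((Z + d1 B)/(Z + d2 B)), whose
#' difference between roots equals the molar Gibbs-energy difference in RT
#' units at fixed T, P and composition).
#'
#' @param eos `"pr"` or `"srk"`.
#' @param A,B dimensionless EoS parameters; `B >= 0`.
#' @return list with `Z` (selected root), `n_real` (count of real roots > B),
#'   `roots` (all real roots > B).
#' @export
cubic_solve_z <- function(eos = c("pr", "srk"), A, B) {
  eos <- match.arg(eos)
  stopifnot(B >= 0)
  if (eos == "pr") {
    r <- .cubic_real_roots(-(1 - B), A - 3 * B^2 - 2 * B, -(A * B - B^2 - B^3))
  } else {
    r <- .cubic_real_roots(-1, A - B - B^2, -A * B)
  }
  r <- sort(r[is.finite(r) & r > B])
  if (length(r) == 0L) stop("unphysical state: no real root Z > B")
  if (length(r) > 1L && B > 0) {
    d <- .cubic_deltas(eos)
    g <- r - 1 - log(r - B) -
      A / (B * (d[1] - d[2])) * log((r + d[1] * B) / (r + d[2] * B))
    z <- r[which.min(g)]
  } else z <- r[length(r)]
  list(Z = z, n_real = length(r), roots = r)
}

#' Fugacity coefficients from a cubic EoS with vdW2 mixing rules
#'
#' Closed-form ln phi_i for the generic two-parameter cubic with
#' composition-dependent a_m and b_m (quadratic b mixing makes the partial
#' molar covolume bbar_i = 2 sum_j y_j b_ij - b_m), obtained from the
#' mole-number derivative of the residual Helmholtz energy. Verified against
#' numerical integration of the defining volume integral in the test suite.
#'
#' @param eos `"pr"` or `"srk"`.
#' @param T temperature (K).
#' @param P pressure (Pa).
#' @param y composition vector.
#' @param pures list of [cubic_pure_params()] evaluated at `T`.
#' @param k_ij,l_ij binary interaction parameters.
#' @return list with `ln_phi` (vector), `phi`, `Z`, `v` (molar volume m3/mol),
#'   `n_real`.
#' @export
cubic_fugacity <- function(eos = c("pr", "srk"), T, P, y, pures,
                           k_ij = 0, l_ij = 0) {
  eos <- match.arg(eos)
  mx <- cubic_mix_params(y, pures, k_ij, l_ij)
  a_m <- mx$a_m; b_m <- mx$b_m
  d <- .cubic_deltas(eos); d1 <- d[1]; d2 <- d[2]
  A <- a_m * P / (.R_GAS * T)^2
  B <- b_m * P / (.R_GAS * T)
  zs <- cubic_solve_z(eos, A, B)
  v <- zs$Z * .R_GAS * T / P
  abar <- 2 * drop(mx$a_ij %*% y)
  bbar <- 2 * drop(mx$b_ij %*% y) - b_m
  RT <- .R_GAS * T
  lg <- log((v + d1 * b_m) / (v + d2 * b_m))
  ln_phi <- log(v / (v - b_m)) + bbar / (v - b_m) -
    (abar / (RT * b_m * (d1 - d2)) - a_m * bbar / (RT * b_m^2 * (d1 - d2))) * lg -
    a_m * bbar / (RT * b_m * (d1 - d2)) *
      (d1 / (v + d1 * b_m) - d2 / (v + d2 * b_m)) -
    log(zs$Z)
  list(ln_phi = ln_phi, phi = exp(ln_phi), Z = zs$Z, v = v, n_real = zs$n_real)
}

#' Solid-solute solubility in a supercritical solvent from a cubic EoS
#'
#' Solves the solid-fluid equilibrium
#' y2 = (P_sub / P) (1 / phi2(T, P, y)) exp(v_s (P - P_sub) / RT)
#' (saturated-vapor fugacity coefficient taken as 1 at the tiny sublimation
#' pressures of drug-like solids) by damped fixed-point iteration in y2 from
#' 1e-8, damping factor 0.5 when oscillation is detected, relative tolerance
#' 1e-10, at most 200 iterations.
#'
#' @param eos `"pr"` or `"srk"`.
#' @param T temperature (K); must be supercritical for the solvent.
#' @param P pressure (Pa).
#' @param solute a [solute_properties()].
#' @param solvent a [solvent_properties()].
#' @param k_ij,l_ij binary interaction parameters (solvent = component 1,
#'   solute = component 2).
#' @return solute mole fraction y2.
#' @export
cubic_solid_solubility <- function(eos = c("pr", "srk"), T, P, solute, solvent,
                                   k_ij = 0, l_ij = 0) {
  eos <- match.arg(eos)
  if (T <= solvent$Tc || P <= 0) stop("state must be supercritical for the solvent")
  pures <- list(cubic_pure_params(eos, solvent$Tc, solvent$Pc, solvent$omega, T),
                cubic_pure_params(eos, solute$Tc, solute$Pc, solute$omega, T))
  P_sub <- sublimation_pressure(solute, T)
  pref <- P_sub / P * exp(solute$v_solid * (P - P_sub) / (.R_GAS * T))
  y2 <- 1e-8; y_prev <- NA_real_
  for (it in seq_len(200L)) {
    fg <- cubic_fugacity(eos, T, P, c(1 - y2, y2), pures, k_ij, l_ij)
    y_new <- pref / fg$phi[2]
    if (!is.finite(y_new) || y_new <= 0)
      stop("solid_solubility iteration produced non-physical y2 at iteration ", it)
    if (y_new >= 1) stop("unphysical result: y2 >= 1")
    if (abs(y_new - y2) <= 1e-10 * y2) return(y_new)
    if (!is.na(y_prev) && (y_new - y2) * (y2 - y_prev) < 0)
      y_new <- 0.5 * (y_new + y2)   # damp detected oscillation
    y_prev <- y2; y2 <- y_new
  }
  stop("solid_solubility did not converge in 200 iterations (last y2 = ", y2, ")")
}

#' Regress (k_ij, l_ij) of a cubic EoS against one isotherm
#'
#' Minimizes AARD of the predicted solubilities over (k_ij, l_ij) in
#' `bounds` (default [-1, 1]^2) by deterministic multi-start Nelder-Mead from
#' a fixed 5 x 5 start grid; no randomness, repeated calls agree bitwise.
#'
#' @param eos `"pr"` or `"srk"`.
#' @param dataset a [solubility_dataset()] restricted to (or filtered for) one
#'   temperature; >= 3 points required.
#' @param solute a [solute_properties()].
#' @param solvent a [solvent_properties()].
#' @param T_iso isotherm temperature (K); defaults to the dataset's single
#'   temperature.
#' @param bounds length-2 list or vector c(lo, hi) applied to both parameters.
#' @return object of class `cubic_isotherm_fit`: `T`, `eos`, `k_ij`, `l_ij`,
#'   `stats`, `y_calc`.
#' @export
fit_cubic_isotherm <- function(eos = c("pr", "srk"), dataset, solute, solvent,
                               T_iso = NULL, bounds = c(-1, 1)) {
  eos <- match.arg(eos)
  stopifnot(inherits(dataset, "solubility_dataset"))
  if (is.null(T_iso)) {
    Ts <- unique(dataset$T_K)
    if (length(Ts) != 1L) stop("dataset spans several temperatures; give T_iso")
    T_iso <- Ts
  }
  di <- dataset[abs(dataset$T_K - T_iso) < 1e-6, , drop = FALSE]
  if (nrow(di) < 3L) stop("need >= 3 points at the isotherm")
  P_pa <- di$P_MPa * 1e6
  lo <- bounds[1]; hi <- bounds[2]
  obj <- function(p) {
    if (any(p <= lo) || any(p >= hi)) return(1e8)
    yc <- tryCatch(
      vapply(P_pa, function(P)
        cubic_solid_solubility(eos, T_iso, P, solute, solvent, p[1], p[2]),
        numeric(1)),
      error = function(e) NULL)
    if (is.null(yc) || any(!is.finite(yc))) return(1e8)
    aard(di$y, yc)
  }
  grid1 <- seq(lo, hi, length.out = 7)[2:6]   # interior 5-point grid
  best <- NULL
  for (k0 in grid1) for (l0 in grid1) {
    o <- stats::optim(c(k0, l0), obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-12))
  if (best$value >= 1e8) stop("all optimizer starts failed for the isotherm fit")
  yc <- vapply(P_pa, function(P)
    cubic_solid_solubility(eos, T_iso, P, solute, solvent,
                           best$par[1], best$par[2]), numeric(1))
  structure(list(T = T_iso, eos = eos, k_ij = best$par[1], l_ij = best$par[2],
                 stats = fit_statistics(di$y, yc, 2L), y_calc = yc),
            class = "cubic_isotherm_fit")
}

#' @export
print.cubic_isotherm_fit <- function(x, ...) {
  cat(sprintf("%s isotherm fit at %.1f K: k_ij = %.4f, l_ij = %.4f\n",
              toupper(x$eos), x$T, x$k_ij, x$l_ij))
  print(x$stats)
  invisible(x)
}
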