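# The four semi-empirical density-based solubility correlations, their
# deterministic fitting, the derived dissolution enthalpies, the MST
# self-consistency transform, and crossover-pressure detection.
#
# Model forms (y = solute mole fraction, rho = CO2 density kg/m3, T in K,
# P in bar inside the Bartle and MST products -- the convention of the
# Bartle-model literature; P_ref = 1 bar, rho_ref = 700 kg/m3):
#   chrastil: ln y = a0 + a1 ln rho + a2 / T
#   kj      : ln y = a0 + a1 rho    + a2 / T        (Kumar-Johnston)
#   bartle  : ln(y P / P_ref) = a0 + a1 / T + a2 (rho - rho_ref)
#   mst     : T ln(y P) = a0 + a1 rho + a2 T        (Mendez-Santiago-Teja)

.DENSITY_MODELS <- c("chrastil", "bartle", "mst", "kj")

#' Parameter set for a density-based solubility model
#'
#' @param model_id one of `"chrastil"`, `"bartle"`, `"mst"`, `"kj"`.
#' @param a0,a1,a2 model coefficients. The temperature coefficient (the one
#'   divided by T, or multiplying T for MST) is `a2` for chrastil/kj/mst and
#'   `a1` for bartle.
#' @param P_ref reference pressure in bar (Bartle only).
#' @param rho_ref reference density in kg/m3 (Bartle only).
#' @return object of class `density_model_params`.
#' @export
density_model_params <- function(model_id, a0, a1, a2, P_ref = 1, rho_ref = 700) {
  model_id <- match.arg(model_id, .DENSITY_MODELS)
  stopifnot(P_ref > 0, rho_ref > 0)
  structure(list(model_id = model_id, a0 = a0, a1 = a1, a2 = a2,
                 P_ref = P_ref, rho_ref = rho_ref),
            class = "density_model_params")
}

#' Predict mole-fraction solubility from a density-based model
#'
#' @param params a [density_model_params()].
#' @param T temperature (K).
#' @param P pressure (MPa); converted to bar internally where the model form
#'   contains the product yP.
#' @param rho CO2 density (kg/m3).
#' @return predicted solute mole fraction (vectorized over T/P/rho).
#' @export
predict_density_model <- function(params, T, P, rho) {
  stopifnot(inherits(params, "density_model_params"))
  if (any(T <= 0) || any(P <= 0) || any(rho <= 0))
    stop("domain error: T, P, rho must be positive")
  P_bar <- P * 10
  with(params, switch(model_id,
    chrastil = exp(a0 + a1 * log(rho) + a2 / T),
    kj       = exp(a0 + a1 * rho + a2 / T),
    bartle   = (P_ref / P_bar) * exp(a0 + a1 / T + a2 * (rho - rho_ref)),
    mst      = exp((a0 + a1 * rho + a2 * T) / T) / P_bar))
}

# Linearized design/response for each model: every model is exactly linear in
# (a0, a1, a2) after a known transform of y, which provides both the
# closed-form sse_log optimum and deterministic starting points for the
# AARD minimization.
.dm_linearized <- function(model_id, T, P_bar, rho, y,
                           P_ref = 1, rho_ref = 700) {
  switch(model_id,
    chrastil = list(z = log(y),             X = cbind(1, log(rho), 1 / T)),
    kj       = list(z = log(y),             X = cbind(1, rho, 1 / T)),
    bartle   = list(z = log(y * P_bar / P_ref), X = cbind(1, 1 / T, rho - rho_ref)),
    mst      = list(z = T * log(y * P_bar), X = cbind(1, rho, T)))
}

#' Fit a density-based model to a solubility dataset
#'
#' The default objective minimizes AARD on the mole-fraction scale (the
#' statistic used to rank these models); `"sse_log"` minimizes the sum of
#' squared residuals of the model's linearized form, which has a closed-form
#' least-squares solution. The AARD minimization is a deterministic
#' multi-start Nelder-Mead: starts are the linearized least-squares solution
#' plus profile starts in which the temperature coefficient is scaled over a
#' fixed factor grid and the remaining coefficients re-solved by least
#' squares. Repeated calls agree bitwise; no randomness is used.
#'
#' @param model_id one of `"chrastil"`, `"bartle"`, `"mst"`, `"kj"`.
#' @param dataset a [solubility_dataset()] with at least 2 temperatures and
#'   4 points.
#' @param objective `"aard"` (default) or `"sse_log"`.
#' @param P_ref,rho_ref Bartle reference pressure (bar) and density (kg/m3).
#' @return object of class `density_model_fit`: `params`
#'   ([density_model_params()]), `stats` ([fit_statistics()]), `residuals`
#'   (per-point relative deviations (y_calc - y_exp)/y_exp), `objective`.
#' @export
fit_density_model <- function(model_id, dataset, objective = c("aard", "sse_log"),
                              P_ref = 1, rho_ref = 700) {
  model_id <- match.arg(model_id, .DENSITY_MODELS)
  objective <- match.arg(objective)
  stopifnot(inherits(dataset, "solubility_dataset"))
  if (length(unique(dataset$T_K)) < 2L || nrow(dataset) < 4L)
    stop("need >= 2 temperatures and >= 4 points")
  T <- dataset$T_K; P <- dataset$P_MPa; rho <- dataset$rho_kg_m3; y <- dataset$y
  P_bar <- P * 10
  lin <- .dm_linearized(model_id, T, P_bar, rho, y, P_ref, rho_ref)
  beta_ls <- qr.coef(qr(lin$X), lin$z)

  mk_params <- function(b) density_model_params(model_id, b[1], b[2], b[3],
                                                P_ref, rho_ref)
  if (objective == "sse_log") {
    beta <- beta_ls
  } else {
    obj <- function(b) {
      yc <- predict_density_model(mk_params(b), T, P, rho)
      if (any(!is.finite(yc))) return(1e10)
      aard(y, yc)
    }
    # profile starts: scale the temperature coefficient (index 3, except
    # bartle where it is index 2) and re-solve the rest by least squares
    it <- if (model_id == "bartle") 2L else 3L
    starts <- list(beta_ls)
    for (f in c(0.8, 0.9, 0.95, 1.05, 1.1, 1.15, 1.2, 1.3)) {
      b <- beta_ls
      b[it] <- beta_ls[it] * f
      rest <- qr.coef(qr(lin$X[, -it, drop = FALSE]),
                      lin$z - lin$X[, it] * b[it])
      b[-it] <- rest
      starts <- c(starts, list(b))
    }
    best <- NULL
    for (s in starts) {
      o <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-13))
      if (is.null(best) || o$value < best$value) best <- o
    }
    # polish restarts from the incumbent until no further improvement
    repeat {
      o <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-13))
      if (o$value >= best$value - 1e-12) break
      best <- o
    }
    if (!is.finite(best$value))
      stop("optimizer failed to converge; best objective ", best$value)
    beta <- best$par
  }
  beta <- unname(beta)
  params <- mk_params(beta)
  yc <- predict_density_model(params, T, P, rho)
  structure(list(params = params,
                 stats = fit_statistics(y, yc, 3L),
                 residuals = (yc - y) / y,
                 objective = objective),
            class = "density_model_fit")
}

#' @export
print.density_model_fit <- function(x, ...) {
  cat(sprintf("%s fit (objective %s): a0 = %.6g, a1 = %.6g, a2 = %.6g\n",
              x$params$model_id, x$objective,
              x$params$a0, x$params$a1, x$params$a2))
  print(x$stats)
  invisible(x)
}

#' Dissolution enthalpies from Chrastil and Bartle fits
#'
#' The Chrastil 1/T coefficient carries the apparent total heat of
#' dissolution, dH_total = -R a2(chrastil); the Bartle 1/T coefficient the
#' vaporization (sublimation) enthalpy, dH_vap = -R a1(bartle); the solvation
#' heat is their difference dH_sol = dH_total - dH_vap (negative, exothermic,
#' for favorable solute-solvent interactions). R = 8.314 J/mol/K; results in
#' kJ/mol.
#'
#' @param chrastil_fit,bartle_fit [fit_density_model()] results for the named
#'   models.
#' @return list of class `derived_enthalpies` with `dH_total`, `dH_vap`,
#'   `dH_sol` in kJ/mol.
#' @export
derive_enthalpies <- function(chrastil_fit, bartle_fit) {
  stopifnot(chrastil_fit$params$model_id == "chrastil",
            bartle_fit$params$model_id == "bartle")
  dH_total <- -.R_GAS * chrastil_fit$params$a2 / 1000
  dH_vap <- -.R_GAS * bartle_fit$params$a1 / 1000
  structure(list(dH_total = dH_total, dH_vap = dH_vap,
                 dH_sol = dH_total - dH_vap),
            class = "derived_enthalpies")
}

#' @export
print.derived_enthalpies <- function(x, ...) {
  cat(sprintf("dH_total = %.2f, dH_vap = %.2f, dH_sol = %.2f kJ/mol\n",
              x$dH_total, x$dH_vap, x$dH_sol))
  invisible(x)
}

#' MST self-consistency transform
#'
#' Returns the points (rho_i, T_i ln(y_i P_i) - a2 T_i), with P in bar, which
#' collapse onto a single straight line in density for data consistent with
#' the MST model regardless of temperature. The attached linear-regression R2
#' quantifies the collinearity.
#'
#' @param dataset a [solubility_dataset()].
#' @param mst_fit a fitted MST model from [fit_density_model()].
#' @return data frame with columns `rho` and `value`, attribute `r2_line`.
#' @export
mst_consistency_points <- function(dataset, mst_fit) {
  stopifnot(inherits(dataset, "solubility_dataset"),
            mst_fit$params$model_id == "mst")
  if (nrow(dataset) < 2L) stop("need >= 2 points for a line")
  P_bar <- dataset$P_MPa * 10
  v <- dataset$T_K * log(dataset$y * P_bar) - mst_fit$params$a2 * dataset$T_K
  out <- data.frame(rho = dataset$rho_kg_m3, value = v)
  fit <- stats::lm(value ~ rho, data = out)
  ss_tot <- sum((v - mean(v))^2)
  attr(out, "r2_line") <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  out
}

#' Locate the crossover-pressure interval of a solubility dataset
#'
#' Below the crossover pressure solubility decreases with temperature (the
#' solvent-density effect dominates); above it solubility increases with
#' temperature (the solute vapor-pressure effect dominates). The crossover is
#' reported as the interval between the adjacent grid pressures at which the
#' sign of the Spearman correlation of y with T flips from negative to
#' positive -- the data sit on a pressure grid, and interpolating a single
#' crossover point would overstate the resolution.
#'
#' @param dataset a [solubility_dataset()] with >= 2 isotherms sharing a
#'   pressure grid.
#' @return list with `interval` (c(P_low, P_high) in MPa, or an empty vector),
#'   `trend` (data frame of pressure vs Spearman rho of y with T), and
#'   `diagnostic` message when no sign change exists.
#' @export
find_crossover <- function(dataset) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  if (length(unique(dataset$T_K)) < 2L) stop("need >= 2 isotherms")
  Ps <- sort(unique(dataset$P_MPa))
  rho_s <- vapply(Ps, function(p) {
    sub <- dataset[dataset$P_MPa == p, ]
    if (nrow(sub) < 2L) return(NA_real_)
    stats::cor(sub$T_K, sub$y, method = "spearman")
  }, numeric(1))
  trend <- data.frame(P_MPa = Ps, spearman = rho_s)
  sgn <- sign(rho_s)
  flip <- which(sgn[-length(sgn)] < 0 & sgn[-1] > 0)
  if (length(flip) == 0L)
    return(list(interval = numeric(0), trend = trend,
                diagnostic = "no negative-to-positive sign change in y-vs-T correlation"))
  list(interval = c(Ps[flip[1]], Ps[flip[1] + 1L]), trend = trend,
       diagnostic = NULL)
}
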