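# Fit-quality statistics used by every modeling stage.

#' Average absolute relative deviation (AARD, %)
#'
#' `(100/N) * sum(|y_calc - y_exp| / y_exp)`, the standard ranking statistic
#' in the SC-CO2 solubility literature, computed on mole fractions (not in
#' log space).
#'
#' @param y_exp experimental values, all strictly positive.
#' @param y_calc model values, same length.
#' @return AARD in percent.
#' @export
aard <- function(y_exp, y_calc) {
  if (length(y_exp) != length(y_calc)) stop("length mismatch")
  if (length(y_exp) < 1L) stop("need at least one point")
  if (any(!is.finite(y_exp)) || any(y_exp <= 0))
    stop("domain error: y_exp must be positive and finite")
  100 * mean(abs(y_calc - y_exp) / y_exp)
}

#' Coefficient of determination and its adjusted form
#'
#' R2 = 1 - SS_res/SS_tot computed on the linear y scale (uniformly for all
#' models, including those fitted in log space), and
#' R2_adj = 1 - (1 - R2) (N - 1) / (N - p - 1).
#'
#' @param y_exp experimental values.
#' @param y_calc model values.
#' @param n_params number of fitted parameters p.
#' @return list with elements `r2` and `r2_adj`.
#' @export
r2_adjusted <- function(y_exp, y_calc, n_params) {
  n <- length(y_exp)
  if (n != length(y_calc)) stop("length mismatch")
  if (n <= n_params + 1L) stop("need N > n_params + 1")
  ss_tot <- sum((y_exp - mean(y_exp))^2)
  if (ss_tot == 0) stop("domain error: zero variance in y_exp")
  r2 <- 1 - sum((y_calc - y_exp)^2) / ss_tot
  list(r2 = r2, r2_adj = 1 - (1 - r2) * (n - 1) / (n - n_params - 1))
}

#' Bundle of fit statistics
#'
#' @param y_exp,y_calc experimental and fitted values.
#' @param n_params number of fitted parameters.
#' @return list of class `fit_statistics`: `aard_pct`, `r2`, `r2_adj`,
#'   `n_points`, `n_params`.
#' @export
fit_statistics <- function(y_exp, y_calc, n_params) {
  r <- r2_adjusted(y_exp, y_calc, n_params)
  structure(list(aard_pct = aard(y_exp, y_calc), r2 = r$r2, r2_adj = r$r2_adj,
                 n_points = length(y_exp), n_params = n_params),
            class = "fit_statistics")
}

#' @export
print.fit_statistics <- function(x, ...) {
  cat(sprintf("AARD = %.2f%%, R2 = %.4f, R2_adj = %.4f (N = %d, p = %d)\n",
              x$aard_pct, x$r2, x$r2_adj, x$n_points, x$n_params))
  invisible(x)
}
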