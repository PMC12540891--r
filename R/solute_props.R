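# Pure-component property sets and sublimation-pressure evaluation.

#' Pure-component property set for a solid solute
#'
#' Critical constants and acentric factor are typically group-contribution
#' estimates for drug-like solids; the sublimation-pressure curve is anchored
#' by (T, P_sub) reference points and evaluated by the Clausius-Clapeyron
#' log-linear form in 1/T.
#'
#' @param name compound label.
#' @param Mw molar mass (g/mol).
#' @param Tb normal boiling temperature (K).
#' @param Tc critical temperature (K), must exceed Tb.
#' @param Pc critical pressure (Pa).
#' @param omega acentric factor.
#' @param v_solid solid molar volume (m3/mol).
#' @param pvap_anchors data frame or 2-column matrix of sublimation-pressure
#'   anchors: `T_K` (K), `P_Pa` (Pa); >= 2 rows, strictly increasing in both.
#' @return object of class `solute_properties`.
#' @export
solute_properties <- function(name, Mw, Tb, Tc, Pc, omega, v_solid, pvap_anchors) {
  pvap_anchors <- as.data.frame(pvap_anchors)
  names(pvap_anchors) <- c("T_K", "P_Pa")
  stopifnot(Mw > 0, Tc > Tb, Tb > 0, Pc > 0, v_solid > 0,
            nrow(pvap_anchors) >= 2)
  if (any(diff(pvap_anchors$T_K) <= 0) || any(diff(pvap_anchors$P_Pa) <= 0))
    stop("pvap_anchors must be strictly increasing in T and P")
  structure(list(name = name, Mw = Mw, Tb = Tb, Tc = Tc, Pc = Pc,
                 omega = omega, v_solid = v_solid, pvap_anchors = pvap_anchors),
            class = "solute_properties")
}

#' Pure-component property set for the supercritical solvent
#'
#' @param name solvent label.
#' @param Mw molar mass (g/mol).
#' @param Tc critical temperature (K).
#' @param Pc critical pressure (Pa).
#' @param omega acentric factor.
#' @return object of class `solvent_properties`.
#' @export
solvent_properties <- function(name, Mw, Tc, Pc, omega) {
  stopifnot(Mw > 0, Tc > 0, Pc > 0)
  structure(list(name = name, Mw = Mw, Tc = Tc, Pc = Pc, omega = omega),
            class = "solvent_properties")
}

#' Built-in sumatriptan property set
#'
#' Critical constants, acentric factor and solid molar volume are
#' group-contribution estimates; the two sublimation-pressure anchors bracket
#' the experimental temperature range. Mw 295.40 g/mol, Tb 830.5 K,
#' Tc 1160.3 K, Pc 3.39 MPa, omega 0.647, v_solid 305.2 cm3/mol, anchors
#' (308.2 K, 2.88e-8 Pa) and (338.2 K, 3.45e-6 Pa).
#'
#' @return a [solute_properties()] object.
#' @export
sumatriptan_properties <- function() {
  solute_properties(
    name = "sumatriptan", Mw = 295.40, Tb = 830.5, Tc = 1160.3, Pc = 3.39e6,
    omega = 0.647, v_solid = 3.052e-4,
    pvap_anchors = data.frame(T_K = c(308.2, 338.2), P_Pa = c(2.88e-8, 3.45e-6)))
}

#' Built-in CO2 property set
#'
#' Tc = 304.1 K, Pc = 7.38 MPa. The acentric factor 0.225 is the standard
#' literature value (not part of the bundled dataset's source).
#'
#' @return a [solvent_properties()] object.
#' @export
co2_properties <- function() {
  solvent_properties("CO2", Mw = 44.01, Tc = 304.1, Pc = 7.38e6, omega = 0.225)
}

#' Sublimation pressure of a solid solute
#'
#' ln P_sub is linear in 1/T through the anchor points (exact through two
#' anchors, least squares through more); evaluation is refused more than 5 K
#' outside the anchor range rather than silently extrapolated.
#'
#' @param props a [solute_properties()].
#' @param T temperature (K), within `[min anchor - 5, max anchor + 5]`.
#' @return sublimation pressure (Pa), vectorized over `T`.
#' @export
sublimation_pressure <- function(props, T) {
  stopifnot(inherits(props, "solute_properties"))
  an <- props$pvap_anchors
  lo <- min(an$T_K) - 5; hi <- max(an$T_K) + 5
  if (any(T < lo | T > hi))
    stop(sprintf("extrapolation error: T outside [%g, %g] K", lo, hi))
  cf <- stats::coef(stats::lm(log(P_Pa) ~ I(1 / T_K), data = an))
  exp(cf[[1]] + cf[[2]] / T)
}

#' Clausius-Clapeyron slope of a property set's sublimation curve
#'
#' The coefficient of 1/T in ln P_sub, equal to -dH_sub/R.
#'
#' @param props a [solute_properties()].
#' @return slope in K.
#' @export
sublimation_slope <- function(props) {
  an <- props$pvap_anchors
  stats::coef(stats::lm(log(P_Pa) ~ I(1 / T_K), data = an))[[2]]
}

#' Read or write property sets as YAML
#'
#' Keys: `name`, `Mw_g_mol`, `Tb_K`, `Tc_K`, `Pc_Pa`, `omega`,
#' `v_solid_m3_mol`, `pvap_anchors` (list of `[T_K, P_Pa]` pairs). Solvent
#' sets use the subset without `Tb_K`, `v_solid_m3_mol`, `pvap_anchors`.
#'
#' @param props a [solute_properties()] or [solvent_properties()].
#' @param path YAML file path.
#' @return `write_properties_yaml` returns `path` invisibly;
#'   `read_properties_yaml` the reconstructed object.
#' @export
write_properties_yaml <- function(props, path) {
  if (inherits(props, "solute_properties")) {
    obj <- list(kind = "solute", name = props$name, Mw_g_mol = props$Mw,
                Tb_K = props$Tb, Tc_K = props$Tc, Pc_Pa = props$Pc,
                omega = props$omega, v_solid_m3_mol = props$v_solid,
                pvap_anchors = lapply(seq_len(nrow(props$pvap_anchors)),
                  function(i) as.list(unname(props$pvap_anchors[i, ]))))
  } else if (inherits(props, "solvent_properties")) {
    obj <- list(kind = "solvent", name = props$name, Mw_g_mol = props$Mw,
                Tc_K = props$Tc, Pc_Pa = props$Pc, omega = props$omega)
  } else stop("unsupported object")
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_properties_yaml
#' @export
read_properties_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (identical(obj$kind, "solvent"))
    return(solvent_properties(obj$name, obj$Mw_g_mol, obj$Tc_K, obj$Pc_Pa,
                              obj$omega))
  anchors <- do.call(rbind, lapply(obj$pvap_anchors, function(p)
    data.frame(T_K = p[[1]], P_Pa = p[[2]])))
  solute_properties(obj$name, obj$Mw_g_mol, obj$Tb_K, obj$Tc_K, obj$Pc_Pa,
                    obj$omega, obj$v_solid_m3_mol, anchors)
}
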