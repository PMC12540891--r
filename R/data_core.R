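# Domain data: solubility datasets, the bundled sumatriptan fixture, CSV I/O,
# and the gravimetric solubility arithmetic.

#' @keywords internal
"_PACKAGE"

# Universal gas constant, J mol^-1 K^-1
.R_GAS <- 8.314462618

# CO2 critical point (solvent supercriticality checks)
.CO2_TC <- 304.1   # K
.CO2_PC <- 7.38    # MPa

.DATASET_COLS <- c("T_K", "P_MPa", "rho_kg_m3", "y", "sd_y", "sol_g_L")

#' Construct a validated solubility dataset
#'
#' A solubility dataset is a data frame of isothermal measurements of a solid
#' solute dissolved in supercritical CO2: temperature `T_K` (K), pressure
#' `P_MPa` (MPa), solvent density `rho_kg_m3` (kg/m3), equilibrium solute mole
#' fraction `y`, its standard deviation `sd_y`, and the reported volumetric
#' solubility `sol_g_L` (g/L, informational only -- never used as fit input).
#'
#' @param records data frame with columns `T_K`, `P_MPa`, `rho_kg_m3`, `y`,
#'   `sd_y` and optionally `sol_g_L`.
#' @param solute_name solute label.
#' @param Mw_solute,Mw_solvent molar masses in g/mol.
#' @return object of class `solubility_dataset` (a data frame with metadata
#'   attributes `solute_name`, `Mw_solute`, `Mw_solvent`).
#' @export
solubility_dataset <- function(records, solute_name = "unknown",
                               Mw_solute = NA_real_, Mw_solvent = 44.01) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("validation error: 'records' must be a non-empty data frame")
  if (!"sol_g_L" %in% names(records)) records$sol_g_L <- NA_real_
  missing_cols <- setdiff(.DATASET_COLS, names(records))
  if (length(missing_cols))
    stop("validation error: missing column(s) ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)[, .DATASET_COLS]
  chk <- function(ok, field) if (!all(ok, na.rm = FALSE))
    stop(sprintf("validation error in field '%s' (row %d)", field, which(!ok)[1]))
  chk(is.finite(records$T_K) & records$T_K > .CO2_TC, "T_K")
  chk(is.finite(records$P_MPa) & records$P_MPa >= .CO2_PC, "P_MPa")
  chk(is.finite(records$rho_kg_m3) & records$rho_kg_m3 > 0, "rho_kg_m3")
  chk(is.finite(records$y) & records$y > 0 & records$y < 1, "y")
  chk(is.finite(records$sd_y) & records$sd_y >= 0, "sd_y")
  if (anyDuplicated(records[, c("T_K", "P_MPa")]))
    stop("validation error in field 'T_K/P_MPa': duplicate state points")
  if (!is.na(Mw_solute) && Mw_solute <= 0) stop("validation error in field 'Mw_solute'")
  if (Mw_solvent <= 0) stop("validation error in field 'Mw_solvent'")
  structure(records,
            solute_name = solute_name,
            Mw_solute = Mw_solute, Mw_solvent = Mw_solvent,
            class = c("solubility_dataset", "data.frame"))
}

#' Load a solubility dataset from CSV or a bundled fixture
#'
#' The CSV dialect is comma-separated with header
#' `T_K,P_MPa,rho_kg_m3,y,sd_y,sol_g_L`, UTF-8, `.` decimal separator.
#' The name `"sumatriptan"` loads the bundled 28-point sumatriptan / SC-CO2
#' dataset (4 temperatures x 7 pressures); see the provenance note shipped
#' next to the fixture (`system.file("extdata", package = "scfsol")`) for the
#' two transcription corrections applied to the printed table.
#'
#' @param path_or_builtin path to a CSV file, or the fixture name
#'   `"sumatriptan"`.
#' @param solute_name,Mw_solute,Mw_solvent metadata for CSV input; ignored for
#'   the builtin fixture.
#' @return a [solubility_dataset()].
#' @export
load_dataset <- function(path_or_builtin, solute_name = "unknown",
                         Mw_solute = NA_real_, Mw_solvent = 44.01) {
  if (identical(path_or_builtin, "sumatriptan")) {
    path <- system.file("extdata", "sumatriptan_sc_co2.csv", package = "scfsol",
                        mustWork = TRUE)
    return(load_dataset(path, solute_name = "sumatriptan",
                        Mw_solute = 295.40, Mw_solvent = 44.01))
  }
  if (!file.exists(path_or_builtin)) stop("no such file: ", path_or_builtin)
  df <- tryCatch(
    utils::read.csv(path_or_builtin, stringsAsFactors = FALSE),
    error = function(e) stop("parse error reading '", path_or_builtin, "': ",
                             conditionMessage(e)))
  if (nrow(df) == 0L) stop("validation error: empty dataset in ", path_or_builtin)
  num_cols <- intersect(.DATASET_COLS, names(df))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value in column '%s', line %d",
                   cc, bad[1] + 1L))
    df[[cc]] <- v
  }
  solubility_dataset(df, solute_name, Mw_solute, Mw_solvent)
}

#' Write a solubility dataset to CSV
#'
#' Inverse of [load_dataset()]: `load_dataset(write_dataset(d, f))` reproduces
#' every field to full double precision.
#'
#' @param dataset a [solubility_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  df <- as.data.frame(dataset)
  # full precision round trip
  for (cc in .DATASET_COLS) df[[cc]] <- formatC(df[[cc]], format = "g", digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.solubility_dataset <- function(x, ...) {
  cat(sprintf("Solubility dataset: %s in SC-CO2 (%d points, %d isotherms)\n",
              attr(x, "solute_name"), nrow(x), length(unique(x$T_K))))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Mass of dissolved solute in a gravimetric run
#'
#' @param m_initial initial solute mass loaded (mg).
#' @param m_undissolved solute mass recovered undissolved (mg).
#' @return dissolved mass (mg).
#' @export
dissolved_mass <- function(m_initial, m_undissolved) {
  if (any(m_undissolved < 0) || any(m_undissolved > m_initial))
    stop("require 0 <= m_undissolved <= m_initial")
  m_initial - m_undissolved
}

#' Equilibrium mole fraction from gravimetric masses
#'
#' Converts the dissolved solute mass and the solvent charge into the solute
#' mole fraction y = n_solute / (n_solute + n_CO2).
#'
#' @param m_dissolved dissolved solute mass (mg).
#' @param m_co2 solvent mass (g).
#' @param Mw_drug,Mw_co2 molar masses (g/mol).
#' @return solute mole fraction (dimensionless).
#' @export
mole_fraction_from_masses <- function(m_dissolved, m_co2,
                                      Mw_drug = 295.40, Mw_co2 = 44.01) {
  if (any(m_dissolved < 0) || any(m_co2 < 0)) stop("masses must be non-negative")
  if (any(m_co2 == 0)) stop("domain error: m_co2 must be positive")
  if (Mw_drug <= 0 || Mw_co2 <= 0) stop("molar masses must be positive")
  n_drug <- (m_dissolved / 1000) / Mw_drug    # mg -> g
  n_co2 <- m_co2 / Mw_co2
  n_drug / (n_drug + n_co2)
}

#' Volumetric solubility (g/L) from mole fraction and solvent density
#'
#' S = rho * Mw_drug * y / (Mw_co2 * (1 - y)), with rho in kg/m3 (== g/L).
#'
#' @param y solute mole fraction, 0 <= y < 1.
#' @param rho solvent density (kg/m3).
#' @param Mw_drug,Mw_co2 molar masses (g/mol).
#' @return solubility in g solute per litre of solvent.
#' @export
gl_from_mole_fraction <- function(y, rho, Mw_drug = 295.40, Mw_co2 = 44.01) {
  if (any(y < 0) || any(y >= 1)) stop("domain error: require 0 <= y < 1")
  rho * Mw_drug * y / (Mw_co2 * (1 - y))
}
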