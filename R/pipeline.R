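# Orchestration: run the full analysis chain (density models -> enthalpies ->
# crossover -> cubic EoS isotherms -> PC-SAFT isotherms) and render/serialize
# the report.

#' Run the complete solubility analysis
#'
#' Executes, in order: the four density-based model fits and the derived
#' dissolution enthalpies; the crossover-pressure analysis; per-isotherm
#' (k_ij, l_ij) regression for PR and SRK; and per-isotherm PC-SAFT k_ij
#' regression. A failing stage is recorded in `$errors` and the remaining
#' stages still run.
#'
#' @param dataset a [solubility_dataset()].
#' @param solute a [solute_properties()].
#' @param solvent a [solvent_properties()].
#' @param config list of options: `stages` (character subset of
#'   `c("density", "cubic", "pcsaft")`), `objective` (density-model
#'   objective), `eos` (cubic EoS subset), `solute_pc`, `solvent_pc`
#'   ([pcsaft_pure()] sets), `seed` (PC-SAFT global-search seed),
#'   `pcsaft_bounds`, `cubic_bounds`.
#' @return object of class `analysis_report`.
#' @export
run_analysis <- function(dataset,
                         solute = sumatriptan_properties(),
                         solvent = co2_properties(),
                         config = list()) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  cfg <- utils::modifyList(list(
    stages = c("density", "cubic", "pcsaft"),
    objective = "aard",
    eos = c("pr", "srk"),
    solute_pc = sumatriptan_pcsaft_synthetic(),
    solvent_pc = co2_pcsaft(),
    seed = 1L,
    pcsaft_bounds = c(-0.5, 0.5),
    cubic_bounds = c(-1, 1)), config)
  report <- list(density_fits = NULL, enthalpies = NULL, crossover = NULL,
                 cubic_fits = list(), pcsaft_fits = list(), errors = list(),
                 provenance = list(
                   package_version = as.character(utils::packageVersion("scfsol")),
                   seed = cfg$seed,
                   n_points = nrow(dataset),
                   solute = attr(dataset, "solute_name"),
                   objective = cfg$objective))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  Ts <- sort(unique(dataset$T_K))

  if ("density" %in% cfg$stages) {
    report$density_fits <- run_stage("density", {
      fits <- lapply(c("chrastil", "bartle", "mst", "kj"), fit_density_model,
                     dataset = dataset, objective = cfg$objective)
      names(fits) <- c("chrastil", "bartle", "mst", "kj")
      fits
    })
    if (!is.null(report$density_fits)) {
      report$enthalpies <- run_stage("enthalpies",
        derive_enthalpies(report$density_fits$chrastil,
                          report$density_fits$bartle))
      report$mst_consistency <- run_stage("mst_consistency",
        mst_consistency_points(dataset, report$density_fits$mst))
    }
    report$crossover <- run_stage("crossover", find_crossover(dataset))
  }

  if ("cubic" %in% cfg$stages) {
    for (eos in cfg$eos) {
      report$cubic_fits[[eos]] <- run_stage(paste0("cubic_", eos), {
        fits <- lapply(Ts, function(Tt)
          fit_cubic_isotherm(eos, dataset, solute, solvent, T_iso = Tt,
                             bounds = cfg$cubic_bounds))
        list(isotherms = fits,
             mean_aard = mean(vapply(fits, function(f) f$stats$aard_pct, 0)),
             mean_r2_adj = mean(vapply(fits, function(f) f$stats$r2_adj, 0)))
      })
    }
  }

  if ("pcsaft" %in% cfg$stages) {
    report$pcsaft_fits <- run_stage("pcsaft", {
      fits <- lapply(Ts, function(Tt)
        fit_pcsaft_isotherm(dataset, cfg$solute_pc, cfg$solvent_pc, solute,
                            T_iso = Tt, bounds = cfg$pcsaft_bounds,
                            seed = cfg$seed))
      list(isotherms = fits,
           mean_aard = mean(vapply(fits, function(f) f$stats$aard_pct, 0)),
           mean_r2_adj = mean(vapply(fits, function(f) f$stats$r2_adj, 0)))
    })
  }
  structure(report, class = "analysis_report")
}

#' Density-model summary table of an analysis report
#'
#' One row per correlation: coefficients, AARD% and adjusted R2.
#'
#' @param report an [run_analysis()] result.
#' @return data frame.
#' @export
density_fit_table <- function(report) {
  stopifnot(inherits(report, "analysis_report"), !is.null(report$density_fits))
  do.call(rbind, lapply(names(report$density_fits), function(id) {
    f <- report$density_fits[[id]]
    data.frame(model = id, a0 = f$params$a0, a1 = f$params$a1,
               a2 = f$params$a2, aard_pct = f$stats$aard_pct,
               r2_adj = f$stats$r2_adj)
  }))
}

#' Per-isotherm EoS summary table of an analysis report
#'
#' @param report an [run_analysis()] result.
#' @return data frame with one row per EoS x isotherm plus mean rows.
#' @export
eos_fit_table <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  rows <- list()
  for (eos in names(report$cubic_fits)) {
    blk <- report$cubic_fits[[eos]]
    if (is.null(blk)) next
    for (f in blk$isotherms)
      rows[[length(rows) + 1L]] <- data.frame(
        model = toupper(eos), T_K = f$T, k_ij = f$k_ij, l_ij = f$l_ij,
        aard_pct = f$stats$aard_pct, r2_adj = f$stats$r2_adj)
    rows[[length(rows) + 1L]] <- data.frame(
      model = toupper(eos), T_K = NA, k_ij = NA, l_ij = NA,
      aard_pct = blk$mean_aard, r2_adj = blk$mean_r2_adj)
  }
  if (!is.null(report$pcsaft_fits) && length(report$pcsaft_fits)) {
    blk <- report$pcsaft_fits
    for (f in blk$isotherms)
      rows[[length(rows) + 1L]] <- data.frame(
        model = "PC-SAFT", T_K = f$T, k_ij = f$k_ij, l_ij = NA,
        aard_pct = f$stats$aard_pct, r2_adj = f$stats$r2_adj)
    rows[[length(rows) + 1L]] <- data.frame(
      model = "PC-SAFT", T_K = NA, k_ij = NA, l_ij = NA,
      aard_pct = blk$mean_aard, r2_adj = blk$mean_r2_adj)
  }
  do.call(rbind, rows)
}

#' Serialize an analysis report to JSON
#'
#' @param report an [run_analysis()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  out <- list(provenance = report$provenance)
  if (!is.null(report$density_fits)) {
    out$density_models <- density_fit_table(report)
    out$enthalpies_kJ_mol <- unclass(report$enthalpies)
  }
  if (!is.null(report$crossover))
    out$crossover_MPa <- report$crossover$interval
  tab <- tryCatch(eos_fit_table(report), error = function(e) NULL)
  if (!is.null(tab)) out$eos_fits <- tab
  if (length(report$errors)) out$errors <- report$errors
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Solubility analysis report ==\n")
  if (!is.null(x$density_fits)) {
    cat("\nDensity-based correlations:\n")
    print(density_fit_table(x), row.names = FALSE, digits = 5)
    if (!is.null(x$enthalpies)) { cat("\nDerived enthalpies: "); print(x$enthalpies) }
  }
  if (!is.null(x$crossover) && length(x$crossover$interval))
    cat(sprintf("\nCrossover pressure between %g and %g MPa\n",
                x$crossover$interval[1], x$crossover$interval[2]))
  tab <- tryCatch(eos_fit_table(x), error = function(e) NULL)
  if (!is.null(tab) && nrow(tab)) {
    cat("\nEquation-of-state isotherm fits (NA temperature = mean row):\n")
    print(tab, row.names = FALSE, digits = 4)
  }
  if (length(x$errors)) {
    cat("\nStage errors:\n")
    for (nm in names(x$errors)) cat(" -", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}
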