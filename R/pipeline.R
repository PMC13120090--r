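#' Assemble a run configuration
#'
#' Defaults reproduce the study settings: 500 individuals, 0-50 years, weekly
#' readouts, solver tolerances atol 1e-9 / rtol 1e-6.
#'
#' @param scenario built-in scenario name (see [builtinScenario()]).
#' @param n number of individuals.
#' @param seed master seed.
#' @param tEnd horizon in years.
#' @param atol,rtol solver tolerances.
#' @param readoutDays readout interval (days).
#' @param maxFormula,brain20x sensitivity switches.
#' @param outDir output directory for [runPipeline()].
#' @return a named list (class \code{"runConfig"}).
#' @export
runConfig <- function(scenario = "GERMANY_2025", n = 500, seed = 1,
                      tEnd = 50, atol = 1e-9, rtol = 1e-6, readoutDays = 7,
                      maxFormula = FALSE, brain20x = FALSE,
                      outDir = "alupbtk_run") {
  cfg <- list(scenario = scenario, n = as.integer(n), seed = as.integer(seed),
              tEnd = tEnd, atol = atol, rtol = rtol,
              readoutDays = readoutDays, maxFormula = maxFormula,
              brain20x = brain20x, outDir = outDir)
  class(cfg) <- "runConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected before any computation. Note that the cohort-size
#' key must be written quoted (\code{"n": 500}): a bare \code{n} is a boolean
#' in YAML 1.1.
#'
#' @param path YAML file path.
#' @return a run configuration list.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(runConfig, vals)
}

# deterministic 31-bit polynomial hash of the deparsed configuration,
# recorded in every output file so reruns are verifiably identical
configHash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outDir <- NULL   # the hash identifies the run settings, not where they land
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full paired-scenario pipeline
#'
#' Samples the virtual population once, simulates it under the food-only
#' baseline and the configured food + vaccination scenario, and writes the
#' artifact bundle: population dump, per-tissue quantile bands for both
#' scenarios, the windowed comparison summary, body burdens at the horizon and
#' a run log (settings, seed, config hash, package version). Stops before
#' writing anything if the configuration is invalid, and errors on any mass
#' balance or negativity violation during simulation.
#'
#' @param config from [runConfig()] or [readRunConfig()].
#' @param params a [ModelParams-class].
#' @param phys a [Physiology-class].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with both experiments, the summary table and the
#'   output paths.
#' @export
runPipeline <- function(config = runConfig(), params = ModelParams(),
                        phys = defaultPhysiology(), quiet = FALSE) {
  stopifnot(inherits(config, "runConfig"))
  scn <- builtinScenario(config$scenario, maxFormula = config$maxFormula,
                         brain20x = config$brain20x)
  base <- builtinScenario("FOOD_ONLY", maxFormula = config$maxFormula,
                          brain20x = config$brain20x)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  pop <- samplePopulation(config$n, seed = config$seed, params = params)
  msg <- function(...) if (!quiet) message(...)
  msg("simulating '", scn@name, "' and '", base@name, "' for ", config$n,
      " individuals ...")
  simArgs <- list(params = params, phys = phys, tEnd = config$tEnd,
                  atol = config$atol, rtol = config$rtol,
                  readoutDays = config$readoutDays)
  expA <- do.call(simulatePopulation, c(list(pop, scn), simArgs))
  expB <- do.call(simulatePopulation, c(list(pop, base), simArgs))
  if (any(assay(expA, "plasma") < -1e-9) || any(assay(expB, "plasma") < -1e-9))
    stop("negative compartment amounts encountered")
  windows <- Filter(function(w) w[2] <= config$tEnd,
                    list(c(0, 2), c(9, 10), c(19, 20)))
  summ <- summaryTable(expA, expB, windows = windows)
  hash <- configHash(config)
  stamp <- function(df) cbind(df, config_hash = hash, seed = config$seed)
  paths <- list(
    population = file.path(config$outDir, "population.csv"),
    summary = file.path(config$outDir, "summary.csv"),
    burden = file.path(config$outDir, "body_burden.csv"),
    log = file.path(config$outDir, "run_log.txt"))
  writePopulation(pop, paths$population)
  utils::write.csv(stamp(summ), paths$summary, row.names = FALSE, quote = FALSE)
  bb <- merge(bodyBurden(expA, config$tEnd), bodyBurden(expB, config$tEnd),
              by = "id", suffixes = c("_vacc", "_food"))
  utils::write.csv(stamp(bb), paths$burden, row.names = FALSE, quote = FALSE)
  for (tt in c("plasma", "bone", "brain", "liver")) {
    paths[[paste0("band_", tt)]] <- file.path(config$outDir,
                                              paste0("band_", tt, ".csv"))
    bands <- cbind(populationQuantiles(expA, tt),
                   food_only_median = populationQuantiles(expB, tt)$median)
    utils::write.csv(stamp(bands), paths[[paste0("band_", tt)]],
                     row.names = FALSE, quote = FALSE)
  }
  writeLines(c(
    paste0("aluPBTK ", as.character(utils::packageVersion("aluPBTK"))),
    paste0("config_hash: ", hash),
    paste0(names(unclass(config)), ": ",
           vapply(unclass(config), function(x) paste(format(x), collapse = ","),
                  character(1)))),
    paths$log)
  msg("artifacts written to ", config$outDir)
  invisible(list(vacc = expA, food = expB, summary = summ, paths = paths))
}

#' Plot an exposure band
#'
#' Median line with the p5-p95 band, the food-only median as a dotted
#' reference and the tissue's reference levels as horizontal dashed lines.
#'
#' @param expA food + vaccination [AlExposureExperiment-class].
#' @param expB food-only experiment on the same grid (optional).
#' @param tissue tissue to plot.
#' @param maxAge truncate the age axis (years).
#' @return a ggplot object.
#' @export
plotExposure <- function(expA, expB = NULL, tissue = "plasma", maxAge = NULL) {
  band <- populationQuantiles(expA, tissue)
  if (!is.null(maxAge)) band <- band[band$age_years <= maxAge, ]
  unit <- if (tissue == "plasma") "µg/L" else "µg/g ww"
  p <- ggplot2::ggplot(band, ggplot2::aes(x = .data$age_years)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "steelblue4") +
    ggplot2::labs(x = "Age (years)",
                  y = paste0("Al in ", tissue, " (", unit, ")"),
                  title = metadata(expA)$scenario@name) +
    ggplot2::theme_minimal()
  if (!is.null(expB)) {
    ref <- populationQuantiles(expB, tissue)
    if (!is.null(maxAge)) ref <- ref[ref$age_years <= maxAge, ]
    p <- p + ggplot2::geom_line(data = ref,
                                ggplot2::aes(y = .data$median),
                                linetype = "dotted")
  }
  refs <- tissueReferences()
  if (tissue %in% refs$tissue)
    p <- p + ggplot2::geom_hline(yintercept = refs$uln_ww[refs$tissue == tissue],
                                 linetype = "dashed", colour = "grey40")
  p
}
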