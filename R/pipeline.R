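#' Default pipeline run configuration
#'
#' Nested configuration consumed by [runPipeline()]: an anatomy block,
#' a sampling block, simulation settings (700 ms beats at 1 ms, 150 Hz
#' low-pass, 0.32 scaling), sensitivity-analysis settings and a root
#' seed from which all named substreams derive.
#'
#' @param seed root seed.
#' @return nested list of class `runConfig`.
#' @export
defaultRunConfig <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    anatomy = unclass(anatomyConfig(seed = seed)),
    sampling = unclass(sampleSpec(seed = seed)),
    simulation = list(horizon = 700, period = 1, cutoff = 150,
                      scale = 0.32),
    sensitivity = list(degree = 3, nRandom = 100),
    exemplar = list(rho = 1.0, z = 0.53, phi = -0.49, ventricle = "RV",
                    tven = 125)
  )
  class(cfg) <- c("runConfig", "list")
  cfg
}

validateRunConfig <- function(cfg) {
  stopIfNot(is.list(cfg), "config must be a list")
  need <- c("seed", "anatomy", "sampling", "simulation")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("invalid config: missing section(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  sim <- cfg$simulation
  stopIfNot(sim$horizon > 0 && sim$period > 0, "invalid simulation settings")
  stopIfNot(sim$cutoff < 500 / sim$period,
            "cutoff must be below the Nyquist frequency")
  cfg$anatomy <- do.call(anatomyConfig, cfg$anatomy)
  cfg$sampling <- do.call(sampleSpec, cfg$sampling)
  cfg$sensitivity <- cfg$sensitivity %||% list(degree = 3, nRandom = 100)
  cfg
}

#' Run a pipeline command
#'
#' Command-line-style orchestration over the package functions. Commands:
#' \describe{
#'   \item{simulate}{one beat for the configured exemplar pathway; writes
#'     the processed ECG as CSV and the extracted features as JSON.}
#'   \item{database}{Latin-hypercube sweep into an ECG database
#'     container plus a companion parameter CSV.}
#'   \item{regional}{per-region summary CSVs from a database.}
#'   \item{sensitivity}{per-ventricle PCE sensitivity analysis; writes
#'     integrated sensitivities/proportions as CSV and metadata JSON.}
#'   \item{localize}{decision-tree evaluation; writes per-beat
#'     predictions CSV and a summary JSON.}
#' }
#' Every artifact directory receives a `provenance.json` with the config
#' hash, seed and package version. Validation failures raise errors
#' before any compute.
#'
#' @param command one of simulate, database, regional, sensitivity,
#'   localize.
#' @param config a `runConfig` list, or a path to a YAML/JSON file.
#' @param out output directory.
#' @param db optional existing database (object or container path) for
#'   the commands that consume one; defaults to `<out>/database`.
#' @param overrides named list overriding top-level config entries.
#' @return invisible list of produced artifact paths.
#' @export
runPipeline <- function(command = c("simulate", "database", "regional",
                                    "sensitivity", "localize"),
                        config = defaultRunConfig(), out = ".",
                        db = NULL, overrides = NULL) {
  command <- match.arg(command)
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.null(overrides))
    config[names(overrides)] <- overrides
  cfg <- validateRunConfig(config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(unclass(cfg))
  artifacts <- character(0)

  loadDb <- function() {
    if (is(db, "ECGDatabase")) return(db)
    p <- db %||% file.path(out, "database")
    readDatabase(p)
  }

  if (command == "simulate") {
    anatomy <- buildAnatomy(cfg$anatomy)
    ex <- cfg$exemplar
    ap <- apDefinition(alpha = ex$alpha %||% NA, gamma = ex$gamma %||% NA,
                       beta = ex$beta %||% NA, cvap = ex$cvap %||% 2.0,
                       rho = ex$rho, z = ex$z, phi = ex$phi,
                       ventricle = ex$ventricle, tven = ex$tven)
    beat <- simulateBeat(anatomy, ap, horizon = cfg$simulation$horizon,
                         period = cfg$simulation$period)
    ecg <- forwardECG(beat, anatomy, period = cfg$simulation$period,
                      cutoff = cfg$simulation$cutoff,
                      scale = cfg$simulation$scale)
    f <- extractFeatures(ecg, qrsOnset = beat$tEarliestVent - 5,
                         qrsOffset = beat$tLatestVent + 10)
    ecgPath <- file.path(out, "exemplar_ecg.csv")
    writeECGcsv(ecg, ecgPath)
    featPath <- file.path(out, "exemplar_features.json")
    jsonlite::write_json(
      lapply(f[c("qrsOnset", "qrsOffset", "inferiorPositives",
                 "mostPositiveDelta", "transitionLead", "v1iRatio",
                 "minDvdtV2")], unname),
      featPath, auto_unbox = TRUE, digits = NA, na = "null")
    artifacts <- c(ecgPath, featPath)
  } else if (command == "database") {
    anatomy <- buildAnatomy(cfg$anatomy)
    samples <- sampleAPs(cfg$sampling, anatomy)
    dbOut <- generateDatabase(samples, anatomy,
                              horizon = cfg$simulation$horizon,
                              period = cfg$simulation$period,
                              cutoff = cfg$simulation$cutoff,
                              scale = cfg$simulation$scale,
                              seed = cfg$seed)
    dbPath <- file.path(out, "database")
    writeDatabase(dbOut, dbPath)
    artifacts <- dbPath
  } else if (command == "regional") {
    sumPath <- file.path(out, "regional")
    writeRegionalSummary(summarizeRegions(loadDb()), sumPath)
    artifacts <- sumPath
  } else if (command == "sensitivity") {
    dbObj <- loadDb()
    for (v in unique(dbParams(dbObj)$ventricle[dbParams(dbObj)$valid])) {
      sa <- analyzeSensitivity(dbObj, v, degree = cfg$sensitivity$degree)
      sens <- sa$sensitivity
      csvPath <- file.path(out, paste0("sensitivity_", v, ".csv"))
      utils::write.csv(data.frame(
        combination = sens@combos, order = sens@comboOrder,
        integrated_mVs = sens@integrated,
        proportion = sens@proportions, check.names = FALSE),
        csvPath, row.names = FALSE)
      err <- surrogateError(sa$model, dbObj, v,
                            nRandom = cfg$sensitivity$nRandom,
                            seed = cfg$seed)
      metaPath <- file.path(out, paste0("sensitivity_", v, ".json"))
      jsonlite::write_json(list(degree = cfg$sensitivity$degree,
                                bounds = as.data.frame(sa$model@bounds),
                                seed = cfg$seed,
                                surrogateErrorMean = err$mean,
                                surrogateErrorSD = err$sd),
                           metaPath, auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, csvPath, metaPath)
    }
  } else if (command == "localize") {
    dbObj <- loadDb()
    for (alg in c("pambrun", "easy-wpw")) {
      ev <- evaluateLocalization(dbObj, alg)
      csvPath <- file.path(out, paste0("localization_", alg, ".csv"))
      utils::write.csv(ev$perBeat, csvPath, row.names = FALSE)
      jsonPath <- file.path(out, paste0("localization_", alg, ".json"))
      jsonlite::write_json(list(algorithm = alg,
                                sideAccuracy = ev$sideAccuracy,
                                indeterminateRate = ev$indeterminateRate),
                           jsonPath, auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, csvPath, jsonPath)
    }
  }

  prov <- file.path(out, "provenance.json")
  jsonlite::write_json(list(command = command, configHash = hash,
                            seed = cfg$seed,
                            package = as.character(utils::packageVersion("wpwsim")),
                            timestamp = format(Sys.time(), tz = "UTC")),
                       prov, auto_unbox = TRUE)
  invisible(list(artifacts = artifacts, provenance = prov,
                 configHash = hash))
}
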