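#' Sampling specification for the accessory-pathway sweep
#'
#' Bounds of the Latin-hypercube sample of pathway definitions. Exit
#' sites are restricted apicobasally to the two basal bullseye bands
#' (default z in [0.5, 1]) over the full rotation and wall depth; atrial
#' insertions cover the annulus shell. Pairs whose geodesic pathway
#' length exceeds `maxLength` (default 60 mm) and exits resolving into
#' the inert RVOT are rejected.
#'
#' @param nPerVentricle accepted samples requested per ventricle.
#' @param zRange,phiRange,rhoRange exit-coordinate bounds.
#' @param alphaRange,gammaRange,betaRange atrial insertion bounds.
#' @param maxLength maximal pathway length (mm, default 60).
#' @param cvap pathway conduction velocity (m/s, default 2.0).
#' @param seed integer seed for the Latin hypercube.
#' @return a list of class `sampleSpec`.
#' @export
sampleSpec <- function(nPerVentricle = 500, zRange = c(0.5, 1),
                       phiRange = c(-pi, pi), rhoRange = c(0, 1),
                       alphaRange = c(0, 1), gammaRange = c(-pi, pi),
                       betaRange = c(0, 1), maxLength = 60, cvap = 2.0,
                       seed = 1L) {
  stopIfNot(maxLength > 0, "maxLength must be positive")
  stopIfNot(cvap > 0, "cvap must be positive")
  rngOk <- function(r, lo, hi) length(r) == 2 && r[1] < r[2] &&
    r[1] >= lo - 1e-6 && r[2] <= hi + 1e-6
  stopIfNot(rngOk(zRange, 0, 1) && rngOk(rhoRange, 0, 1) &&
            rngOk(alphaRange, 0, 1) && rngOk(betaRange, 0, 1) &&
            rngOk(phiRange, -pi, pi) && rngOk(gammaRange, -pi, pi),
            "sampling bounds outside the coordinate ranges")
  out <- list(nPerVentricle = as.integer(nPerVentricle), zRange = zRange,
              phiRange = phiRange, rhoRange = rhoRange,
              alphaRange = alphaRange, gammaRange = gammaRange,
              betaRange = betaRange, maxLength = maxLength, cvap = cvap,
              seed = as.integer(seed))
  class(out) <- c("sampleSpec", "list")
  out
}

# Package-local cache of derived per-anatomy quantities (geodesic
# distances from atrial nodes, atrial activation map, lead weights).
.wpwCache <- new.env(parent = emptyenv())

anatomyDerived <- function(anatomy) {
  key <- paste0(configHash(anatomy@config), "_", nrow(anatomy@nodes))
  hit <- .wpwCache[[key]]
  if (!is.null(hit)) return(hit)
  g <- geomGraph(anatomy)
  atrialIdx <- which(anatomy@tissue == "atria")
  D <- igraph::distances(g$graph, v = atrialIdx, weights = g$len)
  rownames(D) <- as.character(atrialIdx)
  atrialMap <- solveEikonal(anatomy,
    data.frame(node = anatomy@saNode, time = 0))
  A <- leadWeights(anatomy, anatomy@electrodes)
  val <- list(geodesics = D, atrialIdx = atrialIdx, atrialMap = atrialMap,
              leadW = A)
  .wpwCache[[key]] <- val
  val
}

#' Latin-hypercube sample of accessory pathways
#'
#' Draws Latin-hypercube samples of the seven-parameter pathway vector
#' over the specification box, localizes each onto the mesh and rejects
#' pairs farther apart than the maximal pathway length as well as exits
#' in the inert RVOT. Batches are drawn until the requested number of
#' accepted samples per ventricle is reached. Deterministic under the
#' spec seed.
#'
#' @param spec a [sampleSpec()].
#' @param anatomy a [CardiacAnatomy-class] object.
#' @param ventricles which ventricles to sweep.
#' @return list of [apDefinition()] objects with an `acceptanceRate`
#'   attribute.
#' @export
sampleAPs <- function(spec, anatomy, ventricles = c("LV", "RV")) {
  der <- anatomyDerived(anatomy)
  ucc <- anatomy@ucc
  tis <- anatomy@tissue
  out <- list()
  rate <- c()
  for (v in ventricles) {
    set.seed(spec$seed + match(v, c("LV", "RV")))
    vIdx <- which(tis == v | (v == "RV" & tis == "RVOT"))
    accepted <- list()
    tried <- 0L
    batch <- max(200L, 2L * spec$nPerVentricle)
    for (rep in 1:25) {
      if (length(accepted) >= spec$nPerVentricle) break
      X <- lhs::randomLHS(batch, 6)
      sc <- function(u, r) r[1] + u * (r[2] - r[1])
      alpha <- sc(X[, 1], spec$alphaRange)
      gamma <- sc(X[, 2], spec$gammaRange)
      beta  <- sc(X[, 3], spec$betaRange)
      rho   <- sc(X[, 4], spec$rhoRange)
      z     <- sc(X[, 5], spec$zRange)
      phi   <- sc(X[, 6], spec$phiRange)
      for (i in seq_len(batch)) {
        tried <- tried + 1L
        d2v <- (ucc$z[vIdx] - z[i])^2 +
          (angDiff(ucc$phi[vIdx], phi[i]) / pi)^2 +
          (ucc$rho[vIdx] - rho[i])^2
        ventNode <- vIdx[which.min(d2v)]
        if (tis[ventNode] == "RVOT") next
        aIdx <- der$atrialIdx
        d2a <- (ucc$z[aIdx] - alpha[i])^2 +
          (angDiff(ucc$phi[aIdx], gamma[i]) / pi)^2 +
          (ucc$rho[aIdx] - beta[i])^2
        atrialNode <- aIdx[which.min(d2a)]
        d <- der$geodesics[as.character(atrialNode), ventNode]
        if (!is.finite(d) || d > spec$maxLength) next
        accepted[[length(accepted) + 1L]] <- apDefinition(
          alpha = alpha[i], gamma = gamma[i], beta = beta[i],
          cvap = spec$cvap, rho = rho[i], z = z[i], phi = phi[i],
          ventricle = v)
        if (length(accepted) >= spec$nPerVentricle) break
      }
    }
    if (!length(accepted))
      stop("sampling spec error: every sample was rejected", call. = FALSE)
    rate[v] <- length(accepted) / tried
    out <- c(out, accepted)
  }
  attr(out, "acceptanceRate") <- rate
  out
}

#' Generate the swept-pathway ECG database
#'
#' One simulated beat + forward solve + postprocessing per sampled
#' pathway. Beat failures are caught, logged and marked invalid; the run
#' continues.
#'
#' @param samples list of [apDefinition()] (from [sampleAPs()]).
#' @param anatomy a [CardiacAnatomy-class] object.
#' @param horizon,period beat length and sample period (ms).
#' @param cutoff,scale postprocessing settings (Hz, dimensionless).
#' @param seed seed recorded in the metadata.
#' @param verbose print progress.
#' @return an [ECGDatabase-class] object.
#' @export
generateDatabase <- function(samples, anatomy, horizon = 700, period = 1,
                             cutoff = 150, scale = 0.32, seed = 1L,
                             verbose = FALSE) {
  der <- anatomyDerived(anatomy)
  nb <- length(samples)
  nT <- ceiling(horizon / period)
  signals <- array(NA_real_, c(nb, 12, nT),
                   dimnames = list(NULL, leadNames12, NULL))
  rows <- vector("list", nb)
  for (i in seq_len(nb)) {
    ap <- samples[[i]]
    row <- data.frame(beat = i, alpha = ap$alpha, gamma = ap$gamma,
                      beta = ap$beta, cvap = ap$cvap, rho = ap$rho,
                      z = ap$z, phi = ap$phi, ventricle = ap$ventricle,
                      atrialNode = NA_integer_, ventNode = NA_integer_,
                      d = NA_real_, tatria = NA_real_, tven = NA_real_,
                      region = NA_character_, tEarliestVent = NA_real_,
                      tLatestVent = NA_real_, valid = FALSE,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      loc <- localizeAP(anatomy, ap, atrialMap = der$atrialMap)
      if (!is.null(ap$tven)) loc$tven <- ap$tven
      beat <- simulateBeat(anatomy, loc, horizon = horizon,
                           period = period, atrialMap = der$atrialMap)
      pot <- t(der$leadW %*% beat$vm)
      colnames(pot) <- rownames(anatomy@electrodes)
      ecg <- postprocessECG(assemble12Lead(pot, period = period),
                            cutoff = cutoff, scale = scale)
      list(loc = loc, beat = beat, ecg = ecg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (verbose) message("beat ", i, " failed: ", conditionMessage(res))
      rows[[i]] <- row
      next
    }
    row$atrialNode <- res$loc$atrialNode
    row$ventNode <- res$loc$ventNode
    row$d <- res$loc$d
    row$tatria <- res$loc$tatria
    row$tven <- res$loc$tven
    row$region <- bullseyeRegion(ap$ventricle, ap$z, ap$phi)
    row$tEarliestVent <- res$beat$tEarliestVent
    row$tLatestVent <- res$beat$tLatestVent
    row$valid <- TRUE
    rows[[i]] <- row
    signals[i, , ] <- t(ecgSignal(res$ecg))
    if (verbose && i %% 100 == 0) message("beat ", i, "/", nb)
  }
  params <- if (nb > 0) do.call(rbind, rows) else
    data.frame(beat = integer(0), alpha = numeric(0), gamma = numeric(0),
               beta = numeric(0), cvap = numeric(0), rho = numeric(0),
               z = numeric(0), phi = numeric(0), ventricle = character(0),
               atrialNode = integer(0), ventNode = integer(0),
               d = numeric(0), tatria = numeric(0), tven = numeric(0),
               region = character(0), tEarliestVent = numeric(0),
               tLatestVent = numeric(0), valid = logical(0),
               stringsAsFactors = FALSE)
  rownames(params) <- NULL
  new("ECGDatabase", params = params, signals = signals, period = period,
      meta = list(schema = dbSchemaVersion, seed = as.integer(seed),
                  configHash = configHash(anatomy@config),
                  cutoff = cutoff, scale = scale, horizon = horizon))
}

dbSchemaVersion <- "wpwsim-db-1"

#' Persist an ECG database to a directory container
#'
#' Lossless container: `params.csv` (parameter table), `signals.parquet`
#' (one row per beat x lead, samples as columns) and `meta.json`.
#'
#' @param db an [ECGDatabase-class] object.
#' @param path directory to create/overwrite.
#' @return the path, invisibly.
#' @export
writeDatabase <- function(db, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arrow::write_parquet(db@params, file.path(path, "params.parquet"))
  utils::write.csv(db@params, file.path(path, "params.csv"),
                   row.names = FALSE)  # human-readable companion
  nb <- dim(db@signals)[1]
  nT <- dim(db@signals)[3]
  flat <- matrix(aperm(db@signals, c(2, 1, 3)), nb * 12, nT)
  df <- data.frame(beat = rep(seq_len(nb), each = 12),
                   lead = rep(leadNames12, times = nb))
  sig <- as.data.frame(flat)
  names(sig) <- paste0("s", seq_len(nT))
  arrow::write_parquet(cbind(df, sig), file.path(path, "signals.parquet"))
  meta <- db@meta
  meta$period <- db@period
  meta$nBeats <- nb
  meta$nSamples <- nT
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ECG database from its directory container
#'
#' @param path directory written by [writeDatabase()].
#' @return an [ECGDatabase-class] object.
#' @export
readDatabase <- function(path) {
  need <- file.path(path, c("params.parquet", "signals.parquet", "meta.json"))
  if (!all(file.exists(need)))
    stop("schema error: not a database container (missing ",
         paste(basename(need[!file.exists(need)]), collapse = ", "), ")",
         call. = FALSE)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$schema, dbSchemaVersion))
    stop("schema-version mismatch: found '", meta$schema %||% "<none>",
         "', expected '", dbSchemaVersion, "'", call. = FALSE)
  params <- as.data.frame(arrow::read_parquet(file.path(path,
                                                        "params.parquet")))
  if (nrow(params) > 0) params$region <- as.character(params$region)
  sig <- arrow::read_parquet(file.path(path, "signals.parquet"))
  nb <- meta$nBeats
  nT <- meta$nSamples
  if (nrow(sig) != nb * 12 || nrow(params) != nb)
    stop("schema error: container is truncated or inconsistent",
         call. = FALSE)
  flat <- as.matrix(sig[, paste0("s", seq_len(nT)), drop = FALSE])
  signals <- aperm(array(flat, c(12, nb, nT)), c(2, 1, 3))
  dimnames(signals) <- list(NULL, leadNames12, NULL)
  period <- meta$period
  meta$period <- NULL; meta$nBeats <- NULL; meta$nSamples <- NULL
  new("ECGDatabase", params = params, signals = signals, period = period,
      meta = as.list(meta))
}
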