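#' Extract morphological features from a 12-lead ECG
#'
#' QRS-window features used by pathway-localization algorithms: per-lead
#' delta-wave polarity/amplitude (mean deflection in the first 40 ms
#' after QRS onset, relative to the pre-onset baseline), per-lead QRS
#' polarity (R vs S dominance), count of positive inferior leads (II,
#' aVF, III), lead with the most positive delta wave, precordial
#' transition lead (first V lead whose R wave exceeds the S-wave
#' amplitude), V1/I R-amplitude ratio, and the minimum dV/dt in the
#' downstroke of the V2 S wave.
#'
#' The QRS window is taken from simulation ground truth when onset/offset
#' hints are given (earliest ventricular activation - 5 ms to latest +
#' 10 ms); otherwise onset is detected from the earliest steep slope
#' across leads.
#'
#' @param ecg an [ECG12-class] object (filtered and scaled).
#' @param qrsOnset,qrsOffset optional window hints (ms).
#' @param deltaWindow delta-wave measurement window after onset (ms).
#' @return list of class `ECGFeatures`.
#' @export
extractFeatures <- function(ecg, qrsOnset = NULL, qrsOffset = NULL,
                            deltaWindow = 40) {
  sig <- ecgSignal(ecg)
  per <- samplePeriod(ecg)
  nT <- nrow(sig)
  if (max(abs(sig)) < 1e-9)
    stop("features undefined: flat signal", call. = FALSE)
  if (is.null(qrsOnset)) {
    dv <- abs(diff(sig)) / per
    steep <- which(apply(dv, 1, max) > 0.2 * max(dv))
    qrsOnset <- (min(steep) - 1) * per
  }
  if (is.null(qrsOffset))
    qrsOffset <- min(qrsOnset + 160, (nT - 1) * per)
  iOn <- max(1L, 1L + floor(qrsOnset / per))
  iOff <- min(nT, 1L + ceiling(qrsOffset / per))
  iBase <- max(1L, iOn - round(10 / per)):iOn
  baseline <- colMeans(sig[iBase, , drop = FALSE])
  w <- sweep(sig[iOn:iOff, , drop = FALSE], 2, baseline)

  rAmp <- pmax(apply(w, 2, max), 0)
  sAmp <- pmin(apply(w, 2, min), 0)
  qrsPolarity <- sign(rAmp - abs(sAmp))

  iDelta <- iOn:min(nT, iOn + round(deltaWindow / per))
  deltaAmp <- colMeans(sig[iDelta, , drop = FALSE]) - baseline
  deltaPolarity <- sign(deltaAmp)

  inferior <- c("II", "aVF", "III")
  inferiorPositives <- sum(qrsPolarity[inferior] > 0)

  vLeads <- paste0("V", 1:6)
  trans <- which(rAmp[vLeads] > abs(sAmp[vLeads]))
  transitionLead <- if (length(trans)) vLeads[min(trans)] else NA_character_

  v1iRatio <- if (rAmp["I"] > 0) unname(rAmp["V1"] / rAmp["I"]) else Inf

  # minimum dV/dt within the downstroke leading into the V2 S trough
  v2 <- w[, "V2"]
  trough <- which.min(v2)
  minDvdtV2 <- if (trough > 1)
    min(diff(v2[1:trough])) / per else NA_real_

  out <- list(qrsOnset = qrsOnset, qrsOffset = qrsOffset,
              baseline = baseline, rAmp = rAmp, sAmp = sAmp,
              qrsPolarity = qrsPolarity, deltaAmp = deltaAmp,
              deltaPolarity = deltaPolarity,
              inferiorPositives = inferiorPositives,
              mostPositiveDelta = names(which.max(deltaAmp)),
              transitionLead = transitionLead, v1iRatio = v1iRatio,
              minDvdtV2 = minDvdtV2, deltaWindow = deltaWindow)
  class(out) <- c("ECGFeatures", "list")
  out
}

localizationResult <- function(algorithm, side, region, branch, features) {
  out <- list(algorithm = algorithm, side = side, region = region,
              branch = branch,
              features = features[c("qrsPolarity", "inferiorPositives",
                                    "mostPositiveDelta", "transitionLead",
                                    "v1iRatio")])
  class(out) <- c("Localization", "list")
  out
}

#' Pathway localization by inferior-lead counting (partial tree)
#'
#' V1 polarity selects the side (negative: right / tricuspid, positive:
#' left / mitral). On the right side the number of positive inferior
#' leads (II, aVF, III) and the V3 polarity discriminate further; only
#' the printed branches are implemented: three positive inferior leads
#' with a positive V3 map to the anterior RV septum (NH region), with a
#' negative V3 to right-anterior (RA). All other combinations, and the
#' entire left-sided branch (whose V1/I-ratio and lead II morphology
#' thresholds are not specified here), return "indeterminate" with the
#' unresolved branch named.
#'
#' @param features an [extractFeatures()] result.
#' @return list of class `Localization` with `algorithm`, `side`,
#'   `region`, `branch` and the feature values used.
#' @export
pambrunTree <- function(features) {
  f <- features
  if (f$qrsPolarity["V1"] < 0) {
    if (f$inferiorPositives == 3 && f$qrsPolarity["V3"] > 0)
      return(localizationResult("pambrun", "right", "NH (anterior RV septum)",
                                "V1-/3 inferior+/V3+", f))
    if (f$inferiorPositives == 3 && f$qrsPolarity["V3"] < 0)
      return(localizationResult("pambrun", "right", "RA",
                                "V1-/3 inferior+/V3-", f))
    return(localizationResult("pambrun", "right", "indeterminate",
      paste0("right-sided combination not printed (inferior positives = ",
             f$inferiorPositives, ")"), f))
  }
  localizationResult("pambrun", "left", "indeterminate",
    "left-sided V1/I-ratio and lead II morphology branch not specified", f)
}

#' Pathway localization by delta-wave and precordial transition (partial tree)
#'
#' V1 polarity selects the side. On the right side the printed
#' combination -- most positive delta wave in lead II with a precordial
#' transition in V2 or V3 -- maps to the anteroseptal RV; everything
#' else, including the whole left-sided branch, is indeterminate with
#' the branch named.
#'
#' @param features an [extractFeatures()] result.
#' @return list of class `Localization`.
#' @export
easyWpwTree <- function(features) {
  f <- features
  if (f$qrsPolarity["V1"] < 0) {
    if (identical(f$mostPositiveDelta, "II") &&
        !is.na(f$transitionLead) && f$transitionLead %in% c("V2", "V3"))
      return(localizationResult("easy-wpw", "right", "anteroseptal RV",
                                "V1-/delta II/transition V2-V3", f))
    return(localizationResult("easy-wpw", "right", "indeterminate",
      "right-sided (delta lead, transition) pair not printed", f))
  }
  localizationResult("easy-wpw", "left", "indeterminate",
                     "left-sided branch not printed", f)
}

#' Evaluate a localization algorithm against database ground truth
#'
#' Runs feature extraction (using the stored QRS ground-truth windows)
#' and a decision tree over every valid beat and tabulates predicted vs
#' true side and region.
#'
#' @param db an [ECGDatabase-class] object.
#' @param algorithm "pambrun", "easy-wpw", or a function mapping an
#'   `ECGFeatures` to a `Localization`.
#' @return list with `perBeat` (data.frame), `sideAccuracy` (among
#'   determinate side calls; NA when none), `indeterminateRate` and
#'   `confusion` (true region x predicted label counts).
#' @export
evaluateLocalization <- function(db, algorithm = "pambrun") {
  tree <- if (is.function(algorithm)) algorithm
          else switch(algorithm, pambrun = pambrunTree,
                      "easy-wpw" = easyWpwTree,
                      stop("unknown algorithm: ", algorithm, call. = FALSE))
  params <- dbParams(db)
  idx <- which(params$valid)
  stopIfNot(length(idx) > 0, "database has no valid beats")
  rows <- lapply(idx, function(i) {
    ecg <- new("ECG12",
               signal = t(dbSignals(db)[i, , ]), period = samplePeriod(db),
               filtered = TRUE, scaled = TRUE)
    colnames(ecg@signal) <- leadNames12
    loc <- tryCatch({
      f <- extractFeatures(ecg,
        qrsOnset = params$tEarliestVent[i] - 5,
        qrsOffset = params$tLatestVent[i] + 10)
      tree(f)
    }, error = function(e) NULL)
    if (is.null(loc))
      return(data.frame(beat = params$beat[i], trueSide = params$ventricle[i],
                        trueRegion = params$region[i],
                        predSide = NA_character_,
                        predRegion = NA_character_,
                        stringsAsFactors = FALSE))
    data.frame(beat = params$beat[i], trueSide = params$ventricle[i],
               trueRegion = params$region[i],
               predSide = loc$side, predRegion = loc$region,
               stringsAsFactors = FALSE)
  })
  perBeat <- do.call(rbind, rows)
  sideMap <- c(LV = "left", RV = "right")
  det <- !is.na(perBeat$predSide)
  sideAccuracy <- if (any(det))
    mean(sideMap[perBeat$trueSide[det]] == perBeat$predSide[det]) else NA_real_
  indeterminateRate <- mean(is.na(perBeat$predRegion) |
                              perBeat$predRegion == "indeterminate")
  confusion <- table(true = perBeat$trueRegion,
                     predicted = perBeat$predRegion, useNA = "ifany")
  list(perBeat = perBeat, sideAccuracy = sideAccuracy,
       indeterminateRate = indeterminateRate, confusion = confusion)
}
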