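bullseyeSectors <- c("inferolateral", "inferior", "inferoseptal",
                     "anteroseptal", "anterior", "anterolateral")

#' Bullseye region of a ventricular coordinate
#'
#' Partition of the sampled basal half of each ventricle into 12 regions:
#' two apicobasal rings (basal and mid) times six 60-degree rotational
#' sectors named after the AHA bullseye convention, applied symmetrically
#' to the RV with the septal sectors facing the LV. The transmural depth
#' plays no role. Points below the mid band are out of band and map to
#' NA.
#'
#' @param ventricle "LV" or "RV" (vectorized).
#' @param z,phi apicobasal and rotational coordinates (vectorized).
#' @param midBoundary lower apicobasal bound of the mid band.
#' @param basalBoundary boundary between the mid and basal bands.
#' @return character vector of region identifiers such as
#'   "LV_basal_anteroseptal", NA for out-of-band points.
#' @export
bullseyeRegion <- function(ventricle, z, phi, midBoundary = 0.5,
                           basalBoundary = 0.75) {
  n <- max(length(ventricle), length(z), length(phi))
  ventricle <- rep_len(as.character(ventricle), n)
  z <- rep_len(z, n)
  phi <- wrapAngle(rep_len(phi, n))
  ring <- ifelse(z >= basalBoundary, "basal",
                 ifelse(z >= midBoundary, "mid", NA_character_))
  # six 60-degree sectors, phi = 0 at mid-septum
  sectorIdx <- pmin(findInterval(phi, seq(-pi, pi, by = pi / 3),
                                 rightmost.closed = TRUE), 6L)
  sector <- bullseyeSectors[sectorIdx]
  out <- ifelse(is.na(ring), NA_character_,
                paste(ventricle, ring, sector, sep = "_"))
  out
}

#' All 12 region identifiers of one ventricle
#'
#' @param ventricle "LV" or "RV".
#' @return character vector of the 12 region identifiers.
#' @export
bullseyeRegions <- function(ventricle) {
  as.vector(outer(paste0(ventricle, "_", c("basal", "mid")),
                  bullseyeSectors, paste, sep = "_"))
}

#' Per-region signal statistics of an ECG database
#'
#' For every bullseye region with at least one valid beat: the beat
#' count, the pointwise mean 12-lead signal and the mean plus/minus two
#' standard deviation envelopes (regions with fewer than two beats
#' report the mean only, with NA envelopes).
#'
#' @param db an [ECGDatabase-class] object.
#' @return list of class `RegionalSummary`: per region a list with
#'   `count`, `mean`, `lower`, `upper` (12 x T matrices, mV), plus
#'   attributes `period` and `counts`.
#' @export
summarizeRegions <- function(db) {
  params <- dbParams(db)
  stopIfNot(nrow(params) > 0, "database is empty")
  ok <- which(params$valid & !is.na(params$region))
  out <- list()
  for (r in sort(unique(params$region[ok]))) {
    idx <- ok[params$region[ok] == r]
    sig <- dbSignals(db)[idx, , , drop = FALSE]
    m <- apply(sig, c(2, 3), mean)
    if (length(idx) >= 2) {
      s <- apply(sig, c(2, 3), stats::sd)
      lower <- m - 2 * s
      upper <- m + 2 * s
    } else {
      lower <- upper <- matrix(NA_real_, 12, dim(sig)[3])
    }
    out[[r]] <- list(count = length(idx), mean = m, lower = lower,
                     upper = upper)
  }
  attr(out, "period") <- samplePeriod(db)
  attr(out, "counts") <- vapply(out, `[[`, integer(1), "count")
  class(out) <- c("RegionalSummary", "list")
  out
}

#' Export a regional summary as per-region CSV traces
#'
#' One CSV per region (mean and envelope traces per lead), named by the
#' region identifier.
#'
#' @param summary a [summarizeRegions()] result.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeRegionalSummary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  period <- attr(summary, "period")
  for (r in names(summary)) {
    s <- summary[[r]]
    tt <- seq(0, by = period, length.out = ncol(s$mean))
    df <- data.frame(time_ms = tt, t(s$mean), t(s$lower), t(s$upper))
    names(df) <- c("time_ms", paste0("mean_", leadNames12),
                   paste0("lower_", leadNames12),
                   paste0("upper_", leadNames12))
    utils::write.csv(df, file.path(dir, paste0(r, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
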