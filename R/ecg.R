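#' Pseudo-ECG lead weights for a set of field points
#'
#' Infinite-medium homogeneous pseudo-ECG: the extracellular potential at
#' an electrode is the volume integral of grad(Vm) . grad(1/r) over the
#' tissue, discretized on the edge graph as the Laplacian quadratic form
#' sum over edges of w_uv (Vm_u - Vm_v)(1/r_u - 1/r_v), with edge weight
#' w_uv = mean node volume / length^2. Since this is linear in Vm, each
#' electrode reduces to a per-node weight vector computed once per
#' anatomy.
#'
#' @param anatomy a [CardiacAnatomy-class] object.
#' @param positions numeric matrix (E x 3, mm) of field points.
#' @param gain global gain constant mapping the discrete integral to mV.
#' @return numeric matrix (E x N) of per-node weights.
#' @keywords internal
leadWeights <- function(anatomy, positions, gain = ecgGainDefault) {
  nodes <- anatomy@nodes
  e <- anatomy@edges
  w <- (anatomy@nodeVolume[e$from] + anatomy@nodeVolume[e$to]) /
    (2 * pmax(e$len, 0.5)^2)
  bb <- apply(nodes, 2, range)
  out <- matrix(0, nrow(positions), nrow(nodes))
  for (k in seq_len(nrow(positions))) {
    if (all(positions[k, ] >= bb[1, ] - 1 & positions[k, ] <= bb[2, ] + 1))
      stop("electrode position lies inside the tissue bounding box",
           call. = FALSE)
    r <- sqrt(colSums((t(nodes) - positions[k, ])^2))
    g <- 1 / r
    dg <- g[e$from] - g[e$to]
    a <- numeric(nrow(nodes))
    acc <- rowsum(c(w * dg, -w * dg), c(e$from, e$to))
    a[as.integer(rownames(acc))] <- acc
    out[k, ] <- gain * a
  }
  rownames(out) <- rownames(positions)
  out
}

# Gain calibrated once so that sinus-rhythm QRS amplitudes on the default
# anatomy are order 1 mV before the global 0.32 scaling. Negative sign:
# the extracellular potential is -k * integral(grad Vm . grad(1/r)) dV, so
# a wavefront travelling towards an electrode deflects it positively.
ecgGainDefault <- -0.028

#' Extracellular potential trace at an arbitrary field point
#'
#' @param vm a [buildVm()] result (or a nodes x T matrix).
#' @param anatomy a [CardiacAnatomy-class] object.
#' @param position numeric length-3 point (mm), outside the tissue.
#' @param gain global gain constant.
#' @return numeric potential trace (mV), one value per sample.
#' @export
electrodePotential <- function(vm, anatomy, position,
                               gain = ecgGainDefault) {
  V <- if (is.list(vm)) vm$vm else vm
  A <- leadWeights(anatomy, matrix(position, 1), gain = gain)
  drop(A %*% V)
}

#' Assemble the 12-lead ECG from nine electrode potentials
#'
#' Standard clinical lead derivation: limb leads from the Einthoven
#' triangle, augmented leads from limb pairs, precordial leads referenced
#' to the Wilson central terminal (the mean of RA, LA and LL).
#'
#' @param potentials numeric matrix (T x 9) with columns RA, LA, LL,
#'   V1..V6 (mV), or a 9 x T matrix which is transposed.
#' @param period sample period (ms).
#' @return an [ECG12-class] object.
#' @export
assemble12Lead <- function(potentials, period = 1) {
  p <- potentials
  if (nrow(p) == 9 && ncol(p) != 9) p <- t(p)
  stopIfNot(ncol(p) == 9, "nine electrode traces (RA, LA, LL, V1..V6) required")
  if (!is.null(colnames(p)))
    p <- p[, c("RA", "LA", "LL", paste0("V", 1:6)), drop = FALSE]
  RA <- p[, 1]; LA <- p[, 2]; LL <- p[, 3]
  wct <- (RA + LA + LL) / 3
  sig <- cbind(I = LA - RA, II = LL - RA, III = LL - LA,
               aVR = RA - (LA + LL) / 2, aVL = LA - (RA + LL) / 2,
               aVF = LL - (RA + LA) / 2,
               p[, 4:9] - wct)
  colnames(sig) <- leadNames12
  new("ECG12", signal = sig, period = period, filtered = FALSE,
      scaled = FALSE)
}

#' Low-pass filter and scale a 12-lead ECG
#'
#' Zero-phase 4th-order Butterworth low-pass at the cutoff (default
#' 150 Hz), then multiplication of all traces by a global amplitude
#' scaling factor (default 0.32). Both operations are lead-wise linear, so
#' the Einthoven and Goldberger lead identities are preserved.
#'
#' @param ecg an [ECG12-class] object.
#' @param cutoff low-pass cutoff (Hz); must be below the Nyquist
#'   frequency of the sample grid.
#' @param scale global amplitude scaling factor.
#' @param order filter order.
#' @return the processed [ECG12-class] object with flags set.
#' @export
postprocessECG <- function(ecg, cutoff = 150, scale = 0.32, order = 4) {
  stopIfNot(is(ecg, "ECG12"), "ecg must be an ECG12 object")
  fs <- 1000 / ecg@period
  if (cutoff >= fs / 2)
    stop("cutoff must be below the Nyquist frequency (", fs / 2, " Hz)",
         call. = FALSE)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  sig <- apply(ecg@signal, 2, function(x) signal::filtfilt(bf, x))
  colnames(sig) <- colnames(ecg@signal)
  new("ECG12", signal = sig * scale, period = ecg@period,
      filtered = TRUE, scaled = TRUE)
}

#' Full forward map from membrane voltages to the processed 12-lead ECG
#'
#' Convenience wrapper: electrode potentials at the anatomy's nine
#' electrodes, lead assembly, then filtering and scaling.
#'
#' @param vm a [buildVm()] result (or nodes x T matrix).
#' @param anatomy a [CardiacAnatomy-class] object.
#' @param period sample period (ms).
#' @param cutoff,scale,gain see [postprocessECG()] and [leadWeights()].
#' @param postprocess apply filtering/scaling (default TRUE).
#' @return an [ECG12-class] object.
#' @export
forwardECG <- function(vm, anatomy, period = 1, cutoff = 150, scale = 0.32,
                       gain = ecgGainDefault, postprocess = TRUE) {
  V <- if (is.list(vm)) vm$vm else vm
  A <- leadWeights(anatomy, anatomy@electrodes, gain = gain)
  pot <- t(A %*% V)
  colnames(pot) <- rownames(anatomy@electrodes)
  ecg <- assemble12Lead(pot, period = period)
  if (postprocess) ecg <- postprocessECG(ecg, cutoff = cutoff, scale = scale)
  ecg
}

#' Write a 12-lead ECG as a wide CSV
#'
#' @param ecg an [ECG12-class] object.
#' @param path output CSV path (columns: time_ms + 12 leads, mV).
#' @return the path, invisibly.
#' @export
writeECGcsv <- function(ecg, path) {
  tt <- seq(0, by = ecg@period, length.out = nrow(ecg@signal))
  utils::write.csv(data.frame(time_ms = tt, ecg@signal, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
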