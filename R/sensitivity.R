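#' Parameter box for sensitivity analysis
#'
#' Min/max bounds of the analysed parameters (by default the four
#' pathway parameters rho, z, phi and tven) and the affine map onto the
#' normalized hypercube.
#'
#' @param bounds numeric 2 x p matrix (rows: min, max) with column
#'   names, or a data.frame/matrix of samples from which the observed
#'   ranges are taken.
#' @param paramNames parameter names when `bounds` are samples.
#' @return list of class `parameterBox` with `bounds` and `paramNames`.
#' @export
parameterBox <- function(bounds, paramNames = colnames(bounds)) {
  b <- as.matrix(bounds)
  if (nrow(b) > 2) b <- apply(b, 2, range)
  stopIfNot(nrow(b) == 2, "bounds must be a 2 x p min/max matrix or samples")
  stopIfNot(all(b[1, ] < b[2, ]), "each parameter needs min < max")
  colnames(b) <- paramNames %||% paste0("x", seq_len(ncol(b)))
  out <- list(bounds = b, paramNames = colnames(b))
  class(out) <- c("parameterBox", "list")
  out
}

# Affine map of samples onto [-1, 1]^p.
toUnitCube <- function(X, bounds) {
  X <- as.matrix(X)
  lo <- bounds[1, ]
  hi <- bounds[2, ]
  sweep(sweep(X, 2, (lo + hi) / 2), 2, (hi - lo) / 2, `/`)
}

# Total-degree multi-index set: all p-tuples of non-negative degrees with
# sum <= degree, constant term first, ordered by total degree.
totalDegreeIndices <- function(p, degree) {
  mi <- as.matrix(expand.grid(rep(list(0:degree), p)))
  mi <- mi[rowSums(mi) <= degree, , drop = FALSE]
  mi <- mi[order(rowSums(mi), apply(mi, 1, paste, collapse = ",")), ,
           drop = FALSE]
  dimnames(mi) <- NULL
  storage.mode(mi) <- "integer"
  mi
}

# Orthonormal Legendre polynomials (uniform measure on [-1,1]) up to
# `degree`, evaluated at x: matrix length(x) x (degree+1).
legendreOrthonormal <- function(x, degree) {
  n <- length(x)
  P <- matrix(0, n, degree + 1)
  P[, 1] <- 1
  if (degree >= 1) P[, 2] <- x
  if (degree >= 2) for (k in 1:(degree - 1))
    P[, k + 2] <- ((2 * k + 1) * x * P[, k + 1] - k * P[, k]) / (k + 1)
  sweep(P, 2, sqrt(2 * (0:degree) + 1), `*`)
}

# Design matrix of the tensorized orthonormal basis at normalized samples.
pceDesign <- function(U, multiIndex) {
  p <- ncol(U)
  maxDeg <- max(multiIndex)
  evals <- lapply(seq_len(p), function(j) legendreOrthonormal(U[, j], maxDeg))
  Phi <- matrix(1, nrow(U), nrow(multiIndex))
  for (j in seq_len(p)) {
    dj <- multiIndex[, j]
    Phi <- Phi * evals[[j]][, dj + 1, drop = FALSE]
  }
  Phi
}

#' Fit a polynomial chaos expansion surrogate
#'
#' Per-lead, per-timepoint least-squares regression of the signals onto a
#' total-degree tensorized orthonormal Legendre basis of the normalized
#' parameters.
#'
#' @param params numeric matrix/data.frame (samples x parameters).
#' @param signals numeric array (samples x leads x timepoints), matrix
#'   (samples x timepoints, treated as one lead) or vector (scalar
#'   output).
#' @param degree total-degree truncation (default 5).
#' @param box optional [parameterBox()]; defaults to the observed sample
#'   ranges.
#' @param time optional sample times (ms) of the signal grid.
#' @return a [PCEModel-class] object.
#' @export
fitPCE <- function(params, signals, degree = 5, box = NULL, time = NULL) {
  X <- as.matrix(params)
  if (is.null(box)) box <- parameterBox(X)
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1)
  if (length(dim(signals)) == 2)
    signals <- array(signals, c(nrow(signals), 1, ncol(signals)))
  n <- dim(signals)[1]
  nL <- dim(signals)[2]
  nT <- dim(signals)[3]
  stopIfNot(nrow(X) == n, "params and signals must have matching sample counts")
  mi <- totalDegreeIndices(ncol(X), degree)
  P <- nrow(mi)
  if (n < 2 * P)
    stop("underdetermined system: ", P, " basis terms require at least ",
         2 * P, " samples (got ", n, ")", call. = FALSE)
  U <- toUnitCube(X, box$bounds)
  Phi <- pceDesign(U, mi)
  Y <- matrix(signals, n, nL * nT)
  qrPhi <- qr(Phi)
  C <- qr.coef(qrPhi, Y)
  C[is.na(C)] <- 0
  res <- Y - Phi %*% C
  rms <- sqrt(colMeans(res^2))
  tt <- time %||% seq_len(nT)
  new("PCEModel", coef = array(C, c(P, nL, nT)), multiIndex = mi,
      degree = as.integer(degree), paramNames = box$paramNames,
      bounds = box$bounds, residual = matrix(rms, nL, nT),
      nSamples = as.integer(n), time = as.numeric(tt))
}

#' Evaluate a PCE surrogate at new parameter values
#'
#' @param model a [PCEModel-class] object.
#' @param params numeric matrix (samples x parameters) on the original
#'   scale.
#' @return numeric array (samples x leads x timepoints).
#' @export
evaluatePCE <- function(model, params) {
  X <- as.matrix(params)
  U <- toUnitCube(X, model@bounds)
  Phi <- pceDesign(U, model@multiIndex)
  dims <- dim(model@coef)
  out <- Phi %*% matrix(model@coef, dims[1], dims[2] * dims[3])
  array(out, c(nrow(X), dims[2], dims[3]))
}

#' Time-resolved Sobol indices from a PCE surrogate
#'
#' For every parameter combination (multi-index support set) the fraction
#' of surrogate variance carried by the basis terms with exactly that
#' support, per lead and timepoint, together with the surrogate standard
#' deviation sigma(t). Indices are masked (NA) where sigma(t) falls
#' below the threshold.
#'
#' @param model a [PCEModel-class] object.
#' @param sigmaMask sigma threshold (mV) below which indices are masked.
#' @return a [SobolResult-class] object.
#' @export
sobolTimeSeries <- function(model, sigmaMask = 1e-9) {
  mi <- model@multiIndex
  p <- ncol(mi)
  support <- mi > 0
  combos <- apply(support, 1, function(s)
    paste(model@paramNames[s], collapse = ":"))
  keep <- which(rowSums(support) > 0)   # drop the constant term
  comboLevels <- unique(combos[keep])
  comboOrder <- vapply(strsplit(comboLevels, ":"), length, integer(1))
  ord <- order(comboOrder, match(sub(":.*", "", comboLevels),
                                 model@paramNames))
  comboLevels <- comboLevels[ord]
  comboOrder <- comboOrder[ord]

  dims <- dim(model@coef)
  nL <- dims[2]; nT <- dims[3]
  C2 <- matrix(model@coef^2, dims[1], nL * nT)
  totVar <- colSums(C2[keep, , drop = FALSE])
  grp <- factor(combos[keep], levels = comboLevels)
  varByCombo <- rowsum(C2[keep, , drop = FALSE], grp)
  S <- sweep(varByCombo, 2, totVar, `/`)
  sigma <- sqrt(totVar)
  S[, sigma < sigmaMask] <- NA_real_
  new("SobolResult",
      indices = array(S, c(length(comboLevels), nL, nT),
                      dimnames = list(comboLevels, NULL, NULL)),
      sigma = matrix(sigma, nL, nT), combos = comboLevels,
      comboOrder = comboOrder, time = model@time)
}

#' Sigma-weighted and time-integrated sensitivities
#'
#' Weighted time-resolved sensitivities (Sobol index times signal
#' standard deviation, mV), their time integrals (trapezoidal rule, in
#' mV s) as the measure of overall measurable parameter importance, and
#' the proportions normalized by the integrated sigma, which sum to one
#' per lead.
#'
#' @param sobol a [SobolResult-class] object.
#' @return a [SensitivityResult-class] object.
#' @export
integrateSensitivity <- function(sobol) {
  S <- sobol@indices
  dims <- dim(S)
  sigma <- sobol@sigma
  tSec <- sobol@time / 1000
  weighted <- S * rep(sigma, each = dims[1])
  dim(weighted) <- dims
  weighted[is.na(weighted)] <- 0
  integrated <- apply(weighted, c(1, 2), function(y)
    pracma::trapz(tSec, y))
  sigmaInt <- apply(sigma, 1, function(y) pracma::trapz(tSec, y))
  proportions <- sweep(integrated, 2, sigmaInt, `/`)
  dimnames(integrated) <- dimnames(proportions) <-
    list(sobol@combos, NULL)
  new("SensitivityResult", weighted = weighted, integrated = integrated,
      proportions = proportions, combos = sobol@combos,
      comboOrder = sobol@comboOrder, time = sobol@time)
}

#' Full sensitivity analysis of an ECG database
#'
#' Fits the PCE surrogate over (rho, z, phi, tven) for one ventricle's
#' beats and returns the weighted/integrated sensitivities.
#'
#' @param db an [ECGDatabase-class] object.
#' @param ventricle "LV" or "RV".
#' @param degree PCE total degree.
#' @return list with `model`, `sobol`, `sensitivity`.
#' @export
analyzeSensitivity <- function(db, ventricle, degree = 5) {
  params <- dbParams(db)
  idx <- which(params$valid & params$ventricle == ventricle)
  stopIfNot(length(idx) > 0, "no valid beats for the requested ventricle")
  X <- as.matrix(params[idx, c("rho", "z", "phi", "tven")])
  nT <- dim(dbSignals(db))[3]
  tt <- seq(0, by = samplePeriod(db), length.out = nT)
  model <- fitPCE(X, dbSignals(db)[idx, , , drop = FALSE], degree = degree,
                  time = tt)
  sobol <- sobolTimeSeries(model)
  list(model = model, sobol = sobol,
       sensitivity = integrateSensitivity(sobol))
}

#' Surrogate reconstruction error
#'
#' Reconstructs a random subset of database beats with the PCE and
#' reports the relative L2 error, normalized by the signal variance of
#' the dataset: per lead the L2 norm of (simulated - reconstructed) is
#' divided by the L2 norm of the dataset's pointwise standard-deviation
#' trace (pooled over all leads if `normalization = "pooled"`), then
#' averaged over leads. Returns mean and SD over beats.
#'
#' @param model a [PCEModel-class] object fitted on the database.
#' @param db an [ECGDatabase-class] object.
#' @param ventricle which ventricle's beats to sample.
#' @param nRandom number of beats to reconstruct.
#' @param seed RNG seed for the subset draw.
#' @param normalization "pooled" (default) or "perlead".
#' @return list with `mean`, `sd`, `perBeat` (relative errors).
#' @export
surrogateError <- function(model, db, ventricle = c("LV", "RV"),
                           nRandom = 100, seed = 1L,
                           normalization = c("pooled", "perlead")) {
  normalization <- match.arg(normalization)
  ventricle <- match.arg(ventricle)
  params <- dbParams(db)
  idx <- which(params$valid & params$ventricle == ventricle)
  stopIfNot(length(idx) > 0, "no valid beats for the requested ventricle")
  sig <- dbSignals(db)[idx, , , drop = FALSE]
  sdTrace <- apply(sig, c(2, 3), stats::sd)     # leads x T
  denomLead <- sqrt(rowSums(sdTrace^2))
  if (normalization == "pooled")
    denomLead <- rep(sqrt(mean(rowSums(sdTrace^2))), 12)
  set.seed(seed)
  pick <- sample(seq_along(idx), min(nRandom, length(idx)))
  X <- as.matrix(params[idx[pick], c("rho", "z", "phi", "tven")])
  recon <- evaluatePCE(model, X)
  perBeat <- vapply(seq_along(pick), function(k) {
    errLead <- sqrt(rowSums((sig[pick[k], , ] - recon[k, , ])^2))
    mean(errLead / denomLead)
  }, numeric(1))
  list(mean = mean(perBeat), sd = stats::sd(perBeat), perBeat = perBeat)
}
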