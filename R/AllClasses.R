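#' CardiacAnatomy: synthetic biventricular anatomy with universal coordinates
#'
#' Container for the procedurally built heart model: node coordinates, the
#' per-node universal cardiac coordinate (UCC) record, tissue tags, the
#' electrical and geometric edge graphs, conduction-velocity field, torso
#' electrodes, His-Purkinje fascicular root sites and the sinoatrial node.
#'
#' Ventricular UCC records store apicobasal `z` in [0,1] (0 = apex,
#' 1 = base), rotational `phi` in (-pi, pi] (0 at mid-septum, increasing
#' towards the anterior wall) and transmural `rho` in [0,1] (0 on the
#' cavity/endocardial surface). Atrial nodes reuse the same three columns
#' for the atrial triple (alpha, gamma, beta): `z` holds alpha (normalized
#' shell height), `phi` holds gamma (global rotational angle) and `rho`
#' holds beta (transmural depth).
#'
#' @slot nodes numeric matrix (N x 3), node coordinates in mm.
#' @slot ucc data.frame with columns `ventricle` ("LV","RV","atria"), `z`,
#'   `phi`, `rho` as described above.
#' @slot tissue character vector per node: "LV", "RV", "atria" or "RVOT"
#'   (electrically inert right-ventricular outflow tract).
#' @slot surface data.frame of logicals `endo`, `epi`, `base` per node.
#' @slot edges data.frame (`from`, `to`, `len`) of electrical edges; atrial
#'   and ventricular node sets share no electrical edge.
#' @slot geomEdges data.frame (`from`, `to`, `len`) of geometric edges:
#'   the electrical edges plus annulus bridging edges, used for geodesic
#'   pathway-length computation only.
#' @slot cv numeric per-node conduction velocity (m/s).
#' @slot nodeVolume numeric per-node lumped tissue volume (mm^3).
#' @slot electrodes numeric matrix (9 x 3, mm) with rownames RA, LA, LL,
#'   V1..V6.
#' @slot rootSites data.frame (`node`, `time`) of His-Purkinje fascicular
#'   root sites and their activation offsets (ms).
#' @slot saNode integer index of the sinoatrial node.
#' @slot config list, the [anatomyConfig()] the model was built from.
#' @seealso [buildAnatomy()]
#' @export
setClass("CardiacAnatomy",
  representation(
    nodes = "matrix",
    ucc = "data.frame",
    tissue = "character",
    surface = "data.frame",
    edges = "data.frame",
    geomEdges = "data.frame",
    cv = "numeric",
    nodeVolume = "numeric",
    electrodes = "matrix",
    rootSites = "data.frame",
    saNode = "integer",
    config = "list"
  )
)

setValidity("CardiacAnatomy", function(object) {
  msg <- character(0)
  n <- nrow(object@nodes)
  if (ncol(object@nodes) != 3) msg <- c(msg, "nodes must be an N x 3 matrix")
  if (nrow(object@ucc) != n) msg <- c(msg, "ucc must have one row per node")
  if (length(object@tissue) != n) msg <- c(msg, "tissue must have one tag per node")
  if (!all(object@tissue %in% c("LV", "RV", "atria", "RVOT")))
    msg <- c(msg, "unknown tissue tag")
  if (length(object@cv) != n || any(object@cv <= 0))
    msg <- c(msg, "cv must be positive per node")
  ed <- object@edges
  if (nrow(ed) > 0) {
    if (any(ed$from < 1 | ed$from > n | ed$to < 1 | ed$to > n))
      msg <- c(msg, "edge endpoints out of range")
    atr <- object@tissue == "atria"
    if (any(atr[ed$from] != atr[ed$to]))
      msg <- c(msg, "electrical edge connects atrial and ventricular tissue")
  }
  vent <- object@ucc$ventricle %in% c("LV", "RV")
  if (any(vent)) {
    u <- object@ucc[vent, ]
    if (any(u$z < 0 | u$z > 1 | u$rho < 0 | u$rho > 1))
      msg <- c(msg, "ventricular UCC out of range")
    if (any(u$phi <= -pi - 1e-9 | u$phi > pi + 1e-9))
      msg <- c(msg, "phi out of (-pi, pi]")
  }
  if (nrow(object@electrodes) != 9)
    msg <- c(msg, "exactly 9 electrodes required")
  bb <- apply(object@nodes, 2, range)
  inside <- apply(object@electrodes, 1, function(p)
    all(p >= bb[1, ] & p <= bb[2, ]))
  if (any(inside))
    msg <- c(msg, "electrodes must lie outside the tissue bounding box")
  if (nrow(object@rootSites) > 0 && any(object@rootSites$time < 0))
    msg <- c(msg, "root-site activation times must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ECG12: a 12-lead electrocardiogram
#'
#' Signal matrix of the standard 12 leads on a uniform sample grid, plus
#' processing flags recording whether the low-pass filter and the global
#' amplitude scaling have been applied.
#'
#' @slot signal numeric matrix (T x 12, mV) with columns I, II, III, aVR,
#'   aVL, aVF, V1..V6.
#' @slot period sample period in ms.
#' @slot filtered logical, low-pass filter applied.
#' @slot scaled logical, global amplitude scaling applied.
#' @export
setClass("ECG12",
  representation(signal = "matrix", period = "numeric",
                 filtered = "logical", scaled = "logical"),
  prototype(period = 1, filtered = FALSE, scaled = FALSE)
)

leadNames12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
                 "V1", "V2", "V3", "V4", "V5", "V6")

setValidity("ECG12", function(object) {
  msg <- character(0)
  if (ncol(object@signal) != 12 ||
      !identical(colnames(object@signal), leadNames12))
    msg <- c(msg, "signal must have the 12 standard lead columns")
  if (length(object@period) != 1 || object@period <= 0)
    msg <- c(msg, "period must be a positive scalar (ms)")
  if (length(msg)) msg else TRUE
})

#' ECGDatabase: a swept accessory-pathway ECG database
#'
#' Parameter table plus signal array for a set of simulated pre-excited
#' beats. Row i of `params` describes the accessory pathway that produced
#' `signals[i, , ]`.
#'
#' @slot params data.frame, one row per beat: the full pathway parameter
#'   vector (alpha, gamma, beta, cvap, rho, z, phi, ventricle), localized
#'   node indices, pathway length `d` (mm), `tatria`, `tven` (ms), bullseye
#'   `region`, QRS-window ground truth (`tEarliestVent`, `tLatestVent`) and
#'   a `valid` flag.
#' @slot signals numeric array (beats x 12 leads x T samples, mV).
#' @slot period sample period (ms).
#' @slot meta list of provenance metadata (schema, seed, config hash).
#' @export
setClass("ECGDatabase",
  representation(params = "data.frame", signals = "array",
                 period = "numeric", meta = "list")
)

setValidity("ECGDatabase", function(object) {
  msg <- character(0)
  if (nrow(object@params) != dim(object@signals)[1])
    msg <- c(msg, "params rows must match signal count")
  if (length(dim(object@signals)) != 3 || dim(object@signals)[2] != 12)
    msg <- c(msg, "signals must be beats x 12 x T")
  if (nrow(object@params) > 0) {
    ok <- object@params$valid
    if (any(!is.finite(object@params$tven[ok])))
      msg <- c(msg, "every valid beat must have finite tven")
  }
  if (length(msg)) msg else TRUE
})

#' PCEModel: polynomial chaos expansion surrogate of an ECG ensemble
#'
#' Per-lead, per-timepoint expansion coefficients over a total-degree
#' tensorized orthonormal Legendre basis of the normalized input
#' parameters.
#'
#' @slot coef numeric array (basis terms x leads x timepoints).
#' @slot multiIndex integer matrix (basis terms x parameters), per-term
#'   polynomial degree in each parameter.
#' @slot degree integer, total-degree truncation.
#' @slot paramNames character, parameter names.
#' @slot bounds numeric matrix (2 x parameters): min/max of the box.
#' @slot residual numeric matrix (leads x timepoints), RMS fit residual.
#' @slot nSamples integer, number of training samples.
#' @slot time numeric, sample times (ms) of the fitted signal grid.
#' @export
setClass("PCEModel",
  representation(coef = "array", multiIndex = "matrix", degree = "integer",
                 paramNames = "character", bounds = "matrix",
                 residual = "matrix", nSamples = "integer", time = "numeric")
)

setValidity("PCEModel", function(object) {
  msg <- character(0)
  if (dim(object@coef)[1] != nrow(object@multiIndex))
    msg <- c(msg, "coef rows must match multi-index count")
  if (ncol(object@multiIndex) != length(object@paramNames))
    msg <- c(msg, "multiIndex columns must match parameter names")
  if (ncol(object@bounds) != length(object@paramNames) ||
      nrow(object@bounds) != 2 || any(object@bounds[1, ] >= object@bounds[2, ]))
    msg <- c(msg, "bounds must be a 2 x p matrix with min < max")
  if (length(msg)) msg else TRUE
})

#' SobolResult: time-resolved Sobol indices of a PCE surrogate
#'
#' @slot indices numeric array (combinations x leads x timepoints),
#'   variance fractions per parameter combination; NA where the total
#'   variance is below the mask threshold.
#' @slot sigma numeric matrix (leads x timepoints), surrogate standard
#'   deviation of the signal (mV).
#' @slot combos character, combination labels such as "tven" or "tven:phi".
#' @slot comboOrder integer, interaction order of each combination.
#' @slot time numeric, sample times in ms.
#' @export
setClass("SobolResult",
  representation(indices = "array", sigma = "matrix", combos = "character",
                 comboOrder = "integer", time = "numeric")
)

#' SensitivityResult: sigma-weighted and integrated sensitivities
#'
#' Time-resolved weighted sensitivities (Sobol index times signal standard
#' deviation, in mV), their time integrals (mV s) as a measure of
#' measurable signal change, and the normalized proportions of parameter
#' importance which sum to one per lead.
#'
#' @slot weighted numeric array (combinations x leads x timepoints, mV).
#' @slot integrated numeric matrix (combinations x leads, mV s).
#' @slot proportions numeric matrix (combinations x leads, dimensionless).
#' @slot combos character, combination labels.
#' @slot comboOrder integer, interaction order per combination.
#' @slot time numeric, sample times in ms.
#' @export
setClass("SensitivityResult",
  representation(weighted = "array", integrated = "matrix",
                 proportions = "matrix", combos = "character",
                 comboOrder = "integer", time = "numeric")
)

setValidity("SensitivityResult", function(object) {
  msg <- character(0)
  pr <- object@proportions
  if (any(pr < -1e-9, na.rm = TRUE))
    msg <- c(msg, "proportions must be non-negative")
  if (length(msg)) msg else TRUE
})
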