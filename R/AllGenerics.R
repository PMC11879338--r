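#' @include AllClasses.R
NULL

#' Accessors for wpwsim S4 objects
#'
#' Slot access goes through these accessors rather than `@`.
#'
#' @param x a wpwsim S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeCoords", function(x) standardGeneric("nodeCoords"))
#' @rdname accessors
#' @export
setMethod("nodeCoords", "CardiacAnatomy", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("uccCoords", function(x) standardGeneric("uccCoords"))
#' @rdname accessors
#' @export
setMethod("uccCoords", "CardiacAnatomy", function(x) x@ucc)

#' @rdname accessors
#' @export
setGeneric("tissueTags", function(x) standardGeneric("tissueTags"))
#' @rdname accessors
#' @export
setMethod("tissueTags", "CardiacAnatomy", function(x) x@tissue)

#' @rdname accessors
#' @export
setGeneric("electrodePositions", function(x) standardGeneric("electrodePositions"))
#' @rdname accessors
#' @export
setMethod("electrodePositions", "CardiacAnatomy", function(x) x@electrodes)

#' @rdname accessors
#' @export
setGeneric("rootSites", function(x) standardGeneric("rootSites"))
#' @rdname accessors
#' @export
setMethod("rootSites", "CardiacAnatomy", function(x) x@rootSites)

#' @rdname accessors
#' @export
setGeneric("saNode", function(x) standardGeneric("saNode"))
#' @rdname accessors
#' @export
setMethod("saNode", "CardiacAnatomy", function(x) x@saNode)

#' @rdname accessors
#' @export
setGeneric("ecgSignal", function(x) standardGeneric("ecgSignal"))
#' @rdname accessors
#' @export
setMethod("ecgSignal", "ECG12", function(x) x@signal)

#' @rdname accessors
#' @export
setGeneric("samplePeriod", function(x) standardGeneric("samplePeriod"))
#' @rdname accessors
#' @export
setMethod("samplePeriod", "ECG12", function(x) x@period)
#' @rdname accessors
#' @export
setMethod("samplePeriod", "ECGDatabase", function(x) x@period)

#' @rdname accessors
#' @export
setGeneric("dbParams", function(x) standardGeneric("dbParams"))
#' @rdname accessors
#' @export
setMethod("dbParams", "ECGDatabase", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("dbSignals", function(x) standardGeneric("dbSignals"))
#' @rdname accessors
#' @export
setMethod("dbSignals", "ECGDatabase", function(x) x@signals)

#' @rdname accessors
#' @export
setGeneric("dbMeta", function(x) standardGeneric("dbMeta"))
#' @rdname accessors
#' @export
setMethod("dbMeta", "ECGDatabase", function(x) x@meta)

#' @rdname accessors
#' @export
setGeneric("sensitivityProportions", function(x) standardGeneric("sensitivityProportions"))
#' @rdname accessors
#' @export
setMethod("sensitivityProportions", "SensitivityResult", function(x) x@proportions)

#' @rdname accessors
#' @export
setGeneric("integratedSensitivities", function(x) standardGeneric("integratedSensitivities"))
#' @rdname accessors
#' @export
setMethod("integratedSensitivities", "SensitivityResult", function(x) x@integrated)

#' @rdname accessors
#' @export
setGeneric("sobolIndices", function(x) standardGeneric("sobolIndices"))
#' @rdname accessors
#' @export
setMethod("sobolIndices", "SobolResult", function(x) x@indices)

setMethod("show", "CardiacAnatomy", function(object) {
  tt <- table(object@tissue)
  cat("CardiacAnatomy:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "electrical edges\n")
  cat("  tissue:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  cat("  electrodes:", paste(rownames(object@electrodes), collapse = " "),
      "\n  root sites:", nrow(object@rootSites),
      "| sinoatrial node:", object@saNode, "\n")
})

setMethod("show", "ECG12", function(object) {
  cat("ECG12:", nrow(object@signal), "samples at", object@period, "ms",
      if (object@filtered) "| filtered" else "| unfiltered",
      if (object@scaled) "| scaled" else "| unscaled", "\n")
})

setMethod("show", "ECGDatabase", function(object) {
  cat("ECGDatabase:", nrow(object@params), "beats x 12 leads x",
      dim(object@signals)[3], "samples at", object@period, "ms\n")
  if (nrow(object@params))
    cat("  ventricles:", paste(names(table(object@params$ventricle)),
        table(object@params$ventricle), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PCEModel", function(object) {
  cat("PCEModel: degree", object@degree, "in",
      length(object@paramNames), "parameters (",
      paste(object@paramNames, collapse = ", "), ");",
      dim(object@coef)[1], "basis terms,",
      object@nSamples, "training samples\n")
})

setMethod("show", "SensitivityResult", function(object) {
  cat("SensitivityResult:", length(object@combos), "parameter combinations x",
      dim(object@weighted)[2], "leads\n")
})
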