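#' Define an antegrade accessory pathway
#'
#' The pathway parameter vector: atrial insertion site in atrial
#' coordinates (alpha, gamma, beta), pathway conduction velocity (m/s),
#' and ventricular exit site in ventricular UCC (rho, z, phi) with a
#' ventricle label. Either a full seven-parameter definition or, matching
#' the exemplar usage, a direct (tven, exit site) pair via `tven`.
#'
#' @param alpha,gamma,beta atrial insertion coordinates (alpha, beta in
#'   [0,1]; gamma in (-pi, pi]).
#' @param cvap pathway conduction velocity (m/s, default 2.0).
#' @param rho,z,phi ventricular exit coordinates.
#' @param ventricle "LV" or "RV".
#' @param tven optional prescribed pre-excitation time (ms); when given,
#'   the atrial insertion and d/CV timing are bypassed.
#' @return a list of class `APDefinition`.
#' @export
apDefinition <- function(alpha = NA, gamma = NA, beta = NA, cvap = 2.0,
                         rho, z, phi, ventricle, tven = NULL) {
  stopIfNot(cvap > 0, "cvap must be positive")
  stopIfNot(ventricle %in% c("LV", "RV"), "ventricle must be LV or RV")
  stopIfNot(rho >= 0 && rho <= 1 && z >= 0 && z <= 1,
            "exit coordinates out of range")
  if (is.null(tven)) {
    stopIfNot(is.finite(alpha) && alpha >= 0 && alpha <= 1 &&
              is.finite(beta) && beta >= 0 && beta <= 1 &&
              is.finite(gamma),
              "atrial insertion coordinates out of range")
  }
  out <- list(alpha = alpha, gamma = gamma, beta = beta, cvap = cvap,
              rho = rho, z = z, phi = wrapAngle(phi), ventricle = ventricle,
              tven = tven)
  class(out) <- c("APDefinition", "list")
  out
}

#' Geodesic path length between two mesh nodes
#'
#' Length (mm) of the shortest path on the combined geometric graph (the
#' electrical edges plus the annulus bridging edges, so atrioventricular
#' isolation is ignored for geometry).
#'
#' @param anatomy a [CardiacAnatomy-class] object.
#' @param a,b node indices.
#' @return geodesic length d (mm).
#' @export
pathLength <- function(anatomy, a, b) {
  n <- nrow(anatomy@nodes)
  stopIfNot(a >= 1 && a <= n && b >= 1 && b <= n, "node index out of range")
  if (a == b) return(0)
  g <- geomGraph(anatomy)
  d <- igraph::distances(g$graph, v = a, to = b, weights = g$len)[1, 1]
  if (!is.finite(d))
    stop("geometric graph is disconnected between the requested nodes",
         call. = FALSE)
  d
}

# Cached geometric igraph for repeated geodesic queries.
geomGraph <- function(anatomy) {
  g <- igraph::graph_from_edgelist(
    as.matrix(anatomy@geomEdges[, c("from", "to")]), directed = FALSE)
  if (igraph::vcount(g) < nrow(anatomy@nodes))
    g <- igraph::add_vertices(g, nrow(anatomy@nodes) - igraph::vcount(g))
  list(graph = g, len = anatomy@geomEdges$len)
}

#' Compute the ventricular pre-excitation time
#'
#' `tven = tatria + d / CVAP`, with d in mm and CVAP in m/s so that the
#' quotient is directly in ms.
#'
#' @param d geodesic pathway length (mm).
#' @param cvap pathway conduction velocity (m/s).
#' @param tatria activation time at the atrial insertion site (ms).
#' @return tven (ms).
#' @export
computeTven <- function(d, cvap, tatria) {
  stopIfNot(cvap > 0, "cvap must be positive")
  tatria + travelTimeMs(d, cvap)
}

#' Localize an accessory pathway onto the mesh
#'
#' Nearest-node localization of the atrial insertion and ventricular exit
#' sites in UCC space, geodesic pathway length, and the pre-excitation
#' timing (from the sinoatrial-driven atrial activation unless `tven` was
#' prescribed directly).
#'
#' @param anatomy a [CardiacAnatomy-class] object.
#' @param ap an [apDefinition()].
#' @param atrialMap optional precomputed atrial activation map (ms); when
#'   omitted it is solved from the sinoatrial node.
#' @return list of class `LocalizedAP` with fields `atrialNode`,
#'   `ventNode`, `d`, `tatria`, `tven`, `cvap`, `ventricle`.
#' @export
localizeAP <- function(anatomy, ap, atrialMap = NULL) {
  ventNode <- localizeUcc(anatomy, ap$ventricle, ap$z, ap$phi, ap$rho)
  if (!is.null(ap$tven)) {
    out <- list(atrialNode = NA_integer_, ventNode = ventNode,
                d = NA_real_, tatria = NA_real_, tven = ap$tven,
                cvap = ap$cvap, ventricle = ap$ventricle)
    class(out) <- c("LocalizedAP", "list")
    return(out)
  }
  atrialNode <- localizeUcc(anatomy, "atria", ap$alpha, ap$gamma, ap$beta)
  d <- pathLength(anatomy, atrialNode, ventNode)
  if (is.null(atrialMap))
    atrialMap <- solveEikonal(anatomy,
      data.frame(node = anatomy@saNode, time = 0))
  tatria <- atrialMap[atrialNode]
  if (!is.finite(tatria))
    stop("atrial insertion site is not reached by sinoatrial activation",
         call. = FALSE)
  out <- list(atrialNode = atrialNode, ventNode = ventNode, d = d,
              tatria = tatria, tven = computeTven(d, ap$cvap, tatria),
              cvap = ap$cvap, ventricle = ap$ventricle)
  class(out) <- c("LocalizedAP", "list")
  out
}

#' Simulate one 700 ms beat, with or without an accessory pathway
#'
#' Atrial activation is solved from the sinoatrial node. The ventricles
#' are activated by the five His-Purkinje root sites at their offsets
#' and, if an accessory pathway is given, additionally by its ventricular
#' exit node at `tven` (pre-excitation). Membrane voltages are recovered
#' with the action-potential template; atrial nodes use a fixed shorter
#' APD.
#'
#' @param anatomy a [CardiacAnatomy-class] object.
#' @param ap a `LocalizedAP` (from [localizeAP()]), an [apDefinition()],
#'   or NULL for plain sinus rhythm.
#' @param horizon beat length (ms, default 700).
#' @param period sample period (ms, default 1).
#' @param template an [apTemplate()].
#' @param apd0,apdSlope ventricular APD mapping coefficients.
#' @param atrialApd fixed atrial APD (ms).
#' @param atrialMap optional precomputed atrial activation map.
#' @return list with `atrialMap`, `ventMap` (full-length activation
#'   vectors, ms), `vm` (nodes x T mV), `time`, `ap` (the localized
#'   pathway or NULL), and the QRS ground-truth window
#'   `tEarliestVent`/`tLatestVent`.
#' @export
simulateBeat <- function(anatomy, ap = NULL, horizon = 700, period = 1,
                         template = apTemplate(), apd0 = 280,
                         apdSlope = -0.3, atrialApd = 150,
                         atrialMap = NULL) {
  if (is.null(atrialMap))
    atrialMap <- solveEikonal(anatomy,
      data.frame(node = anatomy@saNode, time = 0))
  if (inherits(ap, "APDefinition"))
    ap <- localizeAP(anatomy, ap, atrialMap = atrialMap)
  sources <- anatomy@rootSites
  if (!is.null(ap)) {
    if (ap$tven > horizon)
      stop("validation error: tven exceeds the simulation horizon",
           call. = FALSE)
    sources <- rbind(sources, data.frame(node = ap$ventNode, time = ap$tven))
  }
  ventMap <- solveEikonal(anatomy, sources)

  atr <- anatomy@tissue == "atria"
  tau <- ifelse(atr, atrialMap, ventMap)
  tau[atr & !is.finite(atrialMap)] <- Inf
  apd <- apdMap(ventMap, apd0 = apd0, slope = apdSlope)
  apd[atr] <- atrialApd
  vmf <- buildVm(tau, apd, template = template, horizon = horizon,
                 period = period)
  ventTau <- ventMap[!atr & is.finite(ventMap)]
  list(atrialMap = ifelse(atr, atrialMap, Inf),
       ventMap = ifelse(atr, Inf, ventMap),
       vm = vmf$vm, time = vmf$time, ap = ap,
       tEarliestVent = min(ventTau), tLatestVent = max(ventTau))
}
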