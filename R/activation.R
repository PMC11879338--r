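#' Solve the eikonal activation problem on the anatomy graph
#'
#' First-arrival activation times from a set of sources, computed as the
#' minimum over sources of (onset + graph-geodesic travel time) on the
#' electrical edge graph. The travel time of an edge is its length divided
#' by the harmonic mean of the endpoint conduction velocities (or an
#' explicit per-edge velocity for the fast interatrial connection).
#' Electrically inert nodes are excluded from propagation and remain
#' unreached.
#'
#' @param anatomy a [CardiacAnatomy-class] object, or a list with fields
#'   `edges` (data.frame from/to/len, optional cvOverride), `cv` (per-node
#'   m/s) and `n` (node count) for bare-graph use.
#' @param sources data.frame with columns `node` and `time` (ms onsets).
#' @param cv optional per-node conduction velocity override (m/s).
#' @return numeric vector of activation times tau (ms), `Inf` where
#'   unreached.
#' @export
solveEikonal <- function(anatomy, sources, cv = NULL) {
  if (is(anatomy, "CardiacAnatomy")) {
    edges <- anatomy@edges
    nNodes <- nrow(anatomy@nodes)
    cvNode <- cv %||% anatomy@cv
    inert <- anatomy@tissue == "RVOT"
  } else {
    edges <- anatomy$edges
    nNodes <- anatomy$n
    cvNode <- cv %||% anatomy$cv
    inert <- rep(FALSE, nNodes)
  }
  stopIfNot(nrow(sources) >= 1, "at least one source is required")
  stopIfNot(all(sources$node >= 1 & sources$node <= nNodes),
            "source node index out of range")
  stopIfNot(all(is.finite(sources$time)), "source onsets must be finite")
  stopIfNot(all(cvNode > 0), "conduction velocities must be positive")
  if (any(inert[sources$node]))
    stop("no-propagation error: source placed on inert tissue", call. = FALSE)

  keep <- !(inert[edges$from] | inert[edges$to])
  edges <- edges[keep, , drop = FALSE]
  cvEdge <- 2 / (1 / cvNode[edges$from] + 1 / cvNode[edges$to])
  if (!is.null(edges$cvOverride)) {
    ov <- !is.na(edges$cvOverride)
    cvEdge[ov] <- edges$cvOverride[ov]
  }
  w <- travelTimeMs(edges$len, cvEdge)
  g <- igraph::graph_from_edgelist(as.matrix(edges[, c("from", "to")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < nNodes)
    g <- igraph::add_vertices(g, nNodes - igraph::vcount(g))
  d <- igraph::distances(g, v = sources$node, weights = w,
                         algorithm = "dijkstra")
  tau <- do.call(pmin, lapply(seq_len(nrow(sources)),
                              function(i) sources$time[i] + d[i, ]))
  unname(tau)
}

#' Linear activation-to-APD mapping
#'
#' Action potential duration as an affine function of local activation
#' time, `APD(x) = apd0 + slope * (tau(x) - min tau)`, clipped below at a
#' positive floor. This prescribes a repolarization gradient in which
#' late-activated tissue has (for negative slope) shorter action
#' potentials.
#'
#' @param activation numeric activation map (ms); `Inf` entries allowed.
#' @param apd0 baseline APD (ms) at the earliest activation.
#' @param slope dimensionless APD change per ms of activation delay.
#' @param floor minimal APD (ms).
#' @return per-node APD (ms).
#' @export
apdMap <- function(activation, apd0 = 280, slope = -0.3, floor = 120) {
  stopIfNot(apd0 > 0, "apd0 must be positive")
  fin <- is.finite(activation)
  t0 <- if (any(fin)) min(activation[fin]) else 0
  apd <- apd0 + slope * (activation - t0)
  apd[!fin] <- apd0
  pmax(apd, floor)
}

#' Stylized action-potential template
#'
#' Piecewise-smooth template: linear upstroke of `upstroke` ms, a plateau
#' at peak for `plateauFrac` of the APD, then a cosine repolarization back
#' to rest, reaching rest at `upstroke + APD` after local activation.
#'
#' @param rest resting potential (mV).
#' @param peak peak potential (mV).
#' @param upstroke upstroke duration (ms).
#' @param plateauFrac fraction of the APD spent at the plateau.
#' @return list of template parameters.
#' @export
apTemplate <- function(rest = -85, peak = 30, upstroke = 1,
                       plateauFrac = 0.4) {
  stopIfNot(peak > rest, "peak potential must exceed resting potential")
  stopIfNot(upstroke > 0, "upstroke duration must be positive")
  stopIfNot(plateauFrac >= 0 && plateauFrac < 1,
            "plateauFrac must be in [0, 1)")
  list(rest = rest, peak = peak, upstroke = upstroke,
       plateauFrac = plateauFrac)
}

# Normalized template amplitude for elapsed times u (matrix ok) and APD
# (same shape as u, or recycled). Closed form: a clamped linear upstroke
# multiplied by a clamped cosine repolarization phase.
templateAmplitude <- function(u, apd, upstroke, plateauFrac) {
  up <- pmin.int(pmax.int(u / upstroke, 0), 1)
  phase <- (u - upstroke - plateauFrac * apd) / ((1 - plateauFrac) * apd)
  amp <- up * 0.5 * (1 + cos(pi * pmin.int(pmax.int(phase, 0), 1)))
  dim(amp) <- dim(u)
  amp
}

#' Construct membrane voltages from an activation map
#'
#' Reaction-eikonal voltage recovery without diffusion: every node's trace
#' is the action-potential template shifted to its activation time and
#' stretched to its APD. Unreached (infinite tau) nodes stay at rest.
#'
#' @param activation numeric activation map (ms).
#' @param apd per-node APD (ms), recycled if scalar.
#' @param template an [apTemplate()] list.
#' @param horizon simulation length (ms, default 700).
#' @param period sample period (ms, default 1).
#' @return list with `vm` (nodes x samples mV matrix), `time` (ms) and
#'   `apd`.
#' @export
buildVm <- function(activation, apd, template = apTemplate(),
                    horizon = 700, period = 1) {
  n <- length(activation)
  apd <- rep_len(apd, n)
  fin <- is.finite(activation)
  if (any(fin)) {
    need <- max(activation[fin] + template$upstroke + apd[fin])
    if (horizon < need)
      stop("truncation error: horizon ", horizon,
           " ms ends before full repolarization (needs ",
           ceiling(need), " ms)", call. = FALSE)
  }
  times <- seq(0, by = period, length.out = ceiling(horizon / period))
  act0 <- ifelse(fin, activation, Inf)
  u <- outer(-act0, times, `+`)          # elapsed time since activation
  u[!fin, ] <- -1
  amp <- templateAmplitude(u, matrix(apd, n, length(times)),
                           template$upstroke, template$plateauFrac)
  vm <- template$rest + (template$peak - template$rest) * amp
  list(vm = vm, time = times, apd = apd)
}
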