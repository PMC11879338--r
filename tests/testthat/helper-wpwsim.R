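# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

# Default-configuration anatomy, shared across tests.
testAnatomy <- function() {
  if (is.null(.fixtures$anatomy))
    .fixtures$anatomy <- buildAnatomy(anatomyConfig())
  .fixtures$anatomy
}

# Small swept database for bookkeeping-level tests.
testDb <- function() {
  if (is.null(.fixtures$db)) {
    an <- testAnatomy()
    s <- sampleAPs(sampleSpec(nPerVentricle = 15, seed = 11), an)
    .fixtures$db <- generateDatabase(s, an, seed = 11)
  }
  .fixtures$db
}

# Larger database for the directional/morphology acceptance properties.
acceptanceDb <- function() {
  if (is.null(.fixtures$adb)) {
    an <- testAnatomy()
    s <- sampleAPs(sampleSpec(nPerVentricle = 150, seed = 2024), an)
    .fixtures$adb <- generateDatabase(s, an, seed = 2024)
  }
  .fixtures$adb
}

# Independent shortest-path oracle: plain O(V^2) Dijkstra over an edge
# list, min over sources of (onset + distance). Written without igraph so
# it stays independent of the implementation under test.
oracleEikonal <- function(n, edges, weights, sources) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]; w <- weights[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  best <- rep(Inf, n)
  for (s in seq_len(nrow(sources))) {
    dist <- rep(Inf, n)
    dist[sources$node[s]] <- 0
    done <- rep(FALSE, n)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      for (r in seq_len(NROW(adj[[u]]))) {
        v <- adj[[u]][r, 1]; w <- adj[[u]][r, 2]
        if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
      }
    }
    best <- pmin(best, sources$time[s] + dist)
  }
  best
}

# Random connected weighted graph in bare-graph form for solveEikonal.
randomGraph <- function(n, extraEdges = 2L * n) {
  from <- 2:n
  to <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
  e1 <- cbind(from, to)                      # random spanning tree
  e2 <- cbind(sample.int(n, extraEdges, replace = TRUE),
              sample.int(n, extraEdges, replace = TRUE))
  e2 <- e2[e2[, 1] != e2[, 2], , drop = FALSE]
  e <- rbind(e1, e2)
  len <- stats::runif(nrow(e), 0.5, 5)
  list(edges = data.frame(from = e[, 1], to = e[, 2], len = len),
       cv = stats::runif(n, 0.3, 3), n = n)
}

# Random geometric graph on uniform points in a box (convex domain):
# k-nearest-neighbour connectivity, unit conduction velocity.
geometricGraph <- function(nPts = 700, k = 18, box = 24) {
  pts <- matrix(stats::runif(3 * nPts, 0, box), nPts, 3)
  d2 <- as.matrix(stats::dist(pts))
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nPts)) {
    nb <- order(d2[i, ])[2:(k + 1)]
    from <- c(from, rep(i, k)); to <- c(to, nb)
  }
  keep <- from < to
  e <- unique(cbind(from[keep], to[keep]))
  len <- sqrt(rowSums((pts[e[, 1], ] - pts[e[, 2], ])^2))
  list(graph = list(edges = data.frame(from = e[, 1], to = e[, 2],
                                       len = len),
                    cv = rep(1, nPts), n = nPts),
       points = pts, maxEdge = max(len))
}

# Synthetic ECG12 from per-lead traces (defaults: flat zero elsewhere).
syntheticEcg <- function(traces, nT = 300, period = 1) {
  leads <- c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
  sig <- matrix(0, nT, 12, dimnames = list(NULL, leads))
  for (nm in names(traces)) sig[, nm] <- traces[[nm]]
  methods::new("ECG12", signal = sig, period = period, filtered = TRUE,
               scaled = TRUE)
}

# ECGFeatures stand-in assembled directly from stated feature values,
# for exercising the decision trees on printed feature vectors.
featureVector <- function(v1, inferiorPositives = 3, v3 = 1,
                          mostPositiveDelta = "II", transitionLead = "V3",
                          v1iRatio = 1) {
  qrs <- c(I = 1, II = 1, III = 1, aVR = -1, aVL = -1, aVF = 1,
           V1 = v1, V2 = v1, V3 = v3, V4 = 1, V5 = 1, V6 = 1)
  f <- list(qrsPolarity = qrs, inferiorPositives = inferiorPositives,
            mostPositiveDelta = mostPositiveDelta,
            transitionLead = transitionLead, v1iRatio = v1iRatio)
  class(f) <- c("ECGFeatures", "list")
  f
}
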