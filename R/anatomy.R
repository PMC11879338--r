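#' Configuration of the synthetic biventricular anatomy
#'
#' Assembles and validates the parameter list from which [buildAnatomy()]
#' procedurally constructs the model: two thick-walled truncated ellipsoids
#' (LV and a thinner RV placed on the septal side, separated by a small
#' septal gap that is bridged electrically), an electrically isolated
#' atrial shell capping each base ring, nine torso-scale electrodes, five
#' His-Purkinje fascicular root sites and a fast endocardial layer
#' standing in for the distal Purkinje arborization.
#'
#' @param lvEndoRadius,lvEndoLong LV endocardial short/long semi-axes (mm).
#' @param lvWall LV wall thickness (mm).
#' @param rvEndoRadius,rvEndoLong RV endocardial short/long semi-axes (mm).
#' @param rvWall RV wall thickness (mm).
#' @param septalGap gap between the LV and RV epicardial surfaces at the
#'   septal tangent point (mm).
#' @param edgeLength target mesh edge length (mm).
#' @param atrialHeight height of the atrial shell above the base plane (mm).
#' @param electrodeRadius,electrodeHeight precordial electrode ring radius
#'   and height (mm, height relative to the base plane).
#' @param myocardialCV bulk myocardial conduction velocity (m/s).
#' @param fastEndoCV conduction velocity of the fast endocardial layer
#'   (m/s), applied where transmural rho < `fastEndoRho`.
#' @param fastEndoRho transmural extent of the fast endocardial layer.
#' @param atrialCV atrial conduction velocity (m/s).
#' @param interatrialCV conduction velocity of the fast interatrial
#'   connection (m/s).
#' @param hisOffset activation offset of the His-Purkinje root sites after
#'   sinoatrial onset (ms).
#' @param rvotPhiStart,rvotExtent angular start and extent (rad) of the
#'   electrically inert right-ventricular outflow tract sector.
#' @param rvotZmin apicobasal lower bound of the inert RVOT sector.
#' @param septalBridgeMax maximal length (mm) of electrical bridging edges
#'   across the septal gap.
#' @param uccTol tolerance (mm) for declaring a point outside the
#'   myocardium in [uccOfPoint()].
#' @param seed integer random seed recorded with the anatomy.
#' @return a validated named list of class `anatomyConfig`.
#' @export
anatomyConfig <- function(lvEndoRadius = 22, lvEndoLong = 60, lvWall = 10,
                          rvEndoRadius = 18, rvEndoLong = 48, rvWall = 5,
                          septalGap = 2, edgeLength = 6, atrialHeight = 12,
                          electrodeRadius = 120, electrodeHeight = -20,
                          myocardialCV = 0.6, fastEndoCV = 1.5,
                          fastEndoRho = 0.15, atrialCV = 0.8,
                          interatrialCV = 2.0, hisOffset = 150,
                          rvotPhiStart = pi / 3, rvotExtent = 0.7,
                          rvotZmin = 0.8, septalBridgeMax = 15,
                          uccTol = 4, seed = 1L) {
  cfg <- list(lvEndoRadius = lvEndoRadius, lvEndoLong = lvEndoLong,
              lvWall = lvWall, rvEndoRadius = rvEndoRadius,
              rvEndoLong = rvEndoLong, rvWall = rvWall,
              septalGap = septalGap, edgeLength = edgeLength,
              atrialHeight = atrialHeight,
              electrodeRadius = electrodeRadius,
              electrodeHeight = electrodeHeight,
              myocardialCV = myocardialCV, fastEndoCV = fastEndoCV,
              fastEndoRho = fastEndoRho, atrialCV = atrialCV,
              interatrialCV = interatrialCV, hisOffset = hisOffset,
              rvotPhiStart = rvotPhiStart, rvotExtent = rvotExtent,
              rvotZmin = rvotZmin, septalBridgeMax = septalBridgeMax,
              uccTol = uccTol, seed = as.integer(seed))
  lens <- c(lvEndoRadius, lvEndoLong, lvWall, rvEndoRadius, rvEndoLong,
            rvWall, edgeLength, atrialHeight, electrodeRadius)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("anatomy configuration error: all lengths must be positive",
         call. = FALSE)
  cvs <- c(myocardialCV, fastEndoCV, atrialCV, interatrialCV)
  if (any(cvs <= 0))
    stop("anatomy configuration error: conduction velocities must be positive",
         call. = FALSE)
  if (rvotExtent < 0)
    stop("anatomy configuration error: rvotExtent must be >= 0", call. = FALSE)
  if (edgeLength > min(lvEndoLong, rvEndoLong) / 4)
    stop("anatomy configuration error: edge length too coarse for the geometry",
         call. = FALSE)
  class(cfg) <- c("anatomyConfig", "list")
  cfg
}

# Geometry record of one chamber: center (mm), endocardial semi-axes
# (short a0, long c0), wall thickness, and the sign of the septal direction
# (+1: LV septum faces +x; -1: RV septum faces -x, i.e. towards the LV).
chamberGeom <- function(config, ventricle) {
  lvEpiA <- config$lvEndoRadius + config$lvWall
  rvEpiA <- config$rvEndoRadius + config$rvWall
  sep <- lvEpiA + rvEpiA + config$septalGap
  if (ventricle == "LV") {
    list(center = c(0, 0, 0), a0 = config$lvEndoRadius,
         c0 = config$lvEndoLong, wall = config$lvWall, septSign = 1)
  } else {
    list(center = c(sep, 0, 0), a0 = config$rvEndoRadius,
         c0 = config$rvEndoLong, wall = config$rvWall, septSign = -1)
  }
}

# Cartesian point (mm) of a ventricular UCC triple on one chamber.
chamberPoint <- function(geom, z, phi, rho) {
  a <- geom$a0 + rho * geom$wall
  cc <- geom$c0 + rho * geom$wall
  psi <- z * pi / 2
  cbind(geom$center[1] + geom$septSign * a * cos(phi) * sin(psi),
        geom$center[2] + a * sin(phi) * sin(psi),
        geom$center[3] - cc * cos(psi))
}

#' Map a universal cardiac coordinate to a Cartesian point
#'
#' Analytic inverse of [uccOfPoint()] on the ellipsoidal geometry.
#'
#' @param anatomy a [CardiacAnatomy-class] object (or an `anatomyConfig`).
#' @param ucc a list or one-row data.frame with fields `ventricle`
#'   ("LV"/"RV"), `z`, `phi`, `rho`.
#' @return numeric length-3 Cartesian point in mm.
#' @export
pointOfUcc <- function(anatomy, ucc) {
  config <- if (is(anatomy, "CardiacAnatomy")) anatomy@config else anatomy
  v <- as.character(ucc$ventricle)
  stopIfNot(v %in% c("LV", "RV"), "ucc validation error: ventricle must be LV or RV")
  tol <- 1e-9
  if (ucc$rho < -tol || ucc$rho > 1 + tol)
    stop("ucc validation error: rho outside [0, 1]", call. = FALSE)
  if (ucc$z < -tol || ucc$z > 1 + tol)
    stop("ucc validation error: z outside [0, 1]", call. = FALSE)
  if (ucc$phi <= -pi - 1e-6 || ucc$phi > pi + 1e-6)
    stop("ucc validation error: phi outside (-pi, pi]", call. = FALSE)
  g <- chamberGeom(config, v)
  drop(chamberPoint(g, ucc$z, wrapAngle(ucc$phi), ucc$rho))
}

# Invert the chamber parameterization for one chamber. Returns list with
# z, phi, rho (clamped to range) and `excess`, an approximate out-of-domain
# distance in mm (0 if the point is inside the wall).
chamberInvert <- function(geom, p) {
  q <- p - geom$center
  rxy <- sqrt(q[1]^2 + q[2]^2)
  phi <- if (rxy < 1e-12) 0 else atan2(q[2], geom$septSign * q[1])
  f <- function(rho) {
    a <- geom$a0 + rho * geom$wall
    cc <- geom$c0 + rho * geom$wall
    (rxy / a)^2 + (q[3] / cc)^2 - 1
  }
  lo <- -0.9 * geom$a0 / geom$wall
  hi <- 5
  excess <- 0
  if (f(lo) < 0) {          # deep inside the cavity
    rhoRaw <- lo
  } else if (f(hi) > 0) {   # far outside the epicardium
    rhoRaw <- hi
  } else {
    rhoRaw <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  rho <- min(max(rhoRaw, 0), 1)
  excess <- abs(rhoRaw - rho) * geom$wall
  a <- geom$a0 + rho * geom$wall
  cc <- geom$c0 + rho * geom$wall
  psi <- atan2(rxy / a, -q[3] / cc)
  z <- psi / (pi / 2)
  if (z > 1) {
    excess <- excess + (z - 1) * (pi / 2) * cc
    z <- 1
  }
  list(ventricle = NA_character_, z = z, phi = phi, rho = rho,
       excess = excess)
}

#' Universal cardiac coordinate of a Cartesian point
#'
#' Analytic mapping on the ellipsoidal geometry. Points slightly outside
#' the wall are projected onto it; points farther than the configured
#' tolerance raise an out-of-domain error.
#'
#' @param anatomy a [CardiacAnatomy-class] object (or an `anatomyConfig`).
#' @param point numeric length-3 point (mm).
#' @return list with `ventricle`, `z`, `phi`, `rho`.
#' @export
uccOfPoint <- function(anatomy, point) {
  config <- if (is(anatomy, "CardiacAnatomy")) anatomy@config else anatomy
  stopIfNot(length(point) == 3 && all(is.finite(point)),
            "point must be a finite length-3 vector (mm)")
  cands <- lapply(c("LV", "RV"), function(v) {
    r <- chamberInvert(chamberGeom(config, v), point)
    r$ventricle <- v
    r
  })
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "excess"))]]
  if (best$excess > config$uccTol)
    stop("out-of-domain error: point is ", round(best$excess, 1),
         " mm outside the myocardium", call. = FALSE)
  best$excess <- NULL
  best$phi <- wrapAngle(best$phi)
  best
}

# Build the structured (rho, z, phi) node grid for one chamber.
# Returns node coords, ucc rows, surface flags and local grid dims.
chamberGrid <- function(config, ventricle) {
  g <- chamberGeom(config, ventricle)
  h <- config$edgeLength
  aMid <- g$a0 + g$wall / 2
  cMid <- g$c0 + g$wall / 2
  nphi <- max(12L, ceiling(2 * pi * aMid / h))
  arc <- (pi / 2) * sqrt((aMid^2 + cMid^2) / 2)
  nz <- max(8L, ceiling(arc / h))
  nrho <- max(3L, ceiling(g$wall / h) + 1L)
  rho <- seq(0, 1, length.out = nrho)
  z <- seq_len(nz) / nz                       # apex pole excluded
  phi <- wrapAngle(-pi + seq_len(nphi) * 2 * pi / nphi)
  grid <- expand.grid(rho = rho, z = z, phi = phi,
                      KEEP.OUT.ATTRS = FALSE)  # rho fastest, phi slowest
  pts <- chamberPoint(g, grid$z, grid$phi, grid$rho)
  list(nodes = pts,
       ucc = data.frame(ventricle = ventricle, z = grid$z, phi = grid$phi,
                        rho = grid$rho, stringsAsFactors = FALSE),
       dims = c(nrho = nrho, nz = nz, nphi = nphi),
       geom = g)
}

# 26-neighbourhood edges of a (nrho x nz x nphi) grid, phi periodic.
# Offsets enumerated over a half-space so each edge appears once.
gridEdges <- function(dims) {
  nrho <- dims[["nrho"]]; nz <- dims[["nz"]]; nphi <- dims[["nphi"]]
  offs <- expand.grid(dr = -1:1, dz = -1:1, dp = -1:1)
  offs <- offs[offs$dp > 0 | (offs$dp == 0 & (offs$dz > 0 |
            (offs$dz == 0 & offs$dr > 0))), ]
  idx <- function(r, z, p) r + (z - 1L) * nrho + (p - 1L) * nrho * nz
  base <- expand.grid(r = seq_len(nrho), z = seq_len(nz), p = seq_len(nphi))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- base$r + offs$dr[k]
    z2 <- base$z + offs$dz[k]
    p2 <- ((base$p - 1L + offs$dp[k]) %% nphi) + 1L
    ok <- r2 >= 1 & r2 <= nrho & z2 >= 1 & z2 <= nz
    from <- c(from, idx(base$r[ok], base$z[ok], base$p[ok]))
    to <- c(to, idx(r2[ok], z2[ok], p2[ok]))
  }
  cbind(from, to)
}

# Atrial shell cap above one chamber: nphi x 2 heights x 2 depth layers.
atrialCap <- function(config, ventricle, nphi) {
  g <- chamberGeom(config, ventricle)
  alpha <- c(0.25, 0.75)
  beta <- c(0, 1)
  phi <- wrapAngle(-pi + seq_len(nphi) * 2 * pi / nphi)
  grid <- expand.grid(beta = beta, alpha = alpha, phi = phi,
                      KEEP.OUT.ATTRS = FALSE)
  a <- g$a0 + grid$beta * g$wall
  pts <- cbind(g$center[1] + g$septSign * a * cos(grid$phi),
               g$center[2] + a * sin(grid$phi),
               grid$alpha * config$atrialHeight)
  # global rotational angle gamma about the interventricular midline
  sep <- chamberGeom(config, "RV")$center[1]
  gamma <- atan2(pts[, 2], pts[, 1] - sep / 2)
  list(nodes = pts,
       ucc = data.frame(ventricle = "atria", z = grid$alpha, phi = gamma,
                        rho = grid$beta, stringsAsFactors = FALSE),
       dims = c(nrho = 2L, nz = 2L, nphi = nphi),
       cap = ventricle)
}

edgeLengths <- function(nodes, e) {
  d <- nodes[e[, 1], , drop = FALSE] - nodes[e[, 2], , drop = FALSE]
  sqrt(rowSums(d * d))
}

# Short bridging edges between two node subsets: for every node in `fromIdx`
# the nearest node in `toIdx`, kept if closer than maxLen.
nearestBridges <- function(nodes, fromIdx, toIdx, maxLen) {
  if (!length(fromIdx) || !length(toIdx)) return(NULL)
  A <- nodes[fromIdx, , drop = FALSE]
  B <- nodes[toIdx, , drop = FALSE]
  nn <- vapply(seq_len(nrow(A)), function(i) {
    d2 <- colSums((t(B) - A[i, ])^2)
    j <- which.min(d2)
    c(j, sqrt(d2[j]))
  }, numeric(2))
  keep <- nn[2, ] <= maxLen
  if (!any(keep)) return(NULL)
  data.frame(from = fromIdx[keep], to = toIdx[nn[1, keep]],
             len = pmax(nn[2, keep], 0.25))  # floor avoids zero-length edges
}

#' Build the synthetic biventricular anatomy
#'
#' Procedurally constructs the full model from a configuration:
#' structured-grid nodes with exact UCC records on two truncated-ellipsoid
#' chambers, an atrial shell with a sinoatrial node and a fast interatrial
#' connection, electrical edges (with septal bridging between the
#' ventricles, atria electrically isolated), a geometric graph adding
#' annulus bridges for geodesic pathway lengths, the inert RVOT sector,
#' electrodes, conduction-velocity field and His-Purkinje root sites.
#' Construction is deterministic for a fixed configuration.
#'
#' @param config an [anatomyConfig()] list.
#' @return a [CardiacAnatomy-class] object.
#' @export
buildAnatomy <- function(config = anatomyConfig()) {
  if (!inherits(config, "anatomyConfig"))
    config <- do.call(anatomyConfig, config)
  lv <- chamberGrid(config, "LV")
  rv <- chamberGrid(config, "RV")
  la <- atrialCap(config, "LV", lv$dims[["nphi"]])
  ra <- atrialCap(config, "RV", rv$dims[["nphi"]])

  blocks <- list(lv, rv, la, ra)
  counts <- vapply(blocks, function(b) nrow(b$nodes), integer(1))
  offset <- cumsum(c(0L, counts))[1:4]
  nodes <- do.call(rbind, lapply(blocks, `[[`, "nodes"))
  ucc <- do.call(rbind, lapply(blocks, `[[`, "ucc"))
  rownames(ucc) <- NULL
  ucc$cap <- c(rep(NA_character_, counts[1] + counts[2]),
               rep("LV", counts[3]), rep("RV", counts[4]))
  tissue <- c(rep("LV", counts[1]), rep("RV", counts[2]),
              rep("atria", counts[3] + counts[4]))

  # inert RVOT sector within the RV
  if (config$rvotExtent > 0) {
    rvIdx <- offset[2] + seq_len(counts[2])
    dphi <- wrapAngle(ucc$phi[rvIdx] - config$rvotPhiStart)
    inRvot <- ucc$z[rvIdx] >= config$rvotZmin &
      dphi >= 0 & dphi <= config$rvotExtent
    tissue[rvIdx[inRvot]] <- "RVOT"
  }

  # intra-block structured edges
  edgeList <- lapply(seq_along(blocks), function(i) {
    e <- gridEdges(blocks[[i]]$dims) + offset[i]
    data.frame(from = e[, 1], to = e[, 2])
  })
  edges <- do.call(rbind, edgeList)
  edges$len <- edgeLengths(nodes, as.matrix(edges[, 1:2]))
  edges$cvOverride <- NA_real_

  lvIdx <- offset[1] + seq_len(counts[1])
  rvIdx <- offset[2] + seq_len(counts[2])
  laIdx <- offset[3] + seq_len(counts[3])
  raIdx <- offset[4] + seq_len(counts[4])

  # electrical septal bridges between facing epicardial surfaces
  lvSept <- lvIdx[ucc$rho[lvIdx] == 1 & abs(ucc$phi[lvIdx]) < pi / 3]
  rvSept <- rvIdx[ucc$rho[rvIdx] == 1 & abs(ucc$phi[rvIdx]) < pi / 3]
  sept <- nearestBridges(nodes, rvSept, lvSept, config$septalBridgeMax)
  if (!is.null(sept)) {
    sept$cvOverride <- NA_real_
    edges <- rbind(edges, sept)
  }

  # fast interatrial connection: closest facing atrial node pairs
  inter <- nearestBridges(nodes, raIdx, laIdx, 2.5 * config$edgeLength)
  if (is.null(inter))
    stop("anatomy construction error: no interatrial connection found",
         call. = FALSE)
  inter <- inter[order(inter$len), , drop = FALSE]
  inter <- inter[seq_len(min(3L, nrow(inter))), , drop = FALSE]
  inter$cvOverride <- config$interatrialCV
  edges <- rbind(edges, inter)
  rownames(edges) <- NULL

  # geometric graph: all electrical edges plus annulus bridges linking each
  # atrial cap to the basal ring of its ventricle (geometry only)
  lvBase <- lvIdx[ucc$z[lvIdx] == 1]
  rvBase <- rvIdx[ucc$z[rvIdx] == 1]
  laLow <- laIdx[ucc$z[laIdx] == 0.25]
  raLow <- raIdx[ucc$z[raIdx] == 0.25]
  ann <- rbind(nearestBridges(nodes, laLow, lvBase, 3 * config$edgeLength),
               nearestBridges(nodes, raLow, rvBase, 3 * config$edgeLength))
  ann$cvOverride <- NA_real_
  geomEdges <- rbind(edges, ann)
  rownames(geomEdges) <- NULL

  # conduction velocities: fast endocardial layer within the ventricles
  cv <- rep(config$myocardialCV, nrow(nodes))
  vent <- tissue %in% c("LV", "RV", "RVOT")
  fast <- vent & ucc$rho < config$fastEndoRho
  cv[fast] <- config$fastEndoCV
  cv[tissue == "atria"] <- config$atrialCV

  # lumped node volumes per block (half-ellipsoid shell / cap annulus)
  nodeVolume <- numeric(nrow(nodes))
  for (i in 1:2) {
    g <- blocks[[i]]$geom
    vol <- (2 / 3) * pi * ((g$a0 + g$wall)^2 * (g$c0 + g$wall) -
                             g$a0^2 * g$c0)
    nodeVolume[offset[i] + seq_len(counts[i])] <- vol / counts[i]
  }
  for (i in 3:4) {
    g <- chamberGeom(config, blocks[[i]]$cap)
    vol <- pi * ((g$a0 + g$wall)^2 - g$a0^2) * config$atrialHeight
    nodeVolume[offset[i] + seq_len(counts[i])] <- vol / counts[i]
  }

  surface <- data.frame(endo = ucc$rho == 0, epi = ucc$rho == 1,
                        base = ucc$ventricle != "atria" & ucc$z == 1)

  electrodes <- buildElectrodes(config)

  anatomy <- new("CardiacAnatomy", nodes = nodes, ucc = ucc,
                 tissue = tissue, surface = surface, edges = edges,
                 geomEdges = geomEdges, cv = cv, nodeVolume = nodeVolume,
                 electrodes = electrodes,
                 rootSites = data.frame(node = integer(0), time = numeric(0)),
                 saNode = 1L, config = unclass(config))

  # His-Purkinje fascicular root sites (5), localized in UCC space
  rootUcc <- data.frame(
    ventricle = c("LV", "LV", "LV", "RV", "RV"),
    z = c(0.55, 0.55, 0.60, 0.60, 0.35),
    phi = c(1.6, -1.6, 0.0, 0.0, 2.4),
    rho = 0)
  rootNodes <- vapply(seq_len(nrow(rootUcc)), function(i)
    localizeUcc(anatomy, rootUcc$ventricle[i], rootUcc$z[i],
                rootUcc$phi[i], rootUcc$rho[i]), integer(1))
  anatomy@rootSites <- data.frame(node = rootNodes,
                                  time = rep(config$hisOffset, 5))

  # sinoatrial node on the right atrial cap
  raCand <- raIdx[ucc$rho[raIdx] == 1 & ucc$z[raIdx] == 0.75]
  sa <- raCand[which.min(angDiff(ucc$phi[raCand], 0.3))]
  anatomy@saNode <- as.integer(sa)

  validObject(anatomy)
  anatomy
}

# Torso-scale electrode positions around the heart. Precordial electrodes
# V1..V6 sweep an anterior arc from right-parasternal to left-lateral;
# limb electrodes sit far outside the tissue bounding box.
buildElectrodes <- function(config) {
  sep <- chamberGeom(config, "RV")$center[1]
  cx <- sep / 2
  r <- config$electrodeRadius
  zc <- config$electrodeHeight
  angles <- c(75, 95, 115, 135, 155, 175) * pi / 180
  prec <- cbind(cx + r * cos(angles), r * sin(angles), zc)
  limbs <- rbind(RA = c(cx + 2 * r, 60, 150),
                 LA = c(cx - 2 * r, 60, 150),
                 LL = c(cx - r, 40, -350))
  out <- rbind(limbs, prec)
  rownames(out) <- c("RA", "LA", "LL", paste0("V", 1:6))
  out
}

#' Locate the mesh node nearest to a universal cardiac coordinate
#'
#' Nearest-neighbour localization in UCC space restricted to the requested
#' tissue label. Requests resolving into the electrically inert RVOT are
#' rejected.
#'
#' @param anatomy a [CardiacAnatomy-class] object.
#' @param ventricle "LV", "RV" or "atria".
#' @param z,phi,rho the coordinate triple; for atrial requests these are
#'   the atrial triple (alpha, gamma, beta).
#' @param rejectInert error if the nearest node is inert (default TRUE).
#' @return integer node index.
#' @export
localizeUcc <- function(anatomy, ventricle, z, phi, rho, rejectInert = TRUE) {
  ucc <- anatomy@ucc
  tis <- anatomy@tissue
  cand <- if (ventricle == "atria") which(tis == "atria")
          else which(tis == ventricle | (ventricle == "RV" & tis == "RVOT"))
  stopIfNot(length(cand) > 0, "no nodes with the requested label")
  d2 <- (ucc$z[cand] - z)^2 + (angDiff(ucc$phi[cand], phi) / pi)^2 +
    (ucc$rho[cand] - rho)^2
  node <- cand[which.min(d2)]
  if (rejectInert && tis[node] == "RVOT")
    stop("rejection error: coordinate maps into the inert RVOT", call. = FALSE)
  as.integer(node)
}

#' Export the anatomy as a legacy ASCII VTK unstructured grid
#'
#' Writes nodes, edge cells and the UCC/tissue point data for external
#' visualization. Not used by any computation.
#'
#' @param anatomy a [CardiacAnatomy-class] object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportMeshVTK <- function(anatomy, path) {
  n <- nrow(anatomy@nodes)
  e <- anatomy@edges
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "wpwsim anatomy", "ASCII",
               "DATASET UNSTRUCTURED_GRID", paste("POINTS", n, "float")), con)
  utils::write.table(round(anatomy@nodes, 4), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste("CELLS", nrow(e), 3 * nrow(e)), con)
  utils::write.table(cbind(2L, e$from - 1L, e$to - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines(paste("CELL_TYPES", nrow(e)), con)
  writeLines(as.character(rep(3L, nrow(e))), con)
  writeLines(c(paste("POINT_DATA", n), "SCALARS tissue int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(anatomy@tissue,
    levels = c("LV", "RV", "atria", "RVOT")))), con)
  for (f in c("z", "phi", "rho")) {
    writeLines(c(paste("SCALARS", f, "float 1"), "LOOKUP_TABLE default"), con)
    writeLines(as.character(round(anatomy@ucc[[f]], 5)), con)
  }
  invisible(path)
}
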