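test_that("default anatomy has both ventricles well resolved and tagged", {
  an <- testAnatomy()
  tis <- tissueTags(an)
  expect_gte(sum(tis == "LV"), 500)
  expect_gte(sum(tis %in% c("RV", "RVOT")), 500)
  expect_true(all(tis %in% c("LV", "RV", "atria", "RVOT")))
  expect_gt(sum(tis == "RVOT"), 0)

  ucc <- uccCoords(an)
  vent <- ucc$ventricle %in% c("LV", "RV")
  expect_true(all(ucc$z[vent] >= 0 & ucc$z[vent] <= 1))
  expect_true(all(ucc$rho[vent] >= 0 & ucc$rho[vent] <= 1))
  expect_true(all(ucc$phi > -pi & ucc$phi <= pi + 1e-12))
})

test_that("anatomy construction is deterministic for a fixed config", {
  cfg <- anatomyConfig(edgeLength = 8)
  a1 <- buildAnatomy(cfg)
  a2 <- buildAnatomy(cfg)
  expect_identical(nodeCoords(a1), nodeCoords(a2))
  expect_identical(tissueTags(a1), tissueTags(a2))
  expect_identical(rootSites(a1), rootSites(a2))
})

test_that("zero RVOT angular extent produces no inert tissue", {
  an <- buildAnatomy(anatomyConfig(edgeLength = 8, rvotExtent = 0))
  expect_equal(sum(tissueTags(an) == "RVOT"), 0)
})

test_that("atria and ventricles share no electrical edge", {
  an <- testAnatomy()
  atr <- tissueTags(an) == "atria"
  e <- an@edges
  expect_true(all(atr[e$from] == atr[e$to]))
})

test_that("electrodes lie strictly outside the tissue bounding box", {
  an <- testAnatomy()
  bb <- apply(nodeCoords(an), 2, range)
  el <- electrodePositions(an)
  expect_equal(nrow(el), 9)
  inside <- apply(el, 1, function(p) all(p >= bb[1, ] & p <= bb[2, ]))
  expect_false(any(inside))
})

test_that("degenerate dimensions are rejected at configuration", {
  expect_error(anatomyConfig(lvWall = 0), "positive")
  expect_error(anatomyConfig(myocardialCV = -1), "conduction velocities")
})

test_that("uccOfPoint recovers apex, endocardial surface and base", {
  an <- testAnatomy()
  apex <- pointOfUcc(an, list(ventricle = "LV", z = 0, phi = 0, rho = 0))
  u <- uccOfPoint(an, apex)
  expect_equal(u$ventricle, "LV")
  expect_equal(u$z, 0, tolerance = 1e-6)

  endo <- pointOfUcc(an, list(ventricle = "LV", z = 0.6, phi = 1.1, rho = 0))
  expect_equal(uccOfPoint(an, endo)$rho, 0, tolerance = 1e-6)

  base <- pointOfUcc(an, list(ventricle = "LV", z = 1, phi = -2, rho = 0.5))
  expect_equal(uccOfPoint(an, base)$z, 1, tolerance = 1e-6)
})

test_that("ucc mapping round-trips for random coordinates", {
  an <- testAnatomy()
  set.seed(5)
  for (i in 1:100) {
    u <- list(ventricle = sample(c("LV", "RV"), 1), z = runif(1, 0.02, 1),
              phi = runif(1, -pi + 1e-3, pi), rho = runif(1))
    p <- pointOfUcc(an, u)
    u2 <- uccOfPoint(an, p)
    expect_equal(u2$ventricle, u$ventricle)
    expect_equal(u2$z, u$z, tolerance = 1e-5)
    expect_equal(u2$rho, u$rho, tolerance = 1e-5)
    expect_lt(abs(wpwsim:::angDiff(u2$phi, u$phi)), 1e-5)
  }
})

test_that("out-of-range and out-of-domain requests are rejected", {
  an <- testAnatomy()
  expect_error(pointOfUcc(an, list(ventricle = "LV", z = 0.5, phi = 0,
                                   rho = 1.2)), "rho")
  expect_error(uccOfPoint(an, c(500, 500, 500)), "out-of-domain")
})

test_that("localizeUcc returns an exactly matching node", {
  an <- testAnatomy()
  ucc <- uccCoords(an)
  i <- which(tissueTags(an) == "LV")[123]
  hit <- localizeUcc(an, "LV", ucc$z[i], ucc$phi[i], ucc$rho[i])
  expect_identical(hit, as.integer(i))
})

test_that("requests resolving into the inert RVOT are rejected", {
  an <- testAnatomy()
  rvot <- which(tissueTags(an) == "RVOT")[1]
  ucc <- uccCoords(an)
  expect_error(localizeUcc(an, "RV", ucc$z[rvot], ucc$phi[rvot],
                           ucc$rho[rvot]), "inert")
})

test_that("VTK export writes a parseable legacy mesh file", {
  an <- buildAnatomy(anatomyConfig(edgeLength = 10))
  f <- tempfile(fileext = ".vtk")
  exportMeshVTK(an, f)
  head <- readLines(f, n = 5)
  expect_match(head[1], "vtk DataFile")
  expect_match(head[5], paste("POINTS", nrow(nodeCoords(an))))
})
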