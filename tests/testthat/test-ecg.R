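test_that("spatially uniform membrane voltage produces zero potential", {
  an <- testAnatomy()
  vm <- matrix(17.3, nrow(nodeCoords(an)), 40)
  phi <- electrodePotential(vm, an, c(0, 200, 0))
  expect_equal(max(abs(phi)), 0, tolerance = 1e-9)
})

test_that("the pseudo-ECG is linear in the membrane voltage", {
  an <- testAnatomy()
  set.seed(9)
  n <- nrow(nodeCoords(an))
  v1 <- matrix(rnorm(n * 25), n, 25)
  v2 <- matrix(rnorm(n * 25), n, 25)
  pos <- c(-50, 180, -40)
  p1 <- electrodePotential(v1, an, pos)
  p2 <- electrodePotential(v2, an, pos)
  expect_equal(electrodePotential(-v1, an, pos), -p1, tolerance = 1e-12)
  expect_equal(electrodePotential(2.5 * v1 - 0.7 * v2, an, pos),
               2.5 * p1 - 0.7 * p2, tolerance = 1e-9)
})

test_that("mirror-symmetric voltages give equal mirrored-electrode potentials", {
  # without the (asymmetric) inert RVOT sector the mesh is symmetric
  # about y = 0, so a y-mirrored source pair produces a symmetric Vm and
  # electrodes mirrored in y must record identical potentials
  an <- buildAnatomy(anatomyConfig(edgeLength = 8, rvotExtent = 0))
  ucc <- uccCoords(an)
  src <- which(tissueTags(an) == "LV")[200]
  mirror <- localizeUcc(an, "LV", ucc$z[src], -ucc$phi[src], ucc$rho[src])
  expect_equal(ucc$phi[mirror], -ucc$phi[src])
  tau <- solveEikonal(an, data.frame(node = c(src, mirror), time = 0))
  vm <- buildVm(tau, apd = 200, horizon = 600)$vm
  pA <- electrodePotential(vm, an, c(20, 150, -30))
  pB <- electrodePotential(vm, an, c(20, -150, -30))
  expect_equal(pA, pB, tolerance = 1e-6)
})

test_that("electrode positions inside the tissue are rejected", {
  an <- testAnatomy()
  inside <- colMeans(nodeCoords(an)[tissueTags(an) == "LV", ])
  expect_error(electrodePotential(matrix(0, nrow(nodeCoords(an)), 3),
                                  an, inside), "inside")
})

test_that("lead assembly satisfies the Einthoven and Goldberger identities", {
  set.seed(21)
  pot <- matrix(rnorm(9 * 100), 100, 9)
  colnames(pot) <- c("RA", "LA", "LL", paste0("V", 1:6))
  ecg <- assemble12Lead(pot)
  s <- ecgSignal(ecg)
  expect_equal(s[, "II"], s[, "I"] + s[, "III"], tolerance = 1e-12)
  expect_equal(s[, "aVR"] + s[, "aVL"] + s[, "aVF"], rep(0, 100),
               tolerance = 1e-12)
  # common-mode rejection
  pot2 <- matrix(4.2, 50, 9)
  colnames(pot2) <- colnames(pot)
  expect_equal(max(abs(ecgSignal(assemble12Lead(pot2)))), 0)
})

test_that("postprocessing applies the low-pass and the global scaling", {
  dc <- syntheticEcg(list(V2 = rep(1, 1000)), nT = 1000)
  out <- postprocessECG(dc, cutoff = 150, scale = 0.32)
  expect_true(out@filtered && out@scaled)
  mid <- 200:800
  expect_equal(ecgSignal(out)[mid, "V2"], rep(0.32, length(mid)),
               tolerance = 1e-6)

  # a 400 Hz tone at 1 kHz sampling must be attenuated by >= 20 dB
  tone <- sin(2 * pi * 400 * (0:999) / 1000)
  toneEcg <- syntheticEcg(list(V3 = tone), nT = 1000)
  filt <- postprocessECG(toneEcg, cutoff = 150, scale = 1)
  att <- 20 * log10(sd(ecgSignal(filt)[mid, "V3"]) / sd(tone[mid]))
  expect_lt(att, -20)

  # passivity on white noise near the Nyquist cutoff
  set.seed(2)
  noise <- rnorm(1000)
  ne <- syntheticEcg(list(V4 = noise), nT = 1000)
  out2 <- postprocessECG(ne, cutoff = 499.99, scale = 1)
  expect_lte(var(ecgSignal(out2)[, "V4"]), var(noise) * (1 + 1e-6))

  expect_error(postprocessECG(dc, cutoff = 500), "Nyquist")
})

test_that("the full forward map is linear and preserves lead identities", {
  an <- testAnatomy()
  beat <- simulateBeat(an)
  e1 <- forwardECG(beat$vm, an)
  e2 <- forwardECG(0.5 * beat$vm, an)
  expect_equal(ecgSignal(e2), 0.5 * ecgSignal(e1), tolerance = 1e-9)
  s <- ecgSignal(e1)
  expect_equal(s[, "II"], s[, "I"] + s[, "III"], tolerance = 1e-9)
  expect_equal(max(abs(s[, "aVR"] + s[, "aVL"] + s[, "aVF"])), 0,
               tolerance = 1e-9)
})

test_that("ECG CSV export writes the time grid and all leads", {
  e <- syntheticEcg(list(I = sin(1:300 / 20)), nT = 300)
  f <- tempfile(fileext = ".csv")
  writeECGcsv(e, f)
  df <- read.csv(f, check.names = FALSE)
  expect_equal(names(df)[1], "time_ms")
  expect_equal(ncol(df), 13)
  expect_equal(df$I, ecgSignal(e)[, "I"], tolerance = 1e-9)
})
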