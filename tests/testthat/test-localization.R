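mkQrs <- function(r = 1, s = -0.4, onset = 100, nT = 400) {
  # stylized QRS: R bump then S dip inside [onset, onset+80]
  x <- numeric(nT)
  tt <- seq_len(nT)
  x <- x + r * exp(-((tt - onset - 20)^2) / 50) +
    s * exp(-((tt - onset - 50)^2) / 80)
  x
}

test_that("QRS polarity follows R vs S dominance", {
  e <- syntheticEcg(list(I = mkQrs(1.0, -0.4), II = mkQrs(0.3, -0.9)),
                    nT = 400)
  f <- extractFeatures(e, qrsOnset = 95, qrsOffset = 190)
  expect_gt(f$qrsPolarity["I"], 0)
  expect_lt(f$qrsPolarity["II"], 0)
  expect_equal(unname(f$rAmp["I"]), 1.0, tolerance = 0.05)
})

test_that("the precordial transition is the first lead with R > |S|", {
  e <- syntheticEcg(list(V1 = mkQrs(0.2, -1.0), V2 = mkQrs(0.8, -0.6),
                         V3 = mkQrs(1.0, -0.2), V4 = mkQrs(1.1, -0.1),
                         V5 = mkQrs(1.0, -0.1), V6 = mkQrs(0.9, -0.1)),
                    nT = 400)
  f <- extractFeatures(e, qrsOnset = 95, qrsOffset = 190)
  expect_equal(f$transitionLead, "V2")
})

test_that("negating the ECG flips every polarity feature", {
  e <- syntheticEcg(list(V1 = mkQrs(0.9, -0.2), II = mkQrs(0.8, -0.1),
                         aVF = mkQrs(0.7, -0.2), III = mkQrs(0.6, -0.1),
                         I = mkQrs(0.5, -0.3)), nT = 400)
  f1 <- extractFeatures(e, qrsOnset = 95, qrsOffset = 190)
  eNeg <- e
  eNeg@signal <- -ecgSignal(e)
  f2 <- extractFeatures(eNeg, qrsOnset = 95, qrsOffset = 190)
  expect_equal(f2$qrsPolarity, -f1$qrsPolarity)
  expect_equal(f2$deltaPolarity, -f1$deltaPolarity)
  expect_equal(f2$inferiorPositives, 3 - f1$inferiorPositives)
  # the most positive delta lead becomes the most negative one
  expect_equal(f2$deltaAmp[f1$mostPositiveDelta],
               min(f2$deltaAmp), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("feature extraction is invariant to a common baseline shift", {
  e <- syntheticEcg(list(V1 = mkQrs(0.2, -0.8), V2 = mkQrs(0.9, -0.3),
                         II = mkQrs(0.8, -0.1)), nT = 400)
  f1 <- extractFeatures(e, qrsOnset = 95, qrsOffset = 190)
  eShift <- e
  eShift@signal <- ecgSignal(e) + 0.37
  f2 <- extractFeatures(eShift, qrsOnset = 95, qrsOffset = 190)
  expect_equal(f2$qrsPolarity, f1$qrsPolarity)
  expect_equal(f2$deltaAmp, f1$deltaAmp, tolerance = 1e-9)
  expect_equal(f2$transitionLead, f1$transitionLead)
  expect_equal(f2$minDvdtV2, f1$minDvdtV2, tolerance = 1e-12)
})

test_that("uniformly growing R waves can only advance the transition", {
  base <- list(V1 = mkQrs(0.2, -1.0), V2 = mkQrs(0.5, -0.6),
               V3 = mkQrs(0.7, -0.5), V4 = mkQrs(1.0, -0.2),
               V5 = mkQrs(1.0, -0.1), V6 = mkQrs(1.0, -0.1))
  leadIdx <- function(l) if (is.na(l)) 7L else as.integer(sub("V", "", l))
  prev <- 7L
  for (gain in c(1, 1.5, 2.5, 4)) {
    tr <- lapply(base, function(x) pmax(x, 0) * gain + pmin(x, 0))
    f <- extractFeatures(syntheticEcg(tr, nT = 400),
                         qrsOnset = 95, qrsOffset = 190)
    expect_lte(leadIdx(f$transitionLead), prev)
    prev <- leadIdx(f$transitionLead)
  }
})

test_that("flat signals give a features-undefined error", {
  e <- syntheticEcg(list(), nT = 100)
  expect_error(extractFeatures(e), "flat signal")
})

test_that("the inferior-count tree maps the printed branches", {
  nh <- pambrunTree(featureVector(v1 = -1, inferiorPositives = 3, v3 = 1))
  expect_equal(nh$side, "right")
  expect_match(nh$region, "NH")

  ra <- pambrunTree(featureVector(v1 = -1, inferiorPositives = 3, v3 = -1))
  expect_equal(ra$region, "RA")

  unp <- pambrunTree(featureVector(v1 = -1, inferiorPositives = 1, v3 = 1))
  expect_equal(unp$region, "indeterminate")
  expect_match(unp$branch, "not printed")

  left <- pambrunTree(featureVector(v1 = 1))
  expect_equal(left$side, "left")
  expect_equal(left$region, "indeterminate")
  expect_match(left$branch, "V1/I")
})

test_that("the delta-and-transition tree maps the printed branches", {
  as3 <- easyWpwTree(featureVector(v1 = -1, mostPositiveDelta = "II",
                                   transitionLead = "V3"))
  expect_equal(as3$region, "anteroseptal RV")
  as2 <- easyWpwTree(featureVector(v1 = -1, mostPositiveDelta = "II",
                                   transitionLead = "V2"))
  expect_equal(as2$region, "anteroseptal RV")

  oth <- easyWpwTree(featureVector(v1 = -1, mostPositiveDelta = "aVF",
                                   transitionLead = "V5"))
  expect_equal(oth$region, "indeterminate")

  left <- easyWpwTree(featureVector(v1 = 1))
  expect_equal(left$side, "left")
})

test_that("the evaluation harness bookkeeps sides and indeterminates", {
  db <- testDb()
  ev <- evaluateLocalization(db, "pambrun")
  expect_equal(nrow(ev$perBeat), sum(dbParams(db)$valid))
  expect_true(ev$indeterminateRate >= 0 && ev$indeterminateRate <= 1)

  # truth LV with a left-sided prediction counts as side-correct
  allLeft <- function(f) {
    out <- list(side = "left", region = "indeterminate", branch = "fixed")
    class(out) <- c("Localization", "list")
    out
  }
  evL <- evaluateLocalization(db, allLeft)
  expect_equal(evL$sideAccuracy,
               mean(dbParams(db)$ventricle[dbParams(db)$valid] == "LV"))

  # all-indeterminate algorithm: side accuracy undefined, rate 1
  noCall <- function(f) {
    out <- list(side = NA_character_, region = "indeterminate",
                branch = "none")
    class(out) <- c("Localization", "list")
    out
  }
  evN <- evaluateLocalization(db, noCall)
  expect_true(is.na(evN$sideAccuracy))
  expect_equal(evN$indeterminateRate, 1)
})
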