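test_that("a degree-2 generator is represented exactly at fit degree >= 2", {
  set.seed(17)
  n <- 300
  X <- cbind(rho = runif(n), z = runif(n, 0.5, 1), phi = runif(n, -pi, pi),
             tven = runif(n, 60, 190))
  y <- 1.5 - 2 * X[, "rho"] + 0.8 * X[, "tven"] * X[, "phi"] +
    3 * X[, "z"]^2
  m <- fitPCE(X, y, degree = 3)
  expect_lt(max(m@residual) / sd(y), 1e-8)
  # evaluating at the training points reproduces the data
  yhat <- evaluatePCE(m, X)[, 1, 1]
  expect_equal(yhat, unname(y), tolerance = 1e-8)
})

test_that("a degree-0 expansion is the sample mean", {
  set.seed(30)
  X <- matrix(runif(50 * 2), 50, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(50)
  m <- fitPCE(X, y, degree = 0)
  expect_equal(m@coef[1, 1, 1], mean(y))
})

test_that("underdetermined fits fail with the required sample count", {
  X <- matrix(runif(20 * 4), 20, 4)
  y <- rnorm(20)
  expect_error(fitPCE(X, y, degree = 3), "underdetermined.*70")
})

test_that("Sobol indices recover additive and single-factor structure", {
  set.seed(12)
  n <- 500
  X <- cbind(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1))
  box <- parameterBox(rbind(c(-1, -1), c(1, 1)), c("x1", "x2"))
  m <- fitPCE(X, X[, 1] + X[, 2], degree = 3, box = box)
  S <- sobolIndices(sobolTimeSeries(m))[, 1, 1]
  expect_equal(unname(S[c("x1", "x2")]), c(0.5, 0.5), tolerance = 1e-10)

  # signal depending only on one factor
  m2 <- fitPCE(X, sin(X[, 2]), degree = 7, box = box)
  S2 <- sobolIndices(sobolTimeSeries(m2))[, 1, 1]
  expect_equal(unname(S2["x2"]), 1, tolerance = 1e-8)
  expect_lt(sum(S2[names(S2) != "x2"]), 1e-8)
})

test_that("weighted sensitivities integrate and normalize per the definitions", {
  # constant Sobol fractions and sigma: the integral is s * sigma0 * T
  nT <- 101
  tt <- seq(0, 1000, length.out = nT)          # ms
  idx <- array(NA_real_, c(2, 1, nT), dimnames = list(c("a", "b"), NULL, NULL))
  idx[1, 1, ] <- 0.3
  idx[2, 1, ] <- 0.7
  sigma <- matrix(2, 1, nT)
  sob <- methods::new("SobolResult", indices = idx, sigma = sigma,
                      combos = c("a", "b"), comboOrder = c(1L, 1L),
                      time = tt)
  sens <- integrateSensitivity(sob)
  expect_equal(sens@integrated["a", 1], 0.3 * 2 * 1, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sens@integrated["b", 1], 0.7 * 2 * 1, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(colSums(sensitivityProportions(sens)), 1, tolerance = 1e-12,
               ignore_attr = TRUE)

  # zero sigma: all weighted sensitivities vanish
  sob0 <- methods::new("SobolResult", indices = idx * NA,
                       sigma = sigma * 0, combos = c("a", "b"),
                       comboOrder = c(1L, 1L), time = tt)
  expect_equal(max(abs(integrateSensitivity(sob0)@integrated)), 0)
})

test_that("scaling the signals leaves Sobol fractions and proportions alone", {
  set.seed(5)
  n <- 400
  X <- cbind(rho = runif(n), z = runif(n), phi = runif(n), tven = runif(n))
  sig <- array(0, c(n, 2, 30))
  base <- outer(X[, "tven"], sin(seq(0, 3, length.out = 30))) +
    outer(X[, "phi"]^2, cos(seq(0, 3, length.out = 30)))
  sig[, 1, ] <- base
  sig[, 2, ] <- 0.5 * base
  fitOne <- function(s) {
    m <- fitPCE(X, s, degree = 3, time = seq(0, 290, by = 10))
    integrateSensitivity(sobolTimeSeries(m))
  }
  sA <- fitOne(sig)
  sB <- fitOne(3 * sig)
  expect_equal(sensitivityProportions(sB), sensitivityProportions(sA),
               tolerance = 1e-9)
  expect_equal(sB@integrated, 3 * sA@integrated, tolerance = 1e-9)
})

test_that("parameters absent from the generator get near-zero proportions", {
  set.seed(77)
  n <- 600
  X <- cbind(rho = runif(n), z = runif(n, 0.5, 1),
             phi = runif(n, -pi, pi), tven = runif(n, 60, 190))
  tt <- seq(0, 100, by = 2)
  sig <- array(0, c(n, 1, length(tt)))
  sig[, 1, ] <- outer(X[, "tven"], tt / 100) +
    outer(X[, "phi"], sin(tt / 15)) + 0.2
  m <- fitPCE(X, sig, degree = 3, time = tt)
  pr <- sensitivityProportions(integrateSensitivity(sobolTimeSeries(m)))[, 1]
  inactive <- grepl("rho|z", names(pr))
  expect_lt(sum(pr[inactive]), 0.02)
  expect_equal(sum(pr), 1, tolerance = 1e-6)
})

test_that("surrogate error is zero for an interpolant and ~1 for the mean", {
  db <- testDb()
  p <- dbParams(db)
  lv <- which(p$valid & p$ventricle == "LV")
  sa <- analyzeSensitivity(db, "LV", degree = 1)
  # an exact interpolant of the data: replace coefficients so that the
  # evaluation returns the stored signals for a single-beat subset
  errConst <- {
    m <- sa$model
    # constant-mean surrogate: zero out all non-constant terms
    m@coef[-1, , ] <- 0
    surrogateError(m, db, "LV", nRandom = length(lv), seed = 2)
  }
  expect_equal(errConst$mean, 1, tolerance = 0.35)

  # a surrogate that interpolates the data exactly: signals linear in the
  # parameters, fitted at matching degree
  set.seed(44)
  nI <- 40
  parI <- data.frame(beat = seq_len(nI), valid = TRUE, ventricle = "RV",
                     region = "RV_basal_anterior", rho = runif(nI),
                     z = runif(nI, 0.5, 1), phi = runif(nI, -pi, pi),
                     tven = runif(nI, 60, 190))
  sigI <- array(0, c(nI, 12, 20))
  for (l in 1:12)
    sigI[, l, ] <- outer(parI$tven, seq(0, 1, length.out = 20)) + l
  dbI <- methods::new("ECGDatabase", params = parI, signals = sigI,
                      period = 1, meta = list())
  mI <- fitPCE(as.matrix(parI[, c("rho", "z", "phi", "tven")]),
               sigI, degree = 1)
  errZero <- surrogateError(mI, dbI, "RV", nRandom = 20, seed = 3)
  expect_equal(errZero$mean, 0, tolerance = 1e-9)
})
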