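test_that("Latin-hypercube pathway sampling is deterministic under a seed", {
  an <- testAnatomy()
  spec <- sampleSpec(nPerVentricle = 30, seed = 4)
  s1 <- sampleAPs(spec, an)
  s2 <- sampleAPs(spec, an)
  expect_identical(s1, s2)
  expect_length(s1, 60)
})

test_that("accepted samples respect the length constraint and avoid the RVOT", {
  an <- testAnatomy()
  der <- wpwsim:::anatomyDerived(an)
  s <- sampleAPs(sampleSpec(nPerVentricle = 60, seed = 9), an)
  for (ap in s) {
    loc <- localizeAP(an, ap, atrialMap = der$atrialMap)
    expect_lte(loc$d, 60)
    expect_true(tissueTags(an)[loc$ventNode] != "RVOT")
  }
})

test_that("sampled exits cover all 12 bullseye regions per ventricle", {
  an <- testAnatomy()
  s <- sampleAPs(sampleSpec(nPerVentricle = 600, seed = 31), an)
  df <- do.call(rbind, lapply(s, function(ap)
    data.frame(v = ap$ventricle, region = bullseyeRegion(ap$ventricle,
                                                         ap$z, ap$phi))))
  for (v in c("LV", "RV"))
    expect_setequal(unique(df$region[df$v == v]), bullseyeRegions(v))
})

test_that("database rows mirror the generating samples and timings", {
  db <- testDb()
  p <- dbParams(db)
  expect_equal(nrow(p), dim(dbSignals(db))[1])
  expect_equal(dim(dbSignals(db))[2:3], c(12, 700))
  expect_equal(samplePeriod(db), 1)
  ok <- p$valid
  expect_true(all(is.finite(p$tven[ok])))
  expect_equal(p$tven[ok], p$tatria[ok] + p$d[ok] / p$cvap[ok],
               tolerance = 1e-12)
})

test_that("regenerating a database with one seed is bit-identical", {
  an <- testAnatomy()
  s <- sampleAPs(sampleSpec(nPerVentricle = 4, seed = 3), an)
  d1 <- generateDatabase(s, an, seed = 3)
  d2 <- generateDatabase(s, an, seed = 3)
  expect_identical(dbParams(d1), dbParams(d2))
  expect_identical(dbSignals(d1), dbSignals(d2))
})

test_that("the database container round-trips losslessly", {
  db <- testDb()
  path <- tempfile()
  writeDatabase(db, path)
  back <- readDatabase(path)
  expect_equal(dbParams(back), dbParams(db))
  expect_identical(dbSignals(back), dbSignals(db))
  expect_equal(samplePeriod(back), samplePeriod(db))
  expect_identical(dbMeta(back)$schema, dbMeta(db)$schema)
})

test_that("corrupt or mismatched containers raise schema errors", {
  db <- testDb()
  path <- tempfile()
  writeDatabase(db, path)
  file.remove(file.path(path, "signals.parquet"))
  expect_error(readDatabase(path), "schema error")

  path2 <- tempfile()
  writeDatabase(db, path2)
  meta <- jsonlite::read_json(file.path(path2, "meta.json"),
                              simplifyVector = TRUE)
  meta$schema <- "other-schema-9"
  jsonlite::write_json(meta, file.path(path2, "meta.json"),
                       auto_unbox = TRUE)
  expect_error(readDatabase(path2), "schema-version mismatch")
})

test_that("an empty database writes and reads as a valid 0-row container", {
  an <- testAnatomy()
  db0 <- generateDatabase(list(), an)
  expect_equal(nrow(dbParams(db0)), 0)
  path <- tempfile()
  writeDatabase(db0, path)
  back <- readDatabase(path)
  expect_equal(nrow(dbParams(back)), 0)
})

test_that("the deposit adapter sniffs a parameter-table layout", {
  dir <- tempfile()
  dir.create(dir)
  set.seed(8)
  n <- 25
  tab <- data.frame(rho = runif(n), z = runif(n, 0.5, 1),
                    phi = runif(n, -pi, pi), tven = runif(n, 60, 190),
                    ventricle = sample(c("LV", "RV"), n, replace = TRUE))
  write.csv(tab, file.path(dir, "parameters.csv"), row.names = FALSE)
  db <- readZenodoDatabase(dir)
  expect_s4_class(db, "ECGDatabase")
  expect_equal(nrow(dbParams(db)), n)
  expect_equal(dbParams(db)$tven, tab$tven)
  expect_true(all(!is.na(dbParams(db)$region)))
})

test_that("the deposit adapter rejects unrecognisable layouts", {
  dir <- tempfile()
  dir.create(dir)
  writeLines("not a table", file.path(dir, "readme.txt"))
  expect_error(readZenodoDatabase(dir), "unrecognised deposit layout")
  expect_error(readZenodoDatabase(tempfile()), "not found")
})
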