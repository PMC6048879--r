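# The synthetic study generator: determinism, the statistical structure
# it promises (spatial correlation, stratified Poisson densities, address
# counts, failure injection), and closed-loop field recovery.

test_that("truth fields are deterministic and honour degenerate settings", {
  cfg <- testSimConfig()
  f1 <- generateTruthField(cfg, "Ca", 123)
  f2 <- generateTruthField(cfg, "Ca", 123)
  withr::with_seed(1, {
    px <- runif(100, 0, 10000); py <- runif(100, 0, 10000)
  })
  expect_identical(f1(px, py), f2(px, py))
  expect_false(identical(f1(px, py),
                         generateTruthField(cfg, "Ca", 124)(px, py)))
  # logSd = 0 and unit enrichment -> constant exp(logMean)
  els <- defaultElementParams()[1, ]
  els$logSd <- 0; els$urbanEnrichment <- 1
  cfg0 <- testSimConfig(elements = els)
  f0 <- generateTruthField(cfg0, els$element, 5)
  expect_equal(f0(px, py), rep(exp(els$logMean), 100))
  # enrichment multiplies inside urban discs only
  els$urbanEnrichment <- 1.5
  fE <- generateTruthField(testSimConfig(elements = els), els$element, 5)
  centre <- fE(5000, 5000)       # inside the disc at (5, 5) km
  edge <- fE(9500, 9500)         # outside
  expect_equal(centre / edge, 1.5)
})

test_that("the log-scale field is spatially correlated up to its range", {
  cfg <- testSimConfig(domainKm = c(20, 20),
                       urbanCentres = data.frame(x = numeric(0),
                                                 y = numeric(0),
                                                 radius = numeric(0)))
  f <- generateTruthField(cfg, "Ca", 7)
  withr::with_seed(2, {
    px <- runif(2000, 0, 20000); py <- runif(2000, 0, 20000)
    z <- log(f(px, py))
    i <- sample(2000, 1500, replace = TRUE)
    j <- sample(2000, 1500, replace = TRUE)
  })
  d <- sqrt((px[i] - px[j])^2 + (py[i] - py[j])^2) / 1000
  g <- (z[i] - z[j])^2 / 2
  gamma <- tapply(g, cut(d, seq(0, 5, 1)), mean)
  # empirical variogram rises with lag up to the correlation length (5 km)
  expect_true(gamma[[1]] < gamma[[3]])
  expect_true(gamma[[3]] < gamma[[5]])
})

test_that("survey sampling is Poisson at the configured densities", {
  # a domain that is entirely one urban disc: 100 km^2 at 4 per km^2
  cfg <- testSimConfig(urbanCentres = data.frame(x = 5, y = 5,
                                                 radius = 8))
  f <- generateTruthFields(cfg, 3)
  sv <- generateSurvey(cfg, f, 99)
  n <- sum(siteInfo(sv)$source == "urban")
  expect_gt(n, 400 - 4 * 20)  # 4 sigma around Poisson mean 400
  expect_lt(n, 400 + 4 * 20)
  expect_equal(ncol(sv), n)   # nothing outside the urban stratum
  # zero noise: measured value equals the truth field at the site
  cfg0 <- testSimConfig(noiseSd = 0)
  f0 <- generateTruthFields(cfg0, 3)
  sv0 <- generateSurvey(cfg0, f0, 99)
  sites <- siteInfo(sv0)
  el <- rownames(sv0)[1]
  expect_equal(unname(concentrations(sv0)[el, ]),
               f0[[el]](sites$x, sites$y))
  # detection limit above the field maximum -> everything flagged
  elsHi <- defaultElementParams()[1, ]
  elsHi$detectionLimit <- exp(elsHi$logMean + 10)
  cfgHi <- testSimConfig(elements = elsHi)
  svHi <- generateSurvey(cfgHi, generateTruthFields(cfgHi, 3), 99)
  expect_true(all(belowDetection(svHi)))
  expect_true(all(is.na(concentrations(svHi))))
})

test_that("postcode geography satisfies its structural contracts", {
  cfg <- testSimConfig(postcodeCount = 10000, crosserFraction = 0.02)
  geo <- generatePostcodesAndOas(cfg, 17)
  pc <- geo$postcodes
  expect_silent(validatePostcodes(pc))
  expect_silent(validateOutputAreas(geo$oas))
  # address counts: range 1..100, mean approximately 15
  expect_true(all(pc$address_count >= 1 & pc$address_count <= 100))
  expect_lt(abs(mean(pc$address_count) - 15), 0.5)
  # partition: every postcode in exactly one OA, every OA non-empty
  expect_true(all(pc$oa_id %in% geo$oas$oa_id))
  expect_true(all(geo$oas$oa_id %in% pc$oa_id))
  # OA population proportional to its summed address counts
  oa1 <- geo$oas$oa_id[1]
  expect_equal(geo$oas$population[1],
               round(sum(pc$address_count[pc$oa_id == oa1]) * 2.4))
  # crossers: configured fraction, each with >= 2 candidate areas
  expect_equal(nrow(geo$borderCrossers), floor(0.02 * 10000))
  nCands <- lengths(strsplit(geo$borderCrossers$candidate_oas, ";"))
  expect_true(all(nCands >= 2))
  # crosser fraction 0 -> every postcode has its single home area
  geo0 <- generatePostcodesAndOas(testSimConfig(crosserFraction = 0), 17)
  expect_equal(nrow(geo0$borderCrossers), 0)
})

test_that("population generation injects the configured failure rates", {
  cfg <- testSimConfig(patientCount = 50000,
                       blankPostcodeFraction = 0.02,
                       unknownPostcodeFraction = 0,
                       participationProb = 1, inactiveFraction = 0)
  geo <- generatePostcodesAndOas(cfg, 3)
  popn <- generatePopulation(cfg, geo$postcodes, 4)
  expect_silent(validatePractices(popn$practices))
  expect_silent(validatePatients(popn$patients))
  # participation probability 1 -> all practices participate
  expect_true(all(popn$practices$participating))
  # blank-postcode share 2% within 0.3 percentage points
  share <- mean(popn$patients$postcode == "")
  expect_lt(abs(share - 0.02), 0.003)
  # every non-blank postcode resolves to a generated postcode
  filled <- popn$patients$postcode[popn$patients$postcode != ""]
  expect_true(all(filled %in% geo$postcodes$code))
  # unknown postcodes are injected as unresolvable codes
  cfgU <- testSimConfig(patientCount = 20000,
                        blankPostcodeFraction = 0,
                        unknownPostcodeFraction = 0.03)
  popU <- generatePopulation(cfgU, geo$postcodes, 4)
  bad <- !popU$patients$postcode %in% geo$postcodes$code
  expect_lt(abs(mean(bad) - 0.03), 0.005)
})

test_that("a full study is reproducible under the master seed", {
  cfg <- testSimConfig()
  s1 <- simulateStudy(cfg, 11)
  s2 <- simulateStudy(cfg, 11)
  expect_identical(concentrations(s1$survey), concentrations(s2$survey))
  expect_identical(s1$postcodes, s2$postcodes)
  expect_identical(s1$patients, s2$patients)
  expect_identical(s1$practices, s2$practices)
  s3 <- simulateStudy(cfg, 12)
  expect_false(identical(s1$patients, s3$patients))
  # generated artifacts satisfy every reader contract via a round trip
  dir <- withr::local_tempdir()
  simulateStudy(cfg, 11, outDir = dir)
  expect_silent({
    readSurvey(file.path(dir, "survey.csv"),
               configPanel(cfg))
    readPostcodes(file.path(dir, "postcodes.csv"))
    readOutputAreas(file.path(dir, "output_areas.csv"))
    readPractices(file.path(dir, "practices.csv"))
    readPatients(file.path(dir, "patients.csv"))
  })
})

test_that("interpolation recovers the truth field at survey densities", {
  # rural density (1 per 2 km^2): median absolute relative error <= 15%
  cfgR <- simConfig(domainKm = c(20, 20),
                    urbanCentres = data.frame(x = numeric(0),
                                              y = numeric(0),
                                              radius = numeric(0)),
                    ruralSplit = 1, urbanShare = 0,
                    elements = defaultElementParams()[1:3, ],
                    postcodeCount = 500)
  fR <- generateTruthFields(cfgR, 21)
  svR <- generateSurvey(cfgR, fR, derivedSeed(21, "survey"))
  geoR <- generatePostcodesAndOas(cfgR, derivedSeed(21, "postcodes"))
  sitesR <- siteInfo(svR)
  for (el in rownames(svR)) {
    est <- idwAtPoints(sitesR$x, sitesR$y, interpolationValues(svR, el),
                       geoR$postcodes$x, geoR$postcodes$y, idwConfig())
    truth <- fR[[el]](geoR$postcodes$x, geoR$postcodes$y)
    expect_lt(median(abs(est - truth) / truth), 0.15)
  }
  # urban density (4 per km^2): <= 8% at centroids inside urban centres
  cfgU <- simConfig(elements = defaultElementParams()[1:3, ],
                    postcodeCount = 500)
  fU <- generateTruthFields(cfgU, 22)
  svU <- generateSurvey(cfgU, fU, derivedSeed(22, "survey"))
  geoU <- generatePostcodesAndOas(cfgU, derivedSeed(22, "postcodes"))
  sitesU <- siteInfo(svU)
  u <- cfgU@urbanCentres
  inU <- rep(FALSE, nrow(geoU$postcodes))
  for (k in seq_len(nrow(u))) {
    inU <- inU | ((geoU$postcodes$x / 1000 - u$x[k])^2 +
                    (geoU$postcodes$y / 1000 - u$y[k])^2 <=
                    u$radius[k]^2)
  }
  for (el in rownames(svU)) {
    est <- idwAtPoints(sitesU$x, sitesU$y, interpolationValues(svU, el),
                       geoU$postcodes$x[inU], geoU$postcodes$y[inU],
                       idwConfig())
    truth <- fU[[el]](geoU$postcodes$x[inU], geoU$postcodes$y[inU])
    expect_lt(median(abs(est - truth) / truth), 0.08)
  }
})
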