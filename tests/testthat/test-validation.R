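# Census apportionment, the census-date activity rule, weighted boxplot
# summaries (with the expansion oracle), and distribution comparison.

test_that("populations split equally and conserve exactly", {
  oas <- data.frame(oa_id = c("OA1", "OA2"), region_id = c("R1", "R2"),
                    population = c(100, 37))
  pc <- makePostcodes(sprintf("P%d", 1:6), x = 1:6, y = 1:6,
                      oa_id = c(rep("OA1", 4), rep("OA2", 2)),
                      region_id = c(rep("R1", 4), rep("R2", 2)))
  pp <- apportionPopulation(oas, pc, seed = 1)
  expect_equal(pp$population[pp$assigned_oa == "OA1"], rep(25, 4))
  expect_equal(sum(pp$population), 137)
  expect_equal(pp$assigned_region,
               c(rep("R1", 4), rep("R2", 2)))
  # an OA with population but no postcode is an error naming the OA
  oas2 <- rbind(oas, data.frame(oa_id = "OA3", region_id = "R1",
                                population = 10))
  expect_error(apportionPopulation(oas2, pc, seed = 1), "OA3")
})

test_that("border-crossers are assigned deterministically and uniformly", {
  oas <- data.frame(oa_id = c("OA1", "OA2"), region_id = c("R1", "R2"),
                    population = c(30, 60))
  pc <- makePostcodes(c("A", "B", "X"), x = 1:3, y = 1:3,
                      oa_id = c("OA1", "OA2", "OA1"),
                      region_id = c("R1", "R2", "R1"))
  bc <- data.frame(code = "X", candidate_oas = "OA1;OA2")
  # same seed -> same single assignment on every run
  a1 <- apportionPopulation(oas, pc, bc, seed = 42)
  a2 <- apportionPopulation(oas, pc, bc, seed = 42)
  expect_identical(a1, a2)
  # Monte-Carlo: a 2-candidate crosser lands in each area ~uniformly
  hits <- vapply(1:10000, function(s) {
    pp <- apportionPopulation(oas, pc, bc, seed = s)
    pp$assigned_oa[pp$code == "X"] == "OA1"
  }, logical(1))
  expect_gt(mean(hits), 0.48)
  expect_lt(mean(hits), 0.52)
  # conservation holds exactly for any seed and assignment
  for (s in c(1, 7, 99)) {
    pp <- apportionPopulation(oas, pc, bc, seed = s)
    expect_equal(sum(pp$population), 90)
  }
})

test_that("census-date activity follows the inclusive-start rule", {
  census <- as.Date("2011-03-27")
  pt <- makePatients(6, "PR01", "PC1",
    registration_start = as.Date(c("2005-01-01", "2005-01-01",
                                   "2011-03-27", "2011-03-28",
                                   "2005-01-01", "2005-01-01")),
    registration_end = as.Date(c(NA, NA, NA, NA, "2011-03-27",
                                 "2011-03-26")),
    death_date = as.Date(c(NA, "2010-12-31", NA, NA, NA, NA)))
  expect_equal(activeOn(pt, census),
               c(TRUE,   # open registration, alive
                 FALSE,  # died before the census
                 TRUE,   # registration starts on the census date
                 FALSE,  # registered after the census
                 TRUE,   # registration ends on the census date
                 FALSE)) # deregistered the day before
  # death on the census date itself counts as not alive
  pt2 <- makePatients(1, "PR01", "PC1",
                      registration_start = as.Date("2005-01-01"),
                      death_date = census)
  expect_false(activeOn(pt2, census))
})

test_that("weighted summary reduces, degenerates and expands correctly", {
  # equal weights match the same convention unweighted (tie-free data)
  withr::with_seed(81, {
    for (rep in 1:20) {
      v <- rnorm(sample(5:40, 1))
      expect_equal(
        weightedQuantile(v, rep(1, length(v)), c(0.25, 0.5, 0.75)),
        unname(quantile(v, c(0.25, 0.5, 0.75), type = 5)))
    }
  })
  # single value: all five statistics equal it
  s <- weightedSummary(7.25, 3)
  expect_equal(unlist(s[1, 1:5], use.names = FALSE), rep(7.25, 5))
  expect_equal(s$effective_weight, 3)
  # integer weights {v:1, w:3} match the expanded list [v, w, w, w]
  s1 <- weightedSummary(c(2, 9), c(1, 3))
  s2 <- weightedSummary(c(2, 9, 9, 9), rep(1, 4))
  expect_equal(s1[1:5], s2[1:5])
  # randomized expansion oracle
  withr::with_seed(82, {
    for (rep in 1:200) {
      k <- sample(2:8, 1)
      v <- round(rlnorm(k, 2, 1), 2)
      w <- sample(1:5, k, replace = TRUE)
      a <- weightedSummary(v, w)
      b <- weightedSummary(rep(v, times = w), rep(1, sum(w)))
      expect_equal(a[1:5], b[1:5], tolerance = 1e-12)
    }
  })
  # invariance under weight rescaling
  withr::with_seed(83, {
    v <- rlnorm(30); w <- runif(30, 0.1, 4)
    a <- weightedSummary(v, w)
    b <- weightedSummary(v, w * 17.3)
    expect_equal(a[1:5], b[1:5])
  })
  # zero weights are excluded; all-zero weights are an error
  expect_equal(weightedSummary(c(1, 50), c(2, 0))$median, 1)
  expect_error(weightedSummary(c(1, 2), c(0, 0)), "all weights are zero")
  # ordering invariant of the five numbers
  withr::with_seed(84, {
    for (rep in 1:50) {
      v <- rlnorm(sample(3:30, 1), 1, 1.5)
      w <- runif(length(v), 0, 2)
      w[1] <- 1
      s <- weightedSummary(v, w)
      expect_true(s$lower_adjacent <= s$q1 && s$q1 <= s$median &&
                    s$median <= s$q3 && s$q3 <= s$upper_adjacent)
    }
  })
})

test_that("expected distributions weight postcodes by population", {
  m <- matrix(c(10, 20, 30, 40, 50,
                5, 5, 5, 5, 5), 5, 2,
              dimnames = list(sprintf("P%d", 1:5), c("Pb", "Zn")))
  et <- exposureTable(m)
  pops <- data.frame(code = sprintf("P%d", 1:5),
                     population = c(100, 100, 100, 100, 0),
                     assigned_oa = "OA1", assigned_region = "R1")
  d <- expectedDistribution(et, pops)
  pb <- d[d$element == "Pb", ]
  # zero-weight postcode excluded: summary over 10..40 equal weights
  oracle <- weightedSummary(c(10, 20, 30, 40), rep(1, 4))
  expect_equal(pb$median, oracle$median)
  expect_equal(pb$q1, oracle$q1)
  expect_equal(pb$effective_weight, 400)
  # constant element collapses to five equal numbers
  zn <- d[d$element == "Zn", ]
  expect_equal(unlist(zn[1, 3:7], use.names = FALSE), rep(5, 5))
  # two postcodes with populations 100 and 0 -> the populated value
  pops2 <- pops[1:2, ]; pops2$population <- c(100, 0)
  d2 <- expectedDistribution(exposureTable(m[1:2, ]), pops2)
  expect_equal(d2$median[d2$element == "Pb"], 10)
})

test_that("observed distributions use active patients with unit weight", {
  pr <- makePractices(2, region_id = c("R1", "R2"))
  census <- as.Date("2011-03-27")
  pt <- makePatients(4, c("PR01", "PR01", "PR01", "PR02"), "PC1")
  pt$registration_end[2] <- as.Date("2010-01-01")  # inactive at census
  records <- data.frame(patient_id = pt$patient_id,
                        Pb = c(10, 99, 30, 7), Zn = c(1, 2, NA, 4))
  d <- observedDistribution(records, pt, pr, census)
  r1pb <- d[d$region_id == "R1" & d$element == "Pb", ]
  # inactive patient's 99 is excluded
  expect_equal(r1pb$median, 20)
  expect_equal(r1pb$effective_weight, 2)
  # element-wise missing exclusion
  r1zn <- d[d$region_id == "R1" & d$element == "Zn", ]
  expect_equal(r1zn$effective_weight, 1)
  # one active patient collapses to that patient's values
  r2 <- d[d$region_id == "R2" & d$element == "Pb", ]
  expect_equal(unlist(r2[1, 3:7], use.names = FALSE), rep(7, 5))
  # all patients inactive -> no summaries
  ptOff <- pt; ptOff$registration_end <- as.Date("2009-01-01")
  expect_equal(nrow(observedDistribution(records, ptOff, pr, census)), 0)
  # duplicating a patient doubles the weight, keeps the median
  pt2 <- rbind(pt, transform(pt[1, ], patient_id = "P9999"))
  rec2 <- rbind(records, transform(records[1, ], patient_id = "P9999"))
  d2 <- observedDistribution(rec2, pt2, pr, census)
  r1pb2 <- d2[d2$region_id == "R1" & d2$element == "Pb", ]
  expect_equal(r1pb2$effective_weight, 3)
  oracle <- weightedSummary(c(10, 10, 30), rep(1, 3))
  expect_equal(r1pb2$median, oracle$median)
})

test_that("distribution comparison flags restricted observed ranges", {
  e <- data.frame(region_id = "R1", element = "Pb", median = 20, q1 = 10,
                  q3 = 30, lower_adjacent = 2, upper_adjacent = 50,
                  effective_weight = 100)
  # identical summaries -> ratios 1, no flag
  cmp <- compareDistributions(e, e)
  expect_equal(cmp$median_ratio, 1)
  expect_equal(cmp$iqr_ratio, 1)
  expect_false(cmp$restricted)
  # observed span one tenth of expected -> flag raised
  o <- transform(e, q1 = 19, q3 = 21, lower_adjacent = 18,
                 upper_adjacent = 22.8)
  cmp2 <- compareDistributions(e, o)
  expect_true(cmp2$restricted)
  expect_equal(cmp2$span_ratio, 0.1)
  # absent stratum on either side -> incomparable
  o2 <- transform(e, element = "Zn")
  cmp3 <- compareDistributions(e, o2)
  expect_equal(nrow(cmp3), 2)
  expect_true(all(!cmp3$comparable))
  expect_true(all(is.na(cmp3$restricted)))
})
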