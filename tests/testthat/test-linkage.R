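# Exposure assignment, patient matching, and the participation/coverage
# accounting, including the confidentiality contract.

test_that("detection-limit exclusion counts below-LOD fractions", {
  panel <- twoElementPanel()
  # Pb below LOD in 3 of 4 samples (0.75 >= threshold -> excluded),
  # Zn in 2 of 4 (0.5 -> retained)
  bd <- rbind(c(TRUE, TRUE, TRUE, FALSE),
              c(TRUE, TRUE, FALSE, FALSE))
  sv <- makeSurvey(x = 1:4 * 1000, y = rep(0, 4),
                   values = rbind(Pb = c(1, 1, 1, 5),
                                  Zn = c(2, 2, 8, 9)),
                   panel = panel, belowDetection = bd)
  res <- lodExclusion(sv)
  expect_equal(unname(res$fraction), c(0.75, 0.5))
  expect_equal(res$excluded, "Pb")
  expect_equal(res$retained, "Zn")
  # never below LOD -> retained
  sv2 <- makeSurvey(x = 1:4 * 1000, y = rep(0, 4),
                    values = rbind(Pb = 1:4, Zn = 5:8), panel = panel)
  expect_equal(lodExclusion(sv2)$retained, c("Pb", "Zn"))
  # element with no measurement and no flag anywhere -> error naming it
  conc <- rbind(Pb = rep(NA_real_, 2), Zn = c(1, 2))
  sites <- data.frame(site_id = c("a", "b"), x = c(0, 1), y = c(0, 1),
                      source = "rural")
  sv3 <- SoilSurvey(sites, conc, matrix(FALSE, 2, 2), panel)
  expect_error(lodExclusion(sv3), "absent from all samples: Pb")
})

test_that("exposures are assigned from the cell containing the centroid", {
  vPb <- matrix(c(1, 2, 3, 4), 2, 2)   # cell (1,1)=1 (SW), (2,2)=4 (NE)
  vZn <- matrix(c(10, 20, 30, NA), 2, 2)
  sPb <- concentrationSurface(vPb, c(0, 0), 1000, "Pb")
  sZn <- concentrationSurface(vZn, c(0, 0), 1000, "Zn")
  pc <- makePostcodes(c("A", "B", "C", "D"),
                      x = c(500, 700, 1500, 9000),
                      y = c(500, 500, 1500, 9000))
  et <- assignExposures(pc, list(Pb = sPb, Zn = sZn))
  m <- exposureMatrix(et)
  # direct lookup oracle
  expect_equal(m["A", ], c(Pb = 1, Zn = 10))
  # two postcodes in the same cell -> identical rows
  expect_equal(m["A", ], m["B", ])
  # NE cell has a missing Zn value
  expect_equal(m["C", ], c(Pb = 4, Zn = NA))
  # centroid outside all coverage -> all-missing row
  expect_true(all(is.na(m["D", ])))
  # duplicate postcode codes -> error
  expect_error(assignExposures(rbind(pc, pc[1, ]), list(Pb = sPb)),
               "duplicate postcode")
  # mismatched surface geometry -> error
  sBad <- concentrationSurface(vZn, c(0, 0), 500, "Zn")
  expect_error(assignExposures(pc, list(Pb = sPb, Zn = sBad)),
               "share extent")
})

test_that("patient matching partitions into the six outcome categories", {
  m <- matrix(c(5, 10, NA, 1, NA, NA), 3, 2,
              dimnames = list(c("FULL", "PART", "NONE"), c("Pb", "Zn")))
  et <- exposureTable(m)
  pr <- makePractices(2, participating = c(TRUE, FALSE))
  pt <- makePatients(6, c("PR01", "PR01", "PR01", "PR01", "PR01", "PR02"),
                     c("FULL", "PART", "NONE", "", "GHOST", "FULL"))
  res <- linkPatients(pt, pr, et)
  expect_equal(as.character(res$outcomes$category),
               c("complete", "partial", "no_coverage", "no_postcode",
                 "postcode_unmatched", "practice_not_participating"))
  # partition: categories sum to the patient count
  expect_equal(sum(outcomeCounts(res$outcomes)), nrow(pt))
  # records only for complete/partial, in patient order
  expect_equal(res$records$patient_id, c("P0001", "P0002"))
  expect_equal(res$records$Pb, c(5, 10))
  expect_equal(res$records$Zn, c(1, NA))
  expect_error(linkPatients(makePatients(1, "PRXX", "FULL"), pr, et),
               "unknown practice")
})

test_that("no serialized linkage output contains any input postcode", {
  withr::with_seed(61, {
    codes <- sprintf("ZZ%02d", 1:30)
    m <- matrix(runif(60, 1, 9), 30, 2,
                dimnames = list(codes, c("Pb", "Zn")))
    et <- exposureTable(m)
    pr <- makePractices(3)
    pt <- makePatients(100, pr$practice_id,
                       sample(codes, 100, replace = TRUE))
    res <- linkPatients(pt, pr, et)
    out <- withr::local_tempfile(fileext = ".csv")
    write.csv(res$records, out, row.names = FALSE)
    json <- withr::local_tempfile(fileext = ".json")
    writeReportJson(res$records, json)
    for (f in c(out, json)) {
      text <- paste(readLines(f), collapse = "\n")
      expect_false(any(vapply(codes, grepl, logical(1), x = text,
                              fixed = TRUE)))
    }
    expect_false("postcode" %in% names(res$records))
  })
})

test_that("participation report reproduces printed-table percentages", {
  # national totals: 377 participating of 395 active -> 95%
  pr <- makePractices(450, region_id = "All",
                      active = c(rep(TRUE, 395), rep(FALSE, 55)),
                      participating = c(rep(TRUE, 377), rep(FALSE, 73)))
  rep1 <- participationReport(pr)
  expect_equal(rep1$pct[rep1$region_id == "Total"], 95)
  expect_equal(rep1$active[rep1$region_id == "Total"], 395)
  # 7 of 9 -> 78% (the low-participation region)
  pr2 <- makePractices(9, region_id = "YH",
                       participating = c(rep(TRUE, 7), FALSE, FALSE))
  expect_equal(participationReport(pr2)$pct[1], 78)
  # all participate -> 100%
  pr3 <- makePractices(5)
  expect_equal(participationReport(pr3)$pct, c(100, 100))
  # region with zero active practices is suppressed with a warning
  pr4 <- rbind(makePractices(3, region_id = "A"),
               data.frame(practice_id = "PRX", region_id = "B",
                          active = FALSE, participating = FALSE))
  expect_warning(rep4 <- participationReport(pr4), "no active")
  expect_false("B" %in% rep4$region_id)
})

test_that("coverage percentages use the table denominators and rounding", {
  # national totals row: 7,137,365 / 6,825,382 / 6,320,152 / 6,243,363
  r <- coverageReportFromCounts("All", 7137365, 6825382, 6320152,
                                6243363, addTotal = FALSE)
  expect_equal(r$at_linkage_pct, 95.6)
  expect_equal(r$partial_pct, 92.6)
  expect_equal(r$complete_pct, 91.5)
  # all complete -> 100.0 throughout
  r2 <- coverageReportFromCounts(c("A", "B"), c(10, 20), c(10, 20),
                                 c(10, 20), c(10, 20))
  expect_true(all(r2$at_linkage_pct == 100 & r2$complete_pct == 100))
  # Total row equals the column sums
  expect_equal(r2$total[r2$region_id == "Total"], 30)
  # monotone denominators enforced
  expect_error(coverageReportFromCounts("A", 5, 6, 3, 1),
               "complete <= partial <= at_linkage <= total")
})

test_that("coverage report from outcomes matches hand counts", {
  m <- matrix(c(5, NA, 1, NA), 2, 2,
              dimnames = list(c("FULL", "HALF"), c("Pb", "Zn")))
  m["HALF", "Pb"] <- 3  # HALF has Pb only
  et <- exposureTable(m)
  pr <- rbind(makePractices(2, region_id = c("R1", "R2")),
              data.frame(practice_id = "PR90", region_id = "R1",
                         active = TRUE, participating = FALSE),
              data.frame(practice_id = "PR91", region_id = "R1",
                         active = FALSE, participating = FALSE))
  pt <- makePatients(7,
                     c("PR01", "PR01", "PR01", "PR02", "PR90", "PR91",
                       "PR01"),
                     c("FULL", "HALF", "", "FULL", "FULL", "FULL",
                       "GHOST"))
  res <- linkPatients(pt, pr, et)
  cov <- coverageReport(res$outcomes, pt, pr)
  r1 <- cov[cov$region_id == "R1", ]
  # patient at the inactive practice is excluded from all denominators
  expect_equal(r1$total, 5)
  expect_equal(r1$at_linkage, 4)
  expect_equal(r1$partial, 2)    # FULL + HALF
  expect_equal(r1$complete, 1)   # FULL only
  expect_equal(r1$at_linkage_pct, 80.0)
  expect_equal(r1$partial_pct, 50.0)
  tot <- cov[cov$region_id == "Total", ]
  expect_equal(tot$total, 6)
  expect_equal(tot$complete, 2)
  # monotone invariant in every row
  expect_true(all(cov$complete <= cov$partial &
                    cov$partial <= cov$at_linkage &
                    cov$at_linkage <= cov$total))
})

test_that("reports are deterministic across repeated computation", {
  withr::with_seed(71, {
    codes <- sprintf("PC%03d", 1:50)
    m <- matrix(runif(100), 50, 2,
                dimnames = list(codes, c("Pb", "Zn")))
    et <- exposureTable(m)
    pr <- makePractices(4, region_id = c("A", "A", "B", "B"),
                        participating = c(TRUE, FALSE, TRUE, TRUE))
    pt <- makePatients(200, sample(pr$practice_id, 200, replace = TRUE),
                       sample(c(codes, ""), 200, replace = TRUE))
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    res1 <- linkPatients(pt, pr, et)
    res2 <- linkPatients(pt, pr, et)
    writeReportJson(coverageReport(res1$outcomes, pt, pr), f1)
    writeReportJson(coverageReport(res2$outcomes, pt, pr), f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_equal(sum(outcomeCounts(res1$outcomes)), 200)
  })
})
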