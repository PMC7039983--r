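profC <- alignExposure(exposureHistory(height = 65, ageMenarche = 12,
                                       hbcIntervals = cbind(18, 30)), 42)
profS <- alignExposure(exposureHistory(height = 63, ageMenarche = 13,
                                       birthAges = 26, breastfed = FALSE), 42)
profC$birth_order_elder <- 0L
profS$birth_order_elder <- 1L

test_that("1:3 designs cross genotype and exposure sources in fixed order", {
  m <- buildMatchedSet("f1", "case_parents_plus", casePrs = 0.4,
                       counterpartPrs = -0.1, caseExposure = profC,
                       siblingExposure = profS)
  expect_equal(nrow(m), 4L)
  expect_equal(sum(m$is_case), 1L)
  expect_true(m$is_case[1])
  expect_equal(m$genotype_source,
               c("case", "pseudo_sibling", "case", "pseudo_sibling"))
  expect_equal(m$exposure_source, c("case", "sibling", "sibling", "case"))
  expect_equal(m$prs, c(0.4, -0.1, 0.4, -0.1))
  expect_equal(m$height, c(65, 63, 63, 65))          # follows exposure source
  expect_equal(m$birth_order_elder, c(0L, 1L, 1L, 0L))
  m2 <- buildMatchedSet("f2", "case_sibling_plus", 0.4, -0.1, profC, profS)
  expect_equal(m2$genotype_source, c("case", "sibling", "case", "sibling"))
})

test_that("1:1 designs share one source across both members", {
  m <- buildMatchedSet("f3", "case_plus", casePrs = 0.4, caseExposure = profC,
                       siblingExposure = profS)
  expect_equal(nrow(m), 2L)
  expect_equal(unique(m$prs), 0.4)                    # genotype shared
  expect_equal(m$exposure_source, c("case", "sibling"))
  # case_parents: sibling exposure supplied but unused; case exposure shared
  m2 <- buildMatchedSet("f4", "case_parents", casePrs = 0.4,
                        counterpartPrs = -0.2, caseExposure = profC,
                        siblingExposure = profS)
  expect_equal(nrow(m2), 2L)
  expect_equal(unique(m2$exposure_source), "case")
  expect_equal(unique(m2$height), 65)
  expect_equal(m2$prs, c(0.4, -0.2))
})

test_that("missing required sources raise design-mismatch errors", {
  expect_error(buildMatchedSet("f", "case_parents_plus", 0.4, -0.1, profC),
               "sibling exposure")
  expect_error(buildMatchedSet("f", "case_sibling_plus", 0.4, NA_real_,
                               profC, profS), "counterpart PRS")
  expect_error(buildMatchedSet("f", "nonsense", 0.4, -0.1, profC, profS),
               "unknown design")
})

test_that("member accounting over a simulated cohort matches the design mix", {
  ds <- simulateFamilies(fastConfig(nFamilies = 200, seed = 21))
  prep <- buildMatchedSets(ds)
  m <- setMembers(prep$sets)
  expect_s4_class(prep$sets, "MatchedSets")
  des <- table(m$design[!duplicated(m$set_id)])
  n13 <- sum(des[c("case_parents_plus", "case_sibling_plus")])
  n11 <- sum(des[c("case_parents", "case_plus")])
  expect_equal(nrow(m), 4 * n13 + 2 * n11)
  expect_equal(sum(m$is_case), nSets(prep$sets))
  # one case member per set is enforced by the class validity
  bad <- m; bad$is_case[2] <- TRUE
  expect_error(new("MatchedSets", members = bad, centering = 0), "exactly one case")
  # the TSV export round-trips the member table
  f <- writeMatchedSets(prep$sets, file.path(tempdir(), "sets.tsv"))
  back <- utils::read.delim(f)
  expect_equal(nrow(back), nrow(m))
  expect_equal(back$prs, m$prs, tolerance = 1e-9)
  expect_equal(back$genotype_source, m$genotype_source)
})
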