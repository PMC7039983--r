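test_that("alignExposure truncates time-dependent factors at the index age", {
  h <- exposureHistory(height = 65, ageMenarche = 13, birthAges = c(24, 31),
                       breastfed = TRUE, hbcIntervals = cbind(18, 29))
  p <- alignExposure(h, indexAge = 28)
  expect_equal(p$parity, "1")                 # birth at 31 not yet counted
  expect_equal(p$last_birth_within5, 1L)      # 28 - 24 < 5
  expect_equal(p$afb_cont, 24)
  expect_equal(p$afb_cat, "20-25")
  expect_equal(p$height, 65)                  # time-fixed passthrough
  expect_equal(p$age_menarche, 13)
})

test_that("menopause after the index age leaves the subject premenopausal", {
  h <- exposureHistory(menopauseAge = 47, bmi30 = 24)
  expect_equal(alignExposure(h, 44)$premenopausal, 1L)
  expect_equal(alignExposure(h, 48)$premenopausal, 0L)
  # BMI at 30 is carried only while premenopausal
  expect_equal(alignExposure(h, 44)$bmi30, 24)
  expect_true(is.na(alignExposure(h, 48)$bmi30))
})

test_that("hormonal birth control use is cumulated and windowed at index age", {
  h <- exposureHistory(hbcIntervals = cbind(18, 29))
  p <- alignExposure(h, 45)
  expect_equal(p$hbc_ever, 1L)
  expect_equal(p$hbc_within5, 0L)             # window (40, 45] has no use
  expect_equal(p$hbc_years, ">=10")           # 11 years of use
  # use truncated at the index age
  p2 <- alignExposure(h, 21)
  expect_equal(p2$hbc_years, "2-<10")         # 3 years by index
  expect_equal(p2$hbc_within5, 1L)
  # never-users fall in the lowest years category
  p3 <- alignExposure(exposureHistory(), 45)
  expect_equal(p3$hbc_ever, 0L)
  expect_equal(p3$hbc_years, "<2")
  expect_true(is.na(p3$last_birth_within5))   # nulliparous
})

test_that("alignExposure is monotone in index age for cumulative quantities", {
  set.seed(31)
  for (i in 1:20) {
    h <- exposureHistory(birthAges = sort(stats::runif(sample(0:4, 1), 16, 45)),
                         breastfed = TRUE,
                         hbcIntervals = cbind(16, stats::runif(1, 17, 40)))
    ages <- sort(stats::runif(3, 18, 50))
    par <- vapply(ages, function(a)
      match(alignExposure(h, a)$parity, factorLevels("parity")), 0L)
    expect_true(all(diff(par) >= 0))
    yrs <- vapply(ages, function(a)
      match(alignExposure(h, a)$hbc_years, factorLevels("hbc_years")), 0L)
    expect_true(all(diff(yrs) >= 0))
    # idempotent: same index age, same profile
    expect_identical(alignExposure(h, ages[2]), alignExposure(h, ages[2]))
  }
})

test_that("inconsistent histories are rejected", {
  expect_error(alignExposure(exposureHistory(birthAges = -3), 30), "non-negative")
  expect_error(alignExposure(exposureHistory(hbcIntervals = cbind(25, 20)), 30),
               "start <= stop")
  expect_error(alignExposure(exposureHistory(ageMenarche = 14, menopauseAge = 11), 30),
               "menarche")
  expect_error(alignExposure(exposureHistory(), -1), "positive")
})
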