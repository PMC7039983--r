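test_that("identical seeds reproduce byte-identical dataset files", {
  cfg <- fastConfig(nFamilies = 80, seed = 123)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  p1 <- writeDataset(simulateFamilies(cfg), d1)
  p2 <- writeDataset(simulateFamilies(cfg), d2)
  for (k in names(p1))
    expect_identical(readBin(p1[[k]], "raw", file.size(p1[[k]])),
                     readBin(p2[[k]], "raw", file.size(p2[[k]])),
                     label = paste("file", k))
  # a different seed gives a different dataset
  d3 <- simulateFamilies(fastConfig(nFamilies = 80, seed = 124))
  expect_false(identical(d3@genotypes, simulateFamilies(cfg)@genotypes))
})

test_that("requested design counts are honored exactly", {
  cfg <- fastConfig(nFamilies = 60, seed = 2,
                    designCounts = c(case_parents_plus = 20, case_parents = 5,
                                     case_sibling_plus = 25, case_plus = 10))
  ds <- simulateFamilies(cfg)
  ped <- ds@pedigree
  expect_equal(sum(ped$role == "case"), 60L)
  # availability masking: genotyped parents only in the parent designs
  nPar <- sum(ped$role == "father" & ped$genotyped == 1)
  expect_equal(nPar, 25L)                       # 20 + 5
  nSibG <- sum(ped$role == "control_sister" & ped$genotyped == 1)
  expect_equal(nSibG, 25L)
  nSibE <- sum(ped$role == "control_sister" & ped$exposure == 1)
  expect_equal(nSibE, 55L)                      # all but case_parents
})

test_that("parental genotypes match Hardy-Weinberg dosage means", {
  pan <- defaultPanel(10)
  ds <- simulateFamilies(simConfig(nFamilies = 800, panel = pan, seed = 17,
                                   designCounts = c(case_parents_plus = 1,
                                                    case_parents = 0,
                                                    case_sibling_plus = 0,
                                                    case_plus = 0)))
  ped <- ds@pedigree
  par <- ds@genotypes[ds@genotypes$subject_id %in%
                        ped$subject_id[ped$role %in% c("father", "mother")], ]
  dmeans <- colMeans(par[, snpIds(pan)])
  expected <- 2 * alleleFrequencies(pan)
  # Monte-Carlo tolerance: 4 SDs of a mean of 1600 binomial(2, p) draws
  tol <- 4 * sqrt(2 * alleleFrequencies(pan) * (1 - alleleFrequencies(pan)) / 1600)
  expect_true(all(abs(dmeans - expected) < tol))
})

test_that("ascertainment shifts the case PRS above the control sisters", {
  ds <- simulateFamilies(fastConfig(nFamilies = 900, seed = 19))
  pan <- new("SnpWeightPanel", weights = ds@truth$panel)
  sc <- computePrs(ds@genotypes, pan)
  ped <- ds@pedigree
  prsOf <- function(role) sc$raw[sc$subject_id %in%
                                   ped$subject_id[ped$role == role & ped$genotyped == 1]]
  expect_gt(mean(prsOf("case")), mean(prsOf("control_sister")))
})

test_that("default generator marginals sit near the published reference", {
  ds <- simulateFamilies(fastConfig(nFamilies = 900, seed = 23))
  cal <- compareMarginals(ds)
  get <- function(v, l, col) cal[cal$variable == v & cal$level == l, col][1]
  expect_lt(abs(get("prs", "sd", "control") - 0.46), 0.05)
  expect_lt(abs(get("premenopausal", "1", "control") - 0.89), 0.03)
  expect_lt(abs(get("hbc_ever", "1", "control") - 0.89), 0.03)
  expect_lt(abs(get("height", "mean", "control") - 65.0), 0.3)
  expect_lt(abs(get("parity", "0", "control") - 0.25), 0.05)
  # reference columns are attached for side-by-side reading
  expect_equal(get("prs", "sd", "control_ref"), 0.46)
})

test_that("degenerate exposure prevalence and acceptance floor behave as specified", {
  # prevalence 1 yields proportion exactly 1
  ds <- simulateFamilies(fastConfig(nFamilies = 40, seed = 3,
                                    exposureModel = list(hbc_ever = 1.0)))
  expect_true(all(ds@exposures$hbc_ever == 1))
  # an impossible ascertainment regime aborts with advice
  cfg <- fastConfig(nFamilies = 50, seed = 3, baselineLogit = -18)
  expect_error(simulateFamilies(cfg), "acceptance rate")
})
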