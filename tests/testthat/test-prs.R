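test_that("computePrs is the dosage-weighted sum of log odds ratios", {
  p <- tinyPanel()
  # unit odds ratios carry zero weight
  p1 <- snpWeightPanel(snpIds(p), rep("A", 3), rep(1, 3))
  expect_equal(computePrs(c(rs1 = 2, rs2 = 0.5, rs3 = 1.3), p1)$raw, 0)
  # ln(e) = 1, dosage 2
  pe <- snpWeightPanel("rs9", "G", exp(1))
  expect_equal(computePrs(c(rs9 = 2), pe)$raw, 2.0)
  # hand-computed oracle: 2*ln(1.1) + 1*ln(1.2) + 0*ln(0.9)
  expect_equal(computePrs(c(rs1 = 2, rs2 = 1, rs3 = 0), p)$raw,
               0.3729419, tolerance = 1e-6)
  # order-independence
  expect_equal(computePrs(c(rs3 = 0, rs1 = 2, rs2 = 1), p)$raw,
               computePrs(c(rs1 = 2, rs2 = 1, rs3 = 0), p)$raw)
})

test_that("computePrs handles matrices, missing markers and bad panels", {
  p <- tinyPanel()
  D <- data.frame(subject_id = c("a", "b"), rs1 = c(2, 0), rs2 = c(1, 1),
                  rs3 = c(0, 2))
  sc <- computePrs(D, p)
  expect_equal(sc$subject_id, c("a", "b"))
  expect_equal(sc$raw[1], 0.3729419, tolerance = 1e-6)
  # missing marker under the default policy names the offender
  expect_error(computePrs(c(rs1 = 1, rs2 = 1), p), "rs3")
  # mean-dosage policy needs reference means and then fills in
  expect_error(computePrs(c(rs1 = 1, rs2 = 1), p, missingPolicy = "mean_dosage"),
               "referenceMeans")
  sc2 <- computePrs(c(rs1 = 1, rs2 = 1), p, missingPolicy = "mean_dosage",
                    referenceMeans = c(rs3 = 0.8))
  expect_equal(sc2$raw, log(1.1) + log(1.2) + 0.8 * log(0.9))
  # dosages outside [0, 2] and non-positive odds ratios are rejected
  expect_error(computePrs(c(rs1 = 2.4, rs2 = 1, rs3 = 0), p), "\\[0, 2\\]")
  expect_error(snpWeightPanel("x", "A", -2), "positive")
})

test_that("PRS is additive over concatenated panels and monotone in dosage", {
  set.seed(42)
  for (rep in 1:5) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    ids <- sprintf("m%02d", seq_len(n1 + n2))
    ors <- round(exp(stats::rnorm(n1 + n2, 0, 0.2)), 3)
    d <- stats::setNames(round(stats::runif(n1 + n2, 0, 2), 2), ids)
    pa <- snpWeightPanel(ids[1:n1], rep("A", n1), ors[1:n1])
    pb <- snpWeightPanel(ids[-(1:n1)], rep("A", n2), ors[-(1:n1)])
    pall <- snpWeightPanel(ids, rep("A", n1 + n2), ors)
    expect_equal(computePrs(d, pall)$raw,
                 computePrs(d, pa)$raw + computePrs(d, pb)$raw)
  }
  p <- snpWeightPanel(c("u", "v"), c("A", "A"), c(1.3, 0.8))
  base <- computePrs(c(u = 1, v = 1), p)$raw
  expect_gt(computePrs(c(u = 1.5, v = 1), p)$raw, base)  # OR > 1: increases
  expect_lt(computePrs(c(u = 1, v = 1.5), p)$raw, base)  # OR < 1: decreases
})

test_that("centerScores mean-shifts all subjects by the reference mean", {
  sc <- data.frame(subject_id = c("a", "b", "c"), raw = c(5.2, 4.8, 6.0),
                   centered = NA_real_)
  out <- centerScores(sc, c("a", "b"))
  expect_equal(out$centered, c(0.2, -0.2, 1.0))
  expect_equal(attr(out, "centering"), 5.0)
  out1 <- centerScores(sc, "a")
  expect_equal(out1$centered[1], 0)
  expect_error(centerScores(sc, character()), "non-empty")
  expect_error(centerScores(sc, "zz"), "zz")
})

test_that("control-sister scores from the calibrated generator center to zero", {
  ds <- simulateFamilies(fastConfig(nFamilies = 400, seed = 5))
  sc <- computePrs(ds@genotypes, readWeightPanel(writeWeightPanel(
    new("SnpWeightPanel", weights = ds@truth$panel),
    file.path(tempdir(), "pan.tsv"))))
  sibs <- ds@pedigree$subject_id[ds@pedigree$role == "control_sister" &
                                   ds@pedigree$genotyped == 1]
  out <- centerScores(sc, sibs)
  ctr <- out$centered[out$subject_id %in% sibs]
  se <- sd(ctr) / sqrt(length(ctr))
  expect_lt(abs(mean(ctr)), 3 * se + 1e-12)
  expect_gt(mean(out$raw[out$subject_id %in% sibs]), 4.5)  # near calibrated 5.0
  expect_lt(mean(out$raw[out$subject_id %in% sibs]), 5.5)
})
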