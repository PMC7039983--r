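test_that("pseudo-sibling genotype is the untransmitted parental complement", {
  expect_equal(pseudoSibGenotype(1, 1, 1), 1)
  expect_equal(pseudoSibGenotype(2, 1, 1), 0)
  expect_error(pseudoSibGenotype(2, 0, 2), "Mendelian")
  # allele conservation and involution on vectors
  gc <- c(a = 1, b = 2, c = 0); gf <- c(a = 1, b = 1, c = 1); gm <- c(a = 0, b = 1, c = 0)
  gp <- pseudoSibGenotype(gc, gf, gm)
  expect_equal(gc + gp, gf + gm)
  expect_equal(pseudoSibGenotype(gp, gf, gm), gc)
})

test_that("fractional pseudo-sibling dosages pass through, flagged when out of range", {
  expect_warning(g <- pseudoSibGenotype(c(x = 1.8), c(x = 0.6), c(x = 0.7)),
                 "outside")
  expect_equal(as.numeric(g), -0.5)              # never clamped
  expect_equal(attr(g, "out_of_range"), "x")
})

test_that("mendelianCheck agrees with exhaustive transmission enumeration", {
  grid <- expand.grid(gc = 0:2, gf = 0:2, gm = 0:2)
  oracle <- mapply(trioConsistentOracle, grid$gc, grid$gf, grid$gm)
  got <- mapply(function(gc, gf, gm)
    mendelianCheck(gc, gf, gm)$status == "consistent", grid$gc, grid$gf, grid$gm)
  expect_equal(got, oracle)
  # fully heterozygous trio: clean report across markers
  r <- mendelianCheck(rep(1, 5), rep(1, 5), rep(1, 5))
  expect_true(all(r$status == "consistent"))
  # a single corrupt marker among consistent ones is pinpointed
  r2 <- mendelianCheck(c(1, 2, 1), c(1, 0, 1), c(1, 2, 1))
  expect_equal(r2$status, c("consistent", "inconsistent", "consistent"))
  # fractional dosages beyond the threshold are skipped, not judged
  r3 <- mendelianCheck(1.4, 1, 1, hardCallThreshold = 0.1)
  expect_equal(r3$status, "unchecked")
})

test_that("classifyFamily reproduces the four-design availability table", {
  expect_equal(classifyFamily(TRUE, TRUE, bothParentsGenotyped = TRUE,
                              siblingExposure = TRUE)$design, "case_parents_plus")
  expect_equal(classifyFamily(TRUE, TRUE, bothParentsGenotyped = TRUE)$design,
               "case_parents")
  expect_equal(classifyFamily(TRUE, TRUE, siblingGenotyped = TRUE,
                              siblingExposure = TRUE)$design, "case_sibling_plus")
  expect_equal(classifyFamily(TRUE, TRUE, siblingExposure = TRUE)$design,
               "case_plus")
  # sibling genotype takes precedence over parents
  expect_equal(classifyFamily(TRUE, TRUE, bothParentsGenotyped = TRUE,
                              siblingGenotyped = TRUE,
                              siblingExposure = TRUE)$design, "case_sibling_plus")
  # rejections carry reasons
  r <- classifyFamily(TRUE, TRUE)
  expect_true(is.na(r$design)); expect_match(r$reason, "no matched comparison")
  expect_match(classifyFamily(FALSE, TRUE, siblingExposure = TRUE)$reason, "case")
  expect_match(classifyFamily(TRUE, TRUE, singleParentGenotyped = TRUE)$reason,
               "single")
})

test_that("simulated Mendelian trios are clean and injected corruption is caught", {
  ds <- simulateFamilies(fastConfig(nFamilies = 60, seed = 9,
                                    designCounts = c(case_parents_plus = 60,
                                                     case_parents = 0,
                                                     case_sibling_plus = 0,
                                                     case_plus = 0)))
  g <- ds@genotypes
  ped <- ds@pedigree
  getg <- function(fid, role) {
    sid <- ped$subject_id[ped$family_id == fid & ped$role == role]
    unlist(g[g$subject_id == sid, -1])
  }
  fids <- unique(ped$family_id)
  for (fid in fids[1:10]) {
    r <- mendelianCheck(getg(fid, "case"), getg(fid, "father"), getg(fid, "mother"))
    expect_true(all(r$status == "consistent"))
  }
  # corrupt calls and compare the verdict with exhaustive enumeration
  gc <- getg(fids[1], "case"); gf <- getg(fids[1], "father"); gm <- getg(fids[1], "mother")
  gc <- 2 - gc  # flip every case call
  r <- mendelianCheck(gc, gf, gm)
  oracle <- mapply(trioConsistentOracle, gc, gf, gm)
  expect_equal(unname(r$status == "consistent"), unname(oracle))
})
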