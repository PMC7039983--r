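# Calibrated simulator of ascertained two-sister nuclear families.

#' Default SNP weight panel calibrated to the published PRS distribution
#'
#' Builds a panel of `nSnps` markers whose Hardy-Weinberg population PRS
#' (sum of `2 * freq * log(OR)` contributions) matches a target mean and
#' standard deviation — by default mean 5.0 and SD 0.45, the location and
#' scale of the published 77-SNP score.  Frequencies start on a fixed grid
#' and are shifted on the logit scale, and the log-OR weights scaled, until
#' both moments match; the construction is deterministic.
#'
#' @param nSnps number of markers (77 by default; 10 gives a fast panel for
#'   simulation-heavy testing with identical score moments).
#' @param targetMean,targetSd population PRS moments to calibrate to.
#' @return A [SnpWeightPanel-class] with `allele_freq` filled in.
#' @export
defaultPanel <- function(nSnps = 77L, targetMean = 5.0, targetSd = 0.45) {
  i <- seq_len(nSnps)
  p0 <- 0.15 + 0.7 * (i - 0.5) / nSnps          # base frequency grid
  u <- 0.8 + 0.4 * ((i * 7L) %% nSnps) / nSnps  # relative weight spread
  ratio <- function(t) {
    p <- stats::plogis(stats::qlogis(p0) + t)
    sum(2 * p * u) / sqrt(sum(2 * p * (1 - p) * u^2))
  }
  t <- stats::uniroot(function(t) ratio(t) - targetMean / targetSd,
                      lower = -8, upper = 8)$root
  p <- stats::plogis(stats::qlogis(p0) + t)
  c0 <- targetSd / sqrt(sum(2 * p * (1 - p) * u^2))
  snpWeightPanel(sprintf("snp%02d", i), rep(c("A", "G"), length.out = nSnps),
                 exp(c0 * u), alleleFreq = p)
}

#' Configure the family simulator
#'
#' Defaults reproduce the study conditions of the young-onset breast cancer
#' family analysis: 1152 non-Hispanic-white families split over the four
#' designs as (384, 32, 432, 304); a 77-SNP panel with population PRS mean
#' 5.0 and SD 0.45; disease risk driven by the PRS (log-OR `log(2.33)` per
#' unit), ever-use of hormonal birth control (log-OR `log(1.31)`) and their
#' interaction (log-ROR `log(0.56)`); diagnosis ages normal (45, 3.9)
#' truncated below 50; and sister-sister exposure correlation 0.3.
#'
#' @param nFamilies accepted families to generate.
#' @param panel A [SnpWeightPanel-class] carrying `allele_freq`.
#' @param baselineLogit intercept of the per-daughter disease logit, i.e.
#'   the log-odds of disease at mean PRS and reference exposure.
#' @param betaPrs log-OR per unit of (population-centered) PRS.
#' @param betaExposure named log-ORs; names are risk factors, applied to
#'   their numeric coding (binary 0/1, ordered trend score, continuous
#'   centered at its generating mean).
#' @param betaInteraction named log-RORs for PRS-by-factor products.
#' @param designCounts named counts (summing to `nFamilies`) or proportions
#'   (summing to 1) over the four designs (any other positive weights are
#'   rescaled to `nFamilies` by largest remainder).
#' @param exposureModel named list of overrides for the per-factor exposure
#'   parameters, merged into [defaultExposureModel()]: `mean`/`sd` pairs for
#'   continuous factors, a prevalence for binary ones (conditional on
#'   eligibility for the parity- and use-dependent factors), category
#'   probability vectors for `smoking`, `alcohol`, `parity` and `hbc_years`
#'   (the latter conditional on ever-use).
#' @param sisterRho shared-family latent correlation for exposures.
#' @param ageMean,ageSd diagnosis-age distribution, truncated to (25, 50).
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(nFamilies = 1152L,
                      panel = defaultPanel(),
                      baselineLogit = stats::qlogis(0.08),
                      betaPrs = log(2.33),
                      betaExposure = c(hbc_ever = log(1.31)),
                      betaInteraction = c(hbc_ever = log(0.56)),
                      designCounts = c(case_parents_plus = 384,
                                       case_parents = 32,
                                       case_sibling_plus = 432,
                                       case_plus = 304),
                      exposureModel = list(),
                      sisterRho = 0.3, ageMean = 45, ageSd = 3.9,
                      seed = 1L) {
  if (!isTRUE(all.equal(sum(designCounts), as.numeric(nFamilies))))
    designCounts <- largestRemainderCounts(designCounts / sum(designCounts),
                                           nFamilies)
  em <- utils::modifyList(defaultExposureModel(), exposureModel)
  new("SimConfig", nFamilies = as.integer(nFamilies), panel = panel,
      baselineLogit = baselineLogit, betaPrs = betaPrs,
      betaExposure = betaExposure, betaInteraction = betaInteraction,
      designCounts = designCounts, exposureModel = em, sisterRho = sisterRho,
      ageMean = ageMean, ageSd = ageSd, seed = as.integer(seed))
}

#' Default exposure-generation parameters
#'
#' Calibrated to the published control-sister marginals: normal parameters
#' for the continuous factors, prevalences for the binary ones (conditional
#' on eligibility where relevant) and category probabilities for the
#' categorical ones.
#'
#' @return named list of parameters (see [simConfig()]).
#' @export
defaultExposureModel <- function() {
  list(height = c(mean = 65.0, sd = 2.6),
       bmi30 = c(mean = 23.8, sd = 4.4),
       age_menarche = c(mean = 12.8, sd = 1.5),
       afb = c(mean = 26.7, sd = 5.2),
       premenopausal = 0.89,
       hbc_ever = 0.89,
       hbc_within5 = 0.273,          # among ever-users
       last_birth_within5 = 0.096,   # among parous
       breastfeeding = 0.829,        # among parous
       smoking = c(0.65, 0.26, 0.09),
       alcohol = c(0.08, 0.81, 0.11),
       hbc_years = c(0.130, 0.464, 0.406),  # among ever-users
       parity = c(0.248, 0.167, 0.354, 0.231))
}

largestRemainderCounts <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    up <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[up] <- base[up] + 1
  }
  base
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nFamilies, "families,",
      length(object@panel), "SNPs, seed", object@seed, "\n")
  cat("  designs:", paste(names(object@designCounts), object@designCounts,
                          sep = "=", collapse = ", "), "\n")
  cat("  betaPrs:", sprintf("%.3f", object@betaPrs),
      "| interactions:", if (length(object@betaInteraction))
        paste(names(object@betaInteraction),
              sprintf("%.3f", object@betaInteraction), sep = "=", collapse = ", ")
      else "none", "\n")
})

# generating means used to center continuous factors in the disease model
generatingMeans <- c(height = 65.0, age_menarche = 12.8, bmi30 = 23.8,
                     afb_cont = 26.7)

# numeric coding of a factor column for the disease linear predictor
diseaseCode <- function(profiles, name) {
  type <- factorType(name)
  v <- profiles[[name]]
  x <- switch(type,
              binary = as.numeric(v),
              continuous = as.numeric(v) - generatingMeans[[name]],
              ordered = as.numeric(trendScore(v, name)),
              nominal = as.numeric(trendScore(v, name) > 0))
  x[is.na(x)] <- 0
  x
}

# correlated standard-normal latents for two sisters
sisterLatents <- function(m, rho) {
  zf <- stats::rnorm(m)
  list(s1 = sqrt(rho) * zf + sqrt(1 - rho) * stats::rnorm(m),
       s2 = sqrt(rho) * zf + sqrt(1 - rho) * stats::rnorm(m))
}

cutLatent <- function(z, probs, labels) {
  labels[findInterval(stats::pnorm(z), cumsum(probs)[-length(probs)]) + 1L]
}

# index-age-aligned exposure profile for one sister from her latents
profileFromLatents <- function(z, indexAge, em) {
  pre <- as.integer(z$pre < stats::qnorm(em$premenopausal))
  ever <- as.integer(z$hbc < stats::qnorm(em$hbc_ever))
  yrs <- cutLatent(z$hbcyrs, em$hbc_years, factorLevels("hbc_years"))
  yrs[ever == 0] <- "<2"
  within5 <- as.integer(ever == 1 & z$hbc5 < stats::qnorm(em$hbc_within5))
  parity <- cutLatent(z$par, em$parity, factorLevels("parity"))
  parous <- parity != "0"
  afb <- pmin(pmax(em$afb[["mean"]] + em$afb[["sd"]] * z$afb, 15), indexAge - 0.5)
  afb[!parous] <- NA_real_
  afb_cat <- ifelse(!parous, "nulliparous",
                    ifelse(afb <= 20, "<=20",
                           ifelse(afb <= 25, "20-25",
                                  ifelse(afb <= 30, "25-30", ">30"))))
  data.frame(
    height = round(em$height[["mean"]] + em$height[["sd"]] * z$hei, 1),
    bmi30 = ifelse(pre == 1,
                   round(em$bmi30[["mean"]] + em$bmi30[["sd"]] * z$bmi, 1),
                   NA_real_),
    smoking = cutLatent(z$smo, em$smoking, factorLevels("smoking")),
    alcohol = cutLatent(z$alc, em$alcohol, factorLevels("alcohol")),
    premenopausal = pre,
    age_menarche = round(em$age_menarche[["mean"]] + em$age_menarche[["sd"]] * z$men, 1),
    hbc_ever = ever,
    hbc_years = yrs,
    hbc_within5 = within5,
    parity = parity,
    afb_cat = afb_cat,
    afb_cont = round(afb, 1),
    last_birth_within5 = ifelse(parous,
                                as.integer(z$lb5 < stats::qnorm(em$last_birth_within5)),
                                NA_integer_),
    breastfeeding = ifelse(parous,
                           as.integer(z$bf < stats::qnorm(em$breastfeeding)),
                           NA_integer_),
    index_age = indexAge,
    stringsAsFactors = FALSE)
}

genSisterProfiles <- function(m, rho, indexAge, em) {
  keys <- c("hei", "bmi", "smo", "alc", "pre", "men", "hbc", "hbcyrs",
            "hbc5", "par", "afb", "lb5", "bf")
  z1 <- list(); z2 <- list()
  for (k in keys) {
    l <- sisterLatents(m, rho)
    z1[[k]] <- l$s1; z2[[k]] <- l$s2
  }
  list(p1 = profileFromLatents(z1, indexAge, em),
       p2 = profileFromLatents(z2, indexAge, em))
}

transmitted <- function(G) (G == 2) + (G == 1) * matrix(
  stats::rbinom(length(G), 1L, 0.5), nrow(G), ncol(G))

#' Simulate ascertained two-sister families
#'
#' Draws nuclear families under the generative model of
#' [SimConfig-class]: parents under per-SNP Hardy-Weinberg equilibrium, two
#' daughters by independent Mendelian transmission, familially correlated
#' exposure profiles aligned to the case's diagnosis age, and disease from
#' the configured logistic model.  Families are retained by rejection
#' sampling when exactly one daughter is affected (before age 50, by
#' construction of the diagnosis-age model); accepted families are assigned
#' to the four designs in the configured counts and the corresponding data
#' availability is masked.
#'
#' @param config A [SimConfig-class].
#' @return A [SimulatedDataset-class]; identical seeds give identical
#'   datasets.
#' @examples
#' ds <- simulateFamilies(simConfig(nFamilies = 40, panel = defaultPanel(10),
#'                                  seed = 7))
#' table(ds@pedigree$role)
#' @export
simulateFamilies <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nFamilies
  w <- logOddsWeights(config@panel)
  af <- alleleFrequencies(config@panel)
  ns <- length(w)
  muPop <- sum(2 * af * w)

  acc <- list()
  got <- 0L; totalCand <- 0L; pAcc <- 0.2
  while (got < n) {
    m <- min(max(1000L, ceiling((n - got) / pAcc * 1.25)), 200000L)
    Gf <- matrix(stats::rbinom(m * ns, 2L, rep(af, each = m)), m, ns,
                 dimnames = list(NULL, names(w)))
    Gm <- matrix(stats::rbinom(m * ns, 2L, rep(af, each = m)), m, ns,
                 dimnames = list(NULL, names(w)))
    G1 <- transmitted(Gf) + transmitted(Gm)
    G2 <- transmitted(Gf) + transmitted(Gm)
    prs1 <- as.numeric(G1 %*% w) - muPop
    prs2 <- as.numeric(G2 %*% w) - muPop
    indexAge <- round(rtruncnorm(m, config@ageMean, config@ageSd, 25, 50), 1)
    pr <- genSisterProfiles(m, config@sisterRho, indexAge, config@exposureModel)

    eta <- function(prs, prof) {
      e <- config@baselineLogit + config@betaPrs * prs
      for (f in names(config@betaExposure))
        e <- e + config@betaExposure[[f]] * diseaseCode(prof, f)
      for (f in names(config@betaInteraction))
        e <- e + config@betaInteraction[[f]] * prs * diseaseCode(prof, f)
      e
    }
    a1 <- stats::rbinom(m, 1L, stats::plogis(eta(prs1, pr$p1)))
    a2 <- stats::rbinom(m, 1L, stats::plogis(eta(prs2, pr$p2)))
    keep <- which(a1 + a2 == 1L)
    totalCand <- totalCand + m
    if (length(keep)) {
      keep <- keep[seq_len(min(length(keep), n - got))]
      acc[[length(acc) + 1L]] <- list(
        Gf = Gf[keep, , drop = FALSE], Gm = Gm[keep, , drop = FALSE],
        G1 = G1[keep, , drop = FALSE], G2 = G2[keep, , drop = FALSE],
        p1 = pr$p1[keep, , drop = FALSE], p2 = pr$p2[keep, , drop = FALSE],
        caseIs1 = a1[keep] == 1L, indexAge = indexAge[keep])
      got <- got + length(keep)
    }
    pAcc <- max(got / totalCand, 0.01)
    if (totalCand >= 2e5 && got / totalCand < 1e-4)
      stopf(paste("family acceptance rate below 1e-4; raise baselineLogit or",
                  "weaken effects so that discordant sister pairs occur"))
  }
  accRate <- got / totalCand

  bind <- function(fld) do.call(rbind, lapply(acc, `[[`, fld))
  Gf <- bind("Gf"); Gm <- bind("Gm"); G1 <- bind("G1"); G2 <- bind("G2")
  p1 <- bind("p1"); p2 <- bind("p2")
  caseIs1 <- unlist(lapply(acc, `[[`, "caseIs1"))
  indexAge <- unlist(lapply(acc, `[[`, "indexAge"))

  # orient: Gc/profC for the affected daughter, Gs/profS for the unaffected
  pick <- function(A, B, takeA) { A[!takeA, ] <- B[!takeA, ]; A }
  Gc <- pick(G1, G2, caseIs1); Gs <- pick(G2, G1, caseIs1)
  pc <- pick(p1, p2, caseIs1); ps <- pick(p2, p1, caseIs1)
  caseElder <- stats::rbinom(n, 1L, 0.5)

  design <- rep(names(config@designCounts), config@designCounts)
  fid <- sprintf("F%05d", seq_len(n))
  caseGeno <- rep(TRUE, n)
  parentGeno <- design %in% c("case_parents_plus", "case_parents")
  sibGeno <- design == "case_sibling_plus"
  sibExpo <- design != "case_parents"

  id <- function(suffix) paste0(fid, "_", suffix)
  pedigree <- rbind(
    data.frame(family_id = fid, subject_id = id("C"), role = "case",
               birth_order_rank = ifelse(caseElder == 1L, 1L, 2L),
               genotyped = 1L, exposure = 1L,
               invasive = stats::rbinom(n, 1L, 0.85),
               er_pos = stats::rbinom(n, 1L, 0.81),
               index_age = indexAge, stringsAsFactors = FALSE),
    data.frame(family_id = fid, subject_id = id("S"), role = "control_sister",
               birth_order_rank = ifelse(caseElder == 1L, 2L, 1L),
               genotyped = as.integer(sibGeno), exposure = as.integer(sibExpo),
               invasive = NA_integer_, er_pos = NA_integer_,
               index_age = NA_real_, stringsAsFactors = FALSE),
    data.frame(family_id = fid, subject_id = id("F"), role = "father",
               birth_order_rank = NA_integer_,
               genotyped = as.integer(parentGeno), exposure = 0L,
               invasive = NA_integer_, er_pos = NA_integer_,
               index_age = NA_real_, stringsAsFactors = FALSE),
    data.frame(family_id = fid, subject_id = id("M"), role = "mother",
               birth_order_rank = NA_integer_,
               genotyped = as.integer(parentGeno), exposure = 0L,
               invasive = NA_integer_, er_pos = NA_integer_,
               index_age = NA_real_, stringsAsFactors = FALSE))
  pedigree <- pedigree[order(pedigree$family_id, pedigree$subject_id), ]
  rownames(pedigree) <- NULL

  gmat <- function(ids, G) data.frame(subject_id = ids, G, check.names = FALSE,
                                      stringsAsFactors = FALSE)
  genotypes <- rbind(gmat(id("C"), Gc),
                     gmat(id("S")[sibGeno], Gs[sibGeno, , drop = FALSE]),
                     gmat(id("F")[parentGeno], Gf[parentGeno, , drop = FALSE]),
                     gmat(id("M")[parentGeno], Gm[parentGeno, , drop = FALSE]))
  rownames(genotypes) <- NULL

  exposures <- rbind(
    data.frame(subject_id = id("C"), pc, stringsAsFactors = FALSE),
    data.frame(subject_id = id("S")[sibExpo], ps[sibExpo, , drop = FALSE],
               stringsAsFactors = FALSE))
  rownames(exposures) <- NULL

  truth <- list(betaPrs = config@betaPrs,
                betaExposure = as.list(config@betaExposure),
                betaInteraction = as.list(config@betaInteraction),
                baselineLogit = config@baselineLogit,
                prsPopulationMean = muPop,
                designCounts = as.list(config@designCounts),
                exposureModel = config@exposureModel,
                sisterRho = config@sisterRho,
                ageMean = config@ageMean, ageSd = config@ageSd,
                seed = config@seed, acceptanceRate = accRate,
                panel = config@panel@weights)
  new("SimulatedDataset", pedigree = pedigree, genotypes = genotypes,
      exposures = exposures, truth = truth)
}

setMethod("show", "SimulatedDataset", function(object) {
  nfam <- length(unique(object@pedigree$family_id))
  cat("SimulatedDataset:", nfam, "families,",
      nrow(object@genotypes), "genotyped subjects,",
      nrow(object@exposures), "exposure profiles\n")
  cat("  acceptance rate:", sprintf("%.3f", object@truth$acceptanceRate), "\n")
})

#' Compare simulated marginals with the published participant table
#'
#' Summarises a simulated dataset case-versus-control (PRS and risk-factor
#' means/SDs and category proportions) side by side with the published
#' reference marginals that the generator is calibrated to, for visual and
#' tolerance-based checking.
#'
#' @param ds A [SimulatedDataset-class] (ideally >= 500 families).
#' @return data.frame: `variable`, `level`, `case`, `control`,
#'   `case_ref`, `control_ref` (reference `NA` where the published table has
#'   no entry).
#' @export
compareMarginals <- function(ds) {
  s <- summarizeDataset(ds)
  ref <- marginalReference()
  out <- merge(s, ref, by = c("variable", "level"), all.x = TRUE, sort = FALSE)
  out[order(match(out$variable, unique(s$variable))), ]
}

# published case/control reference marginals used for generator calibration
marginalReference <- function() {
  rbind(
    data.frame(variable = "prs", level = c("mean", "sd"),
               case_ref = c(5.13, 0.44), control_ref = c(5.01, 0.46)),
    data.frame(variable = "height", level = c("mean", "sd"),
               case_ref = c(65.1, 2.5), control_ref = c(65.0, 2.6)),
    data.frame(variable = "age_menarche", level = c("mean", "sd"),
               case_ref = c(12.7, 1.5), control_ref = c(12.8, 1.5)),
    data.frame(variable = "bmi30", level = c("mean", "sd"),
               case_ref = c(23.5, 3.9), control_ref = c(23.8, 4.4)),
    data.frame(variable = "afb_cont", level = c("mean", "sd"),
               case_ref = c(27.6, 5.3), control_ref = c(26.7, 5.2)),
    data.frame(variable = "premenopausal", level = "1",
               case_ref = 0.93, control_ref = 0.89),
    data.frame(variable = "hbc_ever", level = "1",
               case_ref = 0.91, control_ref = 0.89),
    data.frame(variable = "hbc_within5", level = "1",
               case_ref = 0.29, control_ref = 0.27),
    data.frame(variable = "smoking", level = factorLevels("smoking"),
               case_ref = c(0.65, 0.28, 0.07), control_ref = c(0.65, 0.26, 0.09)),
    data.frame(variable = "alcohol", level = factorLevels("alcohol"),
               case_ref = c(0.11, 0.78, 0.11), control_ref = c(0.08, 0.81, 0.11)),
    data.frame(variable = "hbc_years", level = factorLevels("hbc_years"),
               case_ref = c(0.23, 0.36, 0.41), control_ref = c(0.22, 0.41, 0.36)),
    data.frame(variable = "parity", level = factorLevels("parity"),
               case_ref = c(0.25, 0.18, 0.36, 0.21),
               control_ref = c(0.25, 0.17, 0.35, 0.23)),
    data.frame(variable = "afb_cat", level = factorLevels("afb_cat"),
               case_ref = c(0.25, 0.08, 0.21, 0.26, 0.21),
               control_ref = c(0.25, 0.09, 0.23, 0.27, 0.16)),
    data.frame(variable = "last_birth_within5", level = "1",
               case_ref = 0.11, control_ref = 0.09),
    data.frame(variable = "breastfeeding", level = "1",
               case_ref = 0.84, control_ref = 0.83))
}
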