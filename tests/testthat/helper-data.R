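# shared fixtures, all generated in code

tinyPanel <- function() {
  snpWeightPanel(c("rs1", "rs2", "rs3"), c("A", "A", "A"), c(1.1, 1.2, 0.9))
}

# random matched-set design lists (and a long data.frame for clogit)
randomSetsDesign <- function(nSets, p = 2, seed = 1) {
  set.seed(seed)
  sizes <- sample(c(2L, 4L), nSets, replace = TRUE)
  setId <- rep(seq_len(nSets), sizes)
  n <- length(setId)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  isCase <- !duplicated(setId)
  # put mild signal in so the case is not always the first draw
  lp <- X %*% rep(0.5, p)
  for (s in seq_len(nSets)) {
    i <- which(setId == s)
    pr <- exp(lp[i]); pr <- pr / sum(pr)
    isCase[i] <- seq_along(i) == sample(seq_along(i), 1, prob = pr)
  }
  list(X = X, setId = setId, isCase = isCase,
       df = data.frame(y = as.integer(isCase), X, set = setId))
}

# consistent fractional trio dosages (clearly non-hard-call)
randomFractionalTrio <- function(nSnps, seed = 1) {
  set.seed(seed)
  repeat {
    gf <- round(stats::runif(nSnps, 0.25, 1.75), 2)
    gm <- round(stats::runif(nSnps, 0.25, 1.75), 2)
    lo <- pmax(0, gf + gm - 2); hi <- pmin(2, gf + gm)
    gc <- round(lo + stats::runif(nSnps) * (hi - lo), 2)
    frac <- function(g) all(abs(g - round(g)) > 0.1)
    if (frac(gf) && frac(gm) && frac(gc) && frac(gf + gm - gc)) break
  }
  names(gf) <- names(gm) <- names(gc) <- sprintf("s%02d", seq_len(nSnps))
  list(gc = gc, gf = gf, gm = gm)
}

# brute-force Mendelian oracle: enumerate the four possible transmissions
trioConsistentOracle <- function(gc, gf, gm) {
  tr <- function(g) switch(as.character(g), "0" = 0L, "1" = 0:1, "2" = 1L)
  any(outer(tr(gf), tr(gm), "+") == gc)
}

fastConfig <- function(...) {
  simConfig(panel = defaultPanel(10), ...)
}

# one simulate + single-model fit cycle, returning the ClrFit
simFitHbc <- function(nFamilies, seed, betaInteraction = c(hbc_ever = log(0.56))) {
  ds <- simulateFamilies(fastConfig(nFamilies = nFamilies, seed = seed,
                                    betaInteraction = betaInteraction))
  rep <- runAnalysis(ds, specs = defaultModelSpecs()["hbc_ever"])
  rep@fits[[1]]
}
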