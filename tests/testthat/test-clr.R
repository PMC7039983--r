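test_that("conditional log-likelihood matches closed forms", {
  # one set of four members at beta = 0: log(1/4)
  X <- matrix(rnorm(4), 4, 1)
  expect_equal(conditionalLoglik(0, X, rep(1, 4), c(TRUE, FALSE, FALSE, FALSE)),
               -log(4))
  # a 1:1 pair with x = (1, 0): beta - log(1 + exp(beta))
  Xp <- matrix(c(1, 0), 2, 1)
  for (b in c(-1.3, 0, 0.7))
    expect_equal(conditionalLoglik(b, Xp, c(1, 1), c(TRUE, FALSE)),
                 b - log(1 + exp(b)))
  # additivity over strata: duplicating every set doubles the value
  d <- randomSetsDesign(6, p = 2, seed = 2)
  ll <- conditionalLoglik(c(0.3, -0.2), d$X, d$setId, d$isCase)
  ll2 <- conditionalLoglik(c(0.3, -0.2), rbind(d$X, d$X),
                           c(d$setId, d$setId + 100), rep(d$isCase, 2))
  expect_equal(ll2, 2 * ll)
})

test_that("fitCLR matches a fine grid search on a one-parameter problem", {
  d <- randomSetsDesign(25, p = 1, seed = 3)
  fit <- fitCLR(d)
  grid <- seq(-3, 3, by = 1e-4)
  lg <- vapply(grid, function(b) conditionalLoglik(b, d$X, d$setId, d$isCase), 0)
  expect_equal(unname(coef(fit)), grid[which.max(lg)], tolerance = 1e-3)
  expect_true(converged(fit))
  expect_gte(fit@loglik + 1e-9, max(lg))
})

test_that("estimates are invariant to per-set constant covariate shifts", {
  d <- randomSetsDesign(20, p = 2, seed = 4)
  fit1 <- fitCLR(d)
  offs <- rnorm(max(d$setId))
  Xs <- d$X
  Xs[, 1] <- Xs[, 1] + offs[d$setId]
  Xs[, 2] <- Xs[, 2] - 2 * offs[d$setId]
  fit2 <- fitCLR(list(X = Xs, setId = d$setId, isCase = d$isCase))
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-7)
  expect_equal(fit1@loglik, fit2@loglik, tolerance = 1e-9)
})

test_that("within-set constant directions are reported unidentifiable", {
  d <- randomSetsDesign(15, p = 2, seed = 5)
  Xc <- cbind(d$X, setconst = (d$setId %% 3))   # constant within each set
  colnames(Xc) <- c("x1", "x2", "setconst")
  fit <- fitCLR(list(X = Xc, setId = d$setId, isCase = d$isCase))
  expect_equal(unidentifiableTerms(fit), "setconst")
  expect_false("setconst" %in% names(coef(fit)))
  # and its score component is exactly zero: likelihood does not move
  expect_equal(conditionalLoglik(c(0.2, 0.1, 5), Xc, d$setId, d$isCase),
               conditionalLoglik(c(0.2, 0.1, -5), Xc, d$setId, d$isCase))
})

test_that("separation is detected on a perfectly discriminating covariate", {
  X <- matrix(rep(c(1, 0), 12), ncol = 1)
  fit <- suppressWarnings(fitCLR(list(X = X, setId = rep(1:12, each = 2),
                                      isCase = rep(c(TRUE, FALSE), 12))))
  expect_true(fit@separation)
})

test_that("design matrix follows the coding rules of the model battery", {
  ds <- simulateFamilies(fastConfig(nFamilies = 150, seed = 6))
  sets <- buildMatchedSets(ds)$sets
  # binary target with interaction: indicator, PRS, product, birth order
  dm <- buildDesignMatrix(sets, modelSpec("hbc_ever"))
  expect_equal(dm$terms, c("hbc_ever", "prs", "prs:hbc_ever", "birth_order_elder"))
  # ordered 3-level target: 2 saturated indicators + 1 trend product
  dm2 <- buildDesignMatrix(sets, modelSpec("hbc_years", confounders = "age_menarche"))
  expect_equal(dm2$targetTerms, c("hbc_years:2-<10", "hbc_years:>=10"))
  expect_equal(dm2$interactionTerms, "prs:hbc_years")
  expect_true("age_menarche" %in% dm2$terms)
  sc <- dm2$X[, "prs:hbc_years"] / dm2$X[, "prs"]
  expect_true(all(sc[is.finite(sc)] %in% 0:2))   # integer trend scores
  # smoking is nominal: 2 indicators + 2 product columns
  dm3 <- buildDesignMatrix(sets, modelSpec("smoking", confounders = "alcohol"))
  expect_equal(dm3$targetTerms, c("smoking:former", "smoking:current"))
  expect_equal(dm3$interactionTerms, c("prs:smoking:former", "prs:smoking:current"))
  # risk-factor-only model: trend main effect, no PRS column
  dm4 <- buildDesignMatrix(sets, modelSpec("hbc_years", interaction = FALSE))
  expect_equal(dm4$terms, c("hbc_years", "birth_order_elder"))
  # unknown category labels are rejected
  m <- setMembers(sets); m$hbc_years[1] <- "sometimes"
  expect_error(buildDesignMatrix(new("MatchedSets", members = m, centering = 0),
                                 modelSpec("hbc_years")), "sometimes")
})

test_that("sets with missing covariates are dropped whole, per model", {
  ds <- simulateFamilies(fastConfig(nFamilies = 120, seed = 8))
  sets <- buildMatchedSets(ds)$sets
  m <- setMembers(sets)
  # bmi30 is missing for postmenopausal subjects by construction
  dm <- buildDesignMatrix(sets, modelSpec("bmi30"))
  expect_equal(length(unique(dm$setId)) + dm$nDropped, nSets(sets))
  expect_false(anyNA(dm$X))
})

test_that("composeExposedOR multiplies and rounds like the report", {
  expect_equal(composeExposedOR(3.89, 0.56), 2.18)
  expect_equal(composeExposedOR(1.23, 2.00), 2.46)
  expect_equal(composeExposedOR(1.7, 1.0), 1.7)
  expect_equal(composeExposedOR(3.89, 0.56, digits = NA), 3.89 * 0.56)
  expect_error(composeExposedOR(-1, 0.5), "positive")
  expect_error(composeExposedOR(1.2, 0), "positive")
})

test_that("Wald interaction test is a two-sided normal test", {
  d <- randomSetsDesign(40, p = 2, seed = 11)
  colnames(d$X) <- c("prs", "prs:hbc_ever")
  fit <- fitCLR(d)
  b <- coef(fit)[["prs:hbc_ever"]]
  se <- sqrt(vcov(fit)["prs:hbc_ever", "prs:hbc_ever"])
  expect_equal(waldInteractionTest(fit), 2 * pnorm(-abs(b / se)))
  expect_equal(waldInteractionTest(fit, "prs"),
               orTable(fit)$p_value[orTable(fit)$term == "prs"])
  expect_error(waldInteractionTest(fit, "nope"), "not present")
})
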