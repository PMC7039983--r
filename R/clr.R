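#' Specify a conditional-logistic model
#'
#' @param target risk-factor name (see [exposureFactors()]).
#' @param interaction logical; include PRS main effect and PRS-by-factor
#'   product terms.
#' @param confounders character vector of risk-factor names to adjust for
#'   (trend/continuous coding); the elder-sister birth-order indicator is
#'   always included and need not be listed.
#' @param subset `"all"` (default), `"parous"` or `"premenopausal"`.
#' @param label display label (defaults to the dictionary label).
#' @return A [ModelSpec-class].
#' @export
modelSpec <- function(target, interaction = TRUE, confounders = character(),
                      subset = "all", label = NULL) {
  d <- exposureFactors()
  if (!target %in% d$name) stopf("unknown risk factor '%s'", target)
  bad <- setdiff(confounders, d$name)
  if (length(bad)) stopf("unknown confounder(s): %s", paste(bad, collapse = ", "))
  if (is.null(label)) label <- d$label[match(target, d$name)]
  new("ModelSpec", target = target, interaction = isTRUE(interaction),
      confounders = confounders, subset = subset, label = label)
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@label, "\n")
  cat("  target:", object@target, paste0("(", factorType(object@target), ")"),
      if (object@interaction) "with PRS interaction" else "main effect only", "\n")
  if (length(object@confounders))
    cat("  confounders:", paste(object@confounders, collapse = ", "), "\n")
  if (object@subset != "all") cat("  subset:", object@subset, "\n")
})

#' The standard battery of 14 risk-factor models
#'
#' One model per analysed risk factor, with the standard confounder sets:
#' parity and (categorical) age at first birth in the breastfeeding model,
#' smoking and alcohol mutually adjusted, age at menarche in the
#' years-of-hormonal-birth-control model, age at first birth in the parity
#' model; every model additionally adjusts for birth order.
#'
#' @param interaction logical, build interaction models (default) or
#'   risk-factor-only models.
#' @return named list of [ModelSpec-class] objects.
#' @export
defaultModelSpecs <- function(interaction = TRUE) {
  conf <- list(hbc_ever = character(), hbc_within5 = character(),
               last_birth_within5 = character(),
               breastfeeding = c("parity", "afb_cat"),
               premenopausal = character(), height = character(),
               bmi30 = character(), age_menarche = character(),
               afb_cont = character(),
               smoking = "alcohol", alcohol = "smoking",
               hbc_years = "age_menarche", parity = "afb_cat",
               afb_cat = character())
  specs <- lapply(names(conf), function(t)
    modelSpec(t, interaction = interaction, confounders = conf[[t]]))
  names(specs) <- names(conf)
  specs
}

# one covariate block (main-effect coding) for a factor
codeCovariate <- function(values, name, saturated = FALSE) {
  type <- factorType(name)
  if (type %in% c("continuous", "binary")) {
    X <- matrix(as.numeric(values), ncol = 1, dimnames = list(NULL, name))
    return(X)
  }
  lev <- factorLevels(name)
  score <- trendScore(values, name)
  if (!saturated && type == "ordered") {
    return(matrix(as.numeric(score), ncol = 1, dimnames = list(NULL, name)))
  }
  # saturated: indicators for non-reference levels (nominal always saturated)
  X <- vapply(seq_along(lev)[-1], function(i) as.numeric(score == i - 1L),
              numeric(length(score)))
  colnames(X) <- paste0(name, ":", lev[-1])
  X[is.na(score), ] <- NA_real_
  X
}

#' Build the design matrix for a model over matched sets
#'
#' Applies the coding rules: in interaction models the risk-factor main
#' effect is saturated (indicators per non-reference level) and the
#' interaction column is centered PRS times an integer trend score over the
#' ordered levels — except smoking, which gets one product column per
#' non-reference level; continuous and binary targets get a single product
#' column.  The PRS main-effect column is always included in interaction
#' models.  Risk-factor-only models code ordered factors as a linear trend
#' (smoking saturated) and carry no PRS column.  Confounders enter as
#' trend/continuous covariates and every model includes the elder-sister
#' birth-order indicator.  `height` is centered by the mean height of the
#' control sisters before any product is formed.
#'
#' Sets with a missing value in any required column are dropped whole
#' (complete-case per model) and counted.
#'
#' @param sets A [MatchedSets-class].
#' @param spec A [ModelSpec-class].
#' @return list with `X` (numeric matrix), `setId`, `isCase`, `terms`,
#'   `interactionTerms`, `targetTerms`, `nDropped`.
#' @export
buildDesignMatrix <- function(sets, spec) {
  m <- setMembers(sets)
  if (!nrow(m)) stopf("no matched sets supplied")
  if (spec@subset == "parous")
    m <- m[m$set_id %in% m$set_id[m$is_case & m$parity != "0"], , drop = FALSE]
  if (spec@subset == "premenopausal")
    m <- m[m$set_id %in% m$set_id[m$is_case & m$premenopausal == 1], , drop = FALSE]

  target <- spec@target
  vals <- m[[target]]
  if (target == "height") {
    sib <- m$exposure_source == "sibling" & !duplicated(paste(m$family_id, m$exposure_source))
    ctrlMean <- mean(m$height[sib], na.rm = TRUE)
    if (!is.finite(ctrlMean)) ctrlMean <- 0
    vals <- vals - ctrlMean
  }

  Xmain <- codeCovariate(vals, target, saturated = spec@interaction)
  blocks <- list(Xmain)
  targetTerms <- colnames(Xmain)
  interactionTerms <- character()

  if (spec@interaction) {
    prs <- m$prs
    type <- factorType(target)
    if (type == "nominal") {
      P <- Xmain * prs
      colnames(P) <- paste0("prs:", colnames(Xmain))
    } else {
      tv <- if (type %in% c("continuous", "binary")) as.numeric(vals)
            else as.numeric(trendScore(vals, target))
      P <- matrix(prs * tv, ncol = 1, dimnames = list(NULL, paste0("prs:", target)))
    }
    interactionTerms <- colnames(P)
    blocks <- c(blocks, list(matrix(prs, ncol = 1, dimnames = list(NULL, "prs")), P))
  }

  for (cf in spec@confounders)
    blocks <- c(blocks, list(codeCovariate(m[[cf]], cf, saturated = factorType(cf) == "nominal")))
  blocks <- c(blocks, list(matrix(as.numeric(m$birth_order_elder), ncol = 1,
                                  dimnames = list(NULL, "birth_order_elder"))))

  X <- do.call(cbind, blocks)
  keepSet <- !(m$set_id %in% unique(m$set_id[rowSums(is.na(X)) > 0]))
  nDropped <- length(unique(m$set_id)) - length(unique(m$set_id[keepSet]))
  X <- X[keepSet, , drop = FALSE]
  list(X = X, setId = m$set_id[keepSet], isCase = m$is_case[keepSet],
       terms = colnames(X), interactionTerms = interactionTerms,
       targetTerms = targetTerms, nDropped = nDropped)
}

#' Conditional log-likelihood of matched-set logistic regression
#'
#' \deqn{\ell(\beta) = \sum_s \left[ x_{case,s}\beta -
#'   \log \sum_{j \in s} e^{x_j \beta} \right]}
#' Invariant to adding any constant vector to all rows of one set.
#'
#' @param beta coefficient vector.
#' @param X numeric matrix of member covariate rows.
#' @param setId stratum identifier per row.
#' @param isCase logical per row; exactly one case per stratum.
#' @return numeric(1).
#' @export
conditionalLoglik <- function(beta, X, setId, isCase) {
  eta <- as.numeric(X %*% beta)
  g <- as.integer(factor(setId, levels = unique(setId)))
  mx <- as.numeric(tapply(eta, g, max))
  lse <- log(as.numeric(rowsum(exp(eta - mx[g]), g))) + mx
  sum(eta[isCase]) - sum(lse)
}

# likelihood, score and observed information in one pass
clrDerivatives <- function(beta, X, g, isCase) {
  eta <- as.numeric(X %*% beta)
  mx <- as.numeric(tapply(eta, g, max))
  w <- exp(eta - mx[g])
  S <- as.numeric(rowsum(w, g))
  p <- w / S[g]
  ll <- sum(eta[isCase]) - sum(log(S) + mx)
  score <- as.numeric(crossprod(X, isCase - p))
  M <- rowsum(p * X, g)                  # per-set mean covariate under p
  info <- crossprod(X, p * X) - crossprod(M)
  list(ll = ll, score = score, info = info)
}

#' Fit conditional logistic regression over matched sets
#'
#' Maximises the exact conditional likelihood by Newton-Raphson with
#' step-halving, using analytic score and observed information.  Standard
#' errors come from the inverse observed information at the optimum; 95%
#' intervals are \eqn{\exp(\hat\beta \pm 1.96\,SE)}.
#'
#' Covariate directions with no within-set variation anywhere in the data
#' (and directions collinear within sets) carry no information in a
#' conditional likelihood; they are excluded from estimation and reported in
#' the `unidentifiable` slot.  Monotone likelihoods (separation) are flagged
#' when a coefficient escapes beyond 10 in absolute value on the log-odds
#' scale.
#'
#' @param x A [MatchedSets-class], or a prebuilt design list from
#'   [buildDesignMatrix()].
#' @param spec A [ModelSpec-class]; required when `x` is a `MatchedSets`.
#' @param tol gradient-norm convergence tolerance (default 1e-8).
#' @param maxIter maximum Newton iterations (default 100).
#' @return A [ClrFit-class].
#' @export
fitCLR <- function(x, spec = NULL, tol = 1e-8, maxIter = 100L) {
  if (is(x, "MatchedSets")) {
    if (is.null(spec)) stopf("spec is required when fitting from MatchedSets")
    x <- buildDesignMatrix(x, spec)
  }
  X <- x$X; setId <- x$setId; isCase <- x$isCase
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) == 0L) stopf("no informative matched sets to fit")
  g <- as.integer(factor(setId, levels = unique(setId)))

  # identifiability: within-set centered design must have column variation
  Xc <- centerWithin(X, g)
  novar <- apply(abs(Xc), 2, max) < 1e-12
  unident <- colnames(X)[novar]
  keep <- which(!novar)
  if (length(keep) > 1L) {
    qrd <- qr(Xc[, keep, drop = FALSE])
    if (qrd$rank < length(keep)) {
      drop2 <- keep[qrd$pivot[(qrd$rank + 1L):length(keep)]]
      unident <- c(unident, colnames(X)[drop2])
      keep <- setdiff(keep, drop2)
    }
  }
  if (!length(keep))
    stopf("no identifiable covariate direction: every column is constant within sets")
  Xf <- X[, keep, drop = FALSE]

  beta <- rep(0, ncol(Xf))
  d <- clrDerivatives(beta, Xf, g, isCase)
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    if (max(abs(d$score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(d$info, d$score), error = function(e) NULL)
    if (is.null(step))
      step <- solve(d$info + diag(1e-8, ncol(Xf)), d$score)
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      dc <- clrDerivatives(cand, Xf, g, isCase)
      if (dc$ll >= d$ll - 1e-12 || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    beta <- cand
    d <- dc
  }
  if (!converged && max(abs(d$score)) < tol) converged <- TRUE
  # a log odds ratio beyond 10 signals a monotone likelihood direction: the
  # gradient either still points outward or has underflowed to zero there
  separation <- any(abs(beta) > 10)

  vc <- tryCatch(solve(d$info), error = function(e) matrix(NA_real_, ncol(Xf), ncol(Xf)))
  dimnames(vc) <- list(colnames(Xf), colnames(Xf))
  se <- sqrt(pmax(diag(vc), 0))
  names(beta) <- colnames(Xf)
  z <- beta / se
  ot <- data.frame(term = colnames(Xf), estimate = beta, se = se,
                   or = exp(beta),
                   ci_lower = exp(beta - 1.96 * se),
                   ci_upper = exp(beta + 1.96 * se),
                   p_value = 2 * stats::pnorm(-abs(z)),
                   row.names = NULL, stringsAsFactors = FALSE)
  new("ClrFit", coefficients = beta, vcov = vc, orTable = ot,
      loglik = d$ll, converged = converged, iterations = iter,
      separation = separation, unidentifiable = unname(unident),
      nSets = length(unique(g)),
      nDropped = if (is.null(x$nDropped)) 0L else as.integer(x$nDropped))
}

#' @describeIn fitCLR Coefficients of a fitted model.
#' @param object A [ClrFit-class].
#' @export
setMethod("coef", "ClrFit", function(object) object@coefficients)

#' @describeIn fitCLR Covariance matrix of the coefficients.
#' @export
setMethod("vcov", "ClrFit", function(object) object@vcov)

#' @describeIn fitCLR Odds-ratio table with 95% Wald intervals.
#' @param fit A [ClrFit-class].
#' @export
orTable <- function(fit) fit@orTable

#' @describeIn fitCLR Convergence flag.
#' @export
converged <- function(fit) fit@converged

#' @describeIn fitCLR Covariates excluded as unidentifiable.
#' @export
unidentifiableTerms <- function(fit) fit@unidentifiable

setMethod("show", "ClrFit", function(object) {
  cat("ClrFit over", object@nSets, "matched sets",
      if (object@nDropped) sprintf("(%d dropped for missing covariates)", object@nDropped),
      "\n")
  cat("  log-likelihood:", sprintf("%.4f", object@loglik),
      "| converged:", object@converged,
      "| iterations:", object@iterations, "\n")
  if (object@separation) cat("  WARNING: monotone likelihood (separation) detected\n")
  if (length(object@unidentifiable))
    cat("  unidentifiable:", paste(object@unidentifiable, collapse = ", "), "\n")
  ot <- object@orTable
  ot[-1] <- lapply(ot[-1], function(v) round(v, 3))
  print(ot, row.names = FALSE)
})

#' Compose the exposed-group PRS odds ratio
#'
#' The interaction ratio-of-odds-ratios (ROR) is the PRS odds ratio in the
#' exposed category divided by that in the unexposed category, so the
#' exposed-group PRS OR is their product.
#'
#' @param orUnexposed PRS odds ratio in the unexposed (reference) group.
#' @param ror interaction ratio of odds ratios.
#' @param digits decimals for reporting (default 2); `NA` for no rounding.
#' @return positive numeric(1).
#' @examples
#' composeExposedOR(3.89, 0.56)  # 2.18
#' @export
composeExposedOR <- function(orUnexposed, ror, digits = 2) {
  if (!is.finite(orUnexposed) || orUnexposed <= 0 || !is.finite(ror) || ror <= 0)
    stopf("odds ratios must be positive")
  out <- orUnexposed * ror
  if (!is.na(digits)) out <- round(out, digits)
  out
}

#' Wald test for an interaction term
#'
#' Two-sided normal p-value from \eqn{\hat\beta / SE} for the PRS-by-factor
#' product term of a fitted model.
#'
#' @param fit A [ClrFit-class].
#' @param term coefficient name; defaults to the single `prs:` product term
#'   when unambiguous.
#' @return numeric(1) p-value.
#' @export
waldInteractionTest <- function(fit, term = NULL) {
  if (is.null(term)) {
    term <- grep("^prs:", names(coef(fit)), value = TRUE)
    if (length(term) != 1L)
      stopf("interaction term is ambiguous; specify one of: %s",
            paste(grep("^prs:", names(coef(fit)), value = TRUE), collapse = ", "))
  }
  if (term %in% fit@unidentifiable)
    stopf("term '%s' is unidentifiable; no test is defined", term)
  if (!term %in% names(coef(fit))) stopf("term '%s' not present in fit", term)
  b <- coef(fit)[[term]]
  se <- sqrt(vcov(fit)[term, term])
  2 * stats::pnorm(-abs(b / se))
}
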