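#' Construct a SNP weight panel
#'
#' @param snpId character vector of marker identifiers (unique).
#' @param riskAllele character vector of risk-allele symbols.
#' @param oddsRatio positive numeric vector of per-allele odds ratios; the
#'   additive weight used in the score is `log(oddsRatio)`.
#' @param alleleFreq optional numeric vector of risk-allele frequencies in
#'   (0, 1); required only for simulation.
#' @return A [SnpWeightPanel-class].
#' @examples
#' snpWeightPanel(c("rs1", "rs2"), c("A", "G"), c(1.10, 1.25))
#' @export
snpWeightPanel <- function(snpId, riskAllele, oddsRatio, alleleFreq = NULL) {
  oddsRatio <- as.numeric(oddsRatio)
  if (any(!is.finite(oddsRatio)) || any(oddsRatio <= 0))
    stopf("per-allele odds ratios must be positive and finite")
  w <- data.frame(snp_id = as.character(snpId),
                  risk_allele = as.character(riskAllele),
                  odds_ratio = as.numeric(oddsRatio),
                  log_or = log(as.numeric(oddsRatio)),
                  stringsAsFactors = FALSE)
  if (!is.null(alleleFreq)) w$allele_freq <- as.numeric(alleleFreq)
  new("SnpWeightPanel", weights = w)
}

#' @describeIn snpWeightPanel Marker identifiers of a panel.
#' @param panel A [SnpWeightPanel-class].
#' @export
snpIds <- function(panel) panel@weights$snp_id

#' @describeIn snpWeightPanel Named vector of log odds-ratio weights.
#' @export
logOddsWeights <- function(panel) {
  stats::setNames(panel@weights$log_or, panel@weights$snp_id)
}

#' @describeIn snpWeightPanel Named vector of risk-allele frequencies (NA if
#'   the panel does not carry them).
#' @export
alleleFrequencies <- function(panel) {
  w <- panel@weights
  af <- if ("allele_freq" %in% names(w)) w$allele_freq else rep(NA_real_, nrow(w))
  stats::setNames(af, w$snp_id)
}

setMethod("show", "SnpWeightPanel", function(object) {
  w <- object@weights
  cat("SnpWeightPanel with", nrow(w), "SNPs\n")
  cat("  per-allele OR range: [", sprintf("%.3f", min(w$odds_ratio)), ", ",
      sprintf("%.3f", max(w$odds_ratio)), "]\n", sep = "")
  if ("allele_freq" %in% names(w) && !anyNA(w$allele_freq))
    cat("  population PRS mean ", sprintf("%.3f", sum(2 * w$allele_freq * w$log_or)),
        ", SD ", sprintf("%.3f", sqrt(sum(2 * w$allele_freq * (1 - w$allele_freq) * w$log_or^2))),
        " (Hardy-Weinberg)\n", sep = "")
})

#' Length of a SNP weight panel
#' @param x A [SnpWeightPanel-class].
#' @export
setMethod("length", "SnpWeightPanel", function(x) nrow(x@weights))

#' Compute the multiplicative polygenic risk score
#'
#' The score is the natural-log-scale sum over panel markers,
#' \eqn{PRS = \sum_i g_i \log OR_i}, i.e. the log of the product of the
#' risk-allele-specific odds ratios weighted by risk-allele copy number.
#' Dosages may be fractional (imputed markers); they are never rounded to
#' hard calls.
#'
#' @param dosages either a named numeric vector (one subject; names are SNP
#'   ids, values risk-allele dosages in \[0, 2\]) or a numeric matrix /
#'   data.frame of subjects-by-SNPs dosages.  For the matrix form, subject
#'   identifiers are taken from a `subject_id` column if present, else from
#'   row names.
#' @param panel A [SnpWeightPanel-class].
#' @param missingPolicy `"error"` (default) fails listing the panel SNPs
#'   absent from `dosages`; `"mean_dosage"` substitutes per-SNP reference
#'   mean dosages, which must be supplied.
#' @param referenceMeans named numeric of per-SNP mean dosages, required when
#'   `missingPolicy = "mean_dosage"`.
#' @param subjectId identifier used for the vector form (default `"subject"`).
#' @return data.frame with columns `subject_id`, `raw` and `centered`
#'   (`NA` until [centerScores()] is applied).
#' @examples
#' p <- snpWeightPanel(c("a", "b", "c"), c("A", "A", "A"), c(1.1, 1.2, 0.9))
#' computePrs(c(a = 2, b = 1, c = 0), p)$raw  # 2*log(1.1) + log(1.2)
#' @export
computePrs <- function(dosages, panel,
                       missingPolicy = c("error", "mean_dosage"),
                       referenceMeans = NULL, subjectId = "subject") {
  missingPolicy <- match.arg(missingPolicy)
  validObject(panel)
  ids <- snpIds(panel)
  w <- logOddsWeights(panel)

  if (is.vector(dosages) && !is.list(dosages)) {
    D <- matrix(dosages, nrow = 1, dimnames = list(subjectId, names(dosages)))
  } else {
    D <- as.data.frame(dosages)
    if ("subject_id" %in% names(D)) {
      rn <- as.character(D$subject_id)
      D <- D[, setdiff(names(D), "subject_id"), drop = FALSE]
    } else rn <- rownames(D)
    D <- as.matrix(D)
    rownames(D) <- rn
  }
  if (is.null(colnames(D))) stopf("dosages must be named by snp_id")
  extra <- setdiff(colnames(D), ids)
  if (length(extra)) D <- D[, setdiff(colnames(D), extra), drop = FALSE]

  absent <- setdiff(ids, colnames(D))
  if (length(absent)) {
    if (missingPolicy == "error")
      stopf("missing markers for PRS: %s", paste(absent, collapse = ", "))
    if (is.null(referenceMeans) || !all(absent %in% names(referenceMeans)))
      stopf("missingPolicy = 'mean_dosage' requires referenceMeans for: %s",
            paste(absent, collapse = ", "))
    fill <- matrix(rep(referenceMeans[absent], each = nrow(D)), nrow = nrow(D),
                   dimnames = list(rownames(D), absent))
    D <- cbind(D, fill)
  }
  # per-subject NA entries are treated the same way as absent columns
  if (anyNA(D)) {
    if (missingPolicy == "error") {
      bad <- colnames(D)[colSums(is.na(D)) > 0]
      stopf("missing dosage values for markers: %s", paste(bad, collapse = ", "))
    }
    for (s in colnames(D)[colSums(is.na(D)) > 0]) {
      if (!s %in% names(referenceMeans))
        stopf("missingPolicy = 'mean_dosage' requires referenceMeans for: %s", s)
      D[is.na(D[, s]), s] <- referenceMeans[s]
    }
  }
  rng <- range(D)
  if (rng[1] < 0 || rng[2] > 2)
    stopf("dosages must lie in [0, 2]; observed range [%g, %g]", rng[1], rng[2])

  raw <- as.numeric(D[, ids, drop = FALSE] %*% w[ids])
  data.frame(subject_id = rownames(D), raw = raw, centered = NA_real_,
             stringsAsFactors = FALSE)
}

#' Center polygenic risk scores on a reference subject set
#'
#' Subtracts from every score the mean raw PRS over `centeringIds`
#' (conventionally the actual control sisters), so that the centered score of
#' the reference group averages zero and risk-factor main effects in
#' interaction models are interpretable at the reference-group mean PRS.
#'
#' @param scores data.frame from [computePrs()] (columns `subject_id`, `raw`).
#' @param centeringIds character vector of subject identifiers, non-empty,
#'   all present in `scores`.
#' @return `scores` with the `centered` column filled in; the centering
#'   constant is attached as `attr(, "centering")`.
#' @export
centerScores <- function(scores, centeringIds) {
  if (length(centeringIds) == 0L)
    stopf("centering set must be non-empty")
  miss <- setdiff(centeringIds, scores$subject_id)
  if (length(miss))
    stopf("centering subjects absent from scores: %s", paste(miss, collapse = ", "))
  const <- mean(scores$raw[scores$subject_id %in% centeringIds])
  scores$centered <- scores$raw - const
  attr(scores, "centering") <- const
  scores
}
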