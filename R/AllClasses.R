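#' @import methods
NULL

#' SnpWeightPanel: risk-allele weight panel for a polygenic risk score
#'
#' A panel of SNP weights, one row per marker, holding the marker identifier,
#' the risk allele, the published per-allele odds ratio and its natural log
#' (the additive weight actually used by [computePrs()]).  An optional
#' `allele_freq` column carries risk-allele frequencies; it is only needed by
#' the family simulator.
#'
#' The polygenic risk score is the natural-log-scale sum
#' \deqn{PRS = \sum_i g_i \log OR_i}
#' over risk-allele dosages \eqn{g_i \in [0, 2]}.  All "per unit change" PRS
#' odds ratios reported by [fitCLR()] refer to this log scale.
#'
#' @slot weights data.frame with columns `snp_id`, `risk_allele`,
#'   `odds_ratio`, `log_or` and optionally `allele_freq`.
#'
#' @seealso [snpWeightPanel()], [readWeightPanel()], [computePrs()]
#' @export
setClass("SnpWeightPanel", representation(weights = "data.frame"))

setValidity("SnpWeightPanel", function(object) {
  w <- object@weights
  msg <- character()
  need <- c("snp_id", "risk_allele", "odds_ratio", "log_or")
  if (!all(need %in% names(w)))
    msg <- c(msg, paste("weights must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(w) == 0L) msg <- c(msg, "panel must be non-empty")
    if (anyDuplicated(w$snp_id)) msg <- c(msg, "snp_id must be unique within a panel")
    if (any(!is.finite(w$odds_ratio)) || any(w$odds_ratio <= 0))
      msg <- c(msg, "per-allele odds ratios must be positive and finite")
    if ("allele_freq" %in% names(w)) {
      af <- w$allele_freq[!is.na(w$allele_freq)]
      if (any(af <= 0 | af >= 1)) msg <- c(msg, "allele frequencies must lie in (0, 1)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' MatchedSets: conditional-logistic strata built from family designs
#'
#' Container for the matched strata used in conditional logistic regression.
#' Each stratum belongs to one family and crosses genotype sources (case,
#' genotyped sibling or pseudo-sibling) with exposure sources (case, sibling)
#' according to the family's design:
#'
#' * `case_parents_plus` — 1:3, members (Gc,Ec), (Gps,Es), (Gc,Es), (Gps,Ec)
#' * `case_sibling_plus` — 1:3, as above with the genotyped sibling for Gps
#' * `case_parents`      — 1:1, members (Gc,Ec), (Gps,Ec)
#' * `case_plus`         — 1:1, members (Gc,Ec), (Gc,Es)
#'
#' @slot members data.frame with one row per stratum member: `set_id`,
#'   `family_id`, `design`, `member_rank`, `is_case`, `genotype_source`,
#'   `exposure_source`, `prs` (centered), `birth_order_elder`, plus one
#'   column per risk factor carried over from the exposure source.
#' @slot centering numeric(1), the PRS centering constant that was subtracted.
#'
#' @seealso [buildMatchedSets()], [fitCLR()]
#' @export
setClass("MatchedSets",
         representation(members = "data.frame", centering = "numeric"))

setValidity("MatchedSets", function(object) {
  m <- object@members
  msg <- character()
  need <- c("set_id", "family_id", "design", "member_rank", "is_case",
            "genotype_source", "exposure_source", "prs")
  if (!all(need %in% names(m)))
    return(paste("members must have columns:", paste(need, collapse = ", ")))
  if (nrow(m)) {
    ncase <- tapply(m$is_case, m$set_id, sum)
    if (any(ncase != 1L)) msg <- c(msg, "every matched set must contain exactly one case member")
    sz <- tapply(m$is_case, m$set_id, length)
    des <- m$design[!duplicated(m$set_id)]
    names(des) <- m$set_id[!duplicated(m$set_id)]
    expect <- ifelse(des[names(sz)] %in% c("case_parents_plus", "case_sibling_plus"), 4L, 2L)
    if (any(sz != expect)) msg <- c(msg, "set size must be 4 for 1:3 designs and 2 for 1:1 designs")
  }
  if (length(msg)) msg else TRUE
})

#' ModelSpec: one conditional-logistic model of the analysis battery
#'
#' Describes a single model: the target risk factor, whether a PRS-by-factor
#' interaction is estimated, the confounder set, and the coding rules.  In
#' interaction models the risk-factor main effect is saturated (one indicator
#' per non-reference level) while the interaction term uses an integer linear
#' trend over the ordered levels — except smoking, which is nominal and gets
#' one product term per non-reference level.  Risk-factor-only models use a
#' linear trend for ordered categorical factors (smoking again saturated).
#'
#' @slot target character(1), risk-factor name (see [exposureFactors()]).
#' @slot interaction logical(1), whether PRS main effect and PRS-by-factor
#'   product terms are included.
#' @slot confounders character vector of risk-factor names entered as
#'   trend/continuous covariates; the elder-sister birth-order indicator is
#'   always included and is not listed here.
#' @slot subset character(1), one of `"parous"`, `"premenopausal"`, `"all"`:
#'   family-level restriction applied before fitting (based on the case's
#'   exposure profile).
#' @slot label character(1), display label for report tables.
#' @seealso [modelSpec()], [defaultModelSpecs()], [buildDesignMatrix()]
#' @export
setClass("ModelSpec",
         representation(target = "character", interaction = "logical",
                        confounders = "character", subset = "character",
                        label = "character"))

#' ClrFit: fitted conditional logistic regression
#'
#' Result of [fitCLR()]: maximum conditional-likelihood coefficients, the
#' covariance from the inverse observed information, per-term odds ratios
#' (ratios of odds ratios for product terms) with 95% Wald intervals, and
#' convergence diagnostics.  Covariate directions with no within-set
#' variation are excluded from estimation and listed in `unidentifiable`.
#'
#' @slot coefficients named numeric, log-odds scale.
#' @slot vcov covariance matrix of the coefficients.
#' @slot orTable data.frame: `term`, `estimate`, `se`, `or`, `ci_lower`,
#'   `ci_upper`, `p_value`.
#' @slot loglik numeric(1), conditional log-likelihood at the optimum.
#' @slot converged logical(1).
#' @slot iterations integer(1).
#' @slot separation logical(1), monotone-likelihood flag.
#' @slot unidentifiable character, dropped covariate names.
#' @slot nSets integer(1), informative sets used.
#' @slot nDropped integer(1), sets dropped for missing covariates.
#' @export
setClass("ClrFit",
         representation(coefficients = "numeric", vcov = "matrix",
                        orTable = "data.frame", loglik = "numeric",
                        converged = "logical", iterations = "integer",
                        separation = "logical", unidentifiable = "character",
                        nSets = "integer", nDropped = "integer"))

setValidity("ClrFit", function(object) {
  ot <- object@orTable
  if (nrow(ot)) {
    bad <- !is.na(ot$or) & (ot$or <= 0 | ot$ci_lower > ot$or | ot$ci_upper < ot$or)
    if (any(bad)) return("odds ratios must be positive and bracketed by their CIs")
  }
  TRUE
})

#' SimConfig: configuration of the ascertained-family simulator
#'
#' Families are nuclear: two parents drawn per SNP under Hardy-Weinberg
#' equilibrium, two daughters by independent Mendelian transmission.  Each
#' daughter's disease status is Bernoulli with
#' \deqn{logit P = \alpha + \beta_{prs}(PRS - \mu) + \sum \beta_e E +
#'       \sum \beta_{ge} (PRS-\mu) E}
#' where \eqn{\mu} is the panel's population PRS mean.  A family is accepted
#' when exactly one daughter is affected, with a diagnosis age drawn below 50
#' (rejection sampling emulating young-onset ascertainment).  Accepted
#' families are assigned to the four designs and the corresponding genotype
#' and exposure availability is masked.
#'
#' @slot nFamilies integer(1), accepted families to generate.
#' @slot panel SnpWeightPanel with `allele_freq` filled in.
#' @slot baselineLogit numeric(1), \eqn{\alpha}.
#' @slot betaPrs numeric(1), log-OR per PRS unit.
#' @slot betaExposure named numeric, per-factor log-ORs (model-column names,
#'   see [simulateFamilies()]).
#' @slot betaInteraction named numeric, per-factor interaction log-RORs.
#' @slot designCounts named numeric over the four designs; counts (summing to
#'   `nFamilies`) or proportions (summing to 1).
#' @slot exposureModel list of per-factor prevalence/distribution parameters
#'   (see [simConfig()]); defaults are calibrated to the published control
#'   marginals.
#' @slot sisterRho numeric(1) in \[0,1), shared-family latent correlation for
#'   exposures.
#' @slot ageMean,ageSd numeric(1), diagnosis-age normal parameters, truncated
#'   to (25, 50).
#' @slot seed integer(1).
#' @seealso [simConfig()], [simulateFamilies()]
#' @export
setClass("SimConfig",
         representation(nFamilies = "integer", panel = "SnpWeightPanel",
                        baselineLogit = "numeric", betaPrs = "numeric",
                        betaExposure = "numeric", betaInteraction = "numeric",
                        designCounts = "numeric", exposureModel = "list",
                        sisterRho = "numeric",
                        ageMean = "numeric", ageSd = "numeric",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  dn <- c("case_parents_plus", "case_parents", "case_sibling_plus", "case_plus")
  if (!identical(sort(names(object@designCounts)), sort(dn)))
    msg <- c(msg, "designCounts must be named by the four designs")
  tot <- sum(object@designCounts)
  if (!(isTRUE(all.equal(tot, 1)) || isTRUE(all.equal(tot, as.numeric(object@nFamilies)))))
    msg <- c(msg, "designCounts must sum to 1 (proportions) or to nFamilies (counts)")
  if (!"allele_freq" %in% names(object@panel@weights) ||
      anyNA(object@panel@weights$allele_freq))
    msg <- c(msg, "simulation panel must carry allele_freq for every SNP")
  if (object@sisterRho < 0 || object@sisterRho >= 1)
    msg <- c(msg, "sisterRho must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' SimulatedDataset: output of the family simulator
#'
#' Pedigree, genotype and exposure tables in the pipeline's own input
#' formats, plus a truth record of every generating parameter.  Use
#' [writeDataset()] to emit them as TSV/CSV/JSON files that round-trip
#' through the pipeline readers.
#'
#' @slot pedigree data.frame: `family_id`, `subject_id`, `role`,
#'   `birth_order_rank`, `genotyped`, `exposure`, `invasive`, `er_pos`,
#'   `index_age`.
#' @slot genotypes wide data.frame of dosages, `subject_id` + one column per
#'   SNP (only subjects flagged `genotyped`).
#' @slot exposures wide data.frame of index-age-aligned exposure profiles for
#'   subjects flagged `exposure`.
#' @slot truth list of generating parameters (betas, panel, seed, counts).
#' @export
setClass("SimulatedDataset",
         representation(pedigree = "data.frame", genotypes = "data.frame",
                        exposures = "data.frame", truth = "list"))

#' AnalysisReport: end-to-end analysis output
#'
#' @slot results data.frame, one row per model with risk-factor OR and CI,
#'   PRS OR and CI, interaction ROR and CI and the interaction p-value.
#' @slot summary data.frame, case/control dataset summary (counts/proportions
#'   for categorical variables, mean/SD for continuous).
#' @slot exclusions data.frame: `family_id`, `reason` for every family not
#'   contributing to the matched sets.
#' @slot fits named list of [ClrFit-class] objects (one per model).
#' @slot provenance list: configuration echo, package version, timestamps.
#' @export
setClass("AnalysisReport",
         representation(results = "data.frame", summary = "data.frame",
                        exclusions = "data.frame", fits = "list",
                        provenance = "list"))
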