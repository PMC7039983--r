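# Mendelian machinery for case-parent trios.
#
# For a hard-call parent g, the transmissible risk-allele counts are
# {0} for g = 0, {0, 1} for g = 1 and {1} for g = 2; a trio is consistent
# when some pair of transmissions sums to the child's call.

minTransmit <- function(g) as.integer(g == 2)
maxTransmit <- function(g) as.integer(g >= 1)

hardCall <- function(g, threshold) {
  r <- round(g)
  ifelse(abs(g - r) <= threshold, r, NA_real_)
}

#' Pseudo-sibling genotype from a case-parent trio
#'
#' The pseudo-sibling is the hypothetical (equally likely) sister who carries
#' the parental alleles that were not transmitted to the case; her risk-allele
#' dosage at each marker is `gFather + gMother - gCase`.  Allele conservation
#' holds exactly: case plus pseudo-sibling dosages equal the parental total,
#' and applying the operation twice returns the case.
#'
#' Hard-call trios (every dosage within `hardCallThreshold` of an integer)
#' are validated for Mendelian consistency and inconsistent markers raise an
#' error.  Fractional (imputed) dosages are passed through unvalidated; if a
#' fractional result falls outside \[0, 2\] it is flagged via the
#' `"out_of_range"` attribute and a warning, never clamped, since the linear
#' score downstream remains valid.
#'
#' @param gCase,gFather,gMother numeric dosages in \[0, 2\], equal length,
#'   optionally named by snp_id.
#' @param hardCallThreshold dosages within this distance of an integer are
#'   treated as hard calls (default 0.1).
#' @return numeric vector of pseudo-sibling dosages (named as the inputs).
#' @examples
#' pseudoSibGenotype(1, 1, 1)  # 1
#' pseudoSibGenotype(2, 1, 1)  # 0
#' @export
pseudoSibGenotype <- function(gCase, gFather, gMother, hardCallThreshold = 0.1) {
  n <- length(gCase)
  if (length(gFather) != n || length(gMother) != n)
    stopf("trio dosage vectors must have equal length")
  rng <- range(c(gCase, gFather, gMother))
  if (rng[1] < 0 || rng[2] > 2)
    stopf("dosages must lie in [0, 2]")
  ids <- names(gCase)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  rep_ <- mendelianCheck(gCase, gFather, gMother, hardCallThreshold)
  bad <- rep_$snp_id[rep_$status == "inconsistent"]
  if (length(bad))
    stopf("Mendelian inconsistency in trio at marker(s): %s",
          paste(bad, collapse = ", "))

  g <- gFather + gMother - gCase
  names(g) <- names(gCase)
  oor <- which(g < 0 | g > 2)
  if (length(oor)) {
    warnf("pseudo-sibling dosage outside [0, 2] at %d fractional marker(s); passed through unclamped",
          length(oor))
    attr(g, "out_of_range") <- ids[oor]
  }
  g
}

#' Report Mendelian inconsistencies in a trio
#'
#' Checks each marker of a case-parent trio against the set of possible
#' parental transmissions.  Dosages within `hardCallThreshold` of an integer
#' are rounded to that hard call; markers where any trio member is not a hard
#' call are skipped and reported as `"unchecked"`.
#'
#' @inheritParams pseudoSibGenotype
#' @return data.frame with columns `snp_id` and `status` (`"consistent"`,
#'   `"inconsistent"`, `"unchecked"`).
#' @export
mendelianCheck <- function(gCase, gFather, gMother, hardCallThreshold = 0.1) {
  n <- length(gCase)
  ids <- names(gCase)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  hc <- hardCall(gCase, hardCallThreshold)
  hf <- hardCall(gFather, hardCallThreshold)
  hm <- hardCall(gMother, hardCallThreshold)
  checkable <- !(is.na(hc) | is.na(hf) | is.na(hm))
  ok <- checkable &
    hc >= minTransmit(hf) + minTransmit(hm) &
    hc <= maxTransmit(hf) + maxTransmit(hm)
  status <- ifelse(!checkable, "unchecked", ifelse(ok, "consistent", "inconsistent"))
  data.frame(snp_id = ids, status = status, stringsAsFactors = FALSE)
}

#' Classify a family into one of the four matched designs
#'
#' Availability of genotype and risk-factor data places each family into one
#' of four disjoint designs:
#'
#' | design | requires | matching |
#' |---|---|---|
#' | `case_sibling_plus` | case G, sibling G, sibling E | 1:3 |
#' | `case_parents_plus` | case G, both parents G, sibling E | 1:3 |
#' | `case_parents` | case G, both parents G (no sibling E) | 1:1 |
#' | `case_plus` | case G, sibling E only | 1:1 |
#'
#' All designs require the case's genotype and exposure data.  When both the
#' parents and the sibling are genotyped, the sibling genotype takes
#' precedence (`case_sibling_plus`).  Families genotyped for exactly one
#' parent (and not rescued by a genotyped sibling) are rejected, as are
#' families fitting no design row.
#'
#' @param caseGenotyped,caseExposure logical, case data availability.
#' @param bothParentsGenotyped logical, both parents genotyped.
#' @param siblingGenotyped,siblingExposure logical, control-sister data.
#' @param singleParentGenotyped logical, exactly one parent genotyped.
#' @return list with `design` (one of the four names, or `NA`) and `reason`
#'   (`NA` for classified families, else the exclusion reason).
#' @examples
#' classifyFamily(TRUE, TRUE, bothParentsGenotyped = TRUE,
#'                siblingGenotyped = FALSE, siblingExposure = TRUE)$design
#' @export
classifyFamily <- function(caseGenotyped, caseExposure,
                           bothParentsGenotyped = FALSE,
                           siblingGenotyped = FALSE,
                           siblingExposure = FALSE,
                           singleParentGenotyped = FALSE) {
  if (!caseGenotyped || !caseExposure)
    return(list(design = NA_character_, reason = "missing case genotype or exposure data"))
  if (siblingGenotyped && siblingExposure)
    return(list(design = "case_sibling_plus", reason = NA_character_))
  if (bothParentsGenotyped && siblingExposure)
    return(list(design = "case_parents_plus", reason = NA_character_))
  if (bothParentsGenotyped)
    return(list(design = "case_parents", reason = NA_character_))
  if (singleParentGenotyped)
    return(list(design = NA_character_, reason = "single genotyped parent: no both-parent design applies"))
  if (siblingExposure)
    return(list(design = "case_plus", reason = NA_character_))
  list(design = NA_character_, reason = "no matched comparison possible from available data")
}
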