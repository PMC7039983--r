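designMatchingPlan <- function(design) {
  switch(design,
    case_parents_plus = list(g = c("case", "pseudo_sibling", "case", "pseudo_sibling"),
                             e = c("case", "sibling", "sibling", "case")),
    case_sibling_plus = list(g = c("case", "sibling", "case", "sibling"),
                             e = c("case", "sibling", "sibling", "case")),
    case_parents      = list(g = c("case", "pseudo_sibling"),
                             e = c("case", "case")),
    case_plus         = list(g = c("case", "case"),
                             e = c("case", "sibling")),
    stopf("unknown design '%s'", design))
}

#' Build the conditional-logistic matched set for one family
#'
#' Crosses the family's genotype sources with its exposure sources according
#' to the design (see [MatchedSets-class]), producing the case member first
#' followed by the counterfactual genotype/risk-factor combinations in the
#' standard column order.  Members inherit the exposure profile — including
#' the elder-sister birth-order indicator — from their exposure source, and
#' the PRS from their genotype source.
#'
#' @param familyId family identifier.
#' @param design one of `"case_parents_plus"`, `"case_parents"`,
#'   `"case_sibling_plus"`, `"case_plus"`.
#' @param casePrs centered PRS of the case.
#' @param counterpartPrs centered PRS of the genotype counterpart (the
#'   genotyped sibling or the pseudo-sibling); ignored for `case_plus`.
#' @param caseExposure one-row data.frame, the case's aligned exposure
#'   profile (wide layout, see [exposureFactors()]), including a
#'   `birth_order_elder` column.
#' @param siblingExposure one-row data.frame for the control sister; required
#'   for designs whose matching set uses Es, ignored for `case_parents`.
#' @return data.frame of member rows (`family_id`, `member_rank`, `is_case`,
#'   `genotype_source`, `exposure_source`, `prs`, exposure columns).
#' @export
buildMatchedSet <- function(familyId, design, casePrs, counterpartPrs = NA_real_,
                            caseExposure, siblingExposure = NULL) {
  plan <- designMatchingPlan(design)
  k <- length(plan$g)
  if ("sibling" %in% plan$e && is.null(siblingExposure))
    stopf("family %s (%s): sibling exposure profile is required but absent",
          familyId, design)
  if (any(plan$g != "case") && !is.finite(counterpartPrs))
    stopf("family %s (%s): counterpart PRS (%s) is required but absent",
          familyId, design, setdiff(plan$g, "case"))

  pickE <- function(src) if (src == "case") caseExposure else siblingExposure
  expo <- do.call(rbind, lapply(plan$e, pickE))
  prs <- ifelse(plan$g == "case", casePrs, counterpartPrs)
  meta <- data.frame(family_id = rep(familyId, k),
                     design = design,
                     member_rank = seq_len(k),
                     is_case = seq_len(k) == 1L,
                     genotype_source = plan$g,
                     exposure_source = plan$e,
                     prs = prs,
                     stringsAsFactors = FALSE)
  rownames(expo) <- NULL
  cbind(meta, expo)
}

#' Assemble a MatchedSets container from per-family member tables
#'
#' @param memberList list of data.frames from [buildMatchedSet()].
#' @param centering the PRS centering constant that was applied (numeric(1)).
#' @return A [MatchedSets-class].
#' @export
matchedSets <- function(memberList, centering = NA_real_) {
  members <- do.call(rbind, memberList)
  if (is.null(members)) members <- data.frame()
  else members <- cbind(set_id = rep(seq_along(memberList),
                                     vapply(memberList, nrow, 1L)), members)
  new("MatchedSets", members = members, centering = as.numeric(centering))
}

#' @describeIn matchedSets Member table of a MatchedSets object.
#' @param x A [MatchedSets-class].
#' @export
setMembers <- function(x) x@members

#' @describeIn matchedSets Number of matched sets.
#' @export
nSets <- function(x) length(unique(x@members$set_id))

#' Export matched sets to TSV
#'
#' Writes the member table — `set_id`, `member_rank`, `is_case`,
#' `genotype_source`, `exposure_source`, `prs` and one column per carried
#' covariate — for inspection or use outside the package.
#'
#' @param sets A [MatchedSets-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeMatchedSets <- function(sets, path) {
  utils::write.table(setMembers(sets), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

setMethod("show", "MatchedSets", function(object) {
  m <- object@members
  cat("MatchedSets with", nSets(object), "strata /", nrow(m), "members\n")
  if (nrow(m)) {
    tab <- table(m$design[!duplicated(m$set_id)])
    for (d in names(tab)) cat("  ", d, ": ", tab[[d]], "\n", sep = "")
    if (!is.na(object@centering))
      cat("  PRS centering constant:", sprintf("%.4f", object@centering), "\n")
  }
})
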