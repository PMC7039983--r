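# End-to-end orchestration: dataset -> PRS -> pseudo-siblings -> matched
# sets -> model battery -> report.

panelFromDataset <- function(ds, panel) {
  if (!is.null(panel)) return(panel)
  pw <- ds@truth$panel
  if (is.null(pw)) stopf("no weight panel supplied and none attached to the dataset")
  if (!"log_or" %in% names(pw)) pw$log_or <- log(pw$odds_ratio)
  new("SnpWeightPanel", weights = pw)
}

#' Build all matched sets of a dataset
#'
#' Runs the data-preparation half of the pipeline: applies case-level subset
#' filters, checks availability flags and classifies every family into a
#' design ([classifyFamily()]), computes raw PRS for all genotyped subjects,
#' validates case-parent trios for Mendelian consistency and derives
#' pseudo-sibling scores (`PRS_father + PRS_mother - PRS_case`), centers all
#' scores on the control-sister mean, and assembles the conditional-logistic
#' strata.  Families failing any step are excluded with a logged reason, so
#' that analyzed plus excluded families account for every input family.
#'
#' @param ds A [SimulatedDataset-class] (simulated or read with
#'   [readDataset()]).
#' @param panel A [SnpWeightPanel-class]; defaults to the panel attached to
#'   the dataset.
#' @param filter `"all"`, `"invasive_only"` or `"er_positive_only"`:
#'   case-level restriction applied before set construction.
#' @param centeringScope `"controls"` centers the PRS on the genotyped
#'   control sisters (falling back to pseudo-sibling scores, with a warning,
#'   if no sister is genotyped); `"controls_and_pseudo"` pools actual and
#'   pseudo-sibling scores.
#' @param missingPolicy,referenceMeans forwarded to [computePrs()].
#' @return list with `sets` (a [MatchedSets-class]), `exclusions`
#'   (data.frame `family_id`, `reason`), `centering` (numeric) and
#'   `families` (per-family design table).
#' @export
buildMatchedSets <- function(ds, panel = NULL,
                             filter = c("all", "invasive_only", "er_positive_only"),
                             centeringScope = c("controls", "controls_and_pseudo"),
                             missingPolicy = "error", referenceMeans = NULL) {
  filter <- match.arg(filter)
  centeringScope <- match.arg(centeringScope)
  panel <- panelFromDataset(ds, panel)
  ped <- ds@pedigree
  expo <- ds@exposures
  geno <- ds@genotypes

  fams <- unique(ped$family_id)
  excl <- data.frame(family_id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    if (length(ids))
      excl <<- rbind(excl, data.frame(family_id = ids, reason = reason,
                                      stringsAsFactors = FALSE))
    setdiff(fams, ids)
  }

  caseR <- ped[ped$role == "case", ]
  caseR <- caseR[match(fams, caseR$family_id), ]

  if (filter != "all") {
    flag <- if (filter == "invasive_only") caseR$invasive else caseR$er_pos
    bad <- fams[is.na(flag) | flag != 1]
    fams <- drop(bad, paste0("filtered out: ", filter))
    caseR <- caseR[match(fams, caseR$family_id), ]
  }

  sub <- function(role) {
    r <- ped[ped$role == role, ]
    r[match(fams, r$family_id), ]
  }
  sibR <- sub("control_sister"); fatR <- sub("father"); motR <- sub("mother")

  hasG <- function(r) !is.na(r$subject_id) & r$genotyped == 1 &
    r$subject_id %in% geno$subject_id
  hasE <- function(r) !is.na(r$subject_id) & r$exposure == 1 &
    r$subject_id %in% expo$subject_id
  caseG <- hasG(caseR); caseE <- hasE(caseR)
  sibG <- hasG(sibR); sibE <- hasE(sibR)
  fatG <- hasG(fatR); motG <- hasG(motR)

  cls <- mapply(function(cg, ce, pg, sg, se, sp)
    classifyFamily(cg, ce, bothParentsGenotyped = pg, siblingGenotyped = sg,
                   siblingExposure = se, singleParentGenotyped = sp),
    caseG, caseE, fatG & motG, sibG, sibE, xor(fatG, motG), SIMPLIFY = FALSE)
  design <- vapply(cls, `[[`, "", "design")
  reason <- vapply(cls, `[[`, "", "reason")
  if (any(is.na(design))) {
    bad <- is.na(design)
    excl <- rbind(excl, data.frame(family_id = fams[bad], reason = reason[bad],
                                   stringsAsFactors = FALSE))
    keepIdx <- which(!bad)
  } else keepIdx <- seq_along(fams)
  fams <- fams[keepIdx]; design <- design[keepIdx]
  caseR <- caseR[keepIdx, ]; sibR <- sibR[keepIdx, ]
  fatR <- fatR[keepIdx, ]; motR <- motR[keepIdx, ]
  sibG <- sibG[keepIdx]

  scores <- computePrs(geno, panel, missingPolicy = missingPolicy,
                       referenceMeans = referenceMeans)
  rawOf <- function(ids) scores$raw[match(ids, scores$subject_id)]
  casePrs <- rawOf(caseR$subject_id)

  # Mendelian validation and pseudo-sibling scores for both-parent designs
  trio <- design %in% c("case_parents_plus", "case_parents")
  pseudoPrs <- rep(NA_real_, length(fams))
  if (any(trio)) {
    snpCols <- snpIds(panel)
    gm <- function(ids) as.matrix(geno[match(ids, geno$subject_id), snpCols, drop = FALSE])
    Gc <- gm(caseR$subject_id[trio]); Gf <- gm(fatR$subject_id[trio])
    Gm <- gm(motR$subject_id[trio])
    hc <- hardCall(Gc, 0.1); hf <- hardCall(Gf, 0.1); hm <- hardCall(Gm, 0.1)
    checkable <- !(is.na(hc) | is.na(hf) | is.na(hm))
    bad <- checkable & (hc < minTransmit(hf) + minTransmit(hm) |
                          hc > maxTransmit(hf) + maxTransmit(hm))
    nbad <- rowSums(bad)
    pseudoPrs[trio] <- rawOf(fatR$subject_id[trio]) +
      rawOf(motR$subject_id[trio]) - casePrs[trio]
    if (any(nbad > 0)) {
      badFam <- fams[trio][nbad > 0]
      excl <- rbind(excl, data.frame(
        family_id = badFam,
        reason = sprintf("Mendelian inconsistency at %d marker(s)",
                         nbad[nbad > 0]), stringsAsFactors = FALSE))
      keep <- !fams %in% badFam
      fams <- fams[keep]; design <- design[keep]
      caseR <- caseR[keep, ]; sibR <- sibR[keep, ]
      casePrs <- casePrs[keep]; pseudoPrs <- pseudoPrs[keep]; sibG <- sibG[keep]
    }
  }
  if (!length(fams)) stopf("no family survives preparation; see exclusion log")

  sibPrs <- ifelse(sibG, rawOf(sibR$subject_id), NA_real_)
  counterpart <- ifelse(design == "case_sibling_plus", sibPrs,
                        ifelse(design == "case_plus", NA_real_, pseudoPrs))

  ctrlScores <- sibPrs[design == "case_sibling_plus"]
  if (centeringScope == "controls_and_pseudo")
    ctrlScores <- c(ctrlScores, pseudoPrs[design %in% c("case_parents_plus", "case_parents")])
  if (!length(ctrlScores)) {
    warnf("no genotyped control sister available; centering PRS on pseudo-sibling scores")
    ctrlScores <- pseudoPrs[!is.na(pseudoPrs)]
  }
  if (!length(ctrlScores)) {
    # no sibling of any kind (e.g. a case_plus-only dataset): any constant
    # leaves the conditional likelihood unchanged, so fall back to the cases
    ctrlScores <- casePrs
  }
  centering <- mean(ctrlScores)

  dict <- exposureFactors()$name
  profCols <- c(dict, "index_age")
  profOf <- function(ids, elder) {
    p <- expo[match(ids, expo$subject_id), profCols, drop = FALSE]
    p$birth_order_elder <- as.integer(elder)
    rownames(p) <- NULL
    p
  }
  caseProf <- profOf(caseR$subject_id, caseR$birth_order_rank == 1)
  sibProf <- profOf(sibR$subject_id, sibR$birth_order_rank == 1)

  fam <- data.frame(family_id = fams, design = design,
                    casePrs = casePrs - centering,
                    cpPrs = counterpart - centering,
                    stringsAsFactors = FALSE)
  members <- assembleMembers(fam, caseProf, sibProf)
  sets <- new("MatchedSets", members = members, centering = centering)
  list(sets = sets, exclusions = excl, centering = centering,
       families = cbind(fam, invasive = caseR$invasive, er_pos = caseR$er_pos))
}

# vectorized matched-set assembly over a per-family table
assembleMembers <- function(fam, caseProf, sibProf) {
  rows <- list()
  for (d in unique(fam$design)) {
    idx <- which(fam$design == d)
    plan <- designMatchingPlan(d)
    for (j in seq_along(plan$g)) {
      prof <- if (plan$e[j] == "case") caseProf[idx, , drop = FALSE]
              else sibProf[idx, , drop = FALSE]
      rownames(prof) <- NULL
      meta <- data.frame(family_id = fam$family_id[idx], design = d,
                         member_rank = j, is_case = j == 1L,
                         genotype_source = plan$g[j],
                         exposure_source = plan$e[j],
                         prs = if (plan$g[j] == "case") fam$casePrs[idx]
                               else fam$cpPrs[idx],
                         stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- cbind(meta, prof)
    }
  }
  m <- do.call(rbind, rows)
  m <- m[order(match(m$family_id, fam$family_id), m$member_rank), ]
  m <- cbind(set_id = match(m$family_id, fam$family_id), m)
  rownames(m) <- NULL
  m
}

#' Run the full interaction analysis
#'
#' Executes the pipeline end to end: [buildMatchedSets()] followed by one
#' conditional-logistic fit per model specification, and assembles the
#' report table (risk-factor OR, PRS OR, interaction ROR, each with 95%
#' Wald CI, and the interaction p-value), the case/control dataset summary
#' and the per-family exclusion log.  Given the same inputs and
#' configuration the report is fully reproducible.
#'
#' @inheritParams buildMatchedSets
#' @param specs named list of [ModelSpec-class] (default
#'   [defaultModelSpecs()], the standard battery of 14 models); must be
#'   non-empty.
#' @param strict logical; if `TRUE`, per-model data problems abort instead
#'   of skipping the model.
#' @return An [AnalysisReport-class].
#' @examples
#' ds <- simulateFamilies(simConfig(nFamilies = 120, panel = defaultPanel(10),
#'                                  seed = 11))
#' rep <- runAnalysis(ds, specs = defaultModelSpecs()["hbc_ever"])
#' rep@results[, c("model", "ror", "interaction_p")]
#' @export
runAnalysis <- function(ds, panel = NULL, specs = defaultModelSpecs(),
                        filter = c("all", "invasive_only", "er_positive_only"),
                        centeringScope = c("controls", "controls_and_pseudo"),
                        missingPolicy = "error", referenceMeans = NULL,
                        strict = FALSE) {
  filter <- match.arg(filter)
  centeringScope <- match.arg(centeringScope)
  if (!length(specs)) stopf("model list must be non-empty")
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s@target, "")
  panel <- panelFromDataset(ds, panel)

  prep <- buildMatchedSets(ds, panel, filter = filter,
                           centeringScope = centeringScope,
                           missingPolicy = missingPolicy,
                           referenceMeans = referenceMeans)
  fits <- list()
  res <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    fit <- tryCatch({
      dm <- buildDesignMatrix(prep$sets, spec)
      f <- fitCLR(dm)
      attr(f, "dm") <- dm
      f
    }, error = function(e) if (strict) stop(e) else e)
    if (inherits(fit, "error")) {
      warnf("model '%s' skipped: %s", nm, conditionMessage(fit))
      next
    }
    fits[[nm]] <- fit
    res[[nm]] <- reportRows(nm, spec, fit, attr(fit, "dm"))
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  new("AnalysisReport", results = results,
      summary = summarizeDataset(ds, panel),
      exclusions = prep$exclusions, fits = fits,
      provenance = list(package = "famgxe",
                        version = as.character(utils::packageVersion("famgxe")),
                        filter = filter, centeringScope = centeringScope,
                        centering = prep$centering,
                        n_families_input = length(unique(ds@pedigree$family_id)),
                        n_families_analyzed = nrow(prep$families),
                        models = names(fits)))
}

# one report row per risk-factor term; PRS/ROR columns on the matching rows
reportRows <- function(nm, spec, fit, dm) {
  ot <- orTable(fit)
  pull <- function(term, what) {
    i <- match(term, ot$term)
    if (is.na(i)) NA_real_ else ot[[what]][i]
  }
  tt <- dm$targetTerms
  it <- dm$interactionTerms
  out <- data.frame(model = nm, label = spec@label, term = tt,
                    stringsAsFactors = FALSE)
  for (w in c("or", "ci_lower", "ci_upper", "p_value"))
    out[[paste0("rf_", sub("p_value", "p", w))]] <-
      vapply(tt, pull, 0, what = w)
  out$prs_or <- NA_real_; out$prs_ci_lower <- NA_real_; out$prs_ci_upper <- NA_real_
  out$ror <- NA_real_; out$ror_ci_lower <- NA_real_; out$ror_ci_upper <- NA_real_
  out$interaction_p <- NA_real_
  if (spec@interaction) {
    out$prs_or[1] <- pull("prs", "or")
    out$prs_ci_lower[1] <- pull("prs", "ci_lower")
    out$prs_ci_upper[1] <- pull("prs", "ci_upper")
    rowFor <- if (length(it) == length(tt)) seq_along(it) else rep(1L, length(it))
    for (k in seq_along(it)) {
      r <- rowFor[k]
      out$ror[r] <- pull(it[k], "or")
      out$ror_ci_lower[r] <- pull(it[k], "ci_lower")
      out$ror_ci_upper[r] <- pull(it[k], "ci_upper")
      out$interaction_p[r] <- pull(it[k], "p_value")
    }
  }
  out$n_sets <- fit@nSets
  out$n_dropped <- fit@nDropped
  out$converged <- fit@converged
  out
}

#' Summarize a dataset case versus control
#'
#' Counts and proportions for categorical risk factors, means and SDs for
#' continuous ones (and for the raw PRS of genotyped subjects), split into
#' case sisters versus actual control sisters, with per-variable
#' denominators reflecting missingness.
#'
#' @param ds A [SimulatedDataset-class].
#' @param panel optional [SnpWeightPanel-class] for the PRS rows.
#' @return data.frame: `variable`, `level`, `case_n`, `case`, `control_n`,
#'   `control` (proportions for categorical rows, mean/SD values otherwise).
#' @export
summarizeDataset <- function(ds, panel = NULL) {
  ped <- ds@pedigree
  expo <- ds@exposures
  caseIds <- ped$subject_id[ped$role == "case"]
  ctrlIds <- ped$subject_id[ped$role == "control_sister" & ped$exposure == 1]
  ec <- expo[expo$subject_id %in% caseIds, , drop = FALSE]
  es <- expo[expo$subject_id %in% ctrlIds, , drop = FALSE]

  rows <- list()
  addCont <- function(variable, vc, vs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = c("mean", "sd"),
      case_n = sum(!is.na(vc)), case = c(mean(vc, na.rm = TRUE), stats::sd(vc, na.rm = TRUE)),
      control_n = sum(!is.na(vs)), control = c(mean(vs, na.rm = TRUE), stats::sd(vs, na.rm = TRUE)),
      stringsAsFactors = FALSE)
  }
  addCat <- function(variable, vc, vs, levels) {
    nc <- sum(!is.na(vc)); nsv <- sum(!is.na(vs))
    tc <- table(factor(vc, levels)); ts <- table(factor(vs, levels))
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = levels,
      case_n = as.integer(tc),
      case = if (nc) as.numeric(tc) / nc else NA_real_,
      control_n = as.integer(ts),
      control = if (nsv) as.numeric(ts) / nsv else NA_real_,
      stringsAsFactors = FALSE)
  }

  panel <- tryCatch(panelFromDataset(ds, panel), error = function(e) NULL)
  if (!is.null(panel) && nrow(ds@genotypes)) {
    sc <- computePrs(ds@genotypes, panel)
    addCont("prs", sc$raw[sc$subject_id %in% caseIds],
            sc$raw[sc$subject_id %in% ctrlIds])
  }
  if ("index_age" %in% names(ec))
    addCont("index_age", ec$index_age, rep(NA_real_, 0))

  dict <- exposureFactors()
  for (i in seq_len(nrow(dict))) {
    f <- dict$name[i]
    if (dict$type[i] == "continuous") addCont(f, ec[[f]], es[[f]])
    else if (dict$type[i] == "binary") {
      vc <- ec[[f]]; vs <- es[[f]]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = f, level = "1",
        case_n = sum(vc == 1, na.rm = TRUE),
        case = if (sum(!is.na(vc))) mean(vc == 1, na.rm = TRUE) else NA_real_,
        control_n = sum(vs == 1, na.rm = TRUE),
        control = if (sum(!is.na(vs))) mean(vs == 1, na.rm = TRUE) else NA_real_,
        stringsAsFactors = FALSE)
    } else addCat(f, ec[[f]], es[[f]], factorLevels(f))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport:", length(object@fits), "models over",
      object@provenance$n_families_analyzed, "families (",
      nrow(object@exclusions), "excluded )\n")
  cols <- c("model", "term", "rf_or", "prs_or", "ror", "interaction_p")
  r <- object@results[, intersect(cols, names(object@results))]
  isNum <- vapply(r, is.numeric, TRUE)
  r[isNum] <- lapply(r[isNum], function(v) round(v, 3))
  print(utils::head(r, 20), row.names = FALSE)
  if (nrow(object@results) > 20) cat("  ...\n")
})
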