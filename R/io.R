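# Readers and writers for the pipeline's plain-text formats.

#' Read a SNP weight panel from TSV
#'
#' Expects header columns `snp_id`, `risk_allele`, `odds_ratio` and
#' optionally `allele_freq`; extra columns are ignored.
#'
#' @param path TSV file path.
#' @return A [SnpWeightPanel-class].
#' @export
readWeightPanel <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "risk_allele", "odds_ratio")
  if (!all(need %in% names(d)))
    stopf("weight panel must have columns: %s", paste(need, collapse = ", "))
  snpWeightPanel(d$snp_id, d$risk_allele, d$odds_ratio,
                 alleleFreq = if ("allele_freq" %in% names(d)) d$allele_freq)
}

#' @describeIn readWeightPanel Write a panel back to TSV.
#' @param panel A [SnpWeightPanel-class].
#' @export
writeWeightPanel <- function(panel, path) {
  w <- panel@weights
  utils::write.table(w[setdiff(names(w), "log_or")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide dosage matrix from TSV
#'
#' Rows are subjects (`subject_id` column), remaining columns are markers
#' with risk-allele dosages in \[0, 2\].
#'
#' @param path TSV file path.
#' @return data.frame with `subject_id` plus one numeric column per marker.
#' @export
readDosageMatrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(d)) stopf("dosage matrix must have a subject_id column")
  if (anyDuplicated(d$subject_id)) stopf("duplicate subject_id in dosage matrix")
  d
}

#' @describeIn readDosageMatrix Write a dosage matrix to TSV.
#' @param dosages data.frame as returned by `readDosageMatrix`.
#' @export
writeDosageMatrix <- function(dosages, path) {
  utils::write.table(dosages, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read risk-allele dosages from a VCF
#'
#' Extracts per-subject dosages for the panel markers from a VCF: the `DS`
#' FORMAT field when present, otherwise the ALT-allele count of the `GT`
#' field.  Dosages are oriented to the panel's risk allele: when the risk
#' allele is REF rather than ALT the dosage is flipped (`2 - dosage`), with
#' a per-marker message; markers whose risk allele matches neither REF nor
#' ALT raise an error.  Requires the `vcfR` package.
#'
#' @param path VCF file (plain or bgzipped).
#' @param panel A [SnpWeightPanel-class]; variant IDs are matched against
#'   `snp_id`.
#' @return data.frame with `subject_id` plus one column per panel marker
#'   found in the file.
#' @export
readDosageVcf <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("readDosageVcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- v@fix[, c("ID", "REF", "ALT"), drop = FALSE]
  fix <- data.frame(ID = fm[, "ID"], REF = fm[, "REF"], ALT = fm[, "ALT"],
                    stringsAsFactors = FALSE)
  idx <- which(fix$ID %in% snpIds(panel))
  if (!length(idx)) stopf("no panel markers found in VCF")
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    D <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    D <- matrix(vapply(gsub("[|]", "/", gt), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "/")[[1]]) > 0)
    }, numeric(1)), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  }
  D <- D[idx, , drop = FALSE]
  fix <- fix[idx, , drop = FALSE]
  risk <- panel@weights$risk_allele[match(fix$ID, snpIds(panel))]
  for (i in seq_along(idx)) {
    if (risk[i] == fix$ALT[i]) next
    if (risk[i] == fix$REF[i]) {
      D[i, ] <- 2 - D[i, ]
      message("readDosageVcf: flipped dosage orientation for ", fix$ID[i],
              " (risk allele is REF)")
    } else {
      stopf("marker %s: risk allele %s matches neither REF (%s) nor ALT (%s)",
            fix$ID[i], risk[i], fix$REF[i], fix$ALT[i])
    }
  }
  out <- data.frame(subject_id = colnames(D), t(D), check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  names(out) <- c("subject_id", fix$ID)
  out
}

pedigreeRoles <- c("case", "control_sister", "father", "mother")

#' Read a pedigree/availability table from TSV
#'
#' Columns: `family_id`, `subject_id`, `role` (one of case, control_sister,
#' father, mother), `birth_order_rank` (1 = elder, among the two sisters),
#' `genotyped` (0/1), `exposure` (0/1); optionally `invasive`, `er_pos` and
#' `index_age` on case rows.  Exactly one case per family and at most one of
#' each other role are enforced.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
readPedigree <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "subject_id", "role", "birth_order_rank",
            "genotyped", "exposure")
  if (!all(need %in% names(d)))
    stopf("pedigree must have columns: %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(d$role), pedigreeRoles)
  if (length(bad)) stopf("unknown pedigree role(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(d$subject_id)) stopf("duplicate subject_id in pedigree")
  perFam <- table(d$family_id, d$role)
  if (any(perFam[, "case"] != 1))
    stopf("every family must have exactly one case")
  if (any(perFam[, setdiff(colnames(perFam), "case")] > 1))
    stopf("at most one control_sister, father and mother per family")
  for (cc in c("invasive", "er_pos", "index_age"))
    if (!cc %in% names(d)) d[[cc]] <- NA
  d
}

#' Read a wide exposure table from CSV
#'
#' One row per subject (`subject_id`), one column per risk factor in the
#' [exposureFactors()] layout plus `index_age`.  Category labels are
#' validated against the data dictionary.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
readExposures <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(d)) stopf("exposure table must have a subject_id column")
  dict <- exposureFactors()
  miss <- setdiff(dict$name, names(d))
  if (length(miss)) stopf("exposure table missing factor column(s): %s",
                          paste(miss, collapse = ", "))
  for (f in dict$name[dict$type %in% c("ordered", "nominal")]) {
    v <- d[[f]]
    bad <- setdiff(unique(v[!is.na(v)]), factorLevels(f))
    if (length(bad)) stopf("unknown %s label(s): %s", f, paste(bad, collapse = ", "))
  }
  d
}

#' Write a simulated dataset as pipeline input files
#'
#' Emits `panel.tsv`, `dosages.tsv`, `pedigree.tsv`, `exposures.csv` and
#' `truth.json` into `dir`; the files round-trip losslessly through the
#' pipeline readers and are byte-identical across runs with the same seed.
#'
#' @param ds A [SimulatedDataset-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(panel = file.path(dir, "panel.tsv"),
         dosages = file.path(dir, "dosages.tsv"),
         pedigree = file.path(dir, "pedigree.tsv"),
         exposures = file.path(dir, "exposures.csv"),
         truth = file.path(dir, "truth.json"))
  pw <- ds@truth$panel
  utils::write.table(pw[setdiff(names(pw), "log_or")], p["panel"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds@genotypes, p["dosages"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds@pedigree, p["pedigree"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(ds@exposures, p["exposures"], row.names = FALSE)
  jsonlite::write_json(ds@truth[setdiff(names(ds@truth), "panel")],
                       p["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(p)
}

#' Read a dataset from pipeline input files
#'
#' Counterpart of [writeDataset()]: reads the four input files (the truth
#' sidecar is optional) and returns them in the in-memory container the
#' analysis functions accept.
#'
#' @param dir directory holding `panel.tsv`, `dosages.tsv`, `pedigree.tsv`
#'   and `exposures.csv`.
#' @return A [SimulatedDataset-class] (truth empty unless `truth.json`
#'   exists).
#' @export
readDataset <- function(dir) {
  panel <- readWeightPanel(file.path(dir, "panel.tsv"))
  truth <- list(panel = panel@weights)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj))
    truth <- c(jsonlite::read_json(tj, simplifyVector = TRUE),
               list(panel = panel@weights))
  new("SimulatedDataset",
      pedigree = readPedigree(file.path(dir, "pedigree.tsv")),
      genotypes = readDosageMatrix(file.path(dir, "dosages.tsv")),
      exposures = readExposures(file.path(dir, "exposures.csv")),
      truth = truth)
}

#' Write an analysis report to disk
#'
#' Emits `results.tsv` (the model table), `summary.tsv` (case/control
#' marginals), `exclusions.tsv` (per-family accounting) and `models.json`
#' (full coefficients, covariance and convergence diagnostics per model).
#' Outputs are deterministic: re-running the same configuration on the same
#' inputs reproduces the files byte for byte.
#'
#' @param report An [AnalysisReport-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(results = file.path(dir, "results.tsv"),
         summary = file.path(dir, "summary.tsv"),
         exclusions = file.path(dir, "exclusions.tsv"),
         models = file.path(dir, "models.json"))
  utils::write.table(report@results, p["results"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report@summary, p["summary"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report@exclusions, p["exclusions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  side <- lapply(report@fits, function(f) list(
    coefficients = as.list(coef(f)), vcov = unname(vcov(f)),
    loglik = f@loglik, converged = f@converged, iterations = f@iterations,
    separation = f@separation, unidentifiable = f@unidentifiable,
    n_sets = f@nSets, n_dropped = f@nDropped))
  jsonlite::write_json(list(provenance = report@provenance, models = side),
                       p["models"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(p)
}
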