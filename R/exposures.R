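#' The risk-factor data dictionary
#'
#' Fixed vocabulary for the 14 analysed risk factors: variable names used in
#' wide exposure tables, variable type and, for categorical factors, the
#' ordered level labels.  Binary factors are stored 0/1; continuous factors
#' are numeric; categorical factors use exactly these labels.
#'
#' `bmi30` is defined only for women premenopausal at the index age;
#' `afb_cont`, `last_birth_within5` and `breastfeeding` only for parous
#' women (`NA` otherwise).  `hbc_years` is defined for all subjects, with
#' never-users falling in the lowest (`"<2"`) category.
#'
#' @return data.frame with columns `name`, `type` (`continuous`, `binary`,
#'   `ordered`, `nominal`) and `label`.
#' @export
exposureFactors <- function() {
  data.frame(
    name = c("hbc_ever", "hbc_within5", "last_birth_within5", "breastfeeding",
             "premenopausal", "height", "bmi30", "age_menarche", "afb_cont",
             "smoking", "alcohol", "hbc_years", "parity", "afb_cat"),
    type = c("binary", "binary", "binary", "binary", "binary",
             "continuous", "continuous", "continuous", "continuous",
             "nominal", "ordered", "ordered", "ordered", "ordered"),
    label = c("Ever Use Hormonal Birth Control",
              "Hormonal Birth Control Use within 5 years",
              "Last Birth within 5 years", "Breastfeeding among Parous",
              "Pre-menopause", "Height", "BMI at 30 among Pre-menopausal",
              "Age at Menarche", "Age at First Birth among Parous",
              "Smoking", "Alcohol", "Years Using Hormonal Birth Control",
              "Parity", "Age at First Birth"),
    stringsAsFactors = FALSE)
}

#' @describeIn exposureFactors Ordered level labels for a categorical factor.
#' @param name factor name from the dictionary.
#' @export
factorLevels <- function(name) {
  switch(name,
         smoking = c("never", "former", "current"),
         alcohol = c("never", "<1/day", ">=1/day"),
         hbc_years = c("<2", "2-<10", ">=10"),
         parity = c("0", "1", "2", "3+"),
         afb_cat = c("nulliparous", "<=20", "20-25", "25-30", ">30"),
         stopf("factor '%s' is not categorical", name))
}

factorType <- function(name) {
  d <- exposureFactors()
  i <- match(name, d$name)
  if (is.na(i)) stopf("unknown risk factor '%s'", name)
  d$type[i]
}

# integer trend scores 0, 1, 2, ... over the ordered levels
trendScore <- function(values, name) {
  lev <- factorLevels(name)
  idx <- match(as.character(values), lev)
  if (any(is.na(idx) & !is.na(values)))
    stopf("unknown category label for '%s': %s", name,
          paste(unique(values[is.na(idx) & !is.na(values)]), collapse = ", "))
  idx - 1L
}

#' Build an exposure event history
#'
#' Light constructor for the per-subject event history consumed by
#' [alignExposure()].  Time-fixed quantities (height, age at menarche) are
#' scalars; time-dependent exposures are event ages.
#'
#' @param height height (continuous; the analysis convention is inches).
#' @param ageMenarche age at menarche, years.
#' @param bmi30 self-reported BMI at age 30 (used only while premenopausal).
#' @param smoking,alcohol category labels from [factorLevels()].
#' @param menopauseAge age at menopause, `NA` if none.
#' @param birthAges numeric vector of ages at each live birth (may be empty).
#' @param breastfed logical, ever breastfed (parous women).
#' @param hbcIntervals two-column matrix or data.frame of hormonal birth
#'   control use intervals `(start_age, stop_age)`; may have zero rows.
#' @return list of class `exposure_history`.
#' @export
exposureHistory <- function(height = NA_real_, ageMenarche = NA_real_,
                            bmi30 = NA_real_, smoking = "never",
                            alcohol = "never", menopauseAge = NA_real_,
                            birthAges = numeric(), breastfed = NA,
                            hbcIntervals = NULL) {
  if (is.null(hbcIntervals)) hbcIntervals <- matrix(numeric(), ncol = 2)
  hbcIntervals <- as.matrix(hbcIntervals)
  if (ncol(hbcIntervals) != 2) stopf("hbcIntervals must have two columns (start, stop)")
  h <- list(height = height, age_menarche = ageMenarche, bmi30 = bmi30,
            smoking = smoking, alcohol = alcohol, menopause_age = menopauseAge,
            birth_ages = sort(as.numeric(birthAges)), breastfed = breastfed,
            hbc_intervals = hbcIntervals)
  class(h) <- "exposure_history"
  h
}

validateHistory <- function(h) {
  if (any(h$birth_ages < 0)) stopf("birth ages must be non-negative")
  iv <- h$hbc_intervals
  if (nrow(iv)) {
    if (any(iv < 0)) stopf("hormonal birth control interval ages must be non-negative")
    if (any(iv[, 2] < iv[, 1])) stopf("hormonal birth control intervals must have start <= stop")
  }
  if (!is.na(h$menopause_age) && !is.na(h$age_menarche) &&
      h$menopause_age < h$age_menarche)
    stopf("menopause recorded before menarche")
  invisible(h)
}

#' Align an exposure history to the case's index age
#'
#' Evaluates every time-dependent risk factor as of the proband's age at
#' diagnosis (the index age), so that both sisters have comparable exposure
#' opportunity: events after the index age are ignored, recency windows
#' ("within 5 years") are evaluated against the index age, and cumulative
#' quantities (parity, years of hormonal birth control use) are truncated at
#' the index age.  Time-fixed factors pass through.
#'
#' The operation is idempotent and monotone in `indexAge` for cumulative
#' quantities: parity at a smaller index age never exceeds parity at a
#' larger one.
#'
#' @param history An [exposureHistory()] object.
#' @param indexAge positive number, the case sister's age at diagnosis.
#' @return one-row data.frame in the wide exposure layout of
#'   [exposureFactors()], plus an `index_age` column.
#' @examples
#' h <- exposureHistory(height = 65, ageMenarche = 13, birthAges = c(24, 31),
#'                      breastfed = TRUE, hbcIntervals = cbind(18, 29))
#' alignExposure(h, indexAge = 28)  # parity 1, last birth within 5 years
#' @export
alignExposure <- function(history, indexAge) {
  if (!inherits(history, "exposure_history"))
    stopf("history must be built with exposureHistory()")
  if (!is.finite(indexAge) || indexAge <= 0) stopf("indexAge must be positive")
  validateHistory(history)
  h <- history

  pre <- is.na(h$menopause_age) || h$menopause_age > indexAge

  births <- h$birth_ages[h$birth_ages <= indexAge]
  parity_n <- length(births)
  parity <- factorLevels("parity")[pmin(parity_n, 3L) + 1L]
  afb <- if (parity_n) min(births) else NA_real_
  afb_cat <- if (parity_n == 0L) "nulliparous"
             else if (afb <= 20) "<=20"
             else if (afb <= 25) "20-25"
             else if (afb <= 30) "25-30"
             else ">30"
  last5 <- if (parity_n) as.integer(indexAge - max(births) < 5) else NA_integer_

  iv <- h$hbc_intervals
  yrs <- 0
  recent <- FALSE
  if (nrow(iv)) {
    use <- pmax(0, pmin(iv[, 2], indexAge) - pmin(iv[, 1], indexAge))
    yrs <- sum(use)
    recent <- any(pmin(iv[, 2], indexAge) > indexAge - 5 & iv[, 1] <= indexAge)
  }
  ever <- yrs > 0
  yrs_cat <- if (yrs < 2) "<2" else if (yrs < 10) "2-<10" else ">=10"

  data.frame(
    height = h$height,
    bmi30 = if (pre) h$bmi30 else NA_real_,
    smoking = h$smoking,
    alcohol = h$alcohol,
    premenopausal = as.integer(pre),
    age_menarche = h$age_menarche,
    hbc_ever = as.integer(ever),
    hbc_years = yrs_cat,
    hbc_within5 = as.integer(ever && recent),
    parity = parity,
    afb_cat = afb_cat,
    afb_cont = afb,
    last_birth_within5 = last5,
    breastfeeding = if (parity_n) as.integer(isTRUE(h$breastfed)) else NA_integer_,
    index_age = indexAge,
    stringsAsFactors = FALSE)
}
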