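## Immunologic HCL scores. 4-marker score: one point per positive marker
## among CD11c, CD25, CD103, CD123; a score >= 3 calls HCL. The CD26-extended
## 5-marker score adds one point for CD26 and calls HCL at >= 4 -- the unique
## threshold under which the three CD26-negative score-3 HCL-like patients
## are correctly rejected while every cHCL is retained (see the threshold
## audit in scoreThresholdAudit()).

.SCORE_THRESHOLD <- c(four = 3L, five = 4L)

#' Compute the 4-marker and 5-marker immunologic HCL scores
#'
#' For each patient, the score counts the constituent markers that pass the
#' positivity rule. A variant is evaluable only when every constituent
#' marker was assayed; unevaluable patients get an `NA` score and the
#' predicted label `unevaluable`. Predicted labels: 4-marker score >= 3 ->
#' `HCL`; 5-marker score >= 4 -> `HCL`.
#'
#' @param x A [SampleProfiles-class], or a character matrix of per-patient
#'   marker calls as returned by [patientMarkerCalls()].
#' @return `data.frame` with one row per patient: `patient_id`, `group`
#'   (when available), `score4`, `score5`, `evaluable4`, `evaluable5`,
#'   `predicted4`, `predicted5`.
#' @examples
#' calls <- rbind(P1 = c(CD11c = "positive", CD25 = "positive",
#'                       CD103 = "positive", CD123 = "positive",
#'                       CD26 = "positive"))
#' hclScore(calls)
#' @export
hclScore <- function(x) {
  groups <- NULL
  if (is(x, "SampleProfiles")) {
    cd <- SummarizedExperiment::colData(x)
    first <- !duplicated(cd$patient_id)
    groups <- setNames(cd$group[first], cd$patient_id[first])
    calls <- patientMarkerCalls(x)
  } else calls <- x
  scoreOne <- function(row, markers) {
    st <- row[markers]
    if (any(st == "untested")) return(c(NA_integer_, 0L))
    c(sum(st == "positive"), 1L)
  }
  res <- data.frame(patient_id = rownames(calls), stringsAsFactors = FALSE)
  if (!is.null(groups)) res$group <- unname(groups[res$patient_id])
  for (v in c("four", "five")) {
    mks <- scoreMarkers(v)
    s <- t(apply(calls, 1, scoreOne, markers = mks))
    sc <- as.integer(s[, 1]); ev <- s[, 2] == 1L
    pred <- ifelse(!ev, "unevaluable",
                   ifelse(sc >= .SCORE_THRESHOLD[[v]], "HCL", "not_HCL"))
    suf <- if (v == "four") "4" else "5"
    res[[paste0("score", suf)]] <- sc
    res[[paste0("evaluable", suf)]] <- ev
    res[[paste0("predicted", suf)]] <- pred
  }
  rownames(res) <- NULL
  res
}

#' Diagnostic evaluation of an immunologic score
#'
#' Confusion matrix, sensitivity and specificity of one score variant
#' against the reference diagnosis. Patients unevaluable for the scored
#' variant are excluded from numerator and denominator alike; percentages
#' are rounded half-up to one decimal.
#'
#' @param scores Output of [hclScore()].
#' @param truth Named character of reference groups per patient (defaults to
#'   the `group` column of `scores`).
#' @param variant `"four"` or `"five"`.
#' @param positiveGroups Groups that count as the positive (HCL) class.
#' @return A [DiagnosticReport-class].
#' @export
evaluateScore <- function(scores, truth = NULL,
                          variant = c("four", "five"),
                          positiveGroups = "cHCL") {
  variant <- match.arg(variant)
  if (is.null(truth)) {
    if (is.null(scores$group))
      stop("no truth labels: supply `truth` or a `group` column")
    truth <- setNames(scores$group, scores$patient_id)
  }
  suf <- if (variant == "four") "4" else "5"
  ev <- scores[[paste0("evaluable", suf)]]
  pred <- scores[[paste0("predicted", suf)]][ev]
  actual <- unname(truth[scores$patient_id[ev]]) %in% positiveGroups
  if (!any(actual))
    stop("no evaluable patients in the positive class")
  if (all(actual))
    stop("no evaluable patients in the negative class")
  tp <- sum(actual & pred == "HCL")
  fn <- sum(actual & pred == "not_HCL")
  fp <- sum(!actual & pred == "HCL")
  tn <- sum(!actual & pred == "not_HCL")
  new("DiagnosticReport", variant = variant,
      tp = as.integer(tp), fn = as.integer(fn),
      tn = as.integer(tn), fp = as.integer(fp),
      sensitivity = roundHalfUp(100 * tp / (tp + fn), 1),
      specificity = roundHalfUp(100 * tn / (tn + fp), 1),
      nExcluded = as.integer(sum(!ev)))
}

#' @describeIn evaluateScore Sensitivity accessor.
#' @param report A [DiagnosticReport-class].
#' @export
sensitivity <- function(report) report@sensitivity

#' @describeIn evaluateScore Specificity accessor.
#' @export
specificity <- function(report) report@specificity

#' Score histogram within a diagnosis group
#'
#' Counts of each observed score value among the evaluable patients of one
#' group (or set of groups).
#'
#' @param scores Output of [hclScore()].
#' @param groups Group label(s) to keep; `NULL` keeps all patients.
#' @param variant `"four"` or `"five"`.
#' @return Named integer vector (score value -> count); empty for an empty
#'   selection.
#' @export
scoreDistribution <- function(scores, groups = NULL,
                              variant = c("four", "five")) {
  variant <- match.arg(variant)
  suf <- if (variant == "four") "4" else "5"
  keep <- scores[[paste0("evaluable", suf)]]
  if (!is.null(groups)) keep <- keep & scores$group %in% groups
  s <- scores[[paste0("score", suf)]][keep]
  if (!length(s)) return(setNames(integer(0), character(0)))
  tab <- table(s)
  setNames(as.integer(tab), names(tab))
}

#' Audit all call thresholds of the 5-marker score
#'
#' For every threshold t in 1..5, computes sensitivity and specificity of
#' the rule "score5 >= t -> HCL" over patients evaluable for the 5-marker
#' variant. Documents that >= 4 is the unique threshold achieving 100
#' percent sensitivity and specificity simultaneously on the fixture
#' cohort.
#'
#' @inheritParams evaluateScore
#' @return `data.frame` with columns `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
scoreThresholdAudit <- function(scores, truth = NULL,
                                positiveGroups = "cHCL") {
  if (is.null(truth)) truth <- setNames(scores$group, scores$patient_id)
  ev <- scores$evaluable5
  s <- scores$score5[ev]
  actual <- unname(truth[scores$patient_id[ev]]) %in% positiveGroups
  out <- lapply(1:5, function(t) {
    pred <- s >= t
    data.frame(threshold = t,
               sensitivity = roundHalfUp(100 * sum(actual & pred) /
                                           sum(actual), 1),
               specificity = roundHalfUp(100 * sum(!actual & !pred) /
                                           sum(!actual), 1))
  })
  do.call(rbind, out)
}
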