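## S4 class definitions and validity. Accessors live next to the module code
## that produces each class.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' CohortConfig: calibration of the synthetic cohort generator
#'
#' Holds the group-specific calibration used by [generateCohort()] and
#' [generateSurvival()]: marker positivity frequencies, intensity-class
#' profiles, log-normal fluorescence parameters per intensity class, genotype
#' frequencies, assay-tested fractions, tumor infiltration, blood counts,
#' CD4/CD8 T-cell ratio and exponential survival parameters. Build one with
#' [defaultConfig()] (cohort-calibrated defaults) and adjust via
#' [configUpdate()].
#'
#' @slot groupSizes Named integer, patients per diagnosis group.
#' @slot markerPositivity Per group, named probability per panel marker.
#' @slot intensityProfile Per group, per marker, probability over
#'   dim/moderate/bright classes used when the marker is positive.
#' @slot mfiClassParams Per intensity class (incl. `negative`),
#'   `c(meanlog, sdlog)` of the event-level log-normal fluorescence.
#' @slot genotypeProbs Per group, named mutation probability per gene.
#' @slot testedFractions Per group, named fraction of patients assayed per
#'   marker or gene (assays absent from the list default to 1).
#' @slot infiltrationParams Per group, `c(mean, sd)` of tumor infiltration
#'   (percent of lymphocytes).
#' @slot bloodCountParams Per group, 5x2 matrix (`ALC`, `AMC`, `ANC`, `PC`,
#'   `Hb` rows; `mean`, `sd` columns); counts in G/L, Hb in g/dL.
#' @slot tcellRatioParams Per group, `c(meanlog, sdlog)` of the CD4/CD8 ratio.
#' @slot survivalParams Per stratum, `c(median, censorProb)`; median in
#'   months of the exponential event-time distribution.
#' @slot eventsPerSample Number of cytometry events simulated per sample.
#' @slot positiveEventRate Fraction of tumor events drawn from the positive
#'   fluorescence component when a marker is positive.
#' @slot negativeEventRate Same, when the marker is negative.
#' @slot notes Named character; provenance note per calibration entry.
#' @slot seed Default generator seed.
#'
#' @aliases CohortConfig
#' @name CohortConfig-class
#' @export
setClass("CohortConfig", representation(
  groupSizes = "integer",
  markerPositivity = "list",
  intensityProfile = "list",
  mfiClassParams = "list",
  genotypeProbs = "list",
  testedFractions = "list",
  infiltrationParams = "list",
  bloodCountParams = "list",
  tcellRatioParams = "list",
  survivalParams = "list",
  eventsPerSample = "integer",
  positiveEventRate = "numeric",
  negativeEventRate = "numeric",
  notes = "character",
  seed = "integer"
))

.checkProbList <- function(x, what) {
  for (g in names(x)) {
    p <- unlist(x[[g]])
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      return(sprintf("%s[%s]: probabilities must lie in [0, 1]", what, g))
  }
  NULL
}

setValidity("CohortConfig", function(object) {
  msgs <- character()
  if (!all(.GROUPS %in% names(object@groupSizes)))
    msgs <- c(msgs, "groupSizes must name all diagnosis groups")
  if (any(object@groupSizes < 0L))
    msgs <- c(msgs, "group sizes must be >= 0")
  for (chk in list(.checkProbList(object@markerPositivity, "markerPositivity"),
                   .checkProbList(object@genotypeProbs, "genotypeProbs"),
                   .checkProbList(object@testedFractions, "testedFractions")))
    if (!is.null(chk)) msgs <- c(msgs, chk)
  if (object@eventsPerSample < 100L)
    msgs <- c(msgs, "eventsPerSample must be >= 100")
  for (s in names(object@survivalParams)) {
    p <- object@survivalParams[[s]]
    if (p[["median"]] <= 0 || p[["censorProb"]] < 0 || p[["censorProb"]] > 1)
      msgs <- c(msgs, sprintf("survivalParams[%s] invalid", s))
  }
  if (length(msgs)) msgs else TRUE
})

#' EventTable: per-cell fluorescence for one sample
#'
#' List-mode stand-in for one stained sample: an events-by-markers matrix of
#' nonnegative fluorescence values (arbitrary units; `NA` columns mark
#' markers not assayed for this sample) and a per-event population label
#' (`tumor_B`, `normal_B`, `T4`, `T8`, `other`).
#'
#' @slot sampleId Sample identifier.
#' @slot markers Marker names (column order of `values`).
#' @slot values Numeric matrix, events x markers.
#' @slot population Factor of per-event population labels.
#'
#' @aliases EventTable
#' @name EventTable-class
#' @export
setClass("EventTable", representation(
  sampleId = "character",
  markers = "character",
  values = "matrix",
  population = "factor"
))

setValidity("EventTable", function(object) {
  msgs <- character()
  if (ncol(object@values) != length(object@markers))
    msgs <- c(msgs, "one value column per marker required")
  if (nrow(object@values) != length(object@population))
    msgs <- c(msgs, "one population label per event row required")
  if (!all(levels(object@population) %in% .POPULATIONS))
    msgs <- c(msgs, "unknown population label")
  v <- object@values
  if (any(v[!is.na(v)] < 0))
    msgs <- c(msgs, "fluorescence values must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' HclCohort: patients, samples and event tables
#'
#' Container for one cohort: a patient table (diagnosis group, demographics,
#' light chain, genotype, blood counts, survival endpoints, and the per-marker
#' truth status laid down by the generator), a sample table, and one
#' [EventTable-class] per sample.
#'
#' @slot patients `data.frame`, one row per patient.
#' @slot samples `data.frame`, one row per sample.
#' @slot events Named list of [EventTable-class] objects (may be empty when
#'   the cohort was generated without event synthesis).
#'
#' @aliases HclCohort
#' @name HclCohort-class
#' @export
setClass("HclCohort", representation(
  patients = "data.frame",
  samples = "data.frame",
  events = "list"
))

setValidity("HclCohort", function(object) {
  msgs <- character()
  if (anyDuplicated(object@patients$patient_id))
    msgs <- c(msgs, "duplicate patient_id")
  if (nrow(object@samples) &&
      !all(object@samples$patient_id %in% object@patients$patient_id))
    msgs <- c(msgs, "every sample must reference an existing patient")
  if (length(object@events) &&
      !all(names(object@events) %in% object@samples$sample_id))
    msgs <- c(msgs, "every event table must reference an existing sample")
  if (!all(object@patients$group %in% .GROUPS))
    msgs <- c(msgs, "unknown diagnosis group")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn HclCohort-class Patient table accessor.
#' @param x,object An `HclCohort`.
#' @export
patientData <- function(x) x@patients

#' @describeIn HclCohort-class Sample table accessor.
#' @export
sampleData <- function(x) x@samples

#' @describeIn HclCohort-class Event-table list accessor.
#' @export
eventData <- function(x) x@events

setMethod("show", "HclCohort", function(object) {
  tab <- table(factor(object@patients$group, levels = .GROUPS))
  cat(sprintf("HclCohort: %d patients (%s), %d samples, %d event tables\n",
              nrow(object@patients),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              nrow(object@samples), length(object@events)))
})

#' SampleProfiles: per-sample marker summaries
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with markers as rows and samples as columns. Assays: `percentPositive`
#' (percent of tumor-B events above the event cutoff; `NA` = marker not
#' assayed), `mfi` (median fluorescence of tumor-B events) and
#' `intensityClass` (`negative`/`dim`/`moderate`/`bright`). Column data carry
#' `patient_id`, `group`, `infiltration_pct` (tumor-B percent of
#' lymphocytes), `pct_abnormal_all` (tumor-B percent of all events),
#' `cd4_cd8_ratio` and `cd4_cd8_stratum` (`gt2`/`le2`).
#'
#' Built by [summarizeCohort()].
#'
#' @aliases SampleProfiles
#' @name SampleProfiles-class
#' @export
setClass("SampleProfiles", contains = "SummarizedExperiment")

setValidity("SampleProfiles", function(object) {
  need <- c("percentPositive", "mfi", "intensityClass")
  if (!all(need %in% names(SummarizedExperiment::assays(object))))
    return("assays percentPositive, mfi and intensityClass are required")
  pp <- SummarizedExperiment::assay(object, "percentPositive")
  if (any(pp[!is.na(pp)] < 0 | pp[!is.na(pp)] > 100))
    return("percentPositive must lie in [0, 100]")
  TRUE
})

#' FeatureMatrix: samples-by-features input to PCA
#'
#' @slot sampleIds,featureNames Row and column names of `values`.
#' @slot values Numeric matrix, mean-imputed where `missingMask` is `TRUE`.
#' @slot variant One of `"markers13"`, `"markers4_geno"`,
#'   `"markers4_geno_blood"`.
#' @slot missingMask Logical matrix marking imputed cells.
#' @slot groups Named character, diagnosis group per sample.
#'
#' @aliases FeatureMatrix
#' @name FeatureMatrix-class
#' @export
setClass("FeatureMatrix", representation(
  sampleIds = "character",
  featureNames = "character",
  values = "matrix",
  variant = "character",
  missingMask = "matrix",
  groups = "character"
))

setValidity("FeatureMatrix", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), dim(object@missingMask)))
    msgs <- c(msgs, "values and missingMask must have identical dimensions")
  if (nrow(object@values) != length(object@sampleIds) ||
      ncol(object@values) != length(object@featureNames))
    msgs <- c(msgs, "dimnames lengths must match the matrix")
  if (anyNA(object@values))
    msgs <- c(msgs, "values must be imputed, not NA")
  if (length(msgs)) msgs else TRUE
})

#' PCAModel: standardized principal component decomposition
#'
#' @slot variant Feature-set variant the model was fitted on.
#' @slot center,scale Per-feature standardization parameters.
#' @slot loadings Features x components rotation matrix (orthonormal
#'   columns; sign fixed so each component's largest-magnitude loading is
#'   positive).
#' @slot scores Samples x components coordinates.
#' @slot explainedPct Percent of variance per component (sums to 100 over
#'   all components).
#' @slot groups Named character, diagnosis group per sample.
#' @slot droppedFeatures Zero-variance features removed before fitting.
#'
#' @aliases PCAModel
#' @name PCAModel-class
#' @export
setClass("PCAModel", representation(
  variant = "character",
  center = "numeric",
  scale = "numeric",
  loadings = "matrix",
  scores = "matrix",
  explainedPct = "numeric",
  groups = "character",
  droppedFeatures = "character"
))

setValidity("PCAModel", function(object) {
  if (abs(sum(object@explainedPct) - 100) > 1e-6)
    return("explainedPct must sum to 100")
  TRUE
})

#' @describeIn PCAModel-class Component scores accessor.
#' @param x A `PCAModel`.
#' @export
pcaScores <- function(x) x@scores

#' @describeIn PCAModel-class Loadings accessor.
#' @export
pcaLoadings <- function(x) x@loadings

#' @describeIn PCAModel-class Explained-variance accessor (percent).
#' @export
explainedPct <- function(x) x@explainedPct

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel (%s): %d samples x %d features, PC1 %.1f%%, PC2 %.1f%%\n",
              object@variant, nrow(object@scores), length(object@center),
              object@explainedPct[1],
              if (length(object@explainedPct) > 1) object@explainedPct[2] else 0))
})

#' ConcentrationEllipse: per-group 90 percent ellipse in PC1-PC2
#'
#' Normal-theory concentration ellipse of one diagnosis group in component
#' space: a point lies inside iff its squared Mahalanobis distance from the
#' group mean is at most the chi-square quantile at `level` with 2 df.
#'
#' @slot group Group label.
#' @slot center Mean in PC1-PC2.
#' @slot covariance 2x2 sample covariance.
#' @slot level Coverage level (default 0.90).
#' @slot n Number of samples the ellipse was fitted on.
#'
#' @aliases ConcentrationEllipse
#' @name ConcentrationEllipse-class
#' @export
setClass("ConcentrationEllipse", representation(
  group = "character",
  center = "numeric",
  covariance = "matrix",
  level = "numeric",
  n = "integer"
))

setValidity("ConcentrationEllipse", function(object) {
  msgs <- character()
  S <- object@covariance
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
    msgs <- c(msgs, "covariance must be symmetric")
  if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
    msgs <- c(msgs, "covariance must be positive definite")
  if (object@level <= 0 || object@level >= 1)
    msgs <- c(msgs, "level must lie in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' DiagnosticReport: confusion matrix of an immunologic score
#'
#' Diagnostic evaluation of one score variant against the reference group
#' labels, on the evaluable-patient denominator (patients missing any
#' constituent marker of the variant are excluded from numerator and
#' denominator alike).
#'
#' @slot variant `"four"` or `"five"`.
#' @slot tp,fn,tn,fp Confusion-matrix counts.
#' @slot sensitivity,specificity Percent, rounded half-up to one decimal.
#' @slot nExcluded Patients excluded as unevaluable.
#'
#' @aliases DiagnosticReport
#' @name DiagnosticReport-class
#' @export
setClass("DiagnosticReport", representation(
  variant = "character",
  tp = "integer", fn = "integer", tn = "integer", fp = "integer",
  sensitivity = "numeric", specificity = "numeric",
  nExcluded = "integer"
))

setMethod("show", "DiagnosticReport", function(object) {
  cat(sprintf(paste0(
    "Immunologic score (%s-marker variant)\n",
    "  TP=%d FN=%d TN=%d FP=%d (unevaluable excluded: %d)\n",
    "  sensitivity %.1f%%  specificity %.1f%%\n"),
    object@variant, object@tp, object@fn, object@tn, object@fp,
    object@nExcluded, object@sensitivity, object@specificity))
})

#' KMCurve: product-limit survival estimate
#'
#' @slot time Distinct event times, strictly increasing.
#' @slot surv Survival probability at each event time (nonincreasing).
#' @slot nRisk Number at risk just before each event time.
#' @slot nEvent Events at each event time.
#' @slot n Total subjects.
#'
#' @aliases KMCurve
#' @name KMCurve-class
#' @export
setClass("KMCurve", representation(
  time = "numeric", surv = "numeric",
  nRisk = "integer", nEvent = "integer", n = "integer"
))

setValidity("KMCurve", function(object) {
  msgs <- character()
  if (is.unsorted(object@time, strictly = TRUE))
    msgs <- c(msgs, "event times must be strictly increasing")
  if (any(diff(object@surv) > 1e-12))
    msgs <- c(msgs, "survival must be nonincreasing")
  if (length(object@surv) && (any(object@surv < 0) || any(object@surv > 1)))
    msgs <- c(msgs, "survival must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "KMCurve", function(object) {
  med <- kmMedian(object)
  cat(sprintf("KMCurve: n=%d, %d event times, median %s months\n",
              object@n, length(object@time),
              if (is.na(med)) "not reached" else sprintf("%.1f", med)))
})

#' LogRankResult: two-group log-rank test
#'
#' @slot chiSquare Test statistic (1 df).
#' @slot df Degrees of freedom (1).
#' @slot pValue Two-sided p-value from the chi-square tail.
#'
#' @aliases LogRankResult
#' @name LogRankResult-class
#' @export
setClass("LogRankResult", representation(
  chiSquare = "numeric", df = "integer", pValue = "numeric"
))

setMethod("show", "LogRankResult", function(object) {
  cat(sprintf("Log-rank test: chi-square = %.4f (%d df), p = %.4g\n",
              object@chiSquare, object@df, object@pValue))
})
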