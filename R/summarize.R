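## Event-level -> per-sample marker summaries: percent positive, MFI
## (median fluorescence of tumor-B events), intensity class, tumor
## infiltration and CD4/CD8 T-cell ratio.

.intensityClassFromMfi <- function(mfi) {
  if (mfi < 500) "dim" else if (mfi > 1000) "bright" else "moderate"
}

#' Event cutoff for marker positivity
#'
#' The event-level gate above which a single cell counts as expressing the
#' marker. The default strategy takes a high quantile (99th percentile) of
#' the sample's own normal-B events for that marker, using the normal B-cell
#' population as internal negative reference; `"fixed"` uses a constant.
#'
#' @param events An [EventTable-class].
#' @param marker Marker name.
#' @param strategy `"percentile"` or `"fixed"`.
#' @param percentile Quantile of normal-B fluorescence (default 0.99).
#' @param fixedCutoff Constant cutoff when `strategy = "fixed"`.
#' @return Numeric scalar.
#' @export
eventCutoff <- function(events, marker,
                        strategy = c("percentile", "fixed"),
                        percentile = 0.99, fixedCutoff = 150) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed") return(fixedCutoff)
  if (!marker %in% events@markers)
    stop("marker not in panel: ", marker)
  ref <- events@values[events@population == "normal_B", marker]
  ref <- ref[!is.na(ref)]
  if (!length(ref))
    stop("no normal_B events to derive the percentile cutoff for ", marker)
  unname(quantile(ref, percentile, type = 7))
}

#' Summarize one marker on one sample
#'
#' Computes, over the tumor-B events of a sample: the percent of events with
#' fluorescence above the event cutoff, the MFI (median fluorescence), and
#' the intensity class. The class follows the MFI bands dim (< 500),
#' moderate (500-1000) and bright (> 1000) when the sample-level positivity
#' rule (>= 20 percent of abnormal cells) is met, and is `negative`
#' otherwise regardless of MFI.
#'
#' @param events An [EventTable-class] with at least one tumor-B event.
#' @param marker Marker name.
#' @param eventCutoff Event-level fluorescence cutoff (see [eventCutoff()]).
#' @return `list(marker, percent_positive, mfi, n_events, intensity_class)`.
#' @examples
#' tbl <- new("EventTable", sampleId = "s", markers = "CD25",
#'            values = matrix(c(100, 499, 700), ncol = 1,
#'                            dimnames = list(NULL, "CD25")),
#'            population = factor(rep("tumor_B", 3),
#'                                levels = eventPopulations()))
#' summarizeMarker(tbl, "CD25", eventCutoff = 50)  # mfi 499, class dim
#' @export
summarizeMarker <- function(events, marker, eventCutoff) {
  if (!marker %in% events@markers)
    stop("marker not in panel: ", marker)
  x <- events@values[events@population == "tumor_B", marker]
  if (!length(x))
    stop("no tumor_B events in sample ", events@sampleId)
  if (all(is.na(x)))
    return(list(marker = marker, percent_positive = NA_real_,
                mfi = NA_real_, n_events = length(x),
                intensity_class = NA_character_))
  pct <- 100 * mean(x > eventCutoff)
  mfi <- median(x)                      # even count: mean of the two central
  cls <- if (pct >= 20) .intensityClassFromMfi(mfi) else "negative"
  list(marker = marker, percent_positive = pct, mfi = mfi,
       n_events = length(x), intensity_class = cls)
}

#' Sample-level marker positivity rule
#'
#' A marker is positive when at least 20 percent of the abnormal (tumor-B)
#' cells express it; the boundary is inclusive.
#'
#' @param percentPositive Numeric vector of percent-positive values (or a
#'   list as returned by [summarizeMarker()]).
#' @return Logical vector (`NA` where the marker was not assayed).
#' @examples
#' markerPositive(c(20, 19.9, NA))  # TRUE FALSE NA
#' @export
markerPositive <- function(percentPositive) {
  if (is.list(percentPositive))
    percentPositive <- percentPositive$percent_positive
  percentPositive >= 20
}

#' Tumor infiltration of a sample
#'
#' Percent of abnormal (tumor-B) cells among total lymphocytes (tumor-B +
#' normal-B + T4 + T8); `other` events are excluded from the denominator.
#'
#' @param events An [EventTable-class].
#' @return Numeric percentage.
#' @export
tumorInfiltration <- function(events) {
  pop <- events@population
  lymph <- pop %in% c("tumor_B", "normal_B", "T4", "T8")
  if (!any(lymph)) stop("no lymphocyte events in sample ", events@sampleId)
  100 * sum(pop == "tumor_B") / sum(lymph)
}

#' CD4/CD8 T-cell ratio of a sample
#'
#' Ratio of T4 to T8 event counts, with the survival stratum cut at ratio
#' > 2 (strict).
#'
#' @param events An [EventTable-class].
#' @return `list(ratio, stratum)` with stratum `"gt2"` or `"le2"`.
#' @export
cd4cd8Ratio <- function(events) {
  n4 <- sum(events@population == "T4")
  n8 <- sum(events@population == "T8")
  if (n8 == 0)
    stop("ratio undefined: no T8 events in sample ", events@sampleId)
  r <- n4 / n8
  list(ratio = r, stratum = if (r > 2) "gt2" else "le2")
}

#' Summarize a whole cohort into per-sample marker profiles
#'
#' Applies [summarizeMarker()] to every panel marker of every sample and
#' assembles a [SampleProfiles-class] (markers x samples
#' SummarizedExperiment) with per-sample tumor infiltration, percent
#' abnormal of all events, and CD4/CD8 ratio in the column data.
#'
#' @param cohort An [HclCohort-class] with event tables.
#' @param cutoffStrategy,percentile,fixedCutoff Passed to [eventCutoff()].
#' @return A [SampleProfiles-class].
#' @export
summarizeCohort <- function(cohort, cutoffStrategy = c("percentile", "fixed"),
                            percentile = 0.99, fixedCutoff = 150) {
  cutoffStrategy <- match.arg(cutoffStrategy)
  if (!length(cohort@events))
    stop("cohort carries no event tables; regenerate with events = TRUE")
  mk <- panelMarkers()
  sids <- cohort@samples$sample_id
  sids <- sids[sids %in% names(cohort@events)]
  pp <- mfi <- matrix(NA_real_, length(mk), length(sids),
                      dimnames = list(mk, sids))
  cls <- matrix(NA_character_, length(mk), length(sids),
                dimnames = list(mk, sids))
  infil <- abn <- ratio <- setNames(numeric(length(sids)), sids)
  stratum <- setNames(character(length(sids)), sids)
  for (sid in sids) {
    ev <- cohort@events[[sid]]
    for (m in mk) {
      co <- if (all(is.na(ev@values[, m]))) NA_real_   # marker not assayed
            else eventCutoff(ev, m, cutoffStrategy, percentile, fixedCutoff)
      s <- summarizeMarker(ev, m, co)
      pp[m, sid] <- s$percent_positive
      mfi[m, sid] <- s$mfi
      cls[m, sid] <- s$intensity_class
    }
    infil[sid] <- tumorInfiltration(ev)
    abn[sid] <- 100 * sum(ev@population == "tumor_B") / length(ev@population)
    r <- tryCatch(cd4cd8Ratio(ev), error = function(e) NULL)
    ratio[sid] <- if (is.null(r)) NA_real_ else r$ratio
    stratum[sid] <- if (is.null(r)) NA_character_ else r$stratum
  }
  pidx <- match(cohort@samples$patient_id[match(sids, cohort@samples$sample_id)],
                cohort@patients$patient_id)
  cd <- S4Vectors::DataFrame(
    sample_id = sids,
    patient_id = cohort@patients$patient_id[pidx],
    group = cohort@patients$group[pidx],
    infiltration_pct = infil,
    pct_abnormal_all = abn,
    cd4_cd8_ratio = ratio,
    cd4_cd8_stratum = stratum,
    row.names = sids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(percentPositive = pp, mfi = mfi, intensityClass = cls),
    colData = cd)
  new("SampleProfiles", se)
}

#' Per-patient marker calls from sample profiles
#'
#' Reduces a [SampleProfiles-class] to one call per patient and marker:
#' `"positive"`, `"negative"` or `"untested"`, using each patient's first
#' sample (cohorts generated here carry one sample per patient).
#'
#' @param profiles A [SampleProfiles-class].
#' @return Character matrix, patients x markers.
#' @export
patientMarkerCalls <- function(profiles) {
  cd <- SummarizedExperiment::colData(profiles)
  first <- !duplicated(cd$patient_id)
  pp <- SummarizedExperiment::assay(profiles, "percentPositive")[, first,
                                                                 drop = FALSE]
  out <- ifelse(is.na(pp), "untested",
                ifelse(pp >= 20, "positive", "negative"))
  colnames(out) <- cd$patient_id[first]
  t(out)
}
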