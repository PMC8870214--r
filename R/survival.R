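## Survival endpoints and comparison. The product-limit estimator and the
## two-group log-rank test are implemented here from first principles;
## durations are in months (1 month = 30.4375 days).

.DAYS_PER_MONTH <- 30.4375

#' Compute TTNT, PFS and OS from date fields
#'
#' Endpoint definitions: TTNT runs from the ending date of the first
#' treatment to the date of second treatment (event) or last follow-up
#' (censored); OS from diagnosis to death (event) or last follow-up
#' (censored); PFS from diagnosis to the earliest of progression, relapse
#' or death (event), else last follow-up (censored). Durations are months
#' of 30.4375 days.
#'
#' @param dates A one-row `data.frame` (or list) with `Date`-coercible
#'   fields `diagnosis_date`, `last_followup`, and optionally
#'   `first_treatment_end`, `second_treatment`, `progression_date`,
#'   `relapse_date`, `death_date` (absent/`NA` = did not occur).
#' @return `data.frame` with one row per available endpoint: `endpoint`,
#'   `duration` (months), `event` (0/1).
#' @examples
#' computeEndpoints(list(diagnosis_date = "2010-01-01",
#'                       death_date = "2015-01-01",
#'                       last_followup = "2015-01-01"))
#' @export
computeEndpoints <- function(dates) {
  g <- function(f) {
    v <- dates[[f]]
    if (is.null(v) || is.na(v)) return(NA)
    as.Date(v)
  }
  months <- function(from, to) as.numeric(to - from) / .DAYS_PER_MONTH
  dx <- g("diagnosis_date"); fu <- g("last_followup")
  if (is.na(dx) || is.na(fu)) stop("diagnosis_date and last_followup required")
  out <- list()
  t1 <- g("first_treatment_end"); t2 <- g("second_treatment")
  if (!is.na(t1)) {
    if (!is.na(t2)) {
      if (t2 < t1) stop("second treatment precedes first treatment end")
      out$ttnt <- c(months(t1, t2), 1)
    } else out$ttnt <- c(months(t1, fu), 0)
  }
  death <- g("death_date")
  out$os <- if (!is.na(death)) c(months(dx, death), 1) else c(months(dx, fu), 0)
  cand <- c(g("progression_date"), g("relapse_date"), death)
  cand <- cand[!is.na(cand)]
  out$pfs <- if (length(cand)) c(months(dx, min(as.Date(cand, origin = "1970-01-01"))), 1)
             else c(months(dx, fu), 0)
  data.frame(endpoint = names(out),
             duration = vapply(out, `[`, numeric(1), 1),
             event = as.integer(vapply(out, `[`, numeric(1), 2)),
             row.names = NULL)
}

#' Kaplan-Meier product-limit estimator
#'
#' S(t) is the product over event times up to t of (1 - d/n), where d is
#' the number of events and n the number at risk just before that time.
#' Ties between events and censorings at the same time are resolved
#' events-first (the censored subjects remain in the risk set for that
#' time).
#'
#' @param duration Nonnegative durations in months (or a `data.frame` with
#'   columns `duration` and `event`, as from [generateSurvival()]).
#' @param event 0/1 event indicators.
#' @return A [KMCurve-class].
#' @examples
#' kmFit(c(1, 2, 3), c(1, 0, 1))  # S(1) = 2/3, S(3) = 1/3
#' @export
kmFit <- function(duration, event = NULL) {
  if (is.data.frame(duration)) {
    event <- duration$event
    duration <- duration$duration
  }
  if (length(duration) == 0L) stop("at least one subject required")
  if (any(duration < 0)) stop("negative duration")
  if (!all(event %in% c(0, 1))) stop("event flags must be 0/1")
  n <- length(duration)
  tev <- sort(unique(duration[event == 1]))
  nRisk <- nEvent <- integer(length(tev))
  surv <- numeric(length(tev))
  s <- 1
  for (i in seq_along(tev)) {
    nRisk[i] <- sum(duration >= tev[i])
    nEvent[i] <- sum(duration == tev[i] & event == 1)
    s <- s * (1 - nEvent[i] / nRisk[i])
    surv[i] <- s
  }
  new("KMCurve", time = tev, surv = surv, nRisk = nRisk, nEvent = nEvent,
      n = as.integer(n))
}

#' Median survival time of a fitted curve
#'
#' Smallest event time at which the survival estimate drops to 0.5 or
#' below; `NA` when the curve never reaches 0.5.
#'
#' @param curve A [KMCurve-class].
#' @return Months, or `NA_real_`.
#' @export
kmMedian <- function(curve) {
  i <- which(curve@surv <= 0.5 + 1e-12)
  if (!length(i)) return(NA_real_)
  curve@time[min(i)]
}

#' Two-group log-rank test
#'
#' At every distinct event time, the observed number of events in group A
#' is compared with its hypergeometric expectation given the pooled risk
#' set; the standardized sum of differences yields a chi-square statistic
#' with 1 df and a two-sided p-value from its upper tail.
#'
#' @param durationA,durationB Durations per group (each may be a
#'   `data.frame` with `duration`/`event` columns).
#' @param eventA,eventB 0/1 event indicators.
#' @return A [LogRankResult-class].
#' @export
logrank <- function(durationA, eventA = NULL, durationB, eventB = NULL) {
  if (is.data.frame(durationA)) {
    eventA <- durationA$event; durationA <- durationA$duration
  }
  if (is.data.frame(durationB)) {
    eventB <- durationB$event; durationB <- durationB$duration
  }
  if (!length(durationA) || !length(durationB))
    stop("both groups must be nonempty")
  dur <- c(durationA, durationB)
  evt <- c(eventA, eventB)
  grpA <- rep(c(TRUE, FALSE), c(length(durationA), length(durationB)))
  if (sum(evt) == 0) stop("no events in either group")
  tev <- sort(unique(dur[evt == 1]))
  ## risk sets via counting, vectorized over event times
  nAt <- vapply(tev, function(t) sum(dur >= t), numeric(1))
  nAt1 <- vapply(tev, function(t) sum(dur >= t & grpA), numeric(1))
  d <- vapply(tev, function(t) sum(dur == t & evt == 1), numeric(1))
  d1 <- vapply(tev, function(t) sum(dur == t & evt == 1 & grpA), numeric(1))
  e1 <- d * nAt1 / nAt
  keep <- nAt > 1
  v1 <- d[keep] * (nAt1[keep] / nAt[keep]) *
    (1 - nAt1[keep] / nAt[keep]) * (nAt[keep] - d[keep]) / (nAt[keep] - 1)
  V <- sum(v1)
  OminusE <- sum(d1 - e1)
  chi <- if (V > 0) OminusE^2 / V else 0
  new("LogRankResult", chiSquare = chi, df = 1L,
      pValue = pchisq(chi, df = 1, lower.tail = FALSE))
}
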