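## Synthetic cohort generation. All randomness flows through one RNG stream
## seeded at entry; a given (config, seed) pair is fully reproducible.

.testedFraction <- function(config, group, assay) {
  tf <- config@testedFractions[[group]]
  if (!is.null(tf) && assay %in% names(tf)) tf[[assay]] else 1
}

## Synthesize one sample's event matrix from the patient's per-marker truth.
## `status` is a named character vector over the panel (positive / negative /
## untested), `class` the intensity class for positive markers. Tumor events
## for a positive marker mix positiveEventRate of the class component with
## the negative component; all non-tumor populations draw from the negative
## component (the normal-B population acts as the internal negative
## reference for every panel marker).
.makeEventTable <- function(sampleId, status, class, infiltration, ratio,
                            config) {
  mk <- panelMarkers()
  n <- config@eventsPerSample
  lymphFrac <- 0.6
  pTum <- lymphFrac * infiltration / 100
  pOtherLymph <- lymphFrac - pTum
  pT <- 0.7 * pOtherLymph
  probs <- c(tumor_B = pTum,
             normal_B = 0.3 * pOtherLymph,
             T4 = pT * ratio / (1 + ratio),
             T8 = pT / (1 + ratio),
             other = 1 - lymphFrac)
  pop <- factor(sample(.POPULATIONS, n, replace = TRUE, prob = probs),
                levels = .POPULATIONS)
  isTum <- pop == "tumor_B"
  nTum <- sum(isTum)

  negPar <- config@mfiClassParams[["negative"]]
  meanlog <- matrix(negPar[["meanlog"]], n, length(mk),
                    dimnames = list(NULL, mk))
  sdlog <- matrix(negPar[["sdlog"]], n, length(mk))
  for (j in seq_along(mk)) {
    m <- mk[j]
    if (status[[m]] == "untested") next
    q <- if (status[[m]] == "positive") config@positiveEventRate
         else config@negativeEventRate
    cl <- if (status[[m]] == "positive") class[[m]] else "dim"
    hot <- isTum & (runif(n) < q)       # runif over all rows keeps the
    hot[!isTum] <- FALSE                # stream layout marker-major
    par <- config@mfiClassParams[[cl]]
    meanlog[hot, j] <- par[["meanlog"]]
    sdlog[hot, j] <- par[["sdlog"]]
  }
  values <- matrix(rlnorm(n * length(mk), meanlog = as.vector(meanlog),
                          sdlog = as.vector(sdlog)),
                   n, length(mk), dimnames = list(NULL, mk))
  values[, status[mk] == "untested"] <- NA_real_
  new("EventTable", sampleId = sampleId, markers = mk, values = values,
      population = pop)
}

.drawMarkerTruth <- function(config, group) {
  mk <- panelMarkers()
  status <- setNames(character(length(mk)), mk)
  class <- setNames(rep(NA_character_, length(mk)), mk)
  for (m in mk) {
    if (runif(1) > .testedFraction(config, group, m)) {
      status[[m]] <- "untested"
      next
    }
    if (runif(1) < config@markerPositivity[[group]][[m]]) {
      status[[m]] <- "positive"
      p <- config@intensityProfile[[group]][[m]]
      class[[m]] <- sample(names(p), 1, prob = p)
    } else status[[m]] <- "negative"
  }
  list(status = status, class = class)
}

## One (duration, event) draw: exponential event time with the stratum
## median, under independent exponential censoring whose rate is calibrated
## so that the expected censored fraction equals censorProb. Independence of
## the censoring time from the event time keeps the product-limit estimator
## consistent for the configured median.
.drawOne <- function(median, censorProb) {
  rate <- log(2) / median
  t <- rexp(1, rate)
  if (censorProb <= 0) return(c(t, 1))
  cns <- rexp(1, rate * censorProb / (1 - censorProb))
  if (cns < t) c(cns, 0) else c(t, 1)
}

#' Generate a synthetic cohort
#'
#' Draws patients, samples and (optionally) event-level cytometry tables with
#' the statistical structure encoded in a [CohortConfig-class]: per-patient
#' marker positivity is Bernoulli with the group frequency (independent
#' across markers), positive markers receive an intensity class from the
#' group profile, events are two-component log-normal mixtures so that
#' downstream summarization recovers the class, assay missingness follows
#' the tested fractions, and survival endpoints are exponential with the
#' configured stratum medians (TTNT stratified by the patient's CD4/CD8
#' ratio) under random censoring.
#'
#' The generated per-marker truth is kept in the patient table
#' (`<marker>_status`, `<marker>_class` columns) so that calibration can be
#' checked without event synthesis.
#'
#' @param config A [CohortConfig-class].
#' @param seed Integer seed; defaults to the config's.
#' @param events Synthesize event tables? Set `FALSE` for large calibration
#'   runs where only patient-level draws are needed.
#' @return An [HclCohort-class].
#' @examples
#' cfg <- configUpdate(defaultConfig(),
#'                     groupSizes = c(cHCL = 3L, vHCL_SDRPL = 2L,
#'                                    HCL_like_NOS = 0L),
#'                     eventsPerSample = 500L)
#' generateCohort(cfg, seed = 1)
#' @export
generateCohort <- function(config, seed = config@seed, events = TRUE) {
  validObject(config)
  withSeed(seed, {
    mk <- panelMarkers()
    rows <- list()
    evs <- list()
    samples <- list()
    k <- 0L
    for (g in .GROUPS) {
      ng <- config@groupSizes[[g]]
      if (ng == 0L) next
      for (i in seq_len(ng)) {
        k <- k + 1L
        pid <- sprintf("SIM-%s-%03d", g, i)
        sid <- sprintf("S-%s-%03d", g, i)
        truth <- .drawMarkerTruth(config, g)
        geno <- setNames(character(3), .GENES)
        for (gene in .GENES) {
          geno[[gene]] <- if (runif(1) > .testedFraction(config, g, gene))
            "untested"
          else if (runif(1) < config@genotypeProbs[[g]][[gene]]) "mutated"
          else "wild_type"
        }
        ip <- config@infiltrationParams[[g]]
        infil <- min(95, max(1, rnorm(1, ip[["mean"]], ip[["sd"]])))
        rp <- config@tcellRatioParams[[g]]
        ratio <- rlnorm(1, rp[["meanlog"]], rp[["sdlog"]])
        bcp <- config@bloodCountParams[[g]]
        bc <- pmax(0.01, rnorm(5, bcp[, "mean"], bcp[, "sd"]))
        names(bc) <- rownames(bcp)
        ttntStr <- if (ratio > 2) "ttnt_cd4cd8_gt2" else "ttnt_cd4cd8_le2"
        sv <- function(str) {
          p <- config@survivalParams[[str]]
          .drawOne(p[["median"]], p[["censorProb"]])
        }
        ttnt <- sv(ttntStr); os <- sv("os_all"); pfs <- sv("pfs_all")
        row <- data.frame(
          patient_id = pid, group = g,
          sex = sample(c("M", "F"), 1, prob = c(63, 19)),
          age_years = round(min(95, max(30, rnorm(1, 59.6, 14)))),
          light_chain = sample(c("kappa", "lambda", "undetectable"), 1,
                               prob = c(47, 31, 4)),
          ighv4_34 = "untested",
          stringsAsFactors = FALSE)
        row[paste0(.GENES)] <- as.list(geno)
        row[paste0(mk, "_status")] <- as.list(truth$status)
        row[paste0(mk, "_class")] <- as.list(truth$class)
        row[.ANALYTES] <- as.list(round(bc, 2))
        row$infiltration_pct <- infil
        row$cd4_cd8_ratio <- ratio
        row$ttnt_months <- ttnt[1]; row$ttnt_event <- as.integer(ttnt[2])
        row$os_months <- os[1]; row$os_event <- as.integer(os[2])
        row$pfs_months <- pfs[1]; row$pfs_event <- as.integer(pfs[2])
        rows[[k]] <- row
        samples[[k]] <- data.frame(
          sample_id = sid, patient_id = pid, tissue = "blood",
          timepoint = "diagnosis", device = "CANTO-II",
          stringsAsFactors = FALSE)
        if (events)
          evs[[sid]] <- .makeEventTable(sid, truth$status, truth$class,
                                        infil, ratio, config)
      }
    }
    new("HclCohort",
        patients = do.call(rbind, rows),
        samples = do.call(rbind, samples),
        events = evs)
  })
}

#' Generate event-time observations for one survival stratum
#'
#' Draws `n` exponential event times with the stratum's configured median
#' (rate = ln 2 / median) under independent exponential censoring calibrated
#' so that the expected censored fraction equals the stratum's censoring
#' probability (with `censorProb` 0, every observation is an event).
#'
#' @param stratum Name of a stratum in `config@survivalParams`, e.g.
#'   `"ttnt_cd4cd8_gt2"`.
#' @param n Number of observations.
#' @param config A [CohortConfig-class].
#' @param seed Integer seed.
#' @return `data.frame` with columns `duration` (months) and `event` (0/1).
#' @examples
#' generateSurvival("ttnt_cd23_pos", 5, defaultConfig(), seed = 1)
#' @export
generateSurvival <- function(stratum, n, config = defaultConfig(),
                             seed = config@seed) {
  if (!stratum %in% names(config@survivalParams))
    stop("unknown survival stratum: ", stratum)
  p <- config@survivalParams[[stratum]]
  if (n == 0L)
    return(data.frame(duration = numeric(0), event = integer(0)))
  withSeed(seed, {
    rate <- log(2) / p[["median"]]
    t <- rexp(n, rate)
    pc <- p[["censorProb"]]
    if (pc <= 0)
      return(data.frame(duration = t, event = rep(1L, n)))
    cns <- rexp(n, rate * pc / (1 - pc))
    data.frame(duration = pmin(t, cns), event = as.integer(t <= cns))
  })
}
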