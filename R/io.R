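## Tabular IO (CSV, UTF-8, header row, dot decimal) and the end-to-end
## pipeline. All stage outputs are plain CSV; the run manifest is JSON.

#' Write a cohort to CSV files
#'
#' Writes `patients.csv`, `samples.csv` and one `events/<sample_id>.csv`
#' per event table (marker columns plus a `population` column).
#'
#' @param cohort An [HclCohort-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort@patients, file.path(dir, "patients.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(cohort@samples, file.path(dir, "samples.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")
  if (length(cohort@events)) {
    dir.create(file.path(dir, "events"), showWarnings = FALSE)
    for (sid in names(cohort@events)) {
      ev <- cohort@events[[sid]]
      df <- as.data.frame(ev@values)
      df$population <- as.character(ev@population)
      write.csv(df, file.path(dir, "events", paste0(sid, ".csv")),
                row.names = FALSE, fileEncoding = "UTF-8")
    }
  }
  invisible(dir)
}

#' Read a patient table
#'
#' Typed reader for `patients.csv`: genotype columns are validated against
#' the mutated/wild_type/untested vocabulary (untested is an explicit
#' missing value, never imputed), duplicate patient identifiers are an
#' error, and unknown columns are preserved.
#'
#' @param path Path to `patients.csv`.
#' @return `data.frame`.
#' @export
readPatients <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("patient_id", "group") %in% names(df)))
    stop("patients file must carry patient_id and group columns")
  dup <- duplicated(df$patient_id)
  if (any(dup))
    stop("duplicate patient_id: ", paste(df$patient_id[dup], collapse = ", "))
  bad <- !df$group %in% .GROUPS
  if (any(bad))
    stop("unknown diagnosis group at line ", which(bad)[1] + 1L,
         ": ", df$group[which(bad)[1]])
  ## all-NA character columns (e.g. intensity classes of never-positive
  ## markers) come back logical from type inference; restore them
  for (cc in grep("_class$|_status$", names(df), value = TRUE))
    df[[cc]] <- as.character(df[[cc]])
  for (gene in intersect(.GENES, names(df))) {
    badg <- !df[[gene]] %in% c("mutated", "wild_type", "untested", NA)
    if (any(badg))
      stop("invalid ", gene, " value at line ", which(badg)[1] + 1L,
           ": ", df[[gene]][which(badg)[1]])
    df[[gene]][is.na(df[[gene]])] <- "untested"
  }
  df
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir Directory containing `patients.csv`, `samples.csv` and
#'   optionally `events/`.
#' @return An [HclCohort-class].
#' @export
readCohort <- function(dir) {
  patients <- readPatients(file.path(dir, "patients.csv"))
  samples <- read.csv(file.path(dir, "samples.csv"), stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8")
  evDir <- file.path(dir, "events")
  evs <- list()
  if (dir.exists(evDir)) {
    for (fp in list.files(evDir, pattern = "\\.csv$", full.names = TRUE)) {
      sid <- sub("\\.csv$", "", basename(fp))
      df <- read.csv(fp, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
      pop <- factor(df$population, levels = .POPULATIONS)
      df$population <- NULL
      vals <- as.matrix(df)
      rownames(vals) <- NULL
      evs[[sid]] <- new("EventTable", sampleId = sid,
                        markers = colnames(df),
                        values = vals, population = pop)
    }
  }
  new("HclCohort", patients = patients, samples = samples, events = evs)
}

#' Write sample profiles to CSV
#'
#' One row per sample x marker (percent positive, MFI, intensity class)
#' with the per-sample infiltration, abnormal-cell percentage and CD4/CD8
#' ratio repeated on each row.
#'
#' @param profiles A [SampleProfiles-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  pp <- SummarizedExperiment::assay(profiles, "percentPositive")
  mfi <- SummarizedExperiment::assay(profiles, "mfi")
  cls <- SummarizedExperiment::assay(profiles, "intensityClass")
  cd <- as.data.frame(SummarizedExperiment::colData(profiles))
  long <- do.call(rbind, lapply(colnames(pp), function(sid) {
    data.frame(sample_id = sid, marker = rownames(pp),
               percent_positive = pp[, sid], mfi = mfi[, sid],
               intensity_class = cls[, sid],
               cd[sid, c("patient_id", "group", "infiltration_pct",
                         "pct_abnormal_all", "cd4_cd8_ratio")],
               row.names = NULL)
  }))
  write.csv(long, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the whole pipeline
#'
#' Executes simulate (or fixture construction) -> summarize -> score ->
#' evaluate -> PCA reclassification -> survival comparison, writing each
#' stage's artifact under `outDir` (`patients.csv`, `samples.csv`,
#' `events/`, `profiles.csv`, `scores.csv`, `diagnostics.txt`,
#' `pca_scores.csv`, `reclassification.csv`, `km_ttnt_<stratum>.csv`,
#' `logrank_ttnt.txt`) plus a `manifest.json` describing the run. Rerunning
#' with the same config and seed reproduces identical outputs (only the
#' manifest timestamp differs).
#'
#' @param outDir Writable output directory.
#' @param config A [CohortConfig-class].
#' @param seed Integer seed.
#' @param fixture Use [buildFixtureCohort()] instead of simulation.
#' @param pcaVariant Feature set for the reclassification stage.
#' @return The manifest, invisibly (a list).
#' @export
runPipeline <- function(outDir, config = defaultConfig(), seed = config@seed,
                        fixture = FALSE, pcaVariant = "markers4_geno") {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outDir, mode = 2) != 0)
    stop("output directory not writable: ", outDir)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cohort <- stage("simulate",
                  if (fixture) buildFixtureCohort(
                    eventsPerSample = config@eventsPerSample)
                  else generateCohort(config, seed))
  stage("simulate", writeCohort(cohort, outDir))

  profiles <- stage("summarize", summarizeCohort(cohort))
  stage("summarize", writeProfiles(profiles, file.path(outDir, "profiles.csv")))

  scores <- stage("score", hclScore(profiles))
  write.csv(scores, file.path(outDir, "scores.csv"), row.names = FALSE,
            fileEncoding = "UTF-8")
  reports <- stage("evaluate", lapply(c("four", "five"), function(v)
    evaluateScore(scores, variant = v)))
  diagPath <- file.path(outDir, "diagnostics.txt")
  con <- file(diagPath, "w"); sink(con)
  for (r in reports) show(r)
  sink(); close(con)

  recl <- stage("pca", {
    fm <- assembleFeatures(cohort, profiles, pcaVariant)
    model <- fitPca(fm)
    sc <- data.frame(sample_id = rownames(model@scores),
                     group = unname(model@groups),
                     model@scores[, 1:2, drop = FALSE], row.names = NULL)
    write.csv(sc, file.path(outDir, "pca_scores.csv"), row.names = FALSE,
              fileEncoding = "UTF-8")
    reclassify(model)
  })
  write.csv(recl, file.path(outDir, "reclassification.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")

  stage("survival", {
    pat <- cohort@patients
    strata <- split(seq_len(nrow(pat)), ifelse(pat$cd4_cd8_ratio > 2,
                                               "gt2", "le2"))
    for (s in names(strata)) {
      idx <- strata[[s]]
      curve <- kmFit(pat$ttnt_months[idx], pat$ttnt_event[idx])
      write.csv(data.frame(time = curve@time, surv = curve@surv,
                           n_risk = curve@nRisk, n_event = curve@nEvent),
                file.path(outDir, sprintf("km_ttnt_%s.csv", s)),
                row.names = FALSE, fileEncoding = "UTF-8")
    }
    if (length(strata) == 2) {
      lr <- logrank(pat$ttnt_months[strata$gt2], pat$ttnt_event[strata$gt2],
                    pat$ttnt_months[strata$le2], pat$ttnt_event[strata$le2])
      writeLines(sprintf("TTNT by CD4/CD8 stratum: chi-square %.4f, p %.4g",
                         lr@chiSquare, lr@pValue),
                 file.path(outDir, "logrank_ttnt.txt"))
    }
  })

  cfgFile <- tempfile()
  dput(lapply(slotNames(config), function(s) slot(config, s)), cfgFile)
  manifest <- list(
    command = if (fixture) "run --fixture" else "run",
    config_hash = unname(tools::md5sum(cfgFile)),
    seed = seed,
    inputs = if (fixture) "fixture" else "simulated",
    outputs = sort(setdiff(list.files(outDir), "manifest.json")),
    package_version = as.character(packageVersion("hclpheno")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  unlink(cfgFile)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
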