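smallConfig <- function(...) {
  configUpdate(defaultConfig(),
               groupSizes = c(cHCL = 4L, vHCL_SDRPL = 2L, HCL_like_NOS = 0L),
               eventsPerSample = 500L, ...)
}

test_that("identical config and seed give identical cohorts", {
  a <- generateCohort(smallConfig(), seed = 42)
  b <- generateCohort(smallConfig(), seed = 42)
  expect_identical(a@patients, b@patients)
  expect_identical(a@samples, b@samples)
  for (sid in names(a@events))
    expect_identical(a@events[[sid]]@values, b@events[[sid]]@values)
  c <- generateCohort(smallConfig(), seed = 43)
  expect_false(identical(a@patients, c@patients))
})

test_that("degenerate positivity probabilities are honored", {
  cfg <- configUpdate(smallConfig(),
                      markerPositivity = list(cHCL = c(CD26 = 1, CD5 = 0)),
                      testedFractions = list(cHCL = c(CD26 = 1)))
  co <- generateCohort(cfg, seed = 5)
  pat <- patientData(co)
  chcl <- pat$group == "cHCL"
  expect_true(all(pat$CD26_status[chcl] == "positive"))
  expect_true(all(pat$CD5_status[chcl] == "negative"))
  ## and the summaries agree for the degenerate marker
  prof <- summarizeCohort(co)
  calls <- patientMarkerCalls(prof)
  expect_true(all(calls[pat$patient_id[chcl], "CD26"] == "positive"))
})

test_that("marker positivity rates match calibration (exact binomial bounds)", {
  cfg <- configUpdate(defaultConfig(),
                      groupSizes = c(cHCL = 1000L, vHCL_SDRPL = 1000L,
                                     HCL_like_NOS = 0L))
  co <- generateCohort(cfg, seed = 99, events = FALSE)
  pat <- patientData(co)
  checks <- list(c("cHCL", "CD26"), c("cHCL", "CD23"), c("cHCL", "CD123"),
                 c("vHCL_SDRPL", "CD25"), c("vHCL_SDRPL", "CD103"))
  for (ck in checks) {
    g <- ck[1]; m <- ck[2]
    p <- defaultConfig()@markerPositivity[[g]][[m]]
    st <- pat[[paste0(m, "_status")]][pat$group == g]
    st <- st[st != "untested"]
    k <- sum(st == "positive")
    ## exact binomial 99.9% central interval around the configured rate
    lo <- qbinom(5e-4, length(st), p)
    hi <- qbinom(1 - 5e-4, length(st), p)
    expect_gte(k, lo)
    expect_lte(k, hi)
  }
})

test_that("assay missingness follows the tested fractions", {
  cfg <- configUpdate(defaultConfig(),
                      groupSizes = c(cHCL = 2000L, vHCL_SDRPL = 0L,
                                     HCL_like_NOS = 0L))
  co <- generateCohort(cfg, seed = 7, events = FALSE)
  st <- patientData(co)$CD26_status
  k <- sum(st != "untested")
  lo <- qbinom(5e-4, 2000, 36 / 68); hi <- qbinom(1 - 5e-4, 2000, 36 / 68)
  expect_gte(k, lo); expect_lte(k, hi)
})

test_that("survival generator honors stratum medians and censoring", {
  cfg <- defaultConfig()
  ## no censoring: every flag is an event
  noCens <- configUpdate(cfg, survivalParams = list(
    ttnt_cd4cd8_gt2 = c(median = 174.7, censorProb = 0)))
  sv <- generateSurvival("ttnt_cd4cd8_gt2", 500, noCens, seed = 3)
  expect_true(all(sv$event == 1))
  ## exponential median recovery at n = 5000 (uncensored sample median)
  sv <- generateSurvival("ttnt_cd4cd8_gt2", 5000, noCens, seed = 4)
  expect_lt(abs(median(sv$duration) - 174.7) / 174.7, 0.05)
  ## empty and unknown strata
  expect_identical(nrow(generateSurvival("os_all", 0, cfg, seed = 1)), 0L)
  expect_error(generateSurvival("nope", 10, cfg, seed = 1),
               "unknown survival stratum")
  ## censored fraction close to the configured probability
  sv <- generateSurvival("ttnt_cd4cd8_le2", 5000, cfg, seed = 5)
  expect_lt(abs(mean(sv$event == 0) - 0.2), 0.02)
})

test_that("cohorts round-trip through CSV unchanged", {
  co <- generateCohort(smallConfig(), seed = 8)
  dir <- tempfile("cohort")
  writeCohort(co, dir)
  back <- readCohort(dir)
  expect_equal(patientData(back), patientData(co))
  expect_equal(sampleData(back), sampleData(co))
  expect_setequal(names(eventData(back)), names(eventData(co)))
  for (sid in names(eventData(co))) {
    expect_equal(eventData(back)[[sid]]@values, eventData(co)[[sid]]@values,
                 tolerance = 1e-12)
    expect_identical(eventData(back)[[sid]]@population,
                     eventData(co)[[sid]]@population)
  }
  unlink(dir, recursive = TRUE)
})
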