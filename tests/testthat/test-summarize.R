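test_that("percent positive, MFI and intensity class follow the definitions", {
  ## 1000 tumor events, 300 above the cutoff
  ev <- toyEventTable(c(rep(100, 300), rep(1, 700)))
  s <- summarizeMarker(ev, "CD25", eventCutoff = 50)
  expect_equal(s$percent_positive, 30)
  expect_identical(s$intensity_class, "dim")  # 30% passes the rule; MFI 1 < 500
  ## median of three values is the middle one; MFI 499 -> dim
  s <- summarizeMarker(toyEventTable(c(100, 499, 700)), "CD25", eventCutoff = 50)
  expect_equal(s$mfi, 499)
  expect_identical(s$intensity_class, "dim")
  ## all events below cutoff
  s <- summarizeMarker(toyEventTable(rep(5, 100)), "CD25", eventCutoff = 50)
  expect_equal(s$percent_positive, 0)
  expect_identical(s$intensity_class, "negative")
  ## moderate and bright bands
  s <- summarizeMarker(toyEventTable(rep(700, 100)), "CD25", eventCutoff = 50)
  expect_identical(s$intensity_class, "moderate")
  s <- summarizeMarker(toyEventTable(rep(1500, 100)), "CD25", eventCutoff = 50)
  expect_identical(s$intensity_class, "bright")
  ## errors
  expect_error(summarizeMarker(toyEventTable(1:3), "CD99", 50), "not in panel")
  expect_error(summarizeMarker(toyEventTable(numeric(0)), "CD25", 50),
               "no tumor_B")
})

test_that("positivity rule is >= 20 percent, boundary inclusive", {
  expect_true(markerPositive(20))
  expect_false(markerPositive(19.9))
  expect_false(markerPositive(0))
  expect_identical(markerPositive(NA_real_), NA)
  ev <- toyEventTable(c(rep(100, 20), rep(1, 80)))
  expect_true(markerPositive(summarizeMarker(ev, "CD25", 50)))
})

test_that("MFI equals a brute-force median on small tables", {
  bruteMedian <- function(x) {
    x <- sort(x); n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  }
  set.seed(17)
  for (i in 1:25) {
    n <- sample(1:100, 1)
    x <- round(rlnorm(n, log(300), 1), 3)
    s <- summarizeMarker(toyEventTable(x), "CD25", eventCutoff = 100)
    expect_equal(s$mfi, bruteMedian(x))
  }
})

test_that("summaries are invariant to event order and monotone in cutoff", {
  set.seed(23)
  x <- rlnorm(400, log(400), 0.8)
  ev <- toyEventTable(x)
  perm <- toyEventTable(x[sample(length(x))])
  for (co in c(50, 200, 800)) {
    a <- summarizeMarker(ev, "CD25", co)
    b <- summarizeMarker(perm, "CD25", co)
    expect_equal(a$percent_positive, b$percent_positive)
    expect_equal(a$mfi, b$mfi)
  }
  cuts <- seq(10, 2000, by = 50)
  pct <- vapply(cuts, function(co)
    summarizeMarker(ev, "CD25", co)$percent_positive, numeric(1))
  expect_true(all(diff(pct) <= 0))
})

test_that("tumor infiltration uses the lymphocyte denominator", {
  ev <- toyEventTable(rep(1, 200), normal = rep(1, 500),
                      t4 = rep(1, 200), t8 = rep(1, 100))
  expect_equal(tumorInfiltration(ev), 20)
  expect_equal(tumorInfiltration(toyEventTable(rep(1, 10), normal = numeric(0))),
               100)
  expect_equal(tumorInfiltration(toyEventTable(numeric(0), normal = rep(1, 10))),
               0)
  evNone <- new("EventTable", sampleId = "x", markers = "CD25",
                values = matrix(rep(1, 5), ncol = 1,
                                dimnames = list(NULL, "CD25")),
                population = factor(rep("other", 5),
                                    levels = eventPopulations()))
  expect_error(tumorInfiltration(evNone), "no lymphocyte")
})

test_that("CD4/CD8 ratio stratifies at ratio > 2, strictly", {
  ev <- toyEventTable(rep(1, 10), t4 = rep(1, 400), t8 = rep(1, 200))
  r <- cd4cd8Ratio(ev)
  expect_equal(r$ratio, 2)
  expect_identical(r$stratum, "le2")       # boundary is not > 2
  r <- cd4cd8Ratio(toyEventTable(rep(1, 10), t4 = rep(1, 500),
                                 t8 = rep(1, 100)))
  expect_equal(r$ratio, 5)
  expect_identical(r$stratum, "gt2")
  expect_error(cd4cd8Ratio(toyEventTable(rep(1, 10), t4 = rep(1, 5))),
               "ratio undefined")
})

test_that("summarization recovers the generated intensity classes", {
  cfg <- configUpdate(defaultConfig(),
                      groupSizes = c(cHCL = 8L, vHCL_SDRPL = 4L,
                                     HCL_like_NOS = 0L))
  co <- generateCohort(cfg, seed = 31)
  prof <- summarizeCohort(co)
  pat <- patientData(co)
  cls <- SummarizedExperiment::assay(prof, "intensityClass")
  sampleOf <- setNames(sampleData(co)$sample_id, sampleData(co)$patient_id)
  total <- 0; hit <- 0
  for (k in seq_len(nrow(pat))) {
    for (m in panelMarkers()) {
      want <- pat[[paste0(m, "_class")]][k]
      st <- pat[[paste0(m, "_status")]][k]
      got <- cls[m, sampleOf[[pat$patient_id[k]]]]
      if (st == "positive") {
        total <- total + 1
        hit <- hit + identical(got, want)
      } else if (st == "negative") {
        total <- total + 1
        hit <- hit + identical(got, "negative")
      } else expect_true(is.na(got))
    }
  }
  expect_gte(hit / total, 0.99)
})
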