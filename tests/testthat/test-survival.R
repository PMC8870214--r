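test_that("endpoints follow the date-difference definitions", {
  ep <- computeEndpoints(list(diagnosis_date = "2010-01-01",
                              death_date = "2015-01-01",
                              last_followup = "2015-01-01"))
  os <- ep[ep$endpoint == "os", ]
  expect_equal(os$duration, 1826 / 30.4375, tolerance = 1e-10)  # ~60.0 months
  expect_identical(os$event, 1L)
  ## no second treatment: TTNT censored at last follow-up
  ep <- computeEndpoints(list(diagnosis_date = "2010-01-01",
                              first_treatment_end = "2011-01-01",
                              last_followup = "2013-01-01"))
  tt <- ep[ep$endpoint == "ttnt", ]
  expect_identical(tt$event, 0L)
  expect_equal(tt$duration, 731 / 30.4375, tolerance = 1e-10)
  ## progression before death drives PFS
  ep <- computeEndpoints(list(diagnosis_date = "2010-01-01",
                              progression_date = "2012-01-01",
                              death_date = "2014-01-01",
                              last_followup = "2014-01-01"))
  pf <- ep[ep$endpoint == "pfs", ]
  expect_identical(pf$event, 1L)
  expect_equal(pf$duration, 730 / 30.4375, tolerance = 1e-10)
  expect_error(computeEndpoints(list(diagnosis_date = "2010-01-01",
                                     first_treatment_end = "2012-01-01",
                                     second_treatment = "2011-01-01",
                                     last_followup = "2013-01-01")),
               "precedes")
})

test_that("product-limit estimator matches hand computations", {
  ## no censoring: empirical survival
  km <- kmFit(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km@surv, c(3, 2, 1, 0) / 4)
  ## censored subject leaves the risk set: at t = 3 only one subject remains,
  ## so the curve drops to 0 (verified against survival::survfit)
  km <- kmFit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km@time, c(1, 3))
  expect_equal(km@surv, c(2 / 3, 0))
  ## all censored: S stays at 1 (no event times)
  km <- kmFit(c(5, 6), c(0, 0))
  expect_length(km@time, 0)
  expect_true(is.na(kmMedian(km)))
  expect_error(kmFit(numeric(0), integer(0)), "at least one subject")
  expect_error(kmFit(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM equals the empirical survival on all uncensored inputs", {
  set.seed(19)
  for (i in 1:30) {
    n <- sample(1:20, 1)
    d <- round(rexp(n, 1 / 50), 1)
    km <- kmFit(d, rep(1, n))
    for (j in seq_along(km@time))
      expect_equal(km@surv[j], mean(d > km@time[j]))   # ecdf oracle
  }
})

test_that("KM agrees with an independent implementation under censoring", {
  skip_if_not_installed("survival")
  set.seed(20)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    d <- round(rexp(n, 1 / 30), 1)
    e <- rbinom(n, 1, 0.7)
    if (sum(e) == 0) e[1] <- 1
    km <- kmFit(d, e)
    sf <- survival::survfit(survival::Surv(d, e) ~ 1)
    idx <- match(km@time, sf$time)
    expect_equal(km@surv, sf$surv[idx], tolerance = 1e-12)
    expect_equal(km@nRisk, sf$n.risk[idx], ignore_attr = TRUE)
  }
})

test_that("median rule is the smallest time with S <= 0.5", {
  cv <- new("KMCurve", time = c(10, 20, 30), surv = c(0.75, 0.50, 0.25),
            nRisk = c(4L, 3L, 2L), nEvent = c(1L, 1L, 1L), n = 4L)
  expect_equal(kmMedian(cv), 20)
  cv2 <- new("KMCurve", time = c(10, 20), surv = c(0.9, 0.65),
             nRisk = c(20L, 18L), nEvent = c(2L, 5L), n = 20L)
  expect_true(is.na(kmMedian(cv2)))
})

test_that("log-rank matches hand computation and an independent oracle", {
  ## identical groups: O = E everywhere
  lr <- logrank(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(lr@chiSquare, 0)
  expect_equal(lr@pValue, 1)
  ## hand-tabulated toy: A = {1, 2}, B = {3, 4}, all events
  ## t=1: n=4, nA=2, d=1, dA=1, E=0.5, V=0.25
  ## t=2: n=3, nA=1, d=1, dA=1, E=1/3, V=2/9
  ## t=3: n=2, nA=0, d=1, dA=0, E=0,   V=0... nA=0 so E=0,V=0
  ## t=4: n=1 -> variance term skipped
  ## sum(O-E) = (1-.5)+(1-1/3)+0 = 7/6 ; V = .25+2/9 = 17/36
  lr <- logrank(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(lr@chiSquare, (7 / 6)^2 / (17 / 36), tolerance = 1e-12)
  skip_if_not_installed("survival")
  set.seed(21)
  for (i in 1:10) {
    nA <- sample(5:40, 1); nB <- sample(5:40, 1)
    dA <- round(rexp(nA, 1 / 30), 1); dB <- round(rexp(nB, 1 / 50), 1)
    eA <- rbinom(nA, 1, 0.8); eB <- rbinom(nB, 1, 0.8)
    if (sum(eA) + sum(eB) == 0) eA[1] <- 1
    lr <- logrank(dA, eA, dB, eB)
    sd <- survival::survdiff(
      survival::Surv(c(dA, dB), c(eA, eB)) ~ rep(1:2, c(nA, nB)))
    expect_equal(lr@chiSquare, sd$chisq, tolerance = 1e-8)
  }
  expect_error(logrank(numeric(0), integer(0), 1, 1), "nonempty")
  expect_error(logrank(c(1, 2), c(0, 0), c(3), c(0)), "no events")
})

test_that("time rescaling scales the median and preserves the statistic", {
  set.seed(22)
  dA <- rexp(40, 1 / 30); eA <- rbinom(40, 1, 0.8)
  dB <- rexp(40, 1 / 60); eB <- rbinom(40, 1, 0.8)
  lr1 <- logrank(dA, eA, dB, eB)
  lr2 <- logrank(dA * 3.7, eA, dB * 3.7, eB)
  expect_equal(lr1@chiSquare, lr2@chiSquare, tolerance = 1e-12)
  m1 <- kmMedian(kmFit(dA, eA))
  m2 <- kmMedian(kmFit(dA * 3.7, eA))
  expect_equal(m2, m1 * 3.7, tolerance = 1e-12)
})
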