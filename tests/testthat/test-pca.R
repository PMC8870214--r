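test_that("PCA matches a brute-force correlation-matrix eigendecomposition", {
  set.seed(7)
  X <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, paste0("f", 1:4)))
  m <- fitPca(X)
  ## independent oracle: eigenproblem of the correlation matrix
  E <- eigen(cor(X), symmetric = TRUE)
  expect_equal(explainedPct(m), 100 * E$values / sum(E$values),
               tolerance = 1e-10)
  for (j in 1:4) {
    ratio <- pcaLoadings(m)[, j] / E$vectors[, j]
    expect_equal(abs(ratio), rep(1, 4), tolerance = 1e-8,
                 ignore_attr = TRUE)                       # equal up to sign
    expect_lt(diff(range(ratio)), 1e-8)                    # one common sign
  }
  ## sign convention: largest-magnitude loading positive
  for (j in 1:4)
    expect_gt(pcaLoadings(m)[which.max(abs(pcaLoadings(m)[, j])), j], 0)
})

test_that("explained variance normalizes and reconstruction is exact", {
  set.seed(8)
  X <- matrix(rnorm(60), 10, 6)
  colnames(X) <- paste0("f", 1:6)
  m <- fitPca(X)
  expect_equal(sum(explainedPct(m)), 100, tolerance = 1e-9)
  Z <- scale(X, center = m@center, scale = m@scale)
  expect_equal(unclass(Z), pcaScores(m) %*% t(pcaLoadings(m)),
               tolerance = 1e-8, ignore_attr = TRUE)
  ## a single varying feature carries all the variance
  one <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_warning(m1 <- fitPca(one), "zero-variance")
  expect_equal(explainedPct(m1), 100)
  expect_error(fitPca(X[1:2, ]), "at least 3 samples")
})

test_that("permuting feature columns permutes loadings but not scores", {
  set.seed(9)
  X <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("f", 1:5)))
  perm <- c(3, 1, 5, 2, 4)
  a <- fitPca(X)
  b <- fitPca(X[, perm])
  expect_equal(explainedPct(a), explainedPct(b), tolerance = 1e-10)
  expect_equal(pcaScores(a), pcaScores(b), tolerance = 1e-8)
  expect_equal(pcaLoadings(a)[perm, ], pcaLoadings(b), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("feature sets have the documented shape", {
  co <- fixtureCohort(); prof <- fixtureProfiles()
  f13 <- assembleFeatures(co, prof, "markers13")
  expect_identical(dim(f13@values), c(82L, 28L))
  f4g <- assembleFeatures(co, prof, "markers4_geno")
  expect_identical(dim(f4g@values), c(82L, 12L))
  expect_identical(utils::tail(f4g@featureNames, 3),
                   c("BRAF_V600E", "MAP2K1", "KLF2"))
  expect_true(all(f4g@values[, sequencedGenes()] %in% 0:1))
  f4b <- assembleFeatures(co, prof, "markers4_geno_blood")
  expect_identical(dim(f4b@values), c(82L, 20L))
  ## untested assays are imputed with the feature mean and masked
  expect_false(anyNA(f13@values))
  untested <- patientData(co)$CD23_status == "untested"
  expect_identical(sum(f13@missingMask[, "pct_CD23"]), sum(untested))
  expect_error(assembleFeatures(co, prof, "markers99"), "arg")
})

test_that("concentration ellipse has the chi-square geometry and coverage", {
  ## boundary radius for standard bivariate normal scores
  set.seed(10)
  Z <- matrix(rnorm(400), 200, 2)
  ell <- concentrationEllipse(Z, "g")
  r2 <- qchisq(0.90, 2)
  expect_equal(r2, 4.60517, tolerance = 1e-5)
  dir <- c(1, 0)
  edge <- sqrt(r2 * ell@covariance[1, 1])
  inPt <- ell@center + dir * edge * 0.99
  outPt <- ell@center + dir * edge * 1.01
  expect_true(insideEllipse(rbind(inPt), ell))
  expect_false(insideEllipse(rbind(outPt), ell))
  ## Monte-Carlo coverage at the fitted Gaussian: 0.90 +/- 0.01 at n = 1e4
  E <- eigen(ell@covariance, symmetric = TRUE)
  A <- E$vectors %*% diag(sqrt(E$values))
  set.seed(11)
  sim <- t(ell@center + A %*% matrix(rnorm(2e4), 2))
  expect_lt(abs(mean(insideEllipse(sim, ell)) - 0.90), 0.01)
  expect_error(concentrationEllipse(Z[1:2, ]), ">= 3 samples")
  ## boundary polygon lies on the level contour
  poly <- ellipseBoundary(ell)
  d2 <- mahalanobis(poly, ell@center, ell@covariance)
  expect_equal(d2, rep(r2, nrow(poly)), tolerance = 1e-8)
})

test_that("gray zone flags overlap with foreign ellipses or no ellipse", {
  eA <- new("ConcentrationEllipse", group = "A", center = c(0, 0),
            covariance = diag(2), level = 0.9, n = 10L)
  eB <- new("ConcentrationEllipse", group = "B", center = c(10, 0),
            covariance = diag(2), level = 0.9, n = 10L)
  pts <- rbind(ownCenter = c(0, 0),      # A sample at its own center
               inForeign = c(10, 0),     # A sample inside B's ellipse
               nowhere = c(5, 50))       # outside every ellipse
  gz <- flagGrayZone(pts, labels = c("A", "A", "A"),
                     ellipses = list(A = eA, B = eB))
  expect_identical(unname(gz), c(FALSE, TRUE, TRUE))
})

test_that("reclassification is nearest-Gaussian with a tie rule", {
  ## two clean reference clusters
  set.seed(12)
  sc <- rbind(matrix(rnorm(40, mean = 0, sd = 0.5), 20, 2),
              matrix(rnorm(40, mean = 6, sd = 0.5), 20, 2),
              c(0, 0),                   # exactly at the cHCL centroid-ish
              c(3, 3))                   # far from both, equidistant-ish
  grp <- c(rep("cHCL", 20), rep("vHCL_SDRPL", 20), "HCL_like_NOS",
           "HCL_like_NOS")
  rownames(sc) <- paste0("s", seq_len(nrow(sc)))
  model <- new("PCAModel", variant = "toy", center = c(0, 0), scale = c(1, 1),
               loadings = diag(2), scores = sc,
               explainedPct = c(60, 40), groups = setNames(grp, rownames(sc)),
               droppedFeatures = character(0))
  r <- reclassify(model)
  expect_true(all(r$new_label[r$original_group == "cHCL"] == "HCL"))
  expect_true(all(r$new_label[r$original_group == "vHCL_SDRPL"] == "HCL_like"))
  expect_identical(r$new_label[r$sample_id == "s41"], "HCL")
  ## a point on the mirror plane of two reflected clusters is an exact tie
  base <- cbind(c(-1, -2, -3, -2.5, -1.5), c(0.5, -0.5, 0.2, 0.8, -0.6))
  scT <- rbind(base, cbind(4 - base[, 1], base[, 2]), c(2, 0.1))
  rownames(scT) <- paste0("t", 1:11)
  grpT <- c(rep("cHCL", 5), rep("vHCL_SDRPL", 5), "HCL_like_NOS")
  modelT <- new("PCAModel", variant = "toy", center = c(0, 0),
                scale = c(1, 1), loadings = diag(2), scores = scT,
                explainedPct = c(60, 40),
                groups = setNames(grpT, rownames(scT)),
                droppedFeatures = character(0))
  rT <- reclassify(modelT)
  expect_identical(rT$new_label[rT$sample_id == "t11"], "ambiguous")
})

test_that("the CD25-negative NOS patient with a cHCL profile reclassifies as HCL", {
  co <- fixtureCohort(); prof <- fixtureProfiles()
  model <- fitPca(assembleFeatures(co, prof, "markers4_geno"))
  r <- reclassify(model)
  expect_identical(r$new_label[r$sample_id == "S-N02"], "HCL")
  ## and the reference groups themselves separate perfectly
  expect_true(all(r$new_label[r$original_group == "cHCL"] == "HCL"))
  expect_true(all(r$new_label[r$original_group == "vHCL_SDRPL"] == "HCL_like"))
})
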