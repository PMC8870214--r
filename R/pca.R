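## Unsupervised classification: feature assembly, standardized PCA,
## 90% concentration ellipses, gray-zone flagging and nearest-Gaussian
## (Mahalanobis) reclassification in PC1-PC2.

.FEATURE_VARIANTS <- c("markers13", "markers4_geno", "markers4_geno_blood")

.genoIndicator <- function(v) ifelse(v == "mutated", 1, 0)  # untested -> 0 + mask

#' Assemble a PCA feature matrix
#'
#' Builds the samples-by-features matrix for one of three feature sets:
#' \describe{
#'   \item{`markers13`}{percent positive + MFI of the 13 core panel markers
#'     (CD19...CD25), plus percent abnormal of all events and percent
#'     abnormal of lymphocytes (tumor infiltration): 28 features.}
#'   \item{`markers4_geno`}{percent + MFI of the four score markers (CD11c,
#'     CD103, CD123, CD25), percent abnormal of all events, and the BRAF /
#'     MAP2K1 / KLF2 mutation indicators (mutated = 1): 12 features.}
#'   \item{`markers4_geno_blood`}{`markers4_geno` plus ALC, AMC, ANC, PC,
#'     Hb, the CD4/CD8 ratio and CD26 percent + MFI: 20 features.}
#' }
#' Missing values (untested markers or genes, missing blood counts) are
#' imputed with the feature mean and flagged in the missing mask; an
#' untested gene scores 0 with the mask set.
#'
#' @param cohort An [HclCohort-class] (for genotype and blood counts).
#' @param profiles The matching [SampleProfiles-class].
#' @param variant Feature-set variant.
#' @param device Optional device tag; keeps only samples acquired on it.
#' @return A [FeatureMatrix-class].
#' @export
assembleFeatures <- function(cohort, profiles,
                             variant = c("markers13", "markers4_geno",
                                         "markers4_geno_blood"),
                             device = NULL) {
  variant <- match.arg(variant)
  cd <- SummarizedExperiment::colData(profiles)
  keep <- rep(TRUE, nrow(cd))
  if (!is.null(device)) {
    dev <- cohort@samples$device[match(cd$sample_id, cohort@samples$sample_id)]
    keep <- dev == device
  }
  sids <- cd$sample_id[keep]
  pp <- SummarizedExperiment::assay(profiles, "percentPositive")[, keep,
                                                                 drop = FALSE]
  mfi <- SummarizedExperiment::assay(profiles, "mfi")[, keep, drop = FALSE]
  pidx <- match(cd$patient_id[keep], cohort@patients$patient_id)
  pat <- cohort@patients[pidx, , drop = FALSE]

  markerBlock <- function(markers) {
    vals <- rbind(pp[markers, , drop = FALSE], mfi[markers, , drop = FALSE])
    rownames(vals) <- c(paste0("pct_", markers), paste0("mfi_", markers))
    t(vals)
  }
  if (variant == "markers13") {
    X <- cbind(markerBlock(pcaMarkers()),
               pct_abnormal_sample = cd$pct_abnormal_all[keep],
               pct_abnormal_lymph = cd$infiltration_pct[keep])
    mask <- is.na(X)
  } else {
    X <- cbind(markerBlock(scoreMarkers("four")),
               pct_abnormal_sample = cd$pct_abnormal_all[keep])
    mask <- is.na(X)
    genoRaw <- as.matrix(pat[, .GENES])
    G <- apply(genoRaw, 2, .genoIndicator)
    X <- cbind(X, G)
    mask <- cbind(mask, genoRaw == "untested")
    if (variant == "markers4_geno_blood") {
      B <- as.matrix(pat[, .ANALYTES])
      extra <- cbind(B, cd4_cd8_ratio = cd$cd4_cd8_ratio[keep],
                     pct_CD26 = pp["CD26", ], mfi_CD26 = mfi["CD26", ])
      X <- cbind(X, extra)
      mask <- cbind(mask, is.na(extra))
    }
  }
  ## mean imputation over observed values, per feature
  for (j in seq_len(ncol(X))) {
    bad <- is.na(X[, j])
    if (any(bad)) X[bad, j] <- mean(X[!bad, j])
  }
  rownames(X) <- rownames(mask) <- sids
  new("FeatureMatrix", sampleIds = sids, featureNames = colnames(X),
      values = X, variant = variant,
      missingMask = mask,
      groups = setNames(pat$group, sids))
}

#' Fit a standardized principal component analysis
#'
#' Centers every feature and scales it to unit variance (percent and MFI
#' features live on incommensurate scales), then decomposes. Zero-variance
#' features are dropped with a warning. Components are ordered by decreasing
#' explained variance, and each component's sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param x A [FeatureMatrix-class] or a plain numeric matrix
#'   (samples x features).
#' @param nComponents Components to retain in scores/loadings (default:
#'   all). `explainedPct` always covers all components and sums to 100.
#' @return A [PCAModel-class].
#' @export
fitPca <- function(x, nComponents = NULL) {
  groups <- character(0)
  variant <- "matrix"
  if (is(x, "FeatureMatrix")) {
    groups <- x@groups
    variant <- x@variant
    x <- x@values
  }
  if (nrow(x) < 3) stop("PCA requires at least 3 samples")
  v <- apply(x, 2, var)
  if (any(v == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(x)[v == 0], collapse = ", "))
  }
  dropped <- colnames(x)[v == 0]
  x <- x[, v > 0, drop = FALSE]
  if (ncol(x) < 1) stop("PCA requires at least 1 feature with variance")
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  expl <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  ## sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  k <- if (is.null(nComponents)) ncol(fit$rotation)
       else min(nComponents, ncol(fit$rotation))
  new("PCAModel", variant = variant,
      center = fit$center, scale = fit$scale,
      loadings = fit$rotation[, seq_len(k), drop = FALSE],
      scores = fit$x[, seq_len(k), drop = FALSE],
      explainedPct = expl,
      groups = groups,
      droppedFeatures = dropped)
}

#' Fit a concentration ellipse for one group
#'
#' Normal-theory concentration ellipse in PC1-PC2: center at the group
#' mean, shape from the group sample covariance, boundary at the chi-square
#' quantile with 2 df at the coverage level. A point is inside iff its
#' squared Mahalanobis distance is at most that quantile.
#'
#' @param scores2 Two-column matrix of component scores for the group's
#'   samples (>= 3 rows).
#' @param group Group label stored in the result.
#' @param level Coverage level, default 0.90.
#' @return A [ConcentrationEllipse-class].
#' @export
concentrationEllipse <- function(scores2, group = "", level = 0.90) {
  scores2 <- as.matrix(scores2)
  if (nrow(scores2) < 3)
    stop("concentration ellipse requires >= 3 samples")
  S <- cov(scores2)
  if (abs(det(S)) < 1e-12) stop("singular covariance")
  new("ConcentrationEllipse", group = as.character(group),
      center = colMeans(scores2), covariance = S,
      level = level, n = nrow(scores2))
}

#' @describeIn concentrationEllipse Squared-Mahalanobis test for ellipse
#'   membership.
#' @param points Two-column matrix of points.
#' @param ellipse A [ConcentrationEllipse-class].
#' @return Logical vector.
#' @export
insideEllipse <- function(points, ellipse) {
  points <- matrix(points, ncol = 2)
  d2 <- mahalanobis(points, ellipse@center, ellipse@covariance)
  d2 <= qchisq(ellipse@level, df = 2)
}

#' @describeIn concentrationEllipse Boundary polygon for plotting.
#' @param nSegments Number of polygon vertices.
#' @export
ellipseBoundary <- function(ellipse, nSegments = 120) {
  r <- sqrt(qchisq(ellipse@level, df = 2))
  theta <- seq(0, 2 * pi, length.out = nSegments)
  E <- eigen(ellipse@covariance, symmetric = TRUE)
  A <- E$vectors %*% diag(sqrt(E$values))
  t(ellipse@center + A %*% rbind(r * cos(theta), r * sin(theta)))
}

#' Flag gray-zone samples
#'
#' A sample is in the gray zone iff it lies inside the 90 percent ellipse
#' of a group other than its own label, or outside every ellipse.
#'
#' @param scores2 Two-column matrix of PC1-PC2 scores (rows named by
#'   sample).
#' @param labels Character vector of each sample's own group label.
#' @param ellipses Named list of [ConcentrationEllipse-class] per group.
#' @return Named logical vector.
#' @export
flagGrayZone <- function(scores2, labels, ellipses) {
  scores2 <- as.matrix(scores2)
  inside <- vapply(ellipses, function(e) insideEllipse(scores2, e),
                   logical(nrow(scores2)))
  inside <- matrix(inside, nrow = nrow(scores2),
                   dimnames = list(rownames(scores2), names(ellipses)))
  out <- vapply(seq_len(nrow(scores2)), function(i) {
    others <- setdiff(names(ellipses), labels[i])
    any(inside[i, others]) || !any(inside[i, ])
  }, logical(1))
  setNames(out, rownames(scores2))
}

#' Reclassify samples by nearest reference Gaussian
#'
#' Fits a bivariate Gaussian (mean + covariance in PC1-PC2) to each of the
#' two reference groups and assigns every sample to the nearer one by
#' Mahalanobis distance: nearer to the cHCL reference -> `HCL`, nearer to
#' the vHCL/SDRPL reference -> `HCL_like`. Distances equal within a
#' relative tolerance give `ambiguous`.
#'
#' @param model A [PCAModel-class] with group labels.
#' @param refGroups Length-2 character: the HCL-defining and the
#'   HCL-like-defining reference group.
#' @param tol Relative tie tolerance.
#' @return `data.frame` with `sample_id`, `original_group`, distances to
#'   both references, `new_label` and `gray_zone` (from the reference-group
#'   ellipses).
#' @export
reclassify <- function(model, refGroups = c("cHCL", "vHCL_SDRPL"),
                       tol = 1e-9) {
  sc <- model@scores[, 1:2, drop = FALSE]
  groups <- model@groups
  refs <- lapply(refGroups, function(g) {
    idx <- which(groups == g)
    if (length(idx) < 3)
      stop("reference group ", g, " has fewer than 3 samples")
    S <- cov(sc[idx, , drop = FALSE])
    if (abs(det(S)) < 1e-12) stop("singular covariance for group ", g)
    list(center = colMeans(sc[idx, , drop = FALSE]), cov = S)
  })
  d1 <- sqrt(mahalanobis(sc, refs[[1]]$center, refs[[1]]$cov))
  d2 <- sqrt(mahalanobis(sc, refs[[2]]$center, refs[[2]]$cov))
  tie <- abs(d1 - d2) <= tol * pmax(d1, d2, 1)
  lab <- ifelse(tie, "ambiguous", ifelse(d1 < d2, "HCL", "HCL_like"))
  ells <- setNames(lapply(refs, function(r) {
    new("ConcentrationEllipse", group = "", center = r$center,
        covariance = r$cov, level = 0.90, n = 3L)
  }), refGroups)
  gz <- flagGrayZone(sc, groups, ells)
  out <- data.frame(sample_id = rownames(sc),
                    original_group = unname(groups[rownames(sc)]),
                    dist_HCL = d1, dist_HCL_like = d2,
                    new_label = lab, gray_zone = unname(gz),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
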