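test_that("flag and missingness filters follow their thresholds", {
  x <- matrix(rnorm(60), 10, 6)
  ds <- makeDataset(x)
  rowData(ds)$is_contaminant[1] <- TRUE
  rowData(ds)$is_reverse[2] <- TRUE
  expect_message(out <- filterFlagged(ds), "removed 1 contaminant and 1 reverse")
  expect_equal(nrow(out), 8L)
  dsAll <- makeDataset(x[1:2, ])
  rowData(dsAll)$is_contaminant <- TRUE
  expect_error(suppressMessages(filterFlagged(dsAll)), "all features")

  # 2/6 missing (0.333) > 0.30 -> removed; complete row retained
  x2 <- x
  x2[1, 1:2] <- NA
  ds2 <- makeDataset(x2)
  out2 <- suppressMessages(filterMissing(ds2, 0.30))
  expect_equal(nrow(out2), 9L)
  expect_false("F1" %in% rownames(out2))
  expect_equal(nrow(suppressMessages(filterMissing(ds2, 1.0))), 10L)
})

test_that("log transform validates scale state and positivity", {
  ds <- makeDataset(matrix(c(8, 2, 4, 16), 2, 2), log = FALSE)
  out <- logTransform(ds)
  expect_equal(intensities(out)[1, 1], 3)
  expect_true(isLogTransformed(out))
  expect_error(logTransform(out), "already log-transformed")
  ds0 <- makeDataset(matrix(c(0, 1, 2, 3), 2, 2), log = FALSE)
  expect_error(logTransform(ds0), "non-positive value at feature 'F1'")
  expect_equal(intensities(logTransform(ds0, pseudocount = 1))[1, 1], 0)
})

test_that("normalization methods meet their column contracts", {
  x <- cbind(S1 = c(1, 2, 3), S2 = c(4, 5, 6))
  rownames(x) <- paste0("F", 1:3)
  ds <- makeDataset(x)
  q <- intensities(normalizeIntensities(ds, "quantile"))
  expect_equal(q[, 1], q[, 2], ignore_attr = TRUE)
  expect_equal(sort(q[, 1]), c(2.5, 3.5, 4.5), ignore_attr = TRUE)

  m <- intensities(normalizeIntensities(makeDataset(
    cbind(S1 = c(4, 5, 6), S2 = c(6, 7, 8))), "median"))
  expect_equal(unname(apply(m, 2, median)), c(6, 6))

  z <- intensities(normalizeIntensities(ds, "ztransform"))
  expect_equal(unname(z[, 1]), c(-1, 0, 1))

  mm <- intensities(normalizeIntensities(makeDataset(
    matrix(rnorm(40, 20, c(1, 3)), 10, 4)), "medianMAD"))
  meds <- apply(mm, 2, median)
  mads <- apply(mm, 2, function(v) median(abs(v - median(v))))
  expect_lt(max(abs(meds - mean(meds))), 1e-9)
  expect_lt(max(abs(mads - mean(mads))), 1e-9)
})

test_that("quantile columns share identical value multisets, NA preserved in place", {
  withr::local_seed(7)
  x <- matrix(rnorm(200, 20, 2), 40, 5)
  x[cbind(sample(40, 5), sample(5, 5, replace = TRUE))] <- NA
  ds <- makeDataset(x)
  q <- intensities(normalizeIntensities(ds, "quantile"))
  expect_identical(unname(is.na(q)), unname(is.na(x)))
  xc <- x[rowSums(is.na(x)) == 0, ]
  qc <- intensities(normalizeIntensities(makeDataset(xc), "quantile"))
  for (j in 2:ncol(qc))
    expect_equal(sort(unname(qc[, 1])), sort(unname(qc[, j])),
                 tolerance = 1e-12)
})

test_that("IRS aligns reference intensities across plexes", {
  withr::local_seed(1)
  base <- rnorm(30, 20, 1)
  x <- cbind(S1 = base, S2 = base + 0.1,
             S3 = base + 2, S4 = base + 2.1)   # plex2 shifted up by 2
  ds <- makeDataset(x, groups = c("A", "B", "A", "B"),
                    plex = c("p1", "p1", "p2", "p2"))
  out <- intensities(normalizeIntensities(ds, "irs"))
  # per-feature plex means should now coincide
  p1 <- rowMeans(out[, 1:2]); p2 <- rowMeans(out[, 3:4])
  expect_lt(max(abs(p1 - p2)), 1e-9)
  expect_error(normalizeIntensities(makeDataset(x), "irs"), "plex")
})

test_that("local least squares imputation recovers structured data and is conservative", {
  # rank-1 data: every row a multiple of v -> exact recovery with k = 1
  v <- c(1, 2, 3, 4, 5, 6)
  x <- outer(c(1, 2.5, -1.3, 0.7), v)
  dimnames(x) <- list(paste0("F", 1:4), paste0("S", 1:6))
  masked <- x
  masked[2, 4] <- NA
  ds <- makeDataset(masked)
  out <- intensities(imputeLLS(ds, k = 1))
  expect_lt(abs(out[2, 4] - x[2, 4]), 1e-8)
  expect_identical(out[-2, ], x[-2, ])          # observed cells untouched

  # no missing -> identity
  full <- makeDataset(x)
  expect_identical(intensities(imputeLLS(full)), x)

  # only neighbour constant -> correlation undefined -> row-mean fallback
  y <- rbind(F1 = c(1, 5, NA), F2 = c(2, 2, 2))
  colnames(y) <- paste0("S", 1:3)
  out2 <- intensities(imputeLLS(makeDataset(y), k = 5))
  expect_equal(out2[1, 3], 3)
  expect_error(imputeLLS(makeDataset(y), k = 0), "k must be")
})

test_that("pooled variation metrics match hand calculations", {
  # one group, replicates [1,3]: MAD 1, var 2; [2,4]: CV = sd/mean
  ds <- makeDataset(rbind(F1 = c(1, 3)), groups = c("A", "A"))
  qc <- qcMetrics(ds)
  expect_equal(qc[["PMAD"]], 1)
  expect_equal(qc[["PEV"]], 2)
  qc2 <- qcMetrics(makeDataset(rbind(F1 = c(2, 4)), groups = c("A", "A")))
  expect_equal(qc2[["PCV"]], sd(c(2, 4)) / 3, tolerance = 1e-6)
  expect_equal(qc2[["PCV"]], 0.4714, tolerance = 1e-4)
  # identical replicates -> all zero
  qc3 <- qcMetrics(makeDataset(rbind(F1 = c(5, 5, 5)), groups = rep("A", 3)))
  expect_equal(unname(qc3), c(0, 0, 0))
  expect_error(qcMetrics(makeDataset(rbind(F1 = c(1, 2)),
                                     groups = c("A", "B"))),
               ">= 2 replicates")
})

test_that("variation metrics are invariant to feature and within-group sample order", {
  withr::local_seed(3)
  x <- matrix(rnorm(60, 20), 10, 6)
  grp <- rep(c("A", "B"), each = 3)
  ds <- makeDataset(x, groups = grp)
  ref <- qcMetrics(ds)
  perm <- sample(10)
  expect_equal(qcMetrics(makeDataset(x[perm, ], groups = grp)), ref)
  ord <- c(3, 1, 2, 6, 5, 4)   # permute within groups
  expect_equal(qcMetrics(makeDataset(x[, ord], groups = grp[ord])), ref)
})

test_that("average silhouette width matches the hand-computed fixture", {
  x <- rbind(F1 = c(0, 1, 10, 11))
  colnames(x) <- paste0("S", 1:4)
  ds <- makeDataset(x, groups = c("A", "A", "B", "B"))
  asw <- avgSilhouette(ds, space = "features")
  expect_equal(asw, (10.5 - 1) / 10.5 / 2 + (9.5 - 1) / 9.5 / 2,
               tolerance = 1e-6)
  expect_equal(asw, 0.8997, tolerance = 1e-4)
  # identical groups at the same point -> no separation
  x2 <- rbind(F1 = c(1, 1, 1, 1), F2 = c(2, 2, 2, 2))
  expect_lte(avgSilhouette(makeDataset(x2, groups = c("A", "A", "B", "B")),
                           space = "features"), 0)
  expect_error(avgSilhouette(makeDataset(x, groups = rep("A", 4))),
               ">= 2 groups")
})

test_that("silhouette agrees with the cluster package implementation", {
  skip_if_not_installed("cluster")
  withr::local_seed(11)
  x <- matrix(rnorm(80), 8, 10)
  grp <- rep(c("A", "B"), 5)
  ds <- makeDataset(x, groups = grp)
  ours <- avgSilhouette(ds, space = "features")
  ref <- mean(cluster::silhouette(as.integer(factor(grp)),
                                  dist(t(x)))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("normalization evaluation recommends the dominating method", {
  withr::local_seed(5)
  base <- matrix(rnorm(300, 20, 0.3), 50, 6)
  shift <- matrix(rep(c(0, 1.5, -1, 2, 0.5, -0.7), each = 50), 50, 6)
  ds <- makeDataset(base + shift, groups = rep(c("A", "B"), each = 3))
  rep <- evaluateNormalizations(ds, c("none", "median"))
  tb <- resultTable(rep)
  expect_equal(tb$method[tb$recommended], "median")
  expect_lt(tb$PMAD[tb$method == "median"], tb$PMAD[tb$method == "none"])
  expect_error(evaluateNormalizations(ds, "median"), "two methods")
})

test_that("median normalization restores the no-shift PMAD baseline on shifted data", {
  withr::local_seed(9)
  clean <- matrix(rnorm(600, 20, 0.3), 100, 6)
  grp <- rep(c("A", "B"), each = 3)
  pmadClean <- qcMetrics(makeDataset(clean, groups = grp))[["PMAD"]]
  shifted <- clean + matrix(rep(c(0, 2, -1, 1.5, -0.5, 3), each = 100),
                            100, 6)
  dsNorm <- normalizeIntensities(makeDataset(shifted, groups = grp),
                                 "median")
  pmadNorm <- qcMetrics(dsNorm)[["PMAD"]]
  expect_equal(pmadNorm, pmadClean, tolerance = 0.02)
})

test_that("variable feature selection ranks by variance", {
  withr::local_seed(2)
  x <- matrix(rnorm(600), 100, 6) * seq(0.1, 2, length.out = 100)
  ds <- makeDataset(x)
  top <- variableFeatures(ds, 0.10)
  expect_length(top, 10L)
  expect_length(variableFeatures(ds, 1.0), 100L)
  # constant feature never selected while non-constant features exist
  x2 <- rbind(x[1:9, ], F100 = rep(5, 6))
  rownames(x2) <- paste0("F", 1:10)
  expect_false("F10" %in% variableFeatures(makeDataset(x2), 0.5))
})

test_that("PCA scores are orthogonal with sensible variance fractions", {
  withr::local_seed(4)
  # samples on a line in feature space -> PC1 captures everything
  t_ <- seq(-2, 2, length.out = 6)
  x <- rbind(F1 = 3 * t_, F2 = -1 * t_, F3 = 0.5 * t_)
  colnames(x) <- paste0("S", 1:6)
  pc <- pcaScores(makeDataset(x), 2)
  expect_equal(pc$varianceFraction[1], 1.0, tolerance = 1e-12)
  y <- matrix(rnorm(60), 10, 6)
  pcy <- pcaScores(makeDataset(y), 3)
  cross <- crossprod(pcy$scores)
  expect_lt(max(abs(cross[upper.tri(cross)])), 1e-8)
  expect_true(all(diff(pcy$varianceFraction) <= 1e-12))
  expect_error(pcaScores(makeDataset(y), 7), "exceeds")
  # duplicate samples -> identical scores
  yd <- cbind(y, y[, 1])
  colnames(yd) <- paste0("S", 1:7)
  pcd <- pcaScores(makeDataset(yd), 2)
  expect_equal(pcd$scores[1, ], pcd$scores[7, ], ignore_attr = TRUE)
})

test_that("MD table aligns with the fitted result", {
  ds <- makeTwoGroupData(20, 3, effect = 1, effectIdx = 1:5, seed = 8)
  design <- buildDesign(as.data.frame(sampleMeta(ds)), "group")
  res <- ebayesModerate(fitLinearModel(ds, design, "grouptreated"))
  md <- mdTable(res)
  expect_equal(md$feature_id, resultTable(res)$feature_id)
  expect_equal(md$AveExpr, rowMeans(intensities(ds)), ignore_attr = TRUE)
})
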