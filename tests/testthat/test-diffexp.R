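twoGroupAnn <- function(n = 4) {
  data.frame(sample_id = paste0("S", seq_len(n)),
             group = rep(c("saline", "drug"), each = n / 2),
             stringsAsFactors = FALSE)
}

test_that("design matrices use treatment coding with rank validation", {
  ann <- twoGroupAnn()
  X <- buildDesign(ann, "group", referenceLevels = list(group = "saline"))
  expect_equal(dim(X), c(4L, 2L))
  expect_equal(colnames(X), c("(Intercept)", "groupdrug"))
  expect_equal(unname(X[, "groupdrug"]), c(0, 0, 1, 1))
  # adding a 2-level batch adds one column
  ann$batch <- c("b1", "b2", "b1", "b2")
  X2 <- buildDesign(ann, c("group", "batch"),
                    referenceLevels = list(group = "saline"))
  expect_equal(ncol(X2), 3L)
  # factor perfectly confounded with batch -> rank error naming the column
  ann$confound <- ann$group
  expect_error(buildDesign(ann, c("group", "confound")),
               "rank deficient.*confound")
  expect_error(buildDesign(ann, "nosuch"), "lacks column")
  expect_error(buildDesign(data.frame(sample_id = "S1", group = "A"),
                           "group"), "fewer than 2 levels")
})

test_that("per-feature OLS matches hand computations and handles missingness", {
  ann <- twoGroupAnn()
  x <- rbind(F1 = c(1, 3, 5, 7),       # B - A = 4, s2 = 2, df = 2
             F2 = c(2, 2, 2, 2),       # constant
             F3 = c(1, NA, 4, 6))      # one missing -> df 1
  colnames(x) <- ann$sample_id
  ds <- makeDataset(x, groups = ann$group)
  X <- buildDesign(ann, "group", referenceLevels = list(group = "saline"))
  res <- fitLinearModel(ds, X, "groupdrug")
  tb <- resultTable(res)
  expect_equal(tb$logFC, c(4, 0, 4))
  # F3: group means 1 and 5, SSE = (4-5)^2 + (6-5)^2 = 2 on df = 1
  expect_equal(tb$s2, c(2, 0, 2))
  expect_equal(tb$df.residual, c(2, 2, 1))
  expect_equal(tb$AveExpr[1], 4)
  expect_error(fitLinearModel(ds, X, "nosuch"), "unknown contrast")
  expect_error(fitLinearModel(ds, X, c(0, 0)), "not be all zero")
})

test_that("on balanced two-group data logFC equals the group-mean difference", {
  withr::local_seed(21)
  ds <- makeTwoGroupData(50, 4, effect = 0.8, effectIdx = 1:10)
  ann <- as.data.frame(sampleMeta(ds))
  X <- buildDesign(ann, "group", referenceLevels = list(group = "ctrl"))
  res <- fitLinearModel(ds, X, "grouptreated")
  x <- intensities(ds)
  diffMeans <- rowMeans(x[, 5:8]) - rowMeans(x[, 1:4])
  expect_equal(resultTable(res)$logFC, unname(diffMeans), tolerance = 1e-12)
})

test_that("moderation shrinks variances between s0^2 and s_g^2 and fills p values", {
  withr::local_seed(22)
  # heterogeneous per-feature noise so the prior df is finite
  sds <- sqrt(1 / rchisq(300, 4) * 4)
  x <- matrix(rnorm(300 * 6, 20, sds), 300, 6)
  ds <- makeDataset(x, groups = rep(c("ctrl", "treated"), each = 3))
  ann <- as.data.frame(sampleMeta(ds))
  X <- buildDesign(ann, "group")
  res <- ebayesModerate(fitLinearModel(ds, X, "grouptreated"))
  pr <- variancePrior(res)
  expect_gt(pr$d0, 0)
  tb <- resultTable(res)
  s2post <- if (is.finite(pr$d0))
    (pr$d0 * pr$s0sq + tb$df.residual * tb$s2) / (pr$d0 + tb$df.residual)
  else rep(pr$s0sq, nrow(tb))
  expect_true(all(s2post >= pmin(pr$s0sq, tb$s2) - 1e-12))
  expect_true(all(s2post <= pmax(pr$s0sq, tb$s2) + 1e-12))
  expect_true(all(is.finite(tb$P.Value)))
  expect_true(all(tb$adj.P.Val >= tb$P.Value - 1e-12))
})

test_that("homogeneous variances give an infinite prior df", {
  # identical residual variance for every feature
  ann <- twoGroupAnn(6)
  x <- t(sapply(1:20, function(i) c(1, 2, 3, 1, 2, 3) + i))
  dimnames(x) <- list(paste0("F", 1:20), ann$sample_id)
  ds <- makeDataset(x, groups = ann$group)
  X <- buildDesign(ann, "group")
  res <- ebayesModerate(fitLinearModel(ds, X, paste0("group",
                                                     "saline")))
  pr <- variancePrior(res)
  expect_equal(pr$d0, Inf)
  expect_equal(pr$s0sq, resultTable(res)$s2[1], tolerance = 1e-9)
})

test_that("variance prior estimation recovers known d0 and s0^2", {
  withr::local_seed(23)
  d0 <- 4; s0sq <- 1; dg <- 6; n <- 5000
  sigma2 <- d0 * s0sq / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, dg) / dg
  est <- estimateVariancePrior(s2, dg)
  expect_gt(est$d0, 3); expect_lt(est$d0, 5)
  expect_gt(est$s0sq, 0.9); expect_lt(est$s0sq, 1.1)
})

test_that("null simulations give uniform moderated p and calibrated type-I error", {
  withr::local_seed(24)
  ds <- makeTwoGroupData(2000, 3)
  ann <- as.data.frame(sampleMeta(ds))
  X <- buildDesign(ann, "group")
  res <- ebayesModerate(fitLinearModel(ds, X, "grouptreated"))
  p <- resultTable(res)$P.Value
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  # 99% binomial envelope around alpha = 0.05
  n <- length(p)
  env <- qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(sum(p < 0.05), env[1])
  expect_lte(sum(p < 0.05), env[2])
})

test_that("BH adjustment matches the hand example and the step-up oracle", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustBH(0.3), 0.3)
  expect_equal(adjustBH(rep(1, 5)), rep(1, 5))
  expect_error(adjustBH(c(0.5, 1.2)), "0, 1")
  na <- adjustBH(c(0.01, NA, 0.5))
  expect_true(is.na(na[2]))
  withr::local_seed(25)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(adjustBH(p), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("batch correction removes additive offsets but respects aliasing", {
  withr::local_seed(26)
  ds <- makeTwoGroupData(100, 4)
  ann <- as.data.frame(sampleMeta(ds))
  ann$batch <- rep(c("b1", "b2"), 4)
  x <- intensities(ds)
  x[, ann$batch == "b2"] <- x[, ann$batch == "b2"] + 2
  ds2 <- makeDataset(x, groups = ann$group, extra = list(batch = ann$batch))
  X <- buildDesign(ann, "group")
  out <- correctBatchEffect(ds2, X, "batch")
  y <- intensities(out)
  bdiff <- rowMeans(y[, ann$batch == "b2"]) -
    rowMeans(y[, ann$batch == "b1"])
  expect_lt(max(abs(bdiff)), 1e-8)
  # no batch effect -> essentially unchanged
  out0 <- correctBatchEffect(
    makeDataset(intensities(ds), groups = ann$group,
                extra = list(batch = ann$batch)), X, "batch")
  expect_lt(max(abs(intensities(out0) - intensities(ds))), 0.5)
  annAliased <- ann
  annAliased$batch <- ann$group
  dsA <- makeDataset(x, groups = ann$group,
                     extra = list(batch = annAliased$batch))
  expect_error(correctBatchEffect(dsA, X, "batch"), "aliased")
})

test_that("batch correction improves group silhouette when batch dominates", {
  withr::local_seed(27)
  nFeat <- 200
  ds <- makeTwoGroupData(nFeat, 6, effect = 0.6, effectIdx = 1:60,
                         noiseSd = 0.3)
  ann <- as.data.frame(sampleMeta(ds))
  ann$batch <- rep(c("b1", "b2", "b3"), 4)
  x <- intensities(ds)
  for (b in unique(ann$batch)) {
    off <- rnorm(nFeat, 0, 2)        # batch sigma >> effect
    x[, ann$batch == b] <- x[, ann$batch == b] + off
  }
  noisy <- makeDataset(x, groups = ann$group,
                       extra = list(batch = ann$batch))
  X <- buildDesign(ann, "group")
  corrected <- correctBatchEffect(noisy, X, "batch")
  silRaw <- avgSilhouette(noisy)
  silCor <- avgSilhouette(corrected)
  expect_gt(silCor, silRaw)
})

test_that("ranking metric is signed -log10 p with max-magnitude gene collapse", {
  tb <- data.frame(
    feature_id = c("f1", "f2", "f3"),
    gene_symbol = c("G1", "G2", "G2"),
    logFC = c(2, -1, 1.2), AveExpr = 0, t = 1,
    P.Value = c(0.01, 0.001, 0.1), adj.P.Val = c(0.02, 0.004, 0.2),
    s2 = 1, df.residual = 4, stringsAsFactors = FALSE)
  res <- new("DiffExpResult", table = tb, contrast = c(x = 1),
             fit = NULL, moderated = TRUE, priorDf = 4, priorVar = 1)
  r <- rankMetric(res)
  expect_equal(r[["G1"]], 2)
  expect_equal(r[["G2"]], -3)          # max magnitude of {-3, +1.2...}
  expect_true(all(diff(r) <= 0))
  expect_error(rankMetric(makeFakeResult(c(a = 1, b = 2))), "moderated")
})
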