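#' @include AllClasses.R
NULL

#' Build a treatment-coded design matrix
#'
#' Factors are dummy-encoded against a reference level (lexicographically
#' first unless given in `referenceLevels`), with an intercept; numeric
#' covariates are mean-centered and passed through. Rank deficiency after
#' encoding is an error naming the aliased columns.
#'
#' @param annotation sample annotation `data.frame`.
#' @param factors character vector of factor column names (ordered).
#' @param covariates character vector of numeric covariate column names.
#' @param referenceLevels named list/character vector mapping factor name
#'   to its reference level.
#' @return numeric design matrix (samples x coefficients) with a
#'   `"terms"` attribute recording the generating spec.
#' @export
buildDesign <- function(annotation, factors, covariates = character(),
                        referenceLevels = list()) {
  annotation <- as.data.frame(annotation)
  miss <- setdiff(c(factors, covariates), colnames(annotation))
  if (length(miss))
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- data.frame(row.names = annotation$sample_id)
  for (f in factors) {
    v <- factor(as.character(annotation[[f]]))
    if (nlevels(v) < 2L)
      stop("factor '", f, "' has fewer than 2 levels", call. = FALSE)
    if (!is.null(referenceLevels[[f]]))
      v <- stats::relevel(v, ref = referenceLevels[[f]])
    df[[f]] <- v
  }
  for (cv in covariates) {
    v <- as.numeric(annotation[[cv]])
    df[[cv]] <- v - mean(v)
  }
  form <- stats::as.formula(paste("~", paste(c(factors, covariates),
                                             collapse = " + ")))
  X <- stats::model.matrix(form, data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased coefficient(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  attr(X, "terms") <- NULL
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  attr(X, "spec") <- list(factors = factors, covariates = covariates,
                          referenceLevels = referenceLevels)
  X
}

# contrast may be a coefficient name or a full-length numeric vector
.contrastVector <- function(contrast, design) {
  cn <- colnames(design)
  if (is.character(contrast)) {
    if (length(contrast) != 1L || !contrast %in% cn)
      stop("unknown contrast coefficient '", paste(contrast, collapse = ","),
           "'; available: ", paste(cn, collapse = ", "), call. = FALSE)
    cv <- as.numeric(cn == contrast)
  } else {
    cv <- as.numeric(contrast)
    if (length(cv) != ncol(design))
      stop("contrast vector length must equal the number of coefficients",
           call. = FALSE)
  }
  if (all(cv == 0)) stop("contrast must not be all zero", call. = FALSE)
  names(cv) <- cn
  cv
}

#' Fit per-feature linear models for a contrast
#'
#' Ordinary least squares per feature on that feature's observed samples
#' (complete-case per feature, residual df reduced accordingly), via
#' limma's `lmFit`/`contrasts.fit`. Returns the pre-moderation result:
#' logFC = contrast * beta-hat, the residual variance `s2` with its df,
#' and the average expression (mean of modeled values). Moderated t and p
#' are filled by [ebayesModerate()].
#'
#' @param ds a log-transformed [OmicsDataset-class].
#' @param design design matrix from [buildDesign()].
#' @param contrast coefficient name or numeric contrast vector.
#' @return a [DiffExpResult-class] (pre-moderation).
#' @export
fitLinearModel <- function(ds, design, contrast) {
  if (!isLogTransformed(ds))
    stop("linear modeling expects log-transformed intensities",
         call. = FALSE)
  x <- intensities(ds)
  if (nrow(design) != ncol(x))
    stop("design rows must match samples", call. = FALSE)
  cv <- .contrastVector(contrast, design)
  fit <- limma::lmFit(x, design)
  nDropped <- sum(is.na(fit$coefficients[, ncol(design)]))
  if (nDropped > 0)
    message(sprintf("fitLinearModel: %d feature(s) observed in fewer samples than coefficients; coefficients missing",
                    nDropped))
  fit2 <- limma::contrasts.fit(fit, contrasts = cv)
  fm <- rowData(ds)
  tb <- data.frame(
    feature_id = as.character(fm$feature_id),
    gene_symbol = as.character(fm$gene_symbol),
    logFC = as.vector(fit2$coefficients),
    AveExpr = rowMeans(x, na.rm = TRUE),
    t = NA_real_, P.Value = NA_real_, adj.P.Val = NA_real_,
    s2 = as.vector(fit2$sigma)^2,
    df.residual = as.vector(fit2$df.residual),
    stringsAsFactors = FALSE, row.names = NULL)
  new("DiffExpResult", table = tb, contrast = cv, fit = fit2,
      moderated = FALSE)
}

#' Empirical Bayes variance moderation
#'
#' Fits a scaled inverse chi-square prior to the per-feature residual
#' variances by moment matching on log s2 (trigamma inversion; d0 may be
#' infinite when the variances show no excess spread), shrinks each
#' variance to the posterior s2_tilde = (d0 s0^2 + d s2)/(d0 + d), and
#' computes moderated t statistics with d0 + d degrees of freedom
#' (standard normal when d0 is infinite), two-sided p values, and
#' BH-adjusted p values. Features with zero residual df keep missing
#' t/p and are excluded from prior estimation.
#'
#' @param result a [DiffExpResult-class] from [fitLinearModel()].
#' @return the moderated [DiffExpResult-class].
#' @export
ebayesModerate <- function(result) {
  fit2 <- result@fit
  ok <- fit2$df.residual > 0 & !is.na(fit2$sigma)
  if (sum(ok) < 2L)
    stop("need >= 2 features with positive residual df", call. = FALSE)
  if (all(fit2$sigma[ok] == 0))
    stop("all residual variances are zero (degenerate data)",
         call. = FALSE)
  eb <- limma::eBayes(fit2, robust = FALSE)
  tb <- result@table
  tb$t <- as.vector(eb$t)
  tb$P.Value <- as.vector(eb$p.value)
  noDf <- tb$df.residual == 0 | is.na(tb$df.residual)
  tb$t[noDf] <- NA_real_
  tb$P.Value[noDf] <- NA_real_
  tb$adj.P.Val <- adjustBH(tb$P.Value)
  new("DiffExpResult", table = tb, contrast = result@contrast, fit = eb,
      moderated = TRUE, priorDf = eb$df.prior[1L],
      priorVar = eb$s2.prior[1L])
}

#' Estimate the variance prior from observed variances
#'
#' Moment-matching fit of the scaled inverse chi-square prior
#' (equivalently, an F-distribution fit to s2/s0^2) used by
#' [ebayesModerate()], exposed for calibration studies.
#'
#' @param s2 per-feature residual variances.
#' @param df per-feature residual degrees of freedom (scalar or vector).
#' @return list with `d0` (prior df, possibly `Inf`) and `s0sq`.
#' @export
estimateVariancePrior <- function(s2, df) {
  out <- limma::fitFDist(s2, df1 = df)
  list(d0 = out$df2, s0sq = out$scale)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with cumulative-minimum enforcement, capped at 1,
#' order-preserving with the input; missing values pass through.
#'
#' @param pvals numeric p values in \[0, 1\] (NA allowed).
#' @return adjusted p values aligned with the input.
#' @export
adjustBH <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Subtract batch effects for visualization
#'
#' Estimates batch coefficients jointly with the protected biological
#' design and subtracts only the batch contribution from the matrix
#' (limma's `removeBatchEffect`). Intended for visualization; the modeling
#' path keeps batch in the design so its variance is accounted for within
#' the model.
#'
#' @param ds a log-transformed [OmicsDataset-class].
#' @param design design matrix encoding the biological terms to protect.
#' @param batchColumn sample-annotation column holding the batch label
#'   (>= 2 levels).
#' @return the batch-corrected dataset.
#' @export
correctBatchEffect <- function(ds, design, batchColumn = "batch") {
  batch <- sampleMeta(ds)[[batchColumn]]
  if (is.null(batch)) stop("no such annotation column: ", batchColumn,
                           call. = FALSE)
  batch <- factor(as.character(batch))
  if (nlevels(batch) < 2L)
    stop("batch column needs >= 2 levels", call. = FALSE)
  bmat <- stats::model.matrix(~batch)[, -1L, drop = FALSE]
  if (qr(cbind(design, bmat))$rank < ncol(design) + ncol(bmat))
    stop("batch is aliased with a protected design factor", call. = FALSE)
  x <- limma::removeBatchEffect(intensities(ds), batch = batch,
                                design = design)
  assay(ds, "intensities") <- x
  ds
}

#' Ranking metric for preranked GSEA
#'
#' Per-feature score = sign(logFC) * -log10(raw p); features are ordered
#' by |score| (ties by |logFC|, then feature id) and, when several
#' features map to one gene, the score of largest magnitude is kept.
#'
#' @param result a moderated [DiffExpResult-class].
#' @param scheme ranking scheme (only `"signed_logp"`).
#' @return named numeric vector: gene symbol -> score, sorted decreasing.
#' @export
rankMetric <- function(result, scheme = c("signed_logp")) {
  scheme <- match.arg(scheme)
  if (!result@moderated)
    stop("rankMetric expects a moderated result", call. = FALSE)
  tb <- resultTable(result)
  tb <- tb[is.finite(tb$P.Value) & is.finite(tb$logFC), , drop = FALSE]
  score <- sign(tb$logFC) * (-log10(tb$P.Value))
  ord <- order(-abs(score), -abs(tb$logFC), tb$feature_id)
  tb <- tb[ord, ]
  score <- score[ord]
  keep <- !duplicated(tb$gene_symbol)    # first = largest magnitude
  out <- score[keep]
  names(out) <- tb$gene_symbol[keep]
  sort(out, decreasing = TRUE)
}
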