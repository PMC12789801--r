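#' @include AllClasses.R
NULL

#' Remove flagged contaminant and reverse-decoy features
#'
#' @param ds an [OmicsDataset-class] with `is_contaminant` / `is_reverse`
#'   flags populated.
#' @return the dataset without flagged rows.
#' @export
filterFlagged <- function(ds) {
  fm <- rowData(ds)
  drop <- fm$is_contaminant | fm$is_reverse
  if (all(drop))
    stop("all features are flagged as contaminant/reverse", call. = FALSE)
  message(sprintf("filterFlagged: removed %d contaminant and %d reverse of %d features",
                  sum(fm$is_contaminant), sum(fm$is_reverse), nrow(fm)))
  ds[!drop, ]
}

#' Filter features by missing-value fraction
#'
#' Removes rows whose fraction of missing samples exceeds
#' `maxMissingFrac` (default 0.30).
#'
#' @param ds an [OmicsDataset-class].
#' @param maxMissingFrac maximum tolerated missing fraction in \[0, 1\].
#' @return the filtered dataset.
#' @export
filterMissing <- function(ds, maxMissingFrac = 0.30) {
  stopifnot(maxMissingFrac >= 0, maxMissingFrac <= 1)
  frac <- rowMeans(is.na(intensities(ds)))
  keep <- frac <= maxMissingFrac
  message(sprintf("filterMissing: removed %d/%d features with missing fraction > %.2f",
                  sum(!keep), length(keep), maxMissingFrac))
  ds[keep, ]
}

#' Log-transform intensities
#'
#' @param ds an [OmicsDataset-class] not yet log transformed.
#' @param base logarithm base (default 2).
#' @param pseudocount added before taking the log (default 0).
#' @return the transformed dataset with its log flag set.
#' @export
logTransform <- function(ds, base = 2, pseudocount = 0) {
  if (isLogTransformed(ds))
    stop("dataset is already log-transformed", call. = FALSE)
  x <- intensities(ds) + pseudocount
  bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive value at feature '%s', sample '%s' (use a pseudocount)",
                 rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]]),
         call. = FALSE)
  assay(ds, "intensities") <- log(x, base = base)
  ds@logTransformed <- TRUE
  ds
}

# raw MAD, no consistency constant: median(|x - median(x)|)
.rawMad <- function(x) stats::median(abs(x - stats::median(x)))

#' Normalize a log-scale intensity matrix
#'
#' All methods operate on log2-scale data; missing values are ignored per
#' column and preserved in place.
#'
#' * `quantile` — every column receives the row-rank means
#'   (limma's quantile normalization), so all columns share identical
#'   sorted values.
#' * `median` — each column is shifted so its median equals the grand mean
#'   of column medians.
#' * `medianMAD` — each column is affinely mapped so its median and raw MAD
#'   equal the grand means of column medians and MADs.
#' * `loess` — pairwise cyclic loess on MA pairs (span 0.7, 3 cycles).
#' * `ztransform` — each column centered to mean 0, sd 1.
#' * `irs` — internal reference scaling: per TMT plex, features are
#'   rescaled by the (log-scale arithmetic = raw-scale geometric) mean
#'   ratio of reference-sample intensities across plexes.
#' * `none` — identity (useful as a baseline in
#'   [evaluateNormalizations()]).
#'
#' @param ds a log-transformed [OmicsDataset-class].
#' @param method normalization method name.
#' @param irsReference optional character vector of reference sample ids
#'   for `irs` (default: all samples of each plex).
#' @param plexColumn sample-annotation column holding the plex label.
#' @return the normalized dataset.
#' @export
normalizeIntensities <- function(ds,
                                 method = c("median", "quantile", "medianMAD",
                                            "loess", "ztransform", "irs",
                                            "none"),
                                 irsReference = NULL, plexColumn = "plex") {
  method <- match.arg(method)
  if (!isLogTransformed(ds))
    stop("normalization expects log-transformed intensities", call. = FALSE)
  x <- intensities(ds)
  if (method != "none" && any(colSums(!is.na(x)) == 0))
    stop("column with all values missing", call. = FALSE)
  y <- switch(method,
    none = x,
    quantile = limma::normalizeQuantiles(x, ties = TRUE),
    median = {
      med <- apply(x, 2L, stats::median, na.rm = TRUE)
      sweep(x, 2L, med - mean(med))
    },
    medianMAD = {
      med <- apply(x, 2L, stats::median, na.rm = TRUE)
      md <- apply(x, 2L, function(v) .rawMad(v[!is.na(v)]))
      if (any(md == 0))
        stop("medianMAD: column with zero MAD", call. = FALSE)
      tm <- mean(med); td <- mean(md)
      sweep(sweep(sweep(x, 2L, med), 2L, md, "/") * td, 2L, tm, "+")
    },
    loess = limma::normalizeCyclicLoess(x, span = 0.7, iterations = 3,
                                        method = "pairs"),
    ztransform = {
      mu <- colMeans(x, na.rm = TRUE)
      sdv <- apply(x, 2L, stats::sd, na.rm = TRUE)
      if (any(sdv == 0)) stop("ztransform: constant column", call. = FALSE)
      sweep(sweep(x, 2L, mu), 2L, sdv, "/")
    },
    irs = {
      plex <- sampleMeta(ds)[[plexColumn]]
      if (is.null(plex) || any(is.na(plex)))
        stop("irs requires a complete '", plexColumn,
             "' column in the sample annotation", call. = FALSE)
      plex <- as.character(plex)
      plexes <- unique(plex)
      if (length(plexes) < 2L)
        stop("irs requires at least two plexes", call. = FALSE)
      refIds <- if (is.null(irsReference)) colnames(x) else irsReference
      refMat <- vapply(plexes, function(p) {
        cols <- colnames(x)[plex == p & colnames(x) %in% refIds]
        if (length(cols) == 0L)
          stop("irs: plex '", p, "' has no reference samples",
               call. = FALSE)
        rowMeans(x[, cols, drop = FALSE], na.rm = TRUE)
      }, numeric(nrow(x)))
      target <- rowMeans(refMat, na.rm = TRUE)
      adj <- target - refMat            # per feature x plex, on log scale
      y <- x
      for (p in plexes)
        y[, plex == p] <- x[, plex == p, drop = FALSE] + adj[, p]
      y
    })
  y[is.na(x)] <- NA_real_
  dimnames(y) <- dimnames(x)
  assay(ds, "intensities") <- y
  ds
}

#' Local least squares imputation
#'
#' Fills each missing cell by least-squares regression (with intercept) of
#' the target feature on its `k` most correlated (absolute Pearson,
#' complete pairwise observations) neighbour features that are fully
#' observed in the columns needed for both fitting and prediction.
#' Features with no eligible neighbour fall back to their row mean.
#' Observed values are never modified.
#'
#' @param ds a normalized, log-scale [OmicsDataset-class]; every row must
#'   have at least one observed value.
#' @param k number of neighbour features (default 10).
#' @return the dataset with missing cells imputed.
#' @export
imputeLLS <- function(ds, k = 10) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  x <- intensities(ds)
  if (any(rowSums(!is.na(x)) == 0))
    stop("every feature must have at least one observed value",
         call. = FALSE)
  if (!anyNA(x)) return(ds)
  complete <- !rowSums(is.na(x))         # fully observed features
  out <- x
  for (i in which(rowSums(is.na(x)) > 0)) {
    obs <- !is.na(x[i, ])
    mis <- !obs
    cand <- which(complete)
    cand <- setdiff(cand, i)
    fallback <- mean(x[i, obs])
    fill <- rep(fallback, sum(mis))
    if (length(cand) > 0 && sum(obs) >= 2L) {
      tgt <- x[i, obs]
      cors <- suppressWarnings(
        as.vector(stats::cor(tgt, t(x[cand, obs, drop = FALSE]))))
      eligible <- which(is.finite(cors))
      if (length(eligible) > 0) {
        ord <- eligible[order(-abs(cors[eligible]))]
        nb <- cand[utils::head(ord, min(k, length(ord)))]
        A <- cbind(1, t(x[nb, obs, drop = FALSE]))
        qrA <- qr(A)
        beta <- qr.coef(qrA, tgt)
        beta[is.na(beta)] <- 0
        fill <- as.vector(cbind(1, t(x[nb, mis, drop = FALSE])) %*% beta)
      }
    }
    out[i, mis] <- fill
  }
  assay(ds, "intensities") <- out
  ds
}

#' Pooled within-group variation metrics
#'
#' Per group with at least two replicates, and per feature completely
#' observed in that group: raw MAD (no consistency constant), coefficient
#' of variation sd/|mean| (sample sd), and variance across the group's
#' replicates. The per-group value is the mean over features; the pooled
#' metric is the mean over qualifying groups. Lower values indicate better
#' within-group reproducibility.
#'
#' @param ds an [OmicsDataset-class].
#' @param groupColumn sample-annotation column defining replicate groups.
#' @return named numeric vector `c(PMAD =, PCV =, PEV =)`.
#' @export
qcMetrics <- function(ds, groupColumn = "group") {
  x <- intensities(ds)
  grp <- as.character(sampleMeta(ds)[[groupColumn]])
  if (is.null(grp)) stop("no such annotation column: ", groupColumn,
                         call. = FALSE)
  groups <- names(which(table(grp) >= 2))
  if (length(groups) == 0L)
    stop("no group with >= 2 replicates", call. = FALSE)
  perGroup <- vapply(groups, function(g) {
    xg <- x[, grp == g, drop = FALSE]
    ok <- rowSums(is.na(xg)) == 0
    xg <- xg[ok, , drop = FALSE]
    if (nrow(xg) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    mads <- apply(xg, 1L, .rawMad)
    mns <- rowMeans(xg)
    sds <- apply(xg, 1L, stats::sd)
    cvs <- sds / abs(mns)
    c(mean(mads), mean(cvs[is.finite(cvs)]), mean(sds^2))
  }, numeric(3))
  pooled <- rowMeans(perGroup, na.rm = TRUE)
  c(PMAD = pooled[[1L]], PCV = pooled[[2L]], PEV = pooled[[3L]])
}

# silhouette widths with the singleton-scores-zero convention
.silhouetteWidths <- function(d, cluster) {
  d <- as.matrix(d)
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    own <- cluster == cluster[i]
    nOwn <- sum(own) - 1L
    if (nOwn == 0L) return(0)          # singleton convention
    a <- sum(d[i, own]) / nOwn
    b <- min(vapply(setdiff(unique(cluster), cluster[i]),
                    function(cl) mean(d[i, cluster == cl]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

#' Average silhouette width of the known sample groups
#'
#' Euclidean silhouette over sample vectors, either in the space of the
#' top principal components of the complete-feature submatrix (default,
#' `space = "top_pcs"`) or on the complete features directly. Samples in
#' singleton groups score 0. Higher values indicate better group
#' separation.
#'
#' @param ds an [OmicsDataset-class].
#' @param groupColumn grouping column of the sample annotation.
#' @param space `"top_pcs"` or `"features"`.
#' @param nPcs number of principal components when `space = "top_pcs"`.
#' @return the average silhouette width in \[-1, 1\].
#' @export
avgSilhouette <- function(ds, groupColumn = "group",
                          space = c("top_pcs", "features"), nPcs = 2) {
  space <- match.arg(space)
  grp <- as.character(sampleMeta(ds)[[groupColumn]])
  if (is.null(grp)) stop("no such annotation column: ", groupColumn,
                         call. = FALSE)
  if (length(unique(grp)) < 2L)
    stop("silhouette needs >= 2 groups", call. = FALSE)
  x <- intensities(ds)
  x <- x[rowSums(is.na(x)) == 0, , drop = FALSE]
  if (nrow(x) == 0L) stop("no complete features for silhouette",
                          call. = FALSE)
  pts <- t(x)
  if (space == "top_pcs") {
    pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
    pts <- pc$x[, seq_len(min(nPcs, ncol(pc$x))), drop = FALSE]
  }
  mean(.silhouetteWidths(stats::dist(pts), grp))
}

#' Evaluate candidate normalization methods
#'
#' Runs each method through [normalizeIntensities()], scores it with
#' [qcMetrics()] and [avgSilhouette()], and recommends the method with the
#' best rank-sum (ascending ranks for PMAD/PCV/PEV, descending for
#' silhouette). Ties are broken by the order methods were given.
#'
#' @param ds a log-transformed [OmicsDataset-class].
#' @param methods character vector of >= 2 method names accepted by
#'   [normalizeIntensities()].
#' @param groupColumn grouping column for the metrics.
#' @param ... passed to [normalizeIntensities()] (e.g. `plexColumn`).
#' @return a [NormalizationReport-class].
#' @export
evaluateNormalizations <- function(ds,
                                   methods = c("none", "median", "medianMAD",
                                               "quantile", "loess"),
                                   groupColumn = "group", ...) {
  if (length(methods) < 2L)
    stop("need at least two methods to compare", call. = FALSE)
  rows <- lapply(methods, function(m) {
    dn <- normalizeIntensities(ds, method = m, ...)
    qc <- qcMetrics(dn, groupColumn)
    sil <- avgSilhouette(dn, groupColumn)
    data.frame(method = m, PMAD = qc[["PMAD"]], PCV = qc[["PCV"]],
               PEV = qc[["PEV"]], silhouette = sil,
               stringsAsFactors = FALSE)
  })
  tb <- do.call(rbind, rows)
  tb$rank_sum <- rank(tb$PMAD, ties.method = "average") +
    rank(tb$PCV, ties.method = "average") +
    rank(tb$PEV, ties.method = "average") +
    rank(-tb$silhouette, ties.method = "average")
  best <- which(tb$rank_sum == min(tb$rank_sum))[1L]
  tb$recommended <- seq_len(nrow(tb)) == best
  new("NormalizationReport", table = tb, groupColumn = groupColumn)
}

#' Most variable features
#'
#' Features ranked by variance across samples (missing values excluded);
#' the top `ceiling(topFrac * n)` are returned.
#'
#' @param ds an [OmicsDataset-class].
#' @param topFrac fraction of features to keep (default 0.10).
#' @return character vector of feature ids, most variable first.
#' @export
variableFeatures <- function(ds, topFrac = 0.10) {
  stopifnot(topFrac > 0, topFrac <= 1)
  x <- intensities(ds)
  v <- apply(x, 1L, stats::var, na.rm = TRUE)
  v[is.na(v)] <- -Inf
  n <- ceiling(topFrac * nrow(x))
  ids <- as.character(rowData(ds)$feature_id)
  ids[order(-v)][seq_len(n)]
}

#' Principal component scores of samples
#'
#' Feature-wise mean-centered PCA on the complete-feature submatrix.
#'
#' @param ds an [OmicsDataset-class].
#' @param nComponents number of components to return.
#' @return list with `scores` (samples x components), `loadings`
#'   (features x components) and `varianceFraction` (non-increasing,
#'   summing to <= 1).
#' @export
pcaScores <- function(ds, nComponents = 2) {
  x <- intensities(ds)
  x <- x[rowSums(is.na(x)) == 0, , drop = FALSE]
  if (nComponents > min(dim(x)))
    stop("nComponents exceeds matrix dimensions", call. = FALSE)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  idx <- seq_len(nComponents)
  list(scores = pc$x[, idx, drop = FALSE],
       loadings = pc$rotation[, idx, drop = FALSE],
       varianceFraction = (pc$sdev^2 / sum(pc$sdev^2))[idx])
}

#' Mean-difference table
#'
#' Per-feature (average expression, logFC) pairs from a fitted result, for
#' MD plots and export.
#'
#' @param result a [DiffExpResult-class].
#' @return `data.frame` with `feature_id`, `AveExpr`, `logFC`.
#' @export
mdTable <- function(result) {
  tb <- resultTable(result)
  tb[, c("feature_id", "AveExpr", "logFC")]
}
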