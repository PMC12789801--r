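#' @include AllClasses.R
NULL

#' Standardize a layer's logFCs for integration
#'
#' Transforms each feature's log fold change into a z-score using the
#' layer's mean and sample standard deviation,
#' z_i = (logFC_i - mu_j) / sigma_j, and assigns the layer weight
#' w_j = u_j / sqrt(N_j) where N_j is the number of features with finite
#' logFC and u_j an optional user multiplier (default 1). The inverse
#' square-root weighting keeps layers of very different sizes (e.g. a
#' 10^4-protein proteome vs a 2x10^4-site phosphoproteome) on a fair
#' footing when combined.
#'
#' @param result a [DiffExpResult-class] (typically moderated) carrying
#'   per-feature logFCs and gene symbols.
#' @param layerName label for the layer.
#' @param userWeight positive multiplier u_j (default 1).
#' @return a [LayerStats-class].
#' @export
layerStats <- function(result, layerName, userWeight = 1) {
  stopifnot(userWeight > 0)
  tb <- resultTable(result)
  tb <- tb[is.finite(tb$logFC), , drop = FALSE]
  n <- nrow(tb)
  if (n < 2L)
    stop("layer '", layerName, "' has fewer than 2 finite logFCs",
         call. = FALSE)
  mu <- mean(tb$logFC)
  sigma <- stats::sd(tb$logFC)
  if (sigma == 0)
    stop("layer '", layerName, "' has zero logFC spread (degenerate)",
         call. = FALSE)
  out <- data.frame(feature_id = tb$feature_id,
                    gene_symbol = tb$gene_symbol,
                    logFC = tb$logFC,
                    z = (tb$logFC - mu) / sigma,
                    stringsAsFactors = FALSE)
  new("LayerStats", layerName = as.character(layerName), table = out,
      mu = mu, sigma = sigma, nFeatures = as.integer(n),
      userWeight = userWeight, weight = userWeight / sqrt(n))
}

#' Integrate layers into gene-level S-scores
#'
#' Full join on gene symbol across layers (case-sensitive). For each gene
#' the combined weighted z-score sums w*z over ALL contributing feature
#' records — a gene measured by m features within one layer contributes m
#' terms — and the combined weight is sqrt(sum of w^2) over the same
#' records, so that
#' S = comb_wz / comb_w
#' is standard normal under the null for any weights. Genes present in
#' only some layers use only those layers' terms. Two-sided p values
#' come from the normal CDF and are BH-adjusted over all emitted genes.
#'
#' With `collapse = TRUE`, multiple features of a gene within one layer
#' are first collapsed to the single record of largest |z| (off by
#' default; the default multiplicity rule preserves unit null variance).
#'
#' @param layers list of [LayerStats-class] objects.
#' @param alpha significance threshold for the `significant` flag
#'   (default 0.05).
#' @param collapse collapse within-layer multiplicity to max-|z|.
#' @return an [SScoreTable-class].
#' @export
integrateLayers <- function(layers, alpha = 0.05, collapse = FALSE) {
  if (is(layers, "LayerStats")) layers <- list(layers)
  if (length(layers) < 1L) stop("need >= 1 layer", call. = FALSE)
  contrib <- do.call(rbind, lapply(layers, function(ly) {
    tb <- ly@table
    data.frame(gene = tb$gene_symbol, layer = ly@layerName,
               feature_id = tb$feature_id, z = tb$z, w = ly@weight,
               stringsAsFactors = FALSE)
  }))
  contrib <- contrib[!is.na(contrib$gene) & contrib$gene != "", ,
                     drop = FALSE]
  if (nrow(contrib) == 0L)
    stop("empty join: no genes with symbols across layers", call. = FALSE)
  if (collapse) {
    ord <- order(contrib$gene, contrib$layer, -abs(contrib$z),
                 contrib$feature_id)
    contrib <- contrib[ord, ]
    contrib <- contrib[!duplicated(contrib[, c("gene", "layer")]), ]
  }
  contrib$wz <- contrib$w * contrib$z
  genes <- unique(contrib$gene)
  idx <- factor(match(contrib$gene, genes), levels = seq_along(genes))
  comb_wz <- as.vector(tapply(contrib$wz, idx, sum))
  comb_w <- sqrt(as.vector(tapply(contrib$w^2, idx, sum)))
  nRec <- as.vector(tapply(contrib$w, idx, length))
  nLay <- as.vector(tapply(contrib$layer, idx,
                           function(l) length(unique(l))))
  S <- comb_wz / comb_w
  p <- 2 * stats::pnorm(-abs(S))
  adj <- adjustBH(p)
  tb <- data.frame(gene = genes, comb_wz = comb_wz, comb_w = comb_w,
                   sscore = S, sscore_pval = p, sscore_adj_pval = adj,
                   significant = adj < alpha, n_records = nRec,
                   n_layers = nLay, stringsAsFactors = FALSE)
  tb <- tb[order(-abs(tb$sscore)), ]
  rownames(tb) <- NULL
  new("SScoreTable", table = tb, contributions = contrib, alpha = alpha)
}

#' Significant integrated genes
#'
#' @param sscores an [SScoreTable-class].
#' @param alpha adjusted-p threshold (defaults to the table's alpha).
#' @return character vector of genes with `sscore_adj_pval < alpha`,
#'   ordered by |S| descending.
#' @export
significantGenes <- function(sscores, alpha = NULL) {
  if (is.null(alpha)) alpha <- sscores@alpha
  tb <- resultTable(sscores)
  tb <- tb[tb$sscore_adj_pval < alpha, , drop = FALSE]
  tb$gene[order(-abs(tb$sscore))]
}

#' Write an S-score table as TSV
#'
#' Column names follow the integration output convention (`gene`,
#' `comb_wz`, `comb_w`, `sscore`, `sscore_pval`, `sscore_adj_pval`).
#'
#' @param sscores an [SScoreTable-class].
#' @param path output path.
#' @export
writeSScores <- function(sscores, path) {
  utils::write.table(resultTable(sscores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
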