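#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   rowData rowData<- colData
NULL

#' OmicsDataset: one omic layer as a SummarizedExperiment
#'
#' Container for a single omics layer (proteome, phosphoproteome,
#' metabolome, ...): a feature-by-sample intensity matrix plus per-feature
#' metadata (`feature_id`, `gene_symbol`, contaminant/reverse flags) in
#' `rowData` and per-sample metadata (`sample_id`, `group`, `replicate`,
#' `batch`, `plex`, user covariates) in `colData`.
#'
#' @slot layerName short label for the layer, e.g. `"proteome"`.
#' @slot logTransformed `TRUE` once intensities are on log scale.
#' @export
setClass("OmicsDataset",
  contains = "SummarizedExperiment",
  representation(layerName = "character", logTransformed = "logical"),
  prototype(layerName = "layer", logTransformed = FALSE)
)

setValidity("OmicsDataset", function(object) {
  msg <- character()
  fm <- rowData(object)
  if (!all(c("feature_id", "gene_symbol", "is_contaminant", "is_reverse")
           %in% colnames(fm)))
    msg <- c(msg, "rowData must contain feature_id, gene_symbol, is_contaminant, is_reverse")
  if ("feature_id" %in% colnames(fm) && anyDuplicated(fm$feature_id))
    msg <- c(msg, "feature_id values must be unique within a layer")
  sm <- colData(object)
  if (!"sample_id" %in% colnames(sm))
    msg <- c(msg, "colData must contain sample_id")
  else if (anyDuplicated(sm$sample_id))
    msg <- c(msg, "sample_id values must be unique")
  if (length(object@layerName) != 1L)
    msg <- c(msg, "layerName must be a single string")
  if (length(object@logTransformed) != 1L)
    msg <- c(msg, "logTransformed must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsDataset
#'
#' @param intensities numeric feature-by-sample matrix (NA = missing).
#' @param featureMeta data.frame/DataFrame with at least `feature_id`;
#'   `gene_symbol`, `is_contaminant`, `is_reverse` are filled with defaults
#'   when absent.
#' @param sampleMeta data.frame/DataFrame with at least `sample_id` and
#'   `group`.
#' @param layerName label for the layer.
#' @param logTransformed whether `intensities` are already log scale.
#' @return an [OmicsDataset-class] object.
#' @export
OmicsDataset <- function(intensities, featureMeta, sampleMeta,
                         layerName = "layer", logTransformed = FALSE) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  featureMeta <- as(as.data.frame(featureMeta), "DataFrame")
  sampleMeta <- as(as.data.frame(sampleMeta), "DataFrame")
  if (is.null(featureMeta$gene_symbol))
    featureMeta$gene_symbol <- as.character(featureMeta$feature_id)
  if (is.null(featureMeta$is_contaminant))
    featureMeta$is_contaminant <- FALSE
  if (is.null(featureMeta$is_reverse))
    featureMeta$is_reverse <- FALSE
  rownames(intensities) <- as.character(featureMeta$feature_id)
  colnames(intensities) <- as.character(sampleMeta$sample_id)
  se <- SummarizedExperiment(assays = list(intensities = intensities),
                             rowData = featureMeta, colData = sampleMeta)
  new("OmicsDataset", se, layerName = as.character(layerName),
      logTransformed = isTRUE(logTransformed))
}

#' Per-feature differential expression result
#'
#' Holds the per-feature linear-model output for one contrast: log2 fold
#' change, average expression, ordinary residual variance `s2` with residual
#' degrees of freedom, and (after [ebayesModerate()]) moderated t, raw and
#' BH-adjusted p, plus the global variance prior (`priorDf` = d0,
#' `priorVar` = s0^2).
#'
#' @slot table per-feature `data.frame` (`feature_id`, `gene_symbol`,
#'   `logFC`, `AveExpr`, `t`, `P.Value`, `adj.P.Val`, `s2`, `df.residual`).
#' @slot priorDf prior degrees of freedom d0 (NA before moderation; may be
#'   `Inf`).
#' @slot priorVar prior variance s0^2 (NA before moderation).
#' @slot moderated logical flag.
#' @slot contrast the contrast vector used.
#' @slot fit internal limma fit object (list) used by [ebayesModerate()].
#' @export
setClass("DiffExpResult",
  representation(table = "data.frame", priorDf = "numeric",
                 priorVar = "numeric", moderated = "logical",
                 contrast = "numeric", fit = "ANY"),
  prototype(priorDf = NA_real_, priorVar = NA_real_, moderated = FALSE)
)

setValidity("DiffExpResult", function(object) {
  tb <- object@table
  need <- c("feature_id", "gene_symbol", "logFC", "AveExpr", "t",
            "P.Value", "adj.P.Val", "s2", "df.residual")
  if (!all(need %in% colnames(tb)))
    return(paste("table must contain:", paste(need, collapse = ", ")))
  if (any(tb$df.residual < 0, na.rm = TRUE))
    return("df.residual must be >= 0")
  ok <- is.finite(tb$P.Value) & is.finite(tb$adj.P.Val)
  if (any(tb$adj.P.Val[ok] < tb$P.Value[ok] - 1e-12))
    return("adjusted p must be >= raw p")
  TRUE
})

#' Per-layer standardized logFC statistics
#'
#' Output of [layerStats()]: each feature's logFC transformed to a z-score
#' using the layer mean and standard deviation, with the layer weight
#' w = u / sqrt(N) where N is the number of features with finite logFC and
#' u an optional user multiplier.
#'
#' @slot layerName layer label.
#' @slot table `data.frame` (`feature_id`, `gene_symbol`, `logFC`, `z`).
#' @slot mu mean logFC of the layer.
#' @slot sigma sample sd of the layer's logFCs.
#' @slot nFeatures N, the number of features with finite logFC.
#' @slot userWeight user multiplier u (default 1).
#' @slot weight w = u / sqrt(N).
#' @export
setClass("LayerStats",
  representation(layerName = "character", table = "data.frame",
                 mu = "numeric", sigma = "numeric", nFeatures = "integer",
                 userWeight = "numeric", weight = "numeric")
)

setValidity("LayerStats", function(object) {
  if (object@sigma <= 0) return("sigma must be > 0")
  if (object@nFeatures < 2L) return("layer must have >= 2 features")
  if (object@weight <= 0) return("weight must be > 0")
  TRUE
})

#' Gene-level integrated S-score table
#'
#' @slot table per-gene `data.frame` with `gene`, `comb_wz`, `comb_w`,
#'   `sscore`, `sscore_pval`, `sscore_adj_pval`, `significant`, `n_records`,
#'   `n_layers`.
#' @slot contributions per-record `data.frame` (`gene`, `layer`,
#'   `feature_id`, `z`, `w`, `wz`).
#' @slot alpha significance threshold used for the `significant` flag.
#' @export
setClass("SScoreTable",
  representation(table = "data.frame", contributions = "data.frame",
                 alpha = "numeric")
)

setValidity("SScoreTable", function(object) {
  tb <- object@table
  if (any(tb$comb_w <= 0)) return("comb_w must be > 0 for every gene")
  p <- 2 * stats::pnorm(-abs(tb$sscore))
  if (any(abs(tb$sscore_pval - p) > 1e-12))
    return("sscore_pval must equal 2*pnorm(-|S|)")
  if (any(tb$sscore_adj_pval < tb$sscore_pval - 1e-12))
    return("adjusted p must be >= raw p")
  TRUE
})

#' Confidence-weighted interaction network
#'
#' Undirected simple graph keyed by gene symbol; every edge carries a
#' `confidence` in \[0, 1\] (at or above the configured cutoff) and, after
#' [assignEdgeCosts()], a `cost`.
#'
#' @slot graph an `igraph` object.
#' @slot minConfidence the confidence cutoff applied at load time.
#' @export
setClass("InteractionNetwork",
  representation(graph = "ANY", minConfidence = "numeric")
)

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::any_loop(g)) return("no self-loops allowed")
  if (igraph::any_multiple(g)) return("no parallel edges allowed")
  conf <- igraph::E(g)$confidence
  if (igraph::ecount(g) > 0) {
    if (is.null(conf)) return("edges must carry a confidence attribute")
    if (any(conf < 0 | conf > 1)) return("confidence must lie in [0, 1]")
    if (any(conf < object@minConfidence - 1e-12))
      return("all retained edges must meet the confidence cutoff")
  }
  TRUE
})

#' Node prizes for subnetwork extraction
#'
#' @slot table `data.frame` with `node`, `rawPrize` (|S| for significant
#'   genes, else 0), `degree` (in the filtered base network),
#'   `effectivePrize` (= max(0, rawPrize - mu*degree)), `terminal`
#'   (rawPrize > 0), and `sscore` (signed, for export).
#' @slot mu hub penalty applied.
#' @slot alpha significance threshold used to pick terminals.
#' @export
setClass("PrizeMap",
  representation(table = "data.frame", mu = "numeric", alpha = "numeric")
)

setValidity("PrizeMap", function(object) {
  if (any(object@table$rawPrize < 0)) return("raw prizes must be >= 0")
  if (any(object@table$effectivePrize < 0))
    return("effective prizes must be >= 0")
  TRUE
})

#' Extracted prize-collecting Steiner forest
#'
#' @slot graph `igraph` of the solution; node attributes `prize` (effective),
#'   `terminal`, `sscore`; edge attributes `cost`, `confidence`.
#' @slot objective value of sum(prizes) - lambda * sum(costs).
#' @slot lambda edge-cost multiplier used.
#' @export
setClass("PCSFSolution",
  representation(graph = "ANY", objective = "numeric", lambda = "numeric")
)

setValidity("PCSFSolution", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  nv <- igraph::vcount(g)
  if (nv > 0) {
    comp <- igraph::components(g)$no
    if (igraph::ecount(g) != nv - comp)
      return("solution must be a forest (|E| = |V| - #components)")
    pr <- igraph::V(g)$prize
    cst <- if (igraph::ecount(g) > 0) igraph::E(g)$cost else numeric()
    obj <- sum(pr) - object@lambda * sum(cst)
    if (abs(obj - object@objective) > 1e-9)
      return("objective must be recomputable from the solution")
  } else if (abs(object@objective) > 1e-12) {
    return("empty solution must have objective 0")
  }
  TRUE
})

#' Enrichment analysis result
#'
#' @slot table per-set `data.frame`; for ORA: `set`, `set_size`, `overlap`,
#'   `overlap_genes`, `pval`, `adj_pval`; for GSEA additionally `ES`, `NES`,
#'   `leading_edge`.
#' @slot mode `"ora"` or `"gsea"`.
#' @export
setClass("EnrichmentResult",
  representation(table = "data.frame", mode = "character")
)

#' Normalization evaluation report
#'
#' One row per candidate normalization method with the pooled variation
#' metrics (PMAD, PCV, PEV; lower is better) and the average silhouette
#' width of the known groups (higher is better), plus a flag for the
#' rank-sum-recommended method.
#'
#' @slot table `data.frame` (`method`, `PMAD`, `PCV`, `PEV`, `silhouette`,
#'   `rank_sum`, `recommended`).
#' @slot groupColumn the sample-annotation column used for grouping.
#' @export
setClass("NormalizationReport",
  representation(table = "data.frame", groupColumn = "character")
)

setValidity("NormalizationReport", function(object) {
  tb <- object@table
  if (sum(tb$recommended) != 1L)
    return("exactly one method must be recommended")
  if (any(tb$PMAD < 0 | tb$PCV < 0 | tb$PEV < 0, na.rm = TRUE))
    return("PMAD/PCV/PEV must be >= 0")
  if (any(tb$silhouette < -1 - 1e-9 | tb$silhouette > 1 + 1e-9, na.rm = TRUE))
    return("silhouette must lie in [-1, 1]")
  TRUE
})
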