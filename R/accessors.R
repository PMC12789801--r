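#' @include AllClasses.R
NULL

#' Accessors for crossomics containers
#'
#' `intensities()` returns the assay matrix of an [OmicsDataset-class];
#' `featureMeta()`/`sampleMeta()` return row/column metadata; `layerName()`
#' and `isLogTransformed()` return the layer label and log-scale flag.
#' `resultTable()` returns the tabular payload of result objects.
#'
#' @param object a crossomics object.
#' @name accessors
#' @aliases intensities featureMeta sampleMeta layerName isLogTransformed
#'   resultTable
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setMethod("intensities", "OmicsDataset", function(object)
  assay(object, "intensities"))

#' @rdname accessors
#' @export
setGeneric("featureMeta", function(object) standardGeneric("featureMeta"))

#' @rdname accessors
#' @export
setMethod("featureMeta", "OmicsDataset", function(object)
  rowData(object))

#' @rdname accessors
#' @export
setGeneric("sampleMeta", function(object) standardGeneric("sampleMeta"))

#' @rdname accessors
#' @export
setMethod("sampleMeta", "OmicsDataset", function(object)
  colData(object))

#' @rdname accessors
#' @export
setGeneric("layerName", function(object) standardGeneric("layerName"))

#' @rdname accessors
#' @export
setMethod("layerName", "OmicsDataset", function(object) object@layerName)

#' @rdname accessors
#' @export
setMethod("layerName", "LayerStats", function(object) object@layerName)

#' @rdname accessors
#' @export
setGeneric("isLogTransformed", function(object)
  standardGeneric("isLogTransformed"))

#' @rdname accessors
#' @export
setMethod("isLogTransformed", "OmicsDataset", function(object)
  object@logTransformed)

#' @rdname accessors
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' @rdname accessors
#' @export
setMethod("resultTable", "DiffExpResult", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("resultTable", "LayerStats", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("resultTable", "SScoreTable", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("resultTable", "EnrichmentResult", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("resultTable", "NormalizationReport", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("resultTable", "PrizeMap", function(object) object@table)

#' Variance prior of a moderated result
#'
#' @param object a [DiffExpResult-class].
#' @return named list with `d0` (prior df) and `s0sq` (prior variance).
#' @export
setGeneric("variancePrior", function(object) standardGeneric("variancePrior"))

#' @rdname variancePrior
#' @export
setMethod("variancePrior", "DiffExpResult", function(object)
  list(d0 = object@priorDf, s0sq = object@priorVar))

#' Underlying igraph of network-class objects
#'
#' @param object an [InteractionNetwork-class] or [PCSFSolution-class].
#' @return the `igraph` object.
#' @export
setGeneric("networkGraph", function(object) standardGeneric("networkGraph"))

#' @rdname networkGraph
#' @export
setMethod("networkGraph", "InteractionNetwork", function(object) object@graph)

#' @rdname networkGraph
#' @export
setMethod("networkGraph", "PCSFSolution", function(object) object@graph)

#' Objective value of a PCSF solution
#'
#' @param object a [PCSFSolution-class].
#' @export
setGeneric("objectiveValue", function(object)
  standardGeneric("objectiveValue"))

#' @rdname objectiveValue
#' @export
setMethod("objectiveValue", "PCSFSolution", function(object)
  object@objective)

setMethod("show", "OmicsDataset", function(object) {
  x <- intensities(object)
  cat(sprintf("OmicsDataset '%s': %d features x %d samples (%s scale)\n",
              layerName(object), nrow(x), ncol(x),
              if (isLogTransformed(object)) "log2" else "raw"))
  cat(sprintf("  missing values: %d (%.1f%%)\n", sum(is.na(x)),
              100 * mean(is.na(x))))
  grp <- colData(object)$group
  if (!is.null(grp))
    cat("  groups:", paste(sprintf("%s(%d)", names(table(grp)), table(grp)),
                           collapse = ", "), "\n")
})

setMethod("show", "DiffExpResult", function(object) {
  tb <- object@table
  cat(sprintf("DiffExpResult: %d features, %s\n", nrow(tb),
              if (object@moderated) "eBayes-moderated" else "pre-moderation"))
  if (object@moderated) {
    cat(sprintf("  prior: d0 = %.4g, s0^2 = %.4g\n",
                object@priorDf, object@priorVar))
    cat(sprintf("  significant at adj.p < 0.05: %d\n",
                sum(tb$adj.P.Val < 0.05, na.rm = TRUE)))
  }
})

setMethod("show", "LayerStats", function(object) {
  cat(sprintf("LayerStats '%s': N = %d features, mu = %.4g, sigma = %.4g, w = %.4g\n",
              object@layerName, object@nFeatures, object@mu, object@sigma,
              object@weight))
})

setMethod("show", "SScoreTable", function(object) {
  tb <- object@table
  cat(sprintf("SScoreTable: %d genes from %d contributing records\n",
              nrow(tb), nrow(object@contributions)))
  cat(sprintf("  significant at adj.p < %.3g: %d\n", object@alpha,
              sum(tb$significant)))
})

setMethod("show", "InteractionNetwork", function(object) {
  g <- object@graph
  cat(sprintf("InteractionNetwork: %d nodes, %d edges (confidence >= %.2f)\n",
              igraph::vcount(g), igraph::ecount(g), object@minConfidence))
})

setMethod("show", "PrizeMap", function(object) {
  tb <- object@table
  cat(sprintf("PrizeMap: %d nodes, %d terminals, mu = %.3g, alpha = %.3g\n",
              nrow(tb), sum(tb$terminal), object@mu, object@alpha))
})

setMethod("show", "PCSFSolution", function(object) {
  g <- object@graph
  nt <- if (igraph::vcount(g)) sum(igraph::V(g)$terminal) else 0L
  cat(sprintf("PCSFSolution: %d nodes (%d terminals), %d edges, objective = %.4f (lambda = %.3g)\n",
              igraph::vcount(g), nt, igraph::ecount(g), object@objective,
              object@lambda))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult (%s): %d sets tested, %d at adj.p < 0.05\n",
              object@mode, nrow(object@table),
              sum(object@table$adj_pval < 0.05, na.rm = TRUE)))
})

setMethod("show", "NormalizationReport", function(object) {
  tb <- object@table
  cat(sprintf("NormalizationReport (%d methods, groups by '%s'); recommended: %s\n",
              nrow(tb), object@groupColumn, tb$method[tb$recommended]))
  print(tb[, c("method", "PMAD", "PCV", "PEV", "silhouette", "rank_sum")],
        row.names = FALSE, digits = 4)
})
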