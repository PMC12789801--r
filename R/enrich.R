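#' @include AllClasses.R
NULL

# run code with a private RNG stream, restoring global state afterwards
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.restrictSets <- function(sets, universe, minSize, maxSize) {
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sizes <- lengths(sets)
  sets[sizes >= minSize & sizes <= maxSize]
}

#' Over-representation analysis
#'
#' One-sided hypergeometric upper-tail test of the overlap between a query
#' gene list and each gene set, both restricted to the measured universe,
#' with BH adjustment across tested sets.
#'
#' @param query character vector of genes of interest (intersected with
#'   the universe; dropped genes are reported).
#' @param universe character vector of all measured genes (>= 10).
#' @param sets named list of gene sets (see [readGMT()]).
#' @param minSize,maxSize set-size bounds after restriction to the
#'   universe (defaults 3 and 500).
#' @return an [EnrichmentResult-class] with mode `"ora"`.
#' @export
ora <- function(query, universe, sets, minSize = 3, maxSize = 500) {
  universe <- unique(universe)
  if (length(universe) < 10L)
    stop("universe must contain >= 10 genes", call. = FALSE)
  query0 <- unique(query)
  query <- intersect(query0, universe)
  if (length(query) < length(query0))
    message(sprintf("ora: %d query gene(s) outside the universe dropped",
                    length(query0) - length(query)))
  if (length(query) == 0L)
    stop("empty query after intersection with the universe", call. = FALSE)
  sets <- .restrictSets(sets, universe, minSize, maxSize)
  if (length(sets) == 0L)
    stop("no gene set within the size bounds after restriction",
         call. = FALSE)
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    k <- length(intersect(query, s))
    K <- length(s)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k,
               overlap_genes = paste(sort(intersect(query, s)),
                                     collapse = ";"),
               pval = p, stringsAsFactors = FALSE)
  })
  tb <- do.call(rbind, rows)
  tb$adj_pval <- adjustBH(tb$pval)
  tb <- tb[order(tb$pval, tb$set), ]
  rownames(tb) <- NULL
  new("EnrichmentResult", table = tb, mode = "ora")
}

# classic running-sum enrichment score on an ordered ranking.
# hitIdx: positions of set members in the ranking; absScore: |score| of
# every ranked gene. Returns the signed extremum of the running sum.
.gseaES <- function(hitIdx, absScore, exponent) {
  n <- length(absScore)
  nh <- length(hitIdx)
  inc <- absScore[hitIdx]^exponent
  tot <- sum(inc)
  if (tot == 0) inc <- rep(1 / nh, nh) else inc <- inc / tot
  step <- rep(-1 / (n - nh), n)
  step[hitIdx] <- inc
  run <- cumsum(step)
  i <- which.max(abs(run))
  run[i]
}

#' Preranked gene set enrichment analysis
#'
#' Classic running-sum GSEA on a gene -> score ranking: hits are weighted
#' by |score|^exponent normalized to sum one, misses decrement uniformly,
#' and the enrichment score is the signed extremum of the running sum.
#' The null is gene-label permutation with a fixed seed; the normalized
#' enrichment score divides ES by the mean |null ES| of the same sign, and
#' the permutation p value uses the add-one convention. Sets with no gene
#' in the ranking are skipped with a message.
#'
#' @param scores named numeric vector (gene -> score); no duplicate genes.
#' @param sets named list of gene sets.
#' @param weightExponent 0 (unweighted, classic Kolmogorov-Smirnov) or 1.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param minSize,maxSize set-size bounds after restriction to the
#'   ranked genes.
#' @return an [EnrichmentResult-class] with mode `"gsea"`.
#' @export
gseaPreranked <- function(scores, sets, weightExponent = 1, nPerm = 1000,
                          seed = 1, minSize = 1, maxSize = 500) {
  if (!weightExponent %in% c(0, 1))
    stop("weightExponent must be 0 or 1", call. = FALSE)
  if (anyDuplicated(names(scores)))
    stop("duplicate genes in the ranking", call. = FALSE)
  ord <- order(-scores, names(scores))   # stable: score desc, gene asc
  scores <- scores[ord]
  genes <- names(scores)
  absScore <- abs(scores)
  n <- length(genes)
  restricted <- .restrictSets(sets, genes, minSize, maxSize)
  skipped <- setdiff(names(sets), names(restricted))
  if (length(skipped))
    message("gseaPreranked: skipped set(s) outside the ranking/size bounds: ",
            paste(skipped, collapse = ", "))
  if (length(restricted) == 0L)
    stop("no testable gene set", call. = FALSE)
  rows <- .withSeed(seed, {
    lapply(names(restricted), function(nm) {
      s <- restricted[[nm]]
      hitIdx <- sort(match(s, genes))
      es <- .gseaES(hitIdx, absScore, weightExponent)
      nullES <- vapply(seq_len(nPerm), function(b) {
        .gseaES(sort(sample.int(n, length(s))), absScore, weightExponent)
      }, numeric(1))
      same <- nullES[sign(nullES) == sign(es)]
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      # leading edge: hits at or before the extremum for positive ES,
      # at or after it for negative ES
      run <- {
        inc <- absScore[hitIdx]^weightExponent
        tot <- sum(inc)
        inc <- if (tot == 0) rep(1 / length(hitIdx), length(hitIdx))
               else inc / tot
        step <- rep(-1 / (n - length(hitIdx)), n)
        step[hitIdx] <- inc
        cumsum(step)
      }
      peak <- which.max(abs(run))
      le <- if (es >= 0) genes[hitIdx[hitIdx <= peak]]
            else genes[hitIdx[hitIdx >= peak]]
      data.frame(set = nm, set_size = length(s), ES = es, NES = nes,
                 pval = p, leading_edge = paste(le, collapse = ";"),
                 stringsAsFactors = FALSE)
    })
  })
  tb <- do.call(rbind, rows)
  tb$adj_pval <- adjustBH(tb$pval)
  tb <- tb[order(tb$pval, tb$set), ]
  rownames(tb) <- NULL
  new("EnrichmentResult", table = tb, mode = "gsea")
}

#' Annotate gene clusters by over-representation
#'
#' Runs [ora()] per cluster (clusters below `minSize` are skipped) against
#' a shared universe — typically all nodes of the base interaction
#' network — and flags each cluster's top term as its representative
#' annotation.
#'
#' @param clusters named vector/list: gene -> cluster id, or a list of
#'   gene vectors per cluster.
#' @param universe character vector of background genes.
#' @param sets named list of gene sets.
#' @param minSize minimum cluster size (and ORA set-size lower bound).
#' @param maxSize ORA set-size upper bound.
#' @return named list of [EnrichmentResult-class] per tested cluster; each
#'   result's top row is the representative term.
#' @export
enrichClusters <- function(clusters, universe, sets, minSize = 3,
                           maxSize = 500) {
  if (!is.list(clusters)) {
    cl <- split(names(clusters), as.character(clusters))
  } else cl <- clusters
  cl <- cl[lengths(cl) >= minSize]
  if (length(cl) == 0L)
    stop("no cluster of size >= ", minSize, call. = FALSE)
  out <- lapply(cl, function(genes)
    ora(genes, universe, sets, minSize = minSize, maxSize = maxSize))
  lapply(out, function(res) {
    res@table$representative <- seq_len(nrow(res@table)) == 1L
    res
  })
}
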