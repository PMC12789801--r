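#' @include AllClasses.R
NULL

#' Specification for a synthetic multi-omics study
#'
#' Defaults emulate a two-condition TMT study run as two 18-sample plexes
#' (sessions): Gaussian noise on the log2 scale, additive feature-by-plex
#' batch offsets, plex-block missing-at-random dropout, a proteome layer
#' with one feature per gene and a phosphoproteome layer with one to five
#' sites per gene, and a planted fraction of differential genes whose
#' effects are concordant across layers with a configurable probability.
#'
#' @param nGenes number of genes (default 2000).
#' @param layers per-layer feature multiplicity: named list of integer
#'   vectors to sample features-per-gene from.
#' @param nGroups number of biological groups (default 2).
#' @param nReplicates replicates per group (default 18).
#' @param nPlexes number of TMT plexes = batches/sessions (default 2).
#' @param effectSize planted group effect in log2 units (default 1).
#' @param diffFraction fraction of differential genes (default 0.10).
#' @param concordance probability that a differential gene's effect has
#'   the same sign in every layer (default 0.9).
#' @param noiseSd per-measurement Gaussian noise sd, log2 (default 0.25).
#' @param batchSd sd of additive feature-by-plex batch offsets
#'   (default 0.3).
#' @param missingRate plex-block MAR rate: probability that a feature is
#'   entirely missing within one plex (default 0.1).
#' @param contaminantFraction fraction of extra contaminant rows appended
#'   (default 0.02).
#' @param baselineMean,baselineSd log2 baseline abundance distribution.
#' @param seed RNG seed (mandatory).
#' @return a list of class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(nGenes = 2000,
                          layers = list(proteome = 1L, phospho = 1:5),
                          nGroups = 2, nReplicates = 18, nPlexes = 2,
                          effectSize = 1, diffFraction = 0.10,
                          concordance = 0.9, noiseSd = 0.25,
                          batchSd = 0.3, missingRate = 0.1,
                          contaminantFraction = 0.02,
                          baselineMean = 20, baselineSd = 2, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(nGenes >= 1, nGroups >= 2, nReplicates >= 1, nPlexes >= 1,
            diffFraction >= 0, diffFraction <= 1,
            concordance >= 0, concordance <= 1,
            missingRate >= 0, missingRate <= 1,
            contaminantFraction >= 0, contaminantFraction <= 1,
            is.finite(effectSize))
  structure(as.list(environment()), class = "SyntheticSpec")
}

#' Generate a synthetic multi-omics study with ground truth
#'
#' Log2 intensities are gene baseline + layer offset + group effect
#' (differential genes only) + feature-by-plex batch offset + Gaussian
#' noise; a plex-block MAR mask is applied; contaminant rows are appended
#' with flags. Fully reproducible per seed.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `datasets` (list of [OmicsDataset-class], log2
#'   scale), `annotation` (sample `data.frame`) and `truth` (planted
#'   differential flags, per-layer signed effects, feature map, batch
#'   assignment, missingness masks).
#' @export
generateMultiOmics <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  .withSeed(spec$seed, {
    nSamples <- spec$nGroups * spec$nReplicates
    groups <- paste0("group", seq_len(spec$nGroups))
    ann <- data.frame(
      sample_id = sprintf("S%02d", seq_len(nSamples)),
      group = rep(groups, each = spec$nReplicates),
      replicate = rep(seq_len(spec$nReplicates), times = spec$nGroups),
      stringsAsFactors = FALSE)
    # balanced plex assignment: cycle plexes within each group
    ann$plex <- sprintf("plex%d",
                        ((seq_len(spec$nReplicates) - 1L) %% spec$nPlexes + 1L)[
                          ann$replicate])
    ann$batch <- ann$plex
    genes <- sprintf("G%04d", seq_len(spec$nGenes))
    nDiff <- round(spec$diffFraction * spec$nGenes)
    diffIdx <- if (nDiff > 0) sort(sample.int(spec$nGenes, nDiff))
               else integer()
    isDiff <- seq_len(spec$nGenes) %in% diffIdx
    baseSign <- ifelse(stats::runif(spec$nGenes) < 0.5, -1, 1)
    concordant <- stats::runif(spec$nGenes) < spec$concordance
    baseline <- stats::rnorm(spec$nGenes, spec$baselineMean,
                             spec$baselineSd)
    layerEffects <- list()
    datasets <- list()
    truthFeatures <- list()
    masks <- list()
    for (li in seq_along(spec$layers)) {
      lname <- names(spec$layers)[li]
      mult <- spec$layers[[li]]
      fpg <- if (length(mult) == 1L) rep(mult, spec$nGenes)
             else sample(mult, spec$nGenes, replace = TRUE)
      geneOf <- rep(seq_len(spec$nGenes), times = fpg)
      nFeat <- length(geneOf)
      fid <- sprintf("%s_%s_f%d", lname, genes[geneOf],
                     unlist(lapply(fpg, seq_len)))
      # signed per-layer effect: first layer uses the base sign;
      # discordant genes flip sign in subsequent layers
      sgn <- baseSign
      if (li > 1L) sgn <- ifelse(concordant, baseSign, -baseSign)
      eff <- ifelse(isDiff, sgn * spec$effectSize, 0)
      layerEffects[[lname]] <- eff
      layerOffset <- stats::rnorm(1, 0, 1)
      batchOff <- matrix(stats::rnorm(nFeat * spec$nPlexes, 0,
                                      spec$batchSd),
                         nrow = nFeat)
      colnames(batchOff) <- sprintf("plex%d", seq_len(spec$nPlexes))
      grpIdx <- match(ann$group, groups)
      x <- matrix(0, nFeat, nSamples,
                  dimnames = list(fid, ann$sample_id))
      for (s in seq_len(nSamples)) {
        effS <- if (grpIdx[s] == 2L) eff[geneOf] else 0
        # multi-group: only group2 carries the planted effect; further
        # groups behave as additional null conditions
        x[, s] <- baseline[geneOf] + layerOffset + effS +
          batchOff[, ann$plex[s]] +
          stats::rnorm(nFeat, 0, spec$noiseSd)
      }
      # plex-block MAR dropout
      mask <- matrix(FALSE, nFeat, nSamples,
                     dimnames = dimnames(x))
      if (spec$missingRate > 0) {
        for (p in unique(ann$plex)) {
          drop <- stats::runif(nFeat) < spec$missingRate
          mask[drop, ann$plex == p] <- TRUE
        }
      }
      x[mask] <- NA_real_
      fm <- data.frame(feature_id = fid, gene_symbol = genes[geneOf],
                       is_contaminant = FALSE, is_reverse = FALSE,
                       stringsAsFactors = FALSE)
      nContam <- round(spec$contaminantFraction * nFeat)
      if (nContam > 0) {
        cid <- sprintf("CON_%s_c%d", lname, seq_len(nContam))
        cx <- matrix(stats::rnorm(nContam * nSamples,
                                  spec$baselineMean, spec$baselineSd),
                     nContam, nSamples, dimnames = list(cid, ann$sample_id))
        x <- rbind(x, cx)
        fm <- rbind(fm, data.frame(feature_id = cid, gene_symbol = cid,
                                   is_contaminant = TRUE,
                                   is_reverse = FALSE,
                                   stringsAsFactors = FALSE))
      }
      datasets[[lname]] <- OmicsDataset(x, fm, ann, layerName = lname,
                                        logTransformed = TRUE)
      truthFeatures[[lname]] <- data.frame(feature_id = fid,
                                           gene = genes[geneOf],
                                           stringsAsFactors = FALSE)
      masks[[lname]] <- mask
    }
    truth <- list(genes = genes, differential = isDiff,
                  diffGenes = genes[isDiff],
                  effects = as.data.frame(layerEffects,
                                          row.names = genes),
                  featureMap = truthFeatures,
                  batch = stats::setNames(ann$plex, ann$sample_id),
                  missingMask = masks, spec = spec)
    list(datasets = datasets, annotation = ann, truth = truth)
  })
}

#' Generate a synthetic interaction network with a planted module
#'
#' Wires the planted module densely (`pModuleEdge`) and the background
#' sparsely (`pBackgroundEdge`); confidences are drawn both above and
#' below the cutoff so confidence filtering is exercised.
#'
#' @param backgroundGenes character vector of background node names.
#' @param plantedModule character vector of module node names.
#' @param pBackgroundEdge background edge probability (default 0.02).
#' @param pModuleEdge within-module edge probability (default 0.8).
#' @param confRange,moduleConfRange uniform confidence ranges for
#'   background and module edges.
#' @param minConfidence confidence cutoff for the returned network.
#' @param seed RNG seed.
#' @return list with `network` (filtered [InteractionNetwork-class]),
#'   `edges` (all drawn edges) and `truth` (module gene list).
#' @export
generateNetwork <- function(backgroundGenes, plantedModule,
                            pBackgroundEdge = 0.02, pModuleEdge = 0.8,
                            confRange = c(0.4, 1),
                            moduleConfRange = c(0.75, 0.99),
                            minConfidence = 0.7, seed = 1) {
  .withSeed(seed, {
    allGenes <- unique(c(backgroundGenes, plantedModule))
    drawPairs <- function(nodes, p, rng) {
      if (length(nodes) < 2L) return(NULL)
      pairs <- utils::combn(nodes, 2L)
      pick <- stats::runif(ncol(pairs)) < p
      if (!any(pick)) return(NULL)
      data.frame(from = pairs[1L, pick], to = pairs[2L, pick],
                 confidence = stats::runif(sum(pick), rng[1L], rng[2L]),
                 stringsAsFactors = FALSE)
    }
    bg <- drawPairs(allGenes, pBackgroundEdge, confRange)
    md <- drawPairs(plantedModule, pModuleEdge, moduleConfRange)
    # guarantee the module is connected: add a high-confidence spanning
    # path so planted terminals are reachable at any density
    spine <- if (length(plantedModule) >= 2L)
      data.frame(from = plantedModule[-length(plantedModule)],
                 to = plantedModule[-1L],
                 confidence = stats::runif(length(plantedModule) - 1L,
                                           moduleConfRange[1L],
                                           moduleConfRange[2L]),
                 stringsAsFactors = FALSE) else NULL
    edges <- do.call(rbind, Filter(Negate(is.null), list(bg, md, spine)))
    if (is.null(edges) || nrow(edges) == 0L)
      edges <- data.frame(from = character(), to = character(),
                          confidence = numeric())
    net <- interactionNetwork(edges$from, edges$to, edges$confidence,
                              minConfidence = minConfidence)
    list(network = net, edges = edges,
         truth = list(module = plantedModule))
  })
}

#' Write an end-to-end fixture bundle to disk
#'
#' Writes raw-scale intensity matrices (missing cells as zeros, the TMT
#' export convention), the sample annotation, a GMT whose first sets are
#' aligned with planted differential genes plus decoy sets, an
#' interaction edge list on the STRING 0-1000 scale wired densely among
#' planted genes, and a machine-readable truth file. The `tiny` profile
#' (200 genes, 2 groups x 3 replicates) runs the full pipeline in well
#' under a minute.
#'
#' @param dir output directory (created if needed).
#' @param profile `"tiny"` or `"default"`.
#' @param seed RNG seed.
#' @return invisibly, a named list of the written paths plus the
#'   generating spec.
#' @export
writeFixtureBundle <- function(dir, profile = c("tiny", "default"),
                               seed = 1) {
  profile <- match.arg(profile)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- if (profile == "tiny")
    syntheticSpec(nGenes = 200, nReplicates = 3, effectSize = 1.5,
                  missingRate = 0.05, seed = seed)
  else syntheticSpec(seed = seed)
  sim <- generateMultiOmics(spec)
  paths <- list(spec = spec)
  for (lname in names(sim$datasets)) {
    ds <- sim$datasets[[lname]]
    x <- 2^intensities(ds)               # back to raw scale
    x[is.na(x)] <- 0
    out <- data.frame(feature_id = rowData(ds)$feature_id,
                      gene_symbol = rowData(ds)$gene_symbol, x,
                      check.names = FALSE, stringsAsFactors = FALSE)
    p <- file.path(dir, paste0(lname, "_matrix.tsv"))
    utils::write.table(out[, -2L], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[paste0("matrix_", lname)]] <- p
    pm <- file.path(dir, paste0(lname, "_idmap.tsv"))
    utils::write.table(out[, 1:2], pm, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[paste0("idmap_", lname)]] <- pm
  }
  pa <- file.path(dir, "sample_annotation.tsv")
  utils::write.table(sim$annotation, pa, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$annotation <- pa
  # gene sets: planted-signal sets plus random decoys
  truth <- sim$truth
  sets <- list()
  diffGenes <- truth$diffGenes
  if (length(diffGenes) >= 6L) {
    half <- ceiling(length(diffGenes) / 2)
    sets[["planted_signal_A"]] <- diffGenes[seq_len(half)]
    sets[["planted_signal_B"]] <- diffGenes[(half + 1L):length(diffGenes)]
  } else if (length(diffGenes) >= 3L) {
    sets[["planted_signal_A"]] <- diffGenes
  }
  dec <- .withSeed(seed + 1L, lapply(1:5, function(i)
    sample(truth$genes, min(25L, length(truth$genes)))))
  names(dec) <- sprintf("decoy_set_%d", 1:5)
  sets <- c(sets, dec)
  pg <- file.path(dir, "gene_sets.gmt")
  writeGMT(sets, pg)
  paths$gmt <- pg
  # interaction edges (STRING-style 0-1000 scores)
  nBg <- min(length(truth$genes), 150L)
  bgGenes <- truth$genes[seq_len(nBg)]
  module <- utils::head(diffGenes, 30L)
  netSim <- generateNetwork(bgGenes, module, seed = seed + 2L)
  ed <- netSim$edges
  ed$score <- round(ed$confidence * 1000)
  pe <- file.path(dir, "string_edges.tsv")
  utils::write.table(ed[, c("from", "to", "score")], pe, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths$edges <- pe
  pt <- file.path(dir, "truth.json")
  jsonlite::write_json(list(n_genes = spec$nGenes,
                            diff_genes = truth$diffGenes,
                            module = netSim$truth$module,
                            seed = spec$seed, profile = profile),
                       pt, auto_unbox = TRUE, pretty = TRUE)
  paths$truth <- pt
  invisible(paths)
}
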