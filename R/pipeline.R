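#' @include AllClasses.R
NULL

.defaultConfig <- function() {
  list(
    layers = list(),                 # name -> list(matrix, dialect, weight)
    annotation = NULL,
    id_mapping = list(),             # optional: name -> 2-column TSV path
    max_missing = 0.30,
    normalize = "auto",
    normalize_candidates = c("none", "median", "medianMAD", "quantile",
                             "loess"),
    impute = "none",                 # "none" or "lls"
    impute_k = 10,
    group_column = "group",
    factors = c("group"),
    covariates = character(),
    reference_levels = list(),
    contrast = NULL,
    alpha = 0.05,
    gmt = NULL,
    gsea_nperm = 1000,
    edges = NULL,
    min_confidence = 0.7,
    lambda = 1,
    mu = 0,
    seed = 1,
    out_dir = "crossomics_run"
  )
}

#' Read, resolve and validate a run configuration
#'
#' Reads a YAML config (or takes a list), fills defaults, and validates
#' required fields. The resolved configuration round-trips losslessly
#' through YAML and is written beside the outputs of every run.
#'
#' @param config path to a YAML file, or a named list.
#' @return the resolved configuration list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.defaultConfig(), config)
  if (length(cfg$layers) == 0L)
    stop("config must define at least one layer", call. = FALSE)
  if (is.null(cfg$annotation))
    stop("config must name an annotation file", call. = FALSE)
  if (is.null(cfg$contrast))
    stop("config must name a contrast coefficient", call. = FALSE)
  for (nm in names(cfg$layers)) {
    ly <- cfg$layers[[nm]]
    if (is.null(ly$matrix))
      stop("layer '", nm, "' must name a matrix file", call. = FALSE)
    if (is.null(ly$dialect)) cfg$layers[[nm]]$dialect <- "generic"
    if (is.null(ly$weight)) cfg$layers[[nm]]$weight <- 1
  }
  cfg
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full multi-omics pipeline
#'
#' Executes preprocess -> differential analysis (per layer) -> S-score
#' integration -> enrichment -> PCSF network discovery, writing stage
#' outputs into nested folders (`Preprocessing`, `DE_Results`,
#' `Integration`, `Enrichment`, `Network_Modules`) together with a
#' machine-readable `summary.json`, a plain-text run log, and the
#' resolved configuration. Any stage failure halts with the stage name
#' and cause; outputs of completed stages are retained. All randomness
#' flows from the config seed.
#'
#' @param config path to a YAML config or a list (see [readRunConfig()]).
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run_log.txt")
  logCon <- file(logPath, "w")
  on.exit(close(logCon), add = TRUE)
  logline <- function(...) {
    writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...),
               logCon)
  }
  logline("crossomics ",
          as.character(utils::packageVersion("crossomics")))
  yaml::write_yaml(cfg, file.path(outDir, "resolved_config.yaml"))
  logline("resolved config written; seed = ", cfg$seed)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  summary <- list(stages = list())

  # ---- preprocess ----
  preDir <- file.path(outDir, "Preprocessing")
  dir.create(preDir, showWarnings = FALSE)
  ann <- stage("preprocess", readSampleAnnotation(cfg$annotation))
  datasets <- list()
  preCounts <- list()
  for (nm in names(cfg$layers)) {
    ly <- cfg$layers[[nm]]
    stage("preprocess", {
      ds <- suppressWarnings(
        readMatrix(ly$matrix, ann, dialect = ly$dialect, layerName = nm))
      n0 <- nrow(ds)
      ds <- filterFlagged(ds)
      n1 <- nrow(ds)
      ds <- filterMissing(ds, cfg$max_missing)
      n2 <- nrow(ds)
      ds <- logTransform(ds)
      if (!is.null(cfg$id_mapping[[nm]])) {
        map <- .readTable(cfg$id_mapping[[nm]])
        colnames(map)[1:2] <- c("feature_id", "gene_symbol")
        ds <- mapFeatureIds(ds, map)
      }
      chosen <- cfg$normalize
      if (identical(cfg$normalize, "auto")) {
        rep <- evaluateNormalizations(ds, cfg$normalize_candidates,
                                      groupColumn = cfg$group_column)
        tb <- resultTable(rep)
        chosen <- tb$method[tb$recommended]
        .writeTsv(tb, file.path(preDir,
                                paste0(nm, "_normalization_report.tsv")))
      }
      ds <- normalizeIntensities(ds, method = chosen)
      if (identical(cfg$impute, "lls")) ds <- imputeLLS(ds, cfg$impute_k)
      logline(sprintf(
        "layer %s: %d features imported, %d after flag filter, %d after missing filter; normalization = %s",
        nm, n0, n1, n2, chosen))
      preCounts[[nm]] <- list(imported = n0, after_flag_filter = n1,
                               after_missing_filter = n2,
                               normalization = chosen)
      datasets[[nm]] <- ds
    })
  }
  summary$stages$preprocess <- preCounts

  # ---- differential expression ----
  deDir <- file.path(outDir, "DE_Results")
  dir.create(deDir, showWarnings = FALSE)
  results <- list()
  deCounts <- list()
  for (nm in names(datasets)) {
    stage("diffexp", {
      ds <- datasets[[nm]]
      design <- buildDesign(as.data.frame(sampleMeta(ds)),
                            factors = cfg$factors,
                            covariates = cfg$covariates,
                            referenceLevels = cfg$reference_levels)
      res <- ebayesModerate(fitLinearModel(ds, design, cfg$contrast))
      tb <- resultTable(res)
      .writeTsv(tb[, c("feature_id", "gene_symbol", "logFC", "AveExpr",
                       "t", "P.Value", "adj.P.Val", "df.residual")],
                file.path(deDir, paste0(nm, ".tsv")))
      nSig <- sum(tb$adj.P.Val < cfg$alpha, na.rm = TRUE)
      logline(sprintf("layer %s: %d/%d features at adj.p < %g", nm,
                      nSig, nrow(tb), cfg$alpha))
      deCounts[[nm]] <- list(features = nrow(tb), significant = nSig)
      results[[nm]] <- res
    })
  }
  summary$stages$diffexp <- deCounts

  # ---- integration ----
  intDir <- file.path(outDir, "Integration")
  dir.create(intDir, showWarnings = FALSE)
  sscores <- stage("integrate", {
    layers <- lapply(names(results), function(nm)
      layerStats(results[[nm]], nm,
                 userWeight = cfg$layers[[nm]]$weight))
    ss <- integrateLayers(layers, alpha = cfg$alpha)
    writeSScores(ss, file.path(intDir, "sscores.tsv"))
    ss
  })
  sig <- significantGenes(sscores)
  logline(sprintf("integration: %d genes, %d significant at adj.p < %g",
                  nrow(resultTable(sscores)), length(sig), cfg$alpha))
  summary$stages$integrate <- list(genes = nrow(resultTable(sscores)),
                                   significant = length(sig))

  # ---- enrichment ----
  if (!is.null(cfg$gmt)) {
    enDir <- file.path(outDir, "Enrichment")
    dir.create(enDir, showWarnings = FALSE)
    stage("enrich", {
      sets <- readGMT(cfg$gmt)
      universe <- resultTable(sscores)$gene
      if (length(sig) > 0) {
        oraRes <- ora(sig, universe, sets)
        .writeTsv(resultTable(oraRes), file.path(enDir, "ora.tsv"))
        summary$stages$enrich$ora_sets <-
          nrow(resultTable(oraRes))
      }
      ranks <- stats::setNames(resultTable(sscores)$sscore,
                               resultTable(sscores)$gene)
      gseaRes <- gseaPreranked(ranks, sets, nPerm = cfg$gsea_nperm,
                               seed = cfg$seed)
      .writeTsv(resultTable(gseaRes), file.path(enDir, "gsea.tsv"))
      summary$stages$enrich$gsea_sets <- nrow(resultTable(gseaRes))
      logline(sprintf("enrichment: %d sets through GSEA",
                      nrow(resultTable(gseaRes))))
    })
  }

  # ---- network ----
  if (!is.null(cfg$edges)) {
    netDir <- file.path(outDir, "Network_Modules")
    dir.create(netDir, showWarnings = FALSE)
    stage("network", {
      net <- readEdgeList(cfg$edges, minConfidence = cfg$min_confidence)
      net <- assignEdgeCosts(net)
      prizes <- assignPrizes(net, sscores, alpha = cfg$alpha,
                             mu = cfg$mu)
      sol <- solvePCSF(net, prizes, lambda = cfg$lambda)
      g <- networkGraph(sol)
      writeNetwork(sol, file.path(netDir, "subnetwork.sif"),
                   format = "sif", allowEmpty = TRUE)
      writeNetwork(sol, file.path(netDir, "subnetwork.graphml"),
                   format = "graphml", allowEmpty = TRUE)
      summary$stages$network <- list(
        base_nodes = igraph::vcount(networkGraph(net)),
        base_edges = igraph::ecount(networkGraph(net)),
        solution_nodes = igraph::vcount(g),
        solution_edges = igraph::ecount(g),
        objective = objectiveValue(sol))
      if (igraph::vcount(g) >= 2L) {
        cl <- clusterSolution(sol)
        .writeTsv(data.frame(node = names(cl), cluster = as.integer(cl)),
                  file.path(netDir, "clusters.tsv"))
      }
      if (igraph::vcount(g) >= 3L)
        .writeTsv(rankHubs(sol),
                  file.path(netDir, "hubs.tsv"))
      logline(sprintf("network: solution with %d nodes, objective %.4f",
                      igraph::vcount(g), objectiveValue(sol)))
    })
  }

  summary$parameters <- cfg[c("max_missing", "normalize", "impute",
                              "contrast", "alpha", "lambda", "mu",
                              "min_confidence", "seed")]
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logline("pipeline complete")
  invisible(outDir)
}

#' Summarize a completed (or partial) pipeline run
#'
#' Aggregates per-stage counts recomputed from the stage TSVs into a
#' structured record, and writes `summary.md` beside them. Stages whose
#' outputs are absent are marked as such. Idempotent.
#'
#' @param outputDir directory written by [runPipeline()].
#' @return the summary record (named list), invisibly.
#' @export
summarizeRun <- function(outputDir) {
  if (!dir.exists(outputDir))
    stop("no such run directory: ", outputDir, call. = FALSE)
  rec <- list(run_dir = outputDir, stages = list())
  countRows <- function(path) nrow(.readTable(path))
  deDir <- file.path(outputDir, "DE_Results")
  if (dir.exists(deDir)) {
    fs <- list.files(deDir, "\\.tsv$", full.names = TRUE)
    rec$stages$diffexp <- lapply(stats::setNames(fs, basename(fs)),
                                 countRows)
  } else rec$stages$diffexp <- "absent"
  ssPath <- file.path(outputDir, "Integration", "sscores.tsv")
  if (file.exists(ssPath)) {
    ss <- .readTable(ssPath)
    rec$stages$integrate <- list(genes = nrow(ss),
                                 significant = sum(ss$significant %in%
                                                     c(TRUE, "TRUE")))
  } else rec$stages$integrate <- "absent"
  enDir <- file.path(outputDir, "Enrichment")
  if (dir.exists(enDir)) {
    fs <- list.files(enDir, "\\.tsv$", full.names = TRUE)
    rec$stages$enrich <- lapply(stats::setNames(fs, basename(fs)),
                                countRows)
  } else rec$stages$enrich <- "absent"
  sifPath <- file.path(outputDir, "Network_Modules", "subnetwork.sif")
  if (file.exists(sifPath)) {
    lines <- readLines(sifPath, warn = FALSE)
    lines <- lines[nzchar(lines)]
    rec$stages$network <- list(
      edges = sum(grepl("\tinteracts\t", lines, fixed = TRUE)),
      isolated_nodes = sum(!grepl("\tinteracts\t", lines, fixed = TRUE)))
  } else rec$stages$network <- "absent"
  md <- c("# Pipeline run summary", "",
          paste0("Run directory: `", outputDir, "`"), "")
  for (nm in names(rec$stages)) {
    md <- c(md, paste0("## ", nm), "")
    st <- rec$stages[[nm]]
    if (identical(st, "absent")) {
      md <- c(md, "absent", "")
    } else {
      md <- c(md, vapply(names(st), function(k)
        paste0("- ", k, ": ", st[[k]]), character(1)), "")
    }
  }
  writeLines(md, file.path(outputDir, "summary.md"))
  invisible(rec)
}
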