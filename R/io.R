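#' @include AllClasses.R
NULL

# delimiter by extension: .csv -> comma, anything else -> tab
.delimFor <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.readTable <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = .delimFor(path), header = header,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
}

#' Read a sample annotation table
#'
#' Expects one row per sample with at least `sample_id` and `group`
#' columns; `replicate`, `batch`, `plex`/`channel` and arbitrary covariate
#' columns are carried through.
#'
#' @param path TSV/CSV file path.
#' @return a `data.frame` keyed by `sample_id`.
#' @export
readSampleAnnotation <- function(path) {
  ann <- .readTable(path)
  validateSampleAnnotation(ann)
}

#' Validate a sample annotation data.frame
#'
#' @param ann a `data.frame` with `sample_id` and `group` columns.
#' @return the validated `data.frame` (invisibly the same object).
#' @export
validateSampleAnnotation <- function(ann) {
  ann <- as.data.frame(ann)
  if (!"sample_id" %in% colnames(ann))
    stop("annotation must contain a 'sample_id' column", call. = FALSE)
  ann$sample_id <- as.character(ann$sample_id)
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotation: ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]),
               collapse = ", "), call. = FALSE)
  if (!"group" %in% colnames(ann))
    stop("annotation must contain a 'group' column", call. = FALSE)
  if (any(is.na(ann$group) | ann$group == ""))
    stop("the 'group' column must be non-empty for every sample",
         call. = FALSE)
  ann
}

#' Read a feature-by-sample intensity matrix
#'
#' Supports a generic dialect (column 1 = feature ids, header row = sample
#' ids) and FragPipe TMT-report dialects where the feature id and gene
#' symbol live in named columns. Samples are matched to the annotation by
#' exact `sample_id`; the intersection is used and dropped samples are
#' reported with a warning. Non-numeric cells and (by default) zeros become
#' missing values. Contaminant/reverse flags are set from id prefixes.
#'
#' @param path matrix file (TSV or CSV by extension).
#' @param annotation sample annotation `data.frame` (see
#'   [readSampleAnnotation()]).
#' @param dialect one of `"generic"`, `"fragpipe_protein"`,
#'   `"fragpipe_multisite"`.
#' @param layerName label for the resulting layer.
#' @param idColumn,geneColumn feature id / gene symbol columns for the
#'   FragPipe dialects (defaults `"Index"` and `"Gene"`).
#' @param zeroAsMissing treat exact zeros as missing (default `TRUE`,
#'   the TMT reporter-export convention).
#' @param contaminantRegex,reverseRegex regexes flagging contaminant and
#'   reverse-decoy feature ids.
#' @return an [OmicsDataset-class].
#' @export
readMatrix <- function(path, annotation,
                       dialect = c("generic", "fragpipe_protein",
                                   "fragpipe_multisite"),
                       layerName = "layer",
                       idColumn = "Index", geneColumn = "Gene",
                       zeroAsMissing = TRUE,
                       contaminantRegex = "^(CON_|contam_)",
                       reverseRegex = "^(rev_|REV_)") {
  dialect <- match.arg(dialect)
  annotation <- validateSampleAnnotation(annotation)
  raw <- .readTable(path)
  if (dialect == "generic") {
    ids <- as.character(raw[[1L]])
    genes <- ids
    dataCols <- colnames(raw)[-1L]
    body <- raw[, -1L, drop = FALSE]
  } else {
    if (!idColumn %in% colnames(raw))
      stop(sprintf("format error: id column '%s' not found in %s",
                   idColumn, path), call. = FALSE)
    ids <- as.character(raw[[idColumn]])
    genes <- if (geneColumn %in% colnames(raw))
      as.character(raw[[geneColumn]]) else ids
    genes[is.na(genes) | genes == ""] <- ids[is.na(genes) | genes == ""]
    dataCols <- setdiff(colnames(raw), c(idColumn, geneColumn))
    body <- raw[, dataCols, drop = FALSE]
  }
  if (anyDuplicated(ids))
    stop("duplicate feature_id in matrix: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 10L),
               collapse = ", "), call. = FALSE)
  keep <- intersect(annotation$sample_id, dataCols)
  if (length(keep) == 0L)
    stop("no overlapping samples between matrix columns and annotation",
         call. = FALSE)
  droppedMat <- setdiff(dataCols, annotation$sample_id)
  droppedAnn <- setdiff(annotation$sample_id, dataCols)
  if (length(droppedMat) || length(droppedAnn))
    warning(sprintf(
      "sample intersection used: %d matrix column(s) without annotation [%s]; %d annotated sample(s) without data [%s]",
      length(droppedMat), paste(droppedMat, collapse = ","),
      length(droppedAnn), paste(droppedAnn, collapse = ",")),
      call. = FALSE)
  mat <- vapply(keep, function(cn) suppressWarnings(as.numeric(body[[cn]])),
                numeric(length(ids)))
  if (length(ids) == 1L) mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, keep))
  if (zeroAsMissing) mat[!is.na(mat) & mat == 0] <- NA_real_
  fm <- data.frame(feature_id = ids, gene_symbol = genes,
                   is_contaminant = grepl(contaminantRegex, ids),
                   is_reverse = grepl(reverseRegex, ids),
                   annotation = "", stringsAsFactors = FALSE)
  sm <- annotation[match(keep, annotation$sample_id), , drop = FALSE]
  OmicsDataset(mat, fm, sm, layerName = layerName, logTransformed = FALSE)
}

#' Write an intensity matrix in the generic dialect
#'
#' Inverse of the generic [readMatrix()] dialect: column 1 = feature ids,
#' header row = sample ids. Missing values are written as `NA` so a
#' round-trip preserves both finite values and the missingness mask.
#'
#' @param ds an [OmicsDataset-class].
#' @param path output TSV/CSV path.
#' @export
writeMatrix <- function(ds, path) {
  x <- intensities(ds)
  xc <- apply(x, 2L, function(v)
    ifelse(is.na(v), NA_character_, sprintf("%.17g", v)))
  if (nrow(x) == 1L) xc <- matrix(xc, nrow = 1L,
                                  dimnames = dimnames(x))
  out <- data.frame(feature_id = rowData(ds)$feature_id, xc,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = .delimFor(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then member gene
#' symbols. Duplicate members within a set are deduplicated.
#'
#' @param path GMT file path.
#' @return named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("format error: empty GMT file: ", path, call. = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("format error: GMT line %d has fewer than 3 fields", i),
           call. = FALSE)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("format error: GMT line %d has no members", i),
           call. = FALSE)
    attr(members, "description") <- f[[2L]]
    sets[[f[[1L]]]] <- members
  }
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute per set).
#' @param path output path.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    d <- attr(sets[[nm]], "description")
    if (is.null(d)) d <- nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 3-column interaction edge list
#'
#' Columns: nodeA, nodeB, score. Scores on the STRING 0-1000 scale are
#' divided by 1000 (auto-detected when the maximum score exceeds 1, or
#' forced via `scoreScale`). Self-loops are dropped, parallel edges are
#' collapsed keeping the maximum confidence, and edges below
#' `minConfidence` are removed.
#'
#' @param path edge-list TSV/CSV (header optional; detected from the third
#'   column being non-numeric).
#' @param scoreScale `"auto"`, `"unit"` or `"string1000"`.
#' @param minConfidence confidence cutoff (default 0.7, the high-confidence
#'   STRING convention).
#' @return an [InteractionNetwork-class].
#' @export
readEdgeList <- function(path, scoreScale = c("auto", "unit", "string1000"),
                         minConfidence = 0.7) {
  scoreScale <- match.arg(scoreScale)
  tab <- .readTable(path, header = FALSE)
  if (ncol(tab) < 3L)
    stop("format error: edge list must have 3 columns (nodeA, nodeB, score)",
         call. = FALSE)
  # tolerate a header row
  if (is.na(suppressWarnings(as.numeric(tab[1L, 3L]))))
    tab <- tab[-1L, , drop = FALSE]
  edges <- data.frame(from = as.character(tab[[1L]]),
                      to = as.character(tab[[2L]]),
                      score = suppressWarnings(as.numeric(tab[[3L]])),
                      stringsAsFactors = FALSE)
  if (any(is.na(edges$score)))
    stop("format error: non-numeric score in edge list", call. = FALSE)
  if (scoreScale == "auto")
    scoreScale <- if (max(edges$score) > 1) "string1000" else "unit"
  maxScore <- if (scoreScale == "string1000") 1000 else 1
  if (any(edges$score < 0 | edges$score > maxScore))
    stop(sprintf("format error: scores must lie in [0, %g]", maxScore),
         call. = FALSE)
  conf <- if (scoreScale == "string1000") edges$score / 1000 else edges$score
  interactionNetwork(edges$from, edges$to, conf,
                     minConfidence = minConfidence)
}

#' Build an InteractionNetwork from vectors
#'
#' @param from,to node name vectors.
#' @param confidence per-edge confidence in \[0, 1\].
#' @param minConfidence edges below this are dropped.
#' @return an [InteractionNetwork-class].
#' @export
interactionNetwork <- function(from, to, confidence, minConfidence = 0.7) {
  stopifnot(length(from) == length(to), length(from) == length(confidence))
  keep <- from != to            # drop self-loops
  df <- data.frame(from = from[keep], to = to[keep],
                   confidence = confidence[keep],
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(confidence = "max"))
  if (igraph::ecount(g) > 0)
    g <- igraph::delete_edges(
      g, igraph::E(g)[igraph::E(g)$confidence < minConfidence])
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  new("InteractionNetwork", graph = g, minConfidence = minConfidence)
}

#' Export a PCSF solution as SIF or GraphML
#'
#' SIF writes one `A interacts B` line per edge; isolated prized nodes are
#' emitted as single-node lines. GraphML (Cytoscape-importable) carries the
#' node attributes (`prize`, `sscore`, `terminal`) and edge attributes
#' (`cost`, `confidence`).
#'
#' @param solution a [PCSFSolution-class].
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @param allowEmpty permit writing an empty solution.
#' @export
writeNetwork <- function(solution, path, format = c("sif", "graphml"),
                         allowEmpty = FALSE) {
  format <- match.arg(format)
  g <- networkGraph(solution)
  if (igraph::vcount(g) == 0 && !allowEmpty)
    stop("refusing to write an empty solution (set allowEmpty = TRUE)",
         call. = FALSE)
  if (format == "sif") {
    lines <- character()
    if (igraph::ecount(g) > 0) {
      el <- igraph::as_edgelist(g)
      lines <- c(lines, sprintf("%s\tinteracts\t%s", el[, 1L], el[, 2L]))
    }
    iso <- igraph::V(g)$name[igraph::degree(g) == 0]
    lines <- c(lines, iso)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(lines, con)
  } else {
    gg <- g
    # graphml writers dislike logical attributes
    if (igraph::vcount(gg) > 0 && !is.null(igraph::V(gg)$terminal))
      igraph::V(gg)$terminal <- as.integer(igraph::V(gg)$terminal)
    igraph::write_graph(gg, path, format = "graphml")
  }
  invisible(path)
}

#' Map feature ids to gene symbols with an offline table
#'
#' Fills `gene_symbol` where the mapping provides one; unmapped features
#' keep their original feature id as the symbol and are counted in a
#' message.
#'
#' @param ds an [OmicsDataset-class].
#' @param mapping `data.frame` with columns `feature_id`, `gene_symbol`
#'   (unique `feature_id` keys).
#' @return the dataset with `gene_symbol` updated.
#' @export
mapFeatureIds <- function(ds, mapping) {
  mapping <- as.data.frame(mapping)
  if (!all(c("feature_id", "gene_symbol") %in% colnames(mapping)))
    stop("mapping must have columns feature_id, gene_symbol", call. = FALSE)
  if (anyDuplicated(mapping$feature_id))
    stop("mapping feature_id keys must be unique", call. = FALSE)
  fm <- rowData(ds)
  idx <- match(fm$feature_id, mapping$feature_id)
  mapped <- !is.na(idx)
  sym <- as.character(fm$feature_id)
  sym[mapped] <- as.character(mapping$gene_symbol[idx[mapped]])
  rowData(ds)$gene_symbol <- sym
  message(sprintf("mapFeatureIds: %d/%d features mapped, %d kept their id as symbol",
                  sum(mapped), nrow(fm), sum(!mapped)))
  ds
}
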