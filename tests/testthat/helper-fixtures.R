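# shared in-code fixtures for the test suite

# minimal OmicsDataset from a plain matrix
makeDataset <- function(x, groups = NULL, log = TRUE, layer = "test",
                        plex = NULL, extra = list()) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("F", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("S", seq_len(ncol(x)))
  if (is.null(groups)) groups <- rep("A", ncol(x))
  sm <- data.frame(sample_id = colnames(x), group = groups,
                   stringsAsFactors = FALSE)
  if (!is.null(plex)) sm$plex <- plex
  for (nm in names(extra)) sm[[nm]] <- extra[[nm]]
  fm <- data.frame(feature_id = rownames(x), gene_symbol = rownames(x),
                   is_contaminant = FALSE, is_reverse = FALSE,
                   stringsAsFactors = FALSE)
  OmicsDataset(x, fm, sm, layerName = layer, logTransformed = log)
}

# two-group dataset with n replicates per group and planted effects
makeTwoGroupData <- function(nFeatures, nPerGroup, effect = 0,
                             effectIdx = integer(), noiseSd = 0.3,
                             seed = 1) {
  withr::local_seed(seed)
  n <- 2 * nPerGroup
  x <- matrix(rnorm(nFeatures * n, mean = 20, sd = noiseSd),
              nFeatures, n)
  eff <- rep(0, nFeatures)
  eff[effectIdx] <- effect
  trt <- (seq_len(n) > nPerGroup)
  x[, trt] <- x[, trt] + eff
  rownames(x) <- sprintf("F%03d", seq_len(nFeatures))
  colnames(x) <- sprintf("S%02d", seq_len(n))
  makeDataset(x, groups = rep(c("ctrl", "treated"), each = nPerGroup))
}

# hand-built DiffExpResult carrying given logFCs and gene symbols
makeFakeResult <- function(logFC, genes = names(logFC),
                           features = NULL) {
  if (is.null(genes)) genes <- paste0("G", seq_along(logFC))
  if (is.null(features)) features <- paste0("f", seq_along(logFC))
  tb <- data.frame(feature_id = features, gene_symbol = genes,
                   logFC = logFC, AveExpr = 0, t = NA_real_,
                   P.Value = NA_real_, adj.P.Val = NA_real_, s2 = 1,
                   df.residual = 4, stringsAsFactors = FALSE)
  new("DiffExpResult", table = tb, contrast = c(x = 1), fit = NULL,
      moderated = FALSE)
}

# small InteractionNetwork from explicit edge vectors
makeNetwork <- function(from, to, confidence, minConfidence = 0) {
  assignEdgeCosts(interactionNetwork(from, to, confidence,
                                     minConfidence = minConfidence))
}

# PrizeMap over the nodes of `net` with explicit raw prizes
makePrizes <- function(net, prizes, mu = 0) {
  g <- networkGraph(net)
  nodes <- igraph::V(g)$name
  raw <- rep(0, length(nodes))
  names(raw) <- nodes
  raw[names(prizes)] <- prizes
  deg <- igraph::degree(g)
  tb <- data.frame(node = nodes, rawPrize = as.numeric(raw),
                   degree = as.numeric(deg),
                   effectivePrize = pmax(0, raw - mu * deg),
                   terminal = raw > 0, sscore = as.numeric(raw),
                   stringsAsFactors = FALSE)
  new("PrizeMap", table = tb, mu = mu, alpha = 0.05)
}

# random PCSF instance on <= maxNodes nodes for oracle comparisons
randomPCSFInstance <- function(seed, maxNodes = 10) {
  withr::local_seed(seed)
  n <- sample(4:maxNodes, 1)
  nodes <- paste0("N", seq_len(n))
  pairs <- t(combn(nodes, 2))
  pick <- runif(nrow(pairs)) < 0.45
  if (sum(pick) < 1) pick[1] <- TRUE
  net <- makeNetwork(pairs[pick, 1], pairs[pick, 2],
                     confidence = runif(sum(pick), 0.1, 1))
  g <- networkGraph(net)
  present <- igraph::V(g)$name
  nTerm <- max(1, rbinom(1, length(present), 0.5))
  term <- sample(present, nTerm)
  prizes <- setNames(runif(nTerm, 0, 3), term)
  list(net = net, prizes = makePrizes(net, prizes))
}

# independent brute-force BH step-up oracle
bhOracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- rep(NA_real_, n)
  prev <- Inf
  for (i in n:1) {
    v <- min(prev, p[ord[i]] * n / i)
    adj[ord[i]] <- min(v, 1)
    prev <- v
  }
  adj
}

# exact hypergeometric upper-tail by pmf enumeration (choose-based)
hyperTailOracle <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
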