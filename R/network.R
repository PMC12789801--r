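#' @include AllClasses.R
NULL

#' Set edge costs from confidences
#'
#' c(e) = 1 - confidence, clamped to \[1e-6, 1\] so that no edge is free.
#'
#' @param net an [InteractionNetwork-class].
#' @return the network with an edge `cost` attribute.
#' @export
assignEdgeCosts <- function(net) {
  g <- net@graph
  if (igraph::ecount(g) > 0)
    igraph::E(g)$cost <- pmin(pmax(1 - igraph::E(g)$confidence, 1e-6), 1)
  net@graph <- g
  net
}

#' Assign node prizes from integrated S-scores
#'
#' Significant genes (adjusted p < alpha) present in the network receive
#' raw prize |S|; all other nodes receive 0. The effective prize applies
#' the hub penalty, max(0, raw - mu * degree), with degree taken in the
#' filtered base network. Significant genes absent from the network are
#' reported in a message, not silently dropped.
#'
#' @param net an [InteractionNetwork-class].
#' @param sscores an [SScoreTable-class].
#' @param alpha significance threshold (default 0.05).
#' @param mu hub penalty per unit degree (default 0).
#' @return a [PrizeMap-class].
#' @export
assignPrizes <- function(net, sscores, alpha = 0.05, mu = 0) {
  stopifnot(mu >= 0)
  g <- net@graph
  nodes <- igraph::V(g)$name
  tb <- resultTable(sscores)
  sig <- tb[tb$sscore_adj_pval < alpha, , drop = FALSE]
  inNet <- sig$gene %in% nodes
  if (!any(inNet))
    stop("no significant gene maps into the network; consider a larger ",
         "alpha or a larger network", call. = FALSE)
  if (any(!inNet))
    message(sprintf("assignPrizes: %d significant gene(s) not in the network: %s",
                    sum(!inNet),
                    paste(utils::head(sig$gene[!inNet], 10L),
                          collapse = ", ")))
  raw <- stats::setNames(rep(0, length(nodes)), nodes)
  raw[sig$gene[inNet]] <- abs(sig$sscore[inNet])
  sc <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  idx <- match(nodes, tb$gene)
  sc[!is.na(idx)] <- tb$sscore[idx[!is.na(idx)]]
  deg <- igraph::degree(g)
  eff <- pmax(0, raw - mu * deg)
  out <- data.frame(node = nodes, rawPrize = as.numeric(raw),
                    degree = as.numeric(deg),
                    effectivePrize = as.numeric(eff),
                    terminal = raw > 0, sscore = as.numeric(sc),
                    stringsAsFactors = FALSE)
  new("PrizeMap", table = out, mu = mu, alpha = alpha)
}

# ---- internal forest machinery -------------------------------------------

# union-find
.ufFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# minimum spanning tree of the subgraph induced by `sel` (logical over
# local node indices). edges: data.frame(a, b, cost) in local indices,
# pre-sorted by (cost, a, b) for determinism. Returns list(connected,
# cost, edgeIdx) where connected refers to the induced subgraph.
.inducedMST <- function(edges, sel) {
  nSel <- sum(sel)
  if (nSel == 0L)
    return(list(connected = FALSE, cost = 0, edgeIdx = integer()))
  if (nSel == 1L)
    return(list(connected = TRUE, cost = 0, edgeIdx = integer()))
  parent <- seq_along(sel)
  cost <- 0
  take <- integer()
  got <- 0L
  for (k in seq_len(nrow(edges))) {
    a <- edges$a[k]; b <- edges$b[k]
    if (!sel[a] || !sel[b]) next
    ra <- .ufFind(parent, a); rb <- .ufFind(parent, b)
    if (ra != rb) {
      parent[ra] <- rb
      cost <- cost + edges$cost[k]
      take <- c(take, k)
      got <- got + 1L
      if (got == nSel - 1L) break
    }
  }
  list(connected = got == nSel - 1L, cost = cost, edgeIdx = take)
}

# component context: local edge table sorted by (cost, a, b)
.componentContext <- function(g, nodes) {
  sub <- igraph::induced_subgraph(g, nodes)
  nm <- igraph::V(sub)$name
  if (igraph::ecount(sub) > 0) {
    el <- igraph::as_edgelist(sub)
    ed <- data.frame(a = match(el[, 1L], nm), b = match(el[, 2L], nm),
                     cost = igraph::E(sub)$cost,
                     confidence = igraph::E(sub)$confidence)
    swap <- ed$a > ed$b
    tmp <- ed$a[swap]; ed$a[swap] <- ed$b[swap]; ed$b[swap] <- tmp
    ed <- ed[order(ed$cost, ed$a, ed$b), , drop = FALSE]
  } else {
    ed <- data.frame(a = integer(), b = integer(), cost = numeric(),
                     confidence = numeric())
  }
  list(graph = sub, names = nm, edges = ed)
}

# objective of a selection within one component; -Inf when invalid
.selObjective <- function(ctx, sel, prize, lambda) {
  if (!any(sel)) return(list(value = 0, edgeIdx = integer()))
  mst <- .inducedMST(ctx$edges, sel)
  if (!mst$connected) return(list(value = -Inf, edgeIdx = integer()))
  list(value = sum(prize[sel]) - lambda * mst$cost, edgeIdx = mst$edgeIdx)
}

# local search: deterministic add/remove single-node moves to a fixpoint
.polishSelection <- function(ctx, sel, prize, lambda, maxIter = 200L) {
  n <- length(sel)
  adj <- lapply(seq_len(n), function(i)
    c(ctx$edges$b[ctx$edges$a == i], ctx$edges$a[ctx$edges$b == i]))
  cur <- .selObjective(ctx, sel, prize, lambda)$value
  for (iter in seq_len(maxIter)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      cand <- sel
      if (sel[i]) {
        if (sum(sel) == 1L) next
        cand[i] <- FALSE
      } else {
        if (any(sel) && !any(sel[adj[[i]]])) next  # keep connected growth
        cand[i] <- TRUE
      }
      val <- .selObjective(ctx, cand, prize, lambda)$value
      if (val > cur + 1e-12) {
        sel <- cand; cur <- val; improved <- TRUE
      }
    }
    if (!improved) break
  }
  sel
}

# greedy terminal growth from one seed using shortest paths
.growFromSeed <- function(ctx, seed, prize, lambda) {
  n <- length(ctx$names)
  sel <- rep(FALSE, n)
  sel[seed] <- TRUE
  terminals <- which(prize > 0)
  if (igraph::ecount(ctx$graph) == 0) return(sel)
  w <- lambda * igraph::E(ctx$graph)$cost
  repeat {
    outT <- setdiff(terminals, which(sel))
    if (length(outT) == 0L) break
    dmat <- igraph::distances(ctx$graph, v = outT, to = which(sel),
                              weights = w)
    bestGain <- -Inf; bestPath <- NULL
    for (r in seq_along(outT)) {
      t <- outT[r]
      j <- which.min(dmat[r, ])
      sp <- igraph::shortest_paths(ctx$graph, from = t,
                                   to = which(sel)[j], weights = w)
      pathIdx <- as.integer(sp$vpath[[1L]])
      if (length(pathIdx) == 0L) next
      newNodes <- pathIdx[!sel[pathIdx]]
      gain <- sum(prize[newNodes]) - dmat[r, j]
      if (gain > bestGain + 1e-12) {
        bestGain <- gain; bestPath <- newNodes
      }
    }
    if (is.null(bestPath) || bestGain <= 1e-12) break
    sel[bestPath] <- TRUE
  }
  sel
}

.solutionFromSelections <- function(g, picks, lambda) {
  # picks: list of (names, edge rows with from/to/cost/confidence)
  nodes <- unlist(lapply(picks, `[[`, "names"))
  sg <- igraph::induced_subgraph(g, nodes)
  keep <- do.call(rbind, lapply(picks, `[[`, "edges"))
  sg <- igraph::delete_edges(sg, igraph::E(sg))
  if (!is.null(keep) && nrow(keep) > 0)
    sg <- igraph::add_edges(sg,
            as.vector(rbind(match(keep$from, igraph::V(sg)$name),
                            match(keep$to, igraph::V(sg)$name))),
            attr = list(cost = keep$cost, confidence = keep$confidence))
  obj <- sum(igraph::V(sg)$prize) -
    lambda * (if (igraph::ecount(sg)) sum(igraph::E(sg)$cost) else 0)
  new("PCSFSolution", graph = sg, objective = obj, lambda = lambda)
}

.preparePrizedGraph <- function(net, prizes) {
  g <- net@graph
  if (igraph::ecount(g) > 0 && is.null(igraph::E(g)$cost))
    g <- assignEdgeCosts(net)@graph
  tb <- resultTable(prizes)
  idx <- match(igraph::V(g)$name, tb$node)
  if (anyNA(idx))
    stop("prize map does not cover all network nodes", call. = FALSE)
  igraph::V(g)$prize <- tb$effectivePrize[idx]
  igraph::V(g)$rawPrize <- tb$rawPrize[idx]
  igraph::V(g)$terminal <- tb$terminal[idx] & tb$effectivePrize[idx] > 0
  igraph::V(g)$sscore <- tb$sscore[idx]
  g
}

.pickFromSelection <- function(ctx, sel, prize, lambda) {
  mst <- .inducedMST(ctx$edges, sel)
  ed <- ctx$edges[mst$edgeIdx, , drop = FALSE]
  list(names = ctx$names[sel],
       edges = data.frame(from = ctx$names[ed$a], to = ctx$names[ed$b],
                          cost = ed$cost, confidence = ed$confidence,
                          stringsAsFactors = FALSE),
       value = sum(prize[sel]) - lambda * mst$cost)
}

#' Extract a prize-collecting Steiner forest (heuristic)
#'
#' Maximizes sum of effective node prizes minus lambda times the summed
#' edge costs. Within each connected component of the filtered base
#' network the solution is a single tree (possibly a single prized node,
#' possibly empty); the forest arises across components. The heuristic
#' grows trees from high-prize seeds along cheapest paths between
#' terminals, re-costs the selection with a minimum spanning tree, and
#' polishes it with deterministic add/remove local search. Guarantees:
#' the objective is never below the best single-terminal singleton, and
#' the result is deterministic for a fixed input ordering.
#'
#' @param net an [InteractionNetwork-class] with edge costs (see
#'   [assignEdgeCosts()]; costs are set automatically when absent).
#' @param prizes a [PrizeMap-class] from [assignPrizes()].
#' @param lambda edge-cost multiplier, > 0 (default 1).
#' @param nSeeds number of highest-prize growth seeds per component.
#' @return a [PCSFSolution-class].
#' @export
solvePCSF <- function(net, prizes, lambda = 1, nSeeds = 3) {
  stopifnot(lambda > 0)
  g <- .preparePrizedGraph(net, prizes)
  if (all(igraph::V(g)$prize <= 0)) {
    warning("no positive effective prize; returning an empty solution",
            call. = FALSE)
    return(new("PCSFSolution",
               graph = igraph::make_empty_graph(0, directed = FALSE),
               objective = 0, lambda = lambda))
  }
  comp <- igraph::components(g)
  picks <- list()
  for (ci in seq_len(comp$no)) {
    nodes <- which(comp$membership == ci)
    ctx <- .componentContext(g, nodes)
    prize <- igraph::V(ctx$graph)$prize
    terms <- which(prize > 0)
    if (length(terms) == 0L) next
    seeds <- terms[order(-prize[terms], ctx$names[terms])]
    seeds <- utils::head(seeds, nSeeds)
    best <- NULL
    for (seed in seeds) {
      sel <- .growFromSeed(ctx, seed, prize, lambda)
      sel <- .polishSelection(ctx, sel, prize, lambda)
      cand <- .pickFromSelection(ctx, sel, prize, lambda)
      if (is.null(best) || cand$value > best$value + 1e-12) best <- cand
    }
    # guarantee: never below the best singleton terminal
    singleBest <- terms[order(-prize[terms], ctx$names[terms])][1L]
    if (best$value < prize[singleBest] - 1e-12) {
      sel <- rep(FALSE, length(prize)); sel[singleBest] <- TRUE
      best <- .pickFromSelection(ctx, sel, prize, lambda)
    }
    if (best$value > 1e-12 ||
        (best$value >= 0 && length(best$names) > 0 &&
         max(prize[match(best$names, ctx$names)]) > 0))
      picks[[length(picks) + 1L]] <- best
  }
  if (length(picks) == 0L) {
    warning("no profitable subnetwork; returning an empty solution",
            call. = FALSE)
    return(new("PCSFSolution",
               graph = igraph::make_empty_graph(0, directed = FALSE),
               objective = 0, lambda = lambda))
  }
  .solutionFromSelections(g, picks, lambda)
}

#' Exact prize-collecting Steiner forest by enumeration
#'
#' Test oracle: exhaustively enumerates, within each connected component
#' of the base network (<= 15 nodes total), every node subset whose
#' induced subgraph is connected, scoring it by the sum of effective
#' prizes minus lambda times its minimum-spanning-tree cost. Exact
#' optimum under the same model as [solvePCSF()].
#'
#' @inheritParams solvePCSF
#' @return a [PCSFSolution-class] attaining the optimum.
#' @export
bruteForcePCSF <- function(net, prizes, lambda = 1) {
  stopifnot(lambda > 0)
  g <- .preparePrizedGraph(net, prizes)
  if (igraph::vcount(g) > 15L)
    stop("brute force is capped at 15 nodes", call. = FALSE)
  if (igraph::vcount(g) == 0L)
    return(new("PCSFSolution",
               graph = igraph::make_empty_graph(0, directed = FALSE),
               objective = 0, lambda = lambda))
  comp <- igraph::components(g)
  picks <- list()
  for (ci in seq_len(comp$no)) {
    nodes <- which(comp$membership == ci)
    ctx <- .componentContext(g, nodes)
    prize <- igraph::V(ctx$graph)$prize
    m <- length(prize)
    bestVal <- 0; bestSel <- NULL
    for (mask in seq_len(2^m - 1L)) {
      sel <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
      val <- .selObjective(ctx, sel, prize, lambda)$value
      if (val > bestVal + 1e-12) {
        bestVal <- val; bestSel <- sel
      }
    }
    if (!is.null(bestSel))
      picks[[length(picks) + 1L]] <-
        .pickFromSelection(ctx, bestSel, prize, lambda)
  }
  if (length(picks) == 0L)
    return(new("PCSFSolution",
               graph = igraph::make_empty_graph(0, directed = FALSE),
               objective = 0, lambda = lambda))
  .solutionFromSelections(g, picks, lambda)
}

#' Cluster a PCSF solution into modules
#'
#' Greedy modularity maximization (fast-greedy) on the solution subgraph
#' with edge weights = interaction confidence; deterministic under a
#' fixed node ordering. Singleton clusters are allowed.
#'
#' @param solution a [PCSFSolution-class] (or bare `igraph`) with >= 2
#'   nodes.
#' @return named integer vector: gene -> cluster id.
#' @export
clusterSolution <- function(solution) {
  g <- if (igraph::is_igraph(solution)) solution
       else networkGraph(solution)
  if (igraph::vcount(g) < 2L)
    stop("clustering needs a solution with >= 2 nodes", call. = FALSE)
  if (igraph::ecount(g) == 0) {
    mem <- seq_len(igraph::vcount(g))
  } else {
    w <- igraph::E(g)$confidence
    fc <- igraph::cluster_fast_greedy(g, weights = w)
    mem <- igraph::membership(fc)
    # greedy merging can strand tiny components as singletons; fall back
    # to whole components when they score at least as well
    compMem <- igraph::components(g)$membership
    if (igraph::modularity(g, compMem, weights = w) >=
        igraph::modularity(g, mem, weights = w) - 1e-12 &&
        length(unique(compMem)) < length(unique(mem)))
      mem <- compMem
  }
  stats::setNames(as.integer(mem), igraph::V(g)$name)
}

#' Rank hub nodes of a PCSF solution
#'
#' Hub score = mean of min-max normalized degree and betweenness
#' centrality within the solution subgraph; ties are broken by prize,
#' then node name.
#'
#' @param solution a [PCSFSolution-class] with >= 3 nodes.
#' @param topK number of hubs to return (default all).
#' @return `data.frame` with `node`, `degree`, `betweenness`, `hub_score`,
#'   `prize`, ordered by decreasing hub score.
#' @export
rankHubs <- function(solution, topK = Inf) {
  g <- networkGraph(solution)
  if (igraph::vcount(g) < 3L)
    stop("hub ranking needs a solution with >= 3 nodes", call. = FALSE)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = rep(1, igraph::ecount(g)))
  mm <- function(v) if (diff(range(v)) == 0) rep(0, length(v))
                    else (v - min(v)) / diff(range(v))
  score <- (mm(deg) + mm(btw)) / 2
  prize <- igraph::V(g)$prize
  if (is.null(prize)) prize <- rep(0, igraph::vcount(g))
  ord <- order(-score, -prize, igraph::V(g)$name)
  out <- data.frame(node = igraph::V(g)$name[ord],
                    degree = as.numeric(deg[ord]),
                    betweenness = as.numeric(btw[ord]),
                    hub_score = score[ord], prize = prize[ord],
                    stringsAsFactors = FALSE)
  utils::head(out, topK)
}
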