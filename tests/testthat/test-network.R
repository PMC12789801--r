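test_that("edge costs are one minus confidence with a positive floor", {
  net <- makeNetwork(c("A", "B", "C"), c("B", "C", "D"),
                     c(0.9, 1.0, 0.7))
  g <- networkGraph(net)
  costOf <- function(a, b)
    igraph::E(g)$cost[igraph::get_edge_ids(g, c(a, b))]
  expect_equal(costOf("A", "B"), 0.1)
  expect_equal(costOf("B", "C"), 1e-6)      # clamp: no free edges
  expect_equal(costOf("C", "D"), 0.3)       # cutoff-boundary edge retained
})

test_that("prizes are |S| for significant in-network genes with hub penalty", {
  net <- makeNetwork(c("A", "A", "B"), c("B", "C", "C"), rep(0.9, 3))
  S <- c(-26.68, 5, 10)
  pv <- 2 * pnorm(-abs(S))
  tb <- data.frame(gene = c("A", "B", "Z"),
                   comb_wz = S, comb_w = 1,
                   sscore = S,
                   sscore_pval = pv,
                   sscore_adj_pval = p.adjust(pv, "BH"),
                   significant = TRUE, n_records = 1, n_layers = 1,
                   stringsAsFactors = FALSE)
  ss <- new("SScoreTable", table = tb,
            contributions = data.frame(gene = tb$gene, layer = "l",
                                       feature_id = tb$gene, z = 1,
                                       w = 1, wz = 1),
            alpha = 0.05)
  expect_message(pm <- assignPrizes(net, ss), "Z")   # absent gene logged
  ptb <- resultTable(pm)
  expect_equal(ptb$rawPrize[ptb$node == "A"], 26.68)
  expect_equal(ptb$rawPrize[ptb$node == "C"], 0)     # non-significant
  expect_true(all(ptb$terminal == (ptb$rawPrize > 0)))
  # large mu zeroes every effective prize
  pmMu <- suppressMessages(assignPrizes(net, ss, mu = 100))
  expect_true(all(resultTable(pmMu)$effectivePrize == 0))
  # no significant gene in network -> error
  ssOut <- ss
  ssOut@table$gene <- c("X1", "X2", "X3")
  ssOut@contributions$gene <- ssOut@table$gene
  expect_error(assignPrizes(net, ssOut), "no significant gene")
})

test_that("solver matches brute force on the printed toy fixtures", {
  # two prized neighbours worth connecting
  n1 <- makeNetwork("A", "B", 1 - 1)   # cost exactly 1 via confidence 0
  n1 <- makeNetwork("A", "B", 0)       # confidence 0 -> cost 1
  p1 <- makePrizes(n1, c(A = 5, B = 5))
  s1 <- solvePCSF(n1, p1, lambda = 1)
  b1 <- bruteForcePCSF(n1, p1, lambda = 1)
  expect_equal(objectiveValue(s1), 9)
  expect_equal(objectiveValue(b1), 9)
  expect_setequal(igraph::V(networkGraph(s1))$name, c("A", "B"))

  # cheap prize not worth the expensive edge: singleton {A}
  n2 <- makeNetwork("A", "B", 0)
  g2 <- networkGraph(n2); igraph::E(g2)$cost <- 2
  n2@graph <- g2
  p2 <- makePrizes(n2, c(A = 5, B = 0.5))
  s2 <- solvePCSF(n2, p2, lambda = 1)
  expect_equal(objectiveValue(s2), 5)
  expect_equal(igraph::V(networkGraph(s2))$name, "A")
  expect_equal(objectiveValue(bruteForcePCSF(n2, p2, lambda = 1)), 5)

  # Steiner node collected at no prize to join two terminals
  n3 <- makeNetwork(c("T1", "s"), c("s", "T2"), c(0, 0))
  p3 <- makePrizes(n3, c(T1 = 3, T2 = 3))
  s3 <- solvePCSF(n3, p3, lambda = 1)
  expect_equal(objectiveValue(s3), 4)
  expect_setequal(igraph::V(networkGraph(s3))$name, c("T1", "s", "T2"))
  expect_equal(objectiveValue(bruteForcePCSF(n3, p3, lambda = 1)), 4)
})

test_that("solutions are forests without dangling Steiner leaves", {
  withr::local_seed(51)
  for (seed in 1:30) {
    inst <- randomPCSFInstance(seed)
    sol <- suppressWarnings(solvePCSF(inst$net, inst$prizes, lambda = 1))
    g <- networkGraph(sol)
    if (igraph::vcount(g) == 0) next
    expect_equal(igraph::ecount(g),
                 igraph::vcount(g) - igraph::components(g)$no)
    # no zero-prize leaf: every Steiner node lies between terminals
    deg <- igraph::degree(g)
    leafPrize <- igraph::V(g)$prize[deg <= 1]
    if (length(leafPrize)) expect_true(all(leafPrize > 0))
  }
})

test_that("heuristic objective meets the oracle guarantee on random instances", {
  ratios <- vapply(1:120, function(seed) {
    inst <- randomPCSFInstance(seed)
    sol <- suppressWarnings(solvePCSF(inst$net, inst$prizes, lambda = 1))
    opt <- bruteForcePCSF(inst$net, inst$prizes, lambda = 1)
    if (objectiveValue(opt) <= 1e-12) return(1)
    objectiveValue(sol) / objectiveValue(opt)
  }, numeric(1))
  expect_true(all(ratios >= 0.5 - 1e-9))
  expect_gte(mean(ratios >= 1 - 1e-9), 0.8)
})

test_that("objective never drops below the best singleton and lambda -> inf degenerates", {
  inst <- randomPCSFInstance(99)
  ptb <- resultTable(inst$prizes)
  bestSingle <- max(ptb$effectivePrize)
  sol <- suppressWarnings(solvePCSF(inst$net, inst$prizes, lambda = 1))
  expect_gte(objectiveValue(sol), bestSingle - 1e-9)
  solBig <- suppressWarnings(solvePCSF(inst$net, inst$prizes,
                                       lambda = 1e6))
  expect_equal(igraph::ecount(networkGraph(solBig)), 0L)
  expect_true(all(igraph::V(networkGraph(solBig))$prize > 0))
})

test_that("increasing an included node's prize never lowers the objective", {
  inst <- randomPCSFInstance(7)
  sol <- suppressWarnings(solvePCSF(inst$net, inst$prizes, lambda = 1))
  g <- networkGraph(sol)
  skip_if(igraph::vcount(g) == 0)
  node <- igraph::V(g)$name[which.max(igraph::V(g)$prize)]
  tb <- resultTable(inst$prizes)
  tb$rawPrize[tb$node == node] <- tb$rawPrize[tb$node == node] + 2
  tb$effectivePrize[tb$node == node] <-
    tb$effectivePrize[tb$node == node] + 2
  up <- new("PrizeMap", table = tb, mu = 0, alpha = 0.05)
  sol2 <- suppressWarnings(solvePCSF(inst$net, up, lambda = 1))
  expect_gte(objectiveValue(sol2), objectiveValue(sol) - 1e-9)
})

test_that("solver is deterministic and empty prize maps warn", {
  inst <- randomPCSFInstance(13)
  s1 <- solvePCSF(inst$net, inst$prizes)
  s2 <- solvePCSF(inst$net, inst$prizes)
  expect_identical(igraph::V(networkGraph(s1))$name,
                   igraph::V(networkGraph(s2))$name)
  expect_identical(objectiveValue(s1), objectiveValue(s2))
  zero <- makePrizes(inst$net, setNames(numeric(0), character(0)))
  expect_warning(sEmpty <- solvePCSF(inst$net, zero), "empty solution")
  expect_equal(objectiveValue(sEmpty), 0)
})

test_that("brute force handles trivial instances and enforces its size cap", {
  net <- makeNetwork("A", "B", 0.9)
  pm <- makePrizes(net, c(A = 2))
  sol <- bruteForcePCSF(net, pm)
  expect_equal(igraph::V(networkGraph(sol))$name, "A")
  expect_equal(objectiveValue(sol), 2)
  big <- paste0("N", 1:17)
  netBig <- makeNetwork(big[-17], big[-1], rep(0.9, 16))
  expect_error(bruteForcePCSF(netBig, makePrizes(netBig, c(N1 = 1))),
               "capped")
})

test_that("planted high-prize modules are recovered at default lambda", {
  recovered <- vapply(1:20, function(seed) {
    module <- paste0("M", 1:12)
    bg <- paste0("B", 1:60)
    netSim <- generateNetwork(bg, module, seed = seed)
    net <- assignEdgeCosts(netSim$network)
    present <- intersect(module, igraph::V(networkGraph(net))$name)
    prizes <- makePrizes(net, setNames(abs(rnorm(length(present), 5, 1)),
                                       present))
    sol <- suppressWarnings(solvePCSF(net, prizes, lambda = 1))
    mean(present %in% igraph::V(networkGraph(sol))$name)
  }, numeric(1))
  expect_gte(mean(recovered), 0.8)
})

test_that("module clustering separates dense blocks and tolerates tiny solutions", {
  # two 4-cliques joined by one edge
  cl1 <- paste0("a", 1:4); cl2 <- paste0("b", 1:4)
  e1 <- t(combn(cl1, 2)); e2 <- t(combn(cl2, 2))
  from <- c(e1[, 1], e2[, 1], "a1"); to <- c(e1[, 2], e2[, 2], "b1")
  net <- makeNetwork(from, to, rep(0.9, length(from)))
  mem <- clusterSolution(networkGraph(net))
  expect_equal(length(unique(mem)), 2L)
  expect_equal(length(unique(mem[cl1])), 1L)
  expect_equal(length(unique(mem[cl2])), 1L)
  # a single edge forms one cluster
  net2 <- makeNetwork("A", "B", 0.9)
  sol2 <- solvePCSF(net2, makePrizes(net2, c(A = 5, B = 5)))
  expect_equal(length(unique(clusterSolution(sol2))), 1L)
  expect_error(clusterSolution(new("PCSFSolution",
                                   graph = igraph::make_empty_graph(0, directed = FALSE),
                                   objective = 0, lambda = 1)),
               ">= 2 nodes")
})

test_that("hub ranking prefers central nodes with documented tie-breaks", {
  # star: center dominates degree and betweenness
  net <- makeNetwork(rep("hub", 4), paste0("leaf", 1:4), rep(0.9, 4))
  pm <- makePrizes(net, setNames(rep(3, 5), c("hub", paste0("leaf", 1:4))))
  sol <- solvePCSF(net, pm, lambda = 1)
  hubs <- rankHubs(sol)
  expect_equal(hubs$node[1], "hub")
  # path of three: middle first
  net3 <- makeNetwork(c("x", "y"), c("y", "z"), c(0.9, 0.9))
  sol3 <- solvePCSF(net3, makePrizes(net3, c(x = 3, y = 3, z = 3)))
  expect_equal(rankHubs(sol3)$node[1], "y")
  # symmetric middle nodes of a 4-path: tie broken by larger prize
  net4 <- makeNetwork(c("p", "q", "r"), c("q", "r", "s"), rep(0.9, 3))
  sol4 <- solvePCSF(net4, makePrizes(net4, c(p = 3, q = 1, r = 5, s = 3)))
  expect_equal(rankHubs(sol4)$node[1], "r")
  expect_error(rankHubs(new("PCSFSolution",
                            graph = igraph::make_empty_graph(0, directed = FALSE),
                            objective = 0, lambda = 1)), ">= 3 nodes")
})
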