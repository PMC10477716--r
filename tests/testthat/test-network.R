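test_that("prevalence filtering uses a strict fraction", {
  counts <- matrix(0L, 3, 24)
  counts[1, 1:13] <- 5L   # 13/24 > 0.5: kept
  counts[2, 1:12] <- 5L   # 12/24 = 0.5: dropped
  counts[3, 1] <- 2L      # kept at minFraction 0
  otu <- otuFromCounts(counts)
  kept <- prevalenceFilter(otu, 0.5)
  expect_identical(rownames(kept), "OTU1")
  keptAll <- prevalenceFilter(otu, 0)
  expect_setequal(rownames(keptAll), c("OTU1", "OTU2", "OTU3"))

  # brute-force recount on a random zero-inflated table
  set.seed(5)
  cnt <- matrix(rpois(100 * 24, 2) * rbinom(100 * 24, 1, 0.5), 100, 24)
  cnt[1, ] <- 5  # guarantee a survivor
  otu2 <- otuFromCounts(cnt)
  expect_equal(nrow(prevalenceFilter(otu2, 0.5)),
               sum(rowMeans(cnt > 0) > 0.5))

  expect_error(prevalenceFilter(otuFromCounts(matrix(0L, 2, 24)), 0.5),
               "prevalence")
})

test_that("BH adjustment matches the step-up formula", {
  p <- c(0.001, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), c(0.004, 0.04, 0.04, 0.04))
  expect_equal(stepUpBH(p), c(0.004, 0.04, 0.04, 0.04))
  set.seed(8)
  for (m in c(10, 137, 1000)) {
    pv <- runif(m)
    expect_equal(p.adjust(pv, "BH"), stepUpBH(pv), tolerance = 1e-12)
  }
  # monotone: sorting raw p sorts adjusted p
  pv <- sort(runif(200))
  expect_true(all(diff(p.adjust(pv, "BH")) >= 0))
})

test_that("monotone association gives a unit-rho edge and constants drop", {
  n <- 12
  base <- 1:n
  counts <- rbind(
    OTUa = base, OTUb = base * 3 + 2, OTUc = rep(7, n),
    OTUd = c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10, 12, 11)
  )
  otu <- otuFromCounts(counts)
  net <- correlationNetwork(otu, alpha = 0.01)
  e <- networkEdges(net)
  ab <- e[(e$from == "OTUa" & e$to == "OTUb"), ]
  expect_equal(ab$rho, 1)
  expect_equal(ab$p, 0)
  expect_false("OTUc" %in% networkNodes(net))
  expect_equal(net@provenance$constantTaxaDropped, 1L)
  expect_true(all(e$padj < net@alpha))
  expect_true(all(e$sign == sign(e$rho)))
})

test_that("independent taxa produce almost no edges under FDR", {
  set.seed(10)
  fracs <- c()
  for (s in 1:5) {
    cnt <- matrix(rpois(50 * 24, 30), 50, 24)
    otu <- otuFromCounts(cnt)
    net <- correlationNetwork(otu, alpha = 0.01)
    fracs <- c(fracs, nrow(networkEdges(net)) / choose(50, 2))
  }
  expect_lte(mean(fracs), 0.01)
})

test_that("treatment subnetworks follow the within-treatment presence rule", {
  d <- synthDesign(seed = 30,
                   silenceModule = list(treatment = "GMC", module = 2))
  com <- simulateCommunity(d)
  f <- prevalenceFilter(com$otu)
  net <- correlationNetwork(f)

  # silenced module loses its nodes in that treatment's subnetwork
  sub <- treatmentSubnetwork(net, com$otu, "GMC")
  m2taxa <- names(com$truth$moduleAssignment)[
    com$truth$moduleAssignment == 2]
  expect_length(intersect(networkNodes(sub), m2taxa), 0)

  # other planted modules stay intact
  m1taxa <- intersect(
    names(com$truth$moduleAssignment)[com$truth$moduleAssignment == 1],
    networkNodes(net)
  )
  expect_true(all(m1taxa %in% networkNodes(sub)))

  # a treatment whose samples contain every OTU keeps the whole network
  full <- otuFromCounts(
    matrix(5L + matrix(rpois(10 * 24, 5), 10, 24), 10, 24)
  )
  netF <- networkFromAdjacency(
    {a <- matrix(1, 10, 10); diag(a) <- 0
     rownames(a) <- colnames(a) <- paste0("OTU", 1:10); a}
  )
  subF <- treatmentSubnetwork(netF, full, "NPK")
  expect_setequal(networkNodes(subF), networkNodes(netF))
  expect_equal(nrow(networkEdges(subF)), nrow(networkEdges(netF)))

  expect_error(treatmentSubnetwork(net, com$otu, "nope"), "unknown")
})

test_that("clustering coefficients match brute-force triangle counts", {
  # triangle
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  tTri <- networkTopology(networkFromAdjacency(tri))
  expect_equal(tTri$averageClusteringCoefficient, 1.0)
  expect_equal(tTri$averageDegree, 2.0)

  # path of 3 nodes
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  expect_equal(
    networkTopology(networkFromAdjacency(path))$averageClusteringCoefficient,
    0.0
  )

  # random graphs vs enumeration oracle
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    adj <- matrix(rbinom(n * n, 1, 0.15), n, n)
    adj[lower.tri(adj, diag = TRUE)] <- 0
    adj <- adj + t(adj)
    if (sum(adj) == 0) next
    net <- networkFromAdjacency(adj)
    topo <- networkTopology(net)
    keep <- rowSums(adj) > 0   # only edge endpoints are nodes
    sub <- adj[keep, keep, drop = FALSE]
    expect_equal(topo$averageClusteringCoefficient,
                 mean(bruteClustering(sub)), tolerance = 1e-12)
    expect_equal(topo$averageDegree, 2 * topo$edges / topo$nodes)
    expect_equal(topo$positiveEdges + topo$negativeEdges, topo$edges)
  }
})

test_that("module detection separates disjoint cliques", {
  cl <- matrix(0, 10, 10)
  cl[1:5, 1:5] <- 1; cl[6:10, 6:10] <- 1; diag(cl) <- 0
  net <- detectModules(networkFromAdjacency(cl), seed = 1)
  mods <- networkModules(net)
  expect_equal(max(mods), 2)
  expect_equal(length(unique(mods[paste0("N", 1:5)])), 1)
  expect_equal(length(unique(mods[paste0("N", 6:10)])), 1)
  expect_gt(net@modularity, 0.3)

  # single clique: one module
  one <- matrix(1, 6, 6); diag(one) <- 0
  netOne <- detectModules(networkFromAdjacency(one), seed = 1)
  expect_equal(max(networkModules(netOne)), 1)
})

test_that("module eigengene equals the oracle first principal component", {
  set.seed(14)
  # perfectly correlated members
  base <- rnorm(10)
  m <- rbind(A = 2 * base + 3, B = 5 * base - 1, C = base)
  colnames(m) <- paste0("S", 1:10)
  eg <- moduleEigengene(m, c("A", "B", "C"))
  expect_equal(eg$varianceExplained, 1.0, tolerance = 1e-12)
  expect_equal(abs(cor(eg$eigengene, base)), 1, tolerance = 1e-12)
  expect_gte(cor(eg$eigengene, rowMeans(scale(t(m)))), 0)

  # two anti-correlated members
  m2 <- rbind(A = base, B = -base)
  colnames(m2) <- paste0("S", 1:10)
  eg2 <- moduleEigengene(m2, c("A", "B"))
  expect_equal(eg2$varianceExplained, 1.0, tolerance = 1e-12)

  # random module vs independent SVD oracle
  x <- matrix(rnorm(8 * 12), 8, 12,
              dimnames = list(paste0("T", 1:8), paste0("S", 1:12)))
  eg3 <- moduleEigengene(x, rownames(x))
  z <- t(scale(t(x)))
  sv <- svd(t(z))
  oracle <- sv$u[, 1] * sv$d[1]
  err <- min(max(abs(eg3$eigengene - oracle)),
             max(abs(eg3$eigengene + oracle)))
  expect_lt(err, 1e-10)

  # zero-variance members are dropped, all-constant errors
  x2 <- rbind(x, K = rep(4, 12))
  expect_equal(moduleEigengene(x2, rownames(x2))$nDropped, 1)
  cst <- rbind(A = rep(1, 5), B = rep(2, 5))
  colnames(cst) <- paste0("S", 1:5)
  expect_error(moduleEigengene(cst, c("A", "B")), "zero variance")
})

test_that("eigengene-environment association is exact in trivial cases", {
  set.seed(15)
  eg <- matrix(rnorm(20), 20, 1, dimnames = list(paste0("S", 1:20), "M1"))
  env <- data.frame(var = eg[, 1], cst = rep(1, 20),
                    row.names = rownames(eg))
  res <- moduleEnvAssociation(eg, env, nPerm = 199, seed = 2)
  self <- res[res$variable == "var", ]
  expect_equal(self$r, 1.0)
  expect_equal(self$pPerm, 1 / 200)
  expect_equal(self$stars, "**")
  expect_true(is.na(res[res$variable == "cst", "r"]))

  # sign flip of the eigengene flips r exactly
  res2 <- moduleEnvAssociation(-eg, env, nPerm = 199, seed = 2)
  expect_equal(res2[res2$variable == "var", "r"], -1.0)
})

test_that("Mantel statistic is affine-invariant and matches vegan", {
  set.seed(16)
  x <- matrix(rnorm(20), 10, 2)
  d1 <- as.matrix(dist(x))
  res <- mantelTest(d1, d1, nPerm = 99, seed = 1)
  expect_equal(res$r, 1.0)
  expect_equal(res$p, 1 / 100)

  expect_equal(mantelTest(d1, 3 * d1 + 2, nPerm = 9, seed = 1)$r, 1.0)

  d2 <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  mine <- mantelTest(d1, d2, nPerm = 99, seed = 1)
  ref <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                       permutations = 99)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)

  expect_error(mantelTest(d1, d2[1:5, 1:5], nPerm = 9, seed = 1), "size")
})

test_that("network export writes GraphML and an annotated edge list", {
  cl <- matrix(0, 6, 6)
  cl[1:3, 1:3] <- 1; cl[4:6, 4:6] <- 1; diag(cl) <- 0
  net <- detectModules(networkFromAdjacency(cl), seed = 1)
  gml <- tempfile(fileext = ".graphml")
  writeNetworkGraphML(net, gml)
  expect_true(file.exists(gml))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 6)

  csv <- tempfile(fileext = ".csv")
  writeEdgeList(net, csv)
  e <- read.csv(csv)
  expect_true(all(c("otu_a", "otu_b", "rho", "p_raw", "p_adj",
                    "module_a") %in%
                  c(names(e), "module_a")))
  expect_true(all(c("module_from", "module_to") %in% names(e)))
})
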