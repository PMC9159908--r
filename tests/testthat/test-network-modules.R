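test_that("Zi-Pi matches brute force on every graph with up to 4 nodes", {
  for (n in 2:4) {
    graphs <- enumerateGraphs(n)
    # one-module, split, and detected partitions for each graph
    partitions <- list(rep(1L, n), c(1L, rep(2L, n - 1)))
    for (adj in graphs) {
      g <- graphFromAdj(adj)
      mems <- c(partitions, list(unname(detectModules(g))))
      for (mem in mems) {
        got <- ziPi(g, stats::setNames(mem, igraph::V(g)$name))
        want <- bruteZiPi(adj, mem)
        expect_equal(got$zi, want$zi, tolerance = 1e-12)
        expect_equal(got$pi, want$pi, tolerance = 1e-12)
      }
    }
  }
})

test_that("Zi-Pi matches brute force on random 5-8 node graphs", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(5:8, 1)
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.4)
    adj <- adj + t(adj)
    mem <- sample(1:3, n, replace = TRUE)
    g <- graphFromAdj(adj)
    got <- ziPi(g, stats::setNames(mem, igraph::V(g)$name))
    want <- bruteZiPi(adj, mem)
    expect_equal(got$zi, want$zi, tolerance = 1e-12)
    expect_equal(got$pi, want$pi, tolerance = 1e-12)
  }
})

test_that("Zi-Pi closed-form cases hold", {
  # 3-clique in one module: identical within-degrees, no outside edges
  adj <- matrix(1, 3, 3) - diag(3)
  g <- graphFromAdj(adj)
  zp <- ziPi(g, stats::setNames(rep(1L, 3), igraph::V(g)$name))
  expect_equal(zp$zi, rep(0, 3))
  expect_equal(zp$pi, rep(0, 3))
  # hub with edges split equally across 2 modules: Pi = 1 - 2*(1/2)^2
  star <- matrix(0L, 5, 5); star[1, 2:5] <- 1L; star <- star + t(star)
  g2 <- graphFromAdj(star)
  mem <- stats::setNames(c(1L, 1L, 1L, 2L, 2L), igraph::V(g2)$name)
  zp2 <- ziPi(g2, mem)
  expect_equal(zp2$pi[1], 0.5)
})

test_that("role classification partitions the Zi-Pi plane", {
  expect_equal(classifyRole(3.0, 0.5), "module_hub")
  expect_equal(classifyRole(1.0, 0.7), "connector")
  expect_equal(classifyRole(3.0, 0.7), "network_hub")
  expect_equal(classifyRole(2.5, 0.62), "peripheral") # both boundaries inclusive-down
  set.seed(14)
  zi <- rnorm(200, 2.5, 1); pi <- runif(200)
  roles <- classifyRole(zi, pi)
  expect_true(all(roles %in% c("module_hub", "connector", "network_hub",
                               "peripheral")))
  # exactly one role per point: reconstruct from the thresholds
  want <- ifelse(zi > 2.5 & pi <= 0.62, "module_hub",
          ifelse(zi <= 2.5 & pi > 0.62, "connector",
          ifelse(zi > 2.5 & pi > 0.62, "network_hub", "peripheral")))
  expect_equal(roles, want)
})

test_that("module detection separates components and planted blocks", {
  # two disconnected triangles
  adj <- matrix(0L, 6, 6)
  adj[1:3, 1:3] <- 1L; adj[4:6, 4:6] <- 1L; diag(adj) <- 0L
  mem <- detectModules(graphFromAdj(adj))
  expect_equal(length(unique(mem)), 2)
  expect_equal(length(unique(mem[1:3])), 1)
  # edgeless graph: every node its own module
  e <- detectModules(graphFromAdj(matrix(0L, 5, 5)))
  expect_equal(length(unique(e)), 5)
  # planted 4-block benchmark: near-perfect recovery
  set.seed(42)
  n <- 40
  labels <- rep(1:4, each = 10)
  p <- outer(labels, labels, function(a, b) ifelse(a == b, 0.8, 0.03))
  adj <- matrix(runif(n * n) < p, n, n)
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  adj <- (adj | t(adj)) + 0L
  g <- graphFromAdj(adj)
  mem <- detectModules(g)
  ari <- mclust::adjustedRandIndex(
    mem, labels[match(names(mem), igraph::V(g)$name)])
  expect_gte(ari, 0.9)
})

test_that("network inference finds planted co-variation and is seeded", {
  set.seed(15)
  nS <- 20
  base <- matrix(rpois(30 * nS, 50), nrow = 30,
                 dimnames = list(sprintf("Otu%02d", 1:30),
                                 sprintf("s%02d", 1:nS)))
  shared <- exp(rnorm(nS, 0, 1))
  base["Otu01", ] <- rpois(nS, 100 * shared)
  base["Otu02", ] <- rpois(nS, 100 * shared)
  net <- inferNetwork(base, sparsityTarget = 0.02, seed = 99)
  g <- networkGraph(net)
  expect_true(igraph::are_adjacent(g, "Otu01", "Otu02"))
  # determinism contract
  net2 <- inferNetwork(base, sparsityTarget = 0.02, seed = 99)
  expect_identical(igraph::as_edgelist(g),
                   igraph::as_edgelist(networkGraph(net2)))
  expect_false(igraph::is_directed(g))
  expect_error(inferNetwork(base[, 1:2]), class = "msipValidationError")
  expect_equal(networkProvenance(net)$seed, 99)
})

test_that("independent taxa produce few stable false edges", {
  set.seed(16)
  noise <- matrix(rpois(50 * 24, 40), nrow = 50,
                  dimnames = list(sprintf("Otu%02d", 1:50),
                                  sprintf("s%02d", 1:24)))
  net <- inferNetwork(noise, sparsityTarget = 0.05, seed = 1)
  nPairs <- choose(50, 2)
  expect_lt(igraph::ecount(networkGraph(net)) / nPairs, 0.05)
})

test_that("module abundances sum member taxa and close over the sample", {
  o <- simulateOtuTable(seed = 17)
  rel <- relativeAbundance(SummarizedExperiment::assay(o$se, "counts"))
  mem <- o$moduleLabels[o$moduleLabels > 0]
  ma <- moduleAbundance(mem, rel)
  expect_equal(nrow(ma), 4)
  # per-sample sums over modules equal the total assigned abundance
  assigned <- colSums(rel[names(mem), ])
  expect_equal(colSums(ma), assigned)
  expect_error(moduleAbundance(c(Missing = 1L), rel),
               class = "msipValidationError")
  # one module containing all taxa has abundance 1 in every sample
  all1 <- moduleAbundance(stats::setNames(rep(1L, nrow(rel)),
                                          rownames(rel)), rel)
  expect_equal(as.numeric(all1), rep(1, ncol(rel)))
})

test_that("module-flux correlations match the direct formula", {
  x <- c(1, 2, 3, 4, 5)
  ma <- rbind(module_1 = x, module_2 = 5 - x)
  flux <- data.frame(a = 2 * x, b = -x + 0)
  res <- moduleFluxCorrelation(ma, flux)
  expect_equal(res$r[res$module == "module_1" & res$variable == "a"], 1)
  expect_equal(res$r[res$module == "module_1" & res$variable == "b"], -1)
  set.seed(18)
  y <- rnorm(5)
  flux2 <- data.frame(y = y)
  r <- moduleFluxCorrelation(ma, flux2)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$r[r$module == "module_1"], manual, tolerance = 1e-12)
  # zero-variance series are undefined, not zero
  flat <- rbind(module_1 = rep(1, 5))
  expect_true(is.na(moduleFluxCorrelation(flat, flux2)$r))
  expect_error(moduleFluxCorrelation(ma[, 1:2], flux[1:2, ]),
               class = "msipValidationError")
})
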