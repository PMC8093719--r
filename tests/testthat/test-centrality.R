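# Centrality measures vs hand enumeration and brute-force oracles.

test_that("alpha centrality with attenuation off returns the exogenous vector", {
  net <- randomFamNet(6, seed = 3)
  a <- alphaCentrality(net, alpha = 0, exo = 2)
  expect_equal(unname(a), rep(2, 6))
})

test_that("alpha centrality accumulates parental scores", {
  # u -> w and v -> w: x_u = x_v = 1, x_w = 1 + 1 + 1 = 3
  net <- makeNet(c("u", "v", "w"),
                 data.frame(from = c("u", "v"), to = c("w", "w")))
  a <- alphaCentrality(net, alpha = 1, exo = 1)
  expect_equal(unname(a[c("u", "v", "w")]), c(1, 1, 3))
})

test_that("alpha centrality matches the nilpotent power series on random DAGs", {
  for (seed in 1:30) {
    net <- randomFamNet(sample(3:8, 1), seed = seed)
    ids <- nodeData(net)$id
    got <- alphaCentrality(net)
    want <- alphaSeriesOracle(ids, netEdges(net))
    expect_equal(got[ids], want[ids], tolerance = 1e-9)
  }
})

test_that("path centralities on a 3-node path match hand enumeration", {
  net <- makeNet(c("A", "B", "C"),
                 data.frame(from = c("A", "B"), to = c("B", "C")))
  pc <- pathCentralities(net)
  rownames(pc) <- pc$id
  expect_equal(pc[c("A", "B", "C"), "betweenness"], c(0, 1, 0))
  expect_equal(pc[c("A", "B", "C"), "closeness"], c(1.5, 2, 1.5))
  expect_equal(pc[c("A", "B", "C"), "eccentricity"], c(2, 1, 2))
})

test_that("an isolated node scores zero on all path centralities", {
  net <- makeNet(c("A", "B", "Z"), data.frame(from = "A", to = "B"))
  pc <- pathCentralities(net)
  z <- pc[pc$id == "Z", ]
  expect_equal(unname(unlist(z[, c("betweenness", "closeness", "eccentricity")])),
               c(0, 0, 0))
})

test_that("edge betweenness matches hand enumeration on small motifs", {
  single <- makeNet(c("u", "v"), data.frame(from = "u", to = "v"))
  expect_equal(edgeBetweenness(single)$score, 1)

  path3 <- makeNet(c("A", "B", "C"),
                   data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_equal(sort(edgeBetweenness(path3)$score), c(2, 2))

  # two triangles joined by a bridge: bridge carries all 9 cross pairs
  edges <- data.frame(
    from = c("a1", "a1", "a2", "b1", "b1", "b2", "a3"),
    to   = c("a2", "a3", "a3", "b2", "b3", "b3", "b1"))
  tri <- makeNet(c("a1", "a2", "a3", "b1", "b2", "b3"), edges)
  eb <- edgeBetweenness(tri)
  bridge <- eb$score[(eb$from == "a3" & eb$to == "b1") |
                     (eb$from == "b1" & eb$to == "a3")]
  expect_equal(bridge, 9)
})

test_that("degree centrality counts directed edges and satisfies handshake", {
  net <- makeNet(c("u", "v"), data.frame(from = "u", to = "v"))
  d <- degreeCentrality(net)
  rownames(d) <- d$id
  expect_equal(unname(unlist(d["u", c("degree_in", "degree_out")])), c(0, 1))
  expect_equal(unname(unlist(d["v", c("degree_in", "degree_out")])), c(1, 0))

  net2 <- randomFamNet(8, seed = 5)
  d2 <- degreeCentrality(net2)
  m <- igraph::ecount(asGraph(net2))
  expect_equal(sum(d2$degree_in), m)
  expect_equal(sum(d2$degree_out), m)
})

test_that("all measures agree with brute-force oracles on random graphs", {
  # module-level check at moderate scale (the full 200-graph sweep runs in
  # the acceptance suite)
  for (seed in 1:40) {
    net <- randomFamNet(sample(2:8, 1), seed = 1000 + seed)
    expect_true(oracleAgrees(net))
  }
})

test_that("betweenness of degree-1 nodes is zero", {
  for (seed in 1:20) {
    net <- randomFamNet(sample(3:8, 1), seed = 300 + seed)
    pc <- pathCentralities(net)
    deg <- igraph::degree(igraph::as_undirected(asGraph(net)))
    leaves <- names(deg)[deg == 1]
    expect_true(all(pc$betweenness[pc$id %in% leaves] == 0))
  }
})

test_that("harmonic closeness never decreases when an edge is added", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:8, 1)
    net <- randomFamNet(n, seed = 500 + seed)
    ids <- nodeData(net)$id
    edges <- netEdges(net)
    pair <- sample(ids, 2)
    dup <- any(edges$from == pair[1] & edges$to == pair[2]) ||
           any(edges$from == pair[2] & edges$to == pair[1])
    if (dup) next
    g2 <- igraph::add_edges(asGraph(net), pair)
    if (!igraph::is_dag(g2) || any(igraph::degree(g2, mode = "in") > 2)) next
    before <- pathCentralities(net)
    net2 <- methods::new("FamilialNetwork", graph = g2, nodes = nodeData(net))
    after <- pathCentralities(net2)
    rownames(before) <- before$id; rownames(after) <- after$id
    expect_true(all(after[ids, "closeness"] >= before[ids, "closeness"] - 1e-12))
  }
})

test_that("correlation matrix is symmetric, unit-diagonal and affine-exact", {
  set.seed(1)
  tab <- data.frame(id = sprintf("N%d", 1:10),
                    alpha = rnorm(10), betweenness = runif(10),
                    closeness = rnorm(10), degree = rpois(10, 3),
                    eccentricity = sample(1:5, 10, TRUE))
  tab$degree <- tab$degree + runif(10) * 0.01  # avoid accidental zero variance
  cm <- centralityCorrelations(tab)
  expect_equal(diag(cm), stats::setNames(rep(1, 5), colnames(cm)))
  expect_equal(cm, t(cm))
  # affine dependence: correlation exactly 1
  tab2 <- tab
  tab2$closeness <- 2 * tab2$alpha + 3
  cm2 <- centralityCorrelations(tab2)
  expect_equal(unname(cm2["alpha", "closeness"]), 1)
  # 5-node toy vs the direct Pearson formula
  toy <- tab[1:5, ]
  direct <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  cmToy <- centralityCorrelations(toy)
  expect_equal(unname(cmToy["alpha", "betweenness"]),
               direct(toy$alpha, toy$betweenness), tolerance = 1e-12)
})

test_that("zero-variance measures are flagged undefined, not zeroed", {
  tab <- data.frame(id = sprintf("N%d", 1:6), alpha = rnorm(6),
                    betweenness = rnorm(6), closeness = rnorm(6),
                    degree = rep(2, 6), eccentricity = rnorm(6))
  expect_warning(cm <- centralityCorrelations(tab), "degree")
  expect_equal(attr(cm, "undefined"), "degree")
  expect_true(all(is.na(cm["degree", setdiff(colnames(cm), "degree")])))
})

test_that("PCA contributions normalize to 100 with a 20 percent reference", {
  set.seed(2)
  tab <- data.frame(id = sprintf("N%d", 1:30),
                    alpha = rnorm(30), betweenness = runif(30),
                    closeness = rnorm(30), degree = rpois(30, 3) + runif(30),
                    eccentricity = sample(1:6, 30, TRUE) + runif(30))
  pc <- pcaContributions(tab)
  expect_equal(pc$expectedAvg, 20)
  expect_equal(unname(colSums(pc$contributions)),
               rep(100, ncol(pc$contributions)), tolerance = 1e-6)
  expect_true(length(pc$selected) >= 1)
})

test_that("a dominant standardized measure tops the PC1 contributions", {
  set.seed(3)
  latent <- rnorm(40, sd = 3)
  tab <- data.frame(id = sprintf("N%d", 1:40),
                    alpha = latent + rnorm(40, sd = 0.1),
                    betweenness = latent + rnorm(40, sd = 0.1),
                    closeness = latent + rnorm(40, sd = 0.1),
                    degree = rnorm(40),
                    eccentricity = rnorm(40))
  pc <- pcaContributions(tab)
  # the three latent-aligned measures dominate PC1; the independent noise
  # measures contribute less than the reference there
  expect_gt(min(pc$contributions[c("alpha", "betweenness", "closeness"), 1]),
            max(pc$contributions[c("degree", "eccentricity"), 1]))
  # independent eigen-decomposition of the correlation matrix
  ev <- eigen(stats::cor(as.matrix(tab[, -1])))
  contribOracle <- 100 * ev$vectors[, 1]^2 / sum(ev$vectors[, 1]^2)
  expect_equal(unname(pc$contributions[, 1]), contribOracle, tolerance = 1e-8)
})
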