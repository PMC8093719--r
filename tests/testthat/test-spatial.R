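# Local areas: polygon membership, edge-to-node ratios, first-neighbor
# expansion and group comparison.

squareAt <- function(cx, cy, half = 1) {
  cbind(c(cx - half, cx + half, cx + half, cx - half),
        c(cy - half, cy - half, cy + half, cy + half))
}

test_that("point-in-polygon is boundary inclusive and matches mgcv off-boundary", {
  sq <- squareAt(0, 0, 1)
  expect_true(pointInPolygon(0.2, -0.3, sq))
  expect_false(pointInPolygon(2, 0, sq))
  expect_true(pointInPolygon(1, 0, sq))    # edge
  expect_true(pointInPolygon(1, 1, sq))    # vertex
  expect_false(pointInPolygon(NA_real_, 1, sq))

  library(mgcv)
  set.seed(4)
  px <- runif(300, -2, 2); py <- runif(300, -2, 2)
  got <- pointInPolygon(px, py, sq)
  want <- mgcv::in.out(rbind(sq, sq[1, ]), cbind(px, py))
  offBoundary <- abs(abs(px) - 1) > 1e-6 & abs(abs(py) - 1) > 1e-6
  expect_equal(got[offBoundary], want[offBoundary])
})

test_that("area assignment covers polygons, labels, and inferred nodes", {
  ids <- c("A", "B", "C", "INF")
  net <- makeNet(ids, data.frame(from = "INF", to = "A"),
                 sampled = c(TRUE, TRUE, TRUE, FALSE),
                 x = c(0, 5, 99, NA), y = c(0, 5, 99, NA))
  areas <- list(west = squareAt(0, 0, 2), east = squareAt(5, 5, 2))
  memb <- assignLocalAreas(net, areas)
  expect_equal(unname(memb["A"]), "west")
  expect_equal(unname(memb["B"]), "east")
  expect_true(is.na(memb["C"]))   # outside all polygons
  expect_true(is.na(memb["INF"])) # inferred: no coordinates

  # explicit label interface
  memb2 <- assignLocalAreas(net, c(A = "west", C = "east", INF = "north"))
  expect_equal(unname(memb2["A"]), "west")
  expect_true(is.na(memb2["INF"]))  # labels never attach to inferred nodes

  # overlapping polygons claiming one point is an error
  overlap <- list(p1 = squareAt(0, 0, 2), p2 = squareAt(1, 1, 2))
  expect_error(assignLocalAreas(net, overlap), "overlap")
})

test_that("GeoJSON polygons round-trip into membership", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         properties = list(area = "west"),
         geometry = list(type = "Polygon",
                         coordinates = list(list(list(-2, -2), list(2, -2),
                                                 list(2, 2), list(-2, 2),
                                                 list(-2, -2)))))))
  tf <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, tf, auto_unbox = TRUE)
  areas <- readAreasGeoJSON(tf)
  expect_named(areas, "west")
  expect_true(pointInPolygon(0, 0, areas$west))
})

test_that("edge-to-node ratios count internal edges only", {
  ids <- c("A", "B", "C", "D")
  net <- makeNet(ids, data.frame(from = c("A", "A", "A"), to = c("B", "C", "D")),
                 x = c(0, 0, 0, 99), y = c(0, 1, -1, 99))
  memb <- c(A = "in", B = "in", C = "in", D = "out")
  r <- edgeToNodeRatio(net, memb, "in")
  expect_equal(r$n_nodes, 3)
  expect_equal(r$n_edges, 2)     # A->D leaves the area
  expect_equal(r$ratio, 2 / 3)

  # an area with no internal relationships scores zero
  memb0 <- c(B = "solo", C = "solo")
  expect_equal(edgeToNodeRatio(net, memb0, "solo")$ratio, 0)

  expect_warning(e <- edgeToNodeRatio(net, memb, "nowhere"), "no members")
  expect_true(is.na(e$ratio))
})

test_that("edge-to-node ratio equals a brute-force endpoint scan", {
  for (seed in c(5, 35)) {
    cfg <- simulationConfig(nFounders = 14, nGenerations = 3, samplingFraction = 1,
                            dropoutRate = 0, falseAlleleRate = 0,
                            locusFailureRate = 0, replicateFraction = 0,
                            seed = seed)
    out <- simulateConsolidated(cfg)
    ped <- suppressWarnings(assignParentage(out$individuals, out$pop@freqs,
                                            parentageConfig(errorRate = 0)))
    memb <- stats::setNames(sampleInfo(out$individuals)$stratum,
                            sampleInfo(out$individuals)$individual_id)
    net <- buildFamilialNetwork(ped, out$individuals, membership = memb)
    for (a in unique(memb)) {
      got <- edgeToNodeRatio(net, memb, a)
      members <- names(memb)[memb == a]
      el <- netEdges(net)
      brute <- sum(el$from %in% members & el$to %in% members)
      expect_equal(got$n_edges, brute)
      expect_equal(got$ratio, brute / length(members))
      expect_lte(got$ratio, 2)
    }
  }
})

test_that("first-neighbor expansion adds exactly the one-step neighborhood", {
  # one member dam with three offspring outside the area
  ids <- c("DAM", "O1", "O2", "O3")
  net <- makeNet(ids, data.frame(from = "DAM", to = c("O1", "O2", "O3")),
                 x = c(0, 9, 9, 9), y = c(0, 9, 9, 9))
  memb <- c(DAM = "core")
  e <- firstNeighborExpansion(net, memb, "core")
  expect_equal(e$n_nodes, 1)
  expect_equal(e$n_edges, 0)
  expect_equal(e$expanded_nodes, 4)
  expect_equal(e$expanded_edges, 3)
  expect_equal(e$pct_members_in_largest_cluster, 100)

  # members with no incident edges: expansion adds nobody
  net2 <- makeNet(c("A", "B"), x = c(0, 0), y = c(0, 1))
  memb2 <- c(A = "z", B = "z")
  e2 <- firstNeighborExpansion(net2, memb2, "z")
  expect_equal(e2$expanded_nodes, 2)
  expect_equal(e2$pct_members_in_largest_cluster, 50)  # 100 / n
})

test_that("expansion is idempotent on its internal edge set", {
  net <- randomFamNet(8, seed = 44)
  ids <- nodeData(net)$id
  memb <- stats::setNames(rep(NA_character_, 8), ids)
  memb[ids[1:3]] <- "core"
  e1 <- firstNeighborExpansion(net, memb, "core")
  # re-expand using the expanded node set as explicit members of a fake area
  g <- asGraph(net)
  nb <- unique(unlist(lapply(
    igraph::neighborhood(g, 1, nodes = ids[1:3], mode = "all"),
    function(v) igraph::V(g)$name[v])))
  expanded <- union(ids[1:3], nb)
  sub <- igraph::induced_subgraph(g, expanded)
  expect_equal(e1$expanded_edges, igraph::ecount(sub))
})

test_that("area reports are independent of node ordering", {
  cfg <- simulationConfig(nFounders = 14, nGenerations = 3, samplingFraction = 1,
                          dropoutRate = 0, falseAlleleRate = 0,
                          locusFailureRate = 0, replicateFraction = 0, seed = 55)
  out <- simulateConsolidated(cfg)
  ped <- suppressWarnings(assignParentage(out$individuals, out$pop@freqs,
                                          parentageConfig(errorRate = 0)))
  memb <- stats::setNames(sampleInfo(out$individuals)$stratum,
                          sampleInfo(out$individuals)$individual_id)
  net <- buildFamilialNetwork(ped, out$individuals, membership = memb)
  r1 <- areaReports(net, memb, k = 2)
  r2 <- areaReports(net, rev(memb), k = 2)
  expect_equal(r1, r2)
})

test_that("group comparison flags degenerate inputs and zero differences", {
  tab <- data.frame(id = sprintf("N%d", 1:8),
                    alpha = rep(1, 8), betweenness = seq(0, 7),
                    closeness = rnorm(8), degree = rnorm(8),
                    eccentricity = rnorm(8))
  memb <- stats::setNames(rep(c("a1", "a2", "a3", "a4"), each = 2), tab$id)
  reports <- data.frame(area = c("a1", "a2", "a3", "a4"),
                        ratio = c(0.1, 0.4, 0.9, 1.4))
  expect_warning(cmp <- compareAreaGroups(tab, memb, reports, k = 2), "alpha")
  expect_true("alpha" %in% cmp$undefined)
  expect_true(is.na(cmp$correlations$r[cmp$correlations$measure == "alpha"]))
  # a well-defined measure gets a finite correlation
  expect_true(is.finite(cmp$correlations$r[cmp$correlations$measure == "betweenness"]))
  # identical distributions in both groups: mean difference zero
  s <- cmp$summaries
  am <- s$mean[s$group == "high" & s$measure == "alpha"]
  al <- s$mean[s$group == "low" & s$measure == "alpha"]
  expect_equal(am, al)
  expect_error(compareAreaGroups(tab, memb, reports, k = 3), "2k")
})
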