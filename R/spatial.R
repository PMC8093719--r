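# Local-area analysis: polygon/label membership, edge-to-node cohesion
# ratios, first-neighbor expansion (bringing inferred parents into the
# spatial frame) and high/low-ratio group comparison.

#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd ray casting on planar coordinates; points lying exactly on a
#' polygon edge or vertex count as inside.
#'
#' @param x,y Point coordinate vectors.
#' @param poly Two-column matrix of polygon vertices (closed or open ring).
#' @return Logical vector.
#' @export
pointInPolygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) stop("degenerate polygon: fewer than 3 vertices")
  # drop duplicated closing vertex if present
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  if (nrow(poly) < 3L) stop("degenerate polygon: fewer than 3 distinct vertices")
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  vapply(seq_along(x), function(i) {
    xi <- x[i]; yi <- y[i]
    if (is.na(xi) || is.na(yi)) return(FALSE)
    inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      x1 <- px[j]; y1 <- py[j]; x2 <- px[k]; y2 <- py[k]
      # boundary: point on segment [v_j, v_k]
      cross <- (x2 - x1) * (yi - y1) - (y2 - y1) * (xi - x1)
      if (abs(cross) < 1e-12 &&
          xi >= min(x1, x2) - 1e-12 && xi <= max(x1, x2) + 1e-12 &&
          yi >= min(y1, y2) - 1e-12 && yi <= max(y1, y2) + 1e-12)
        return(TRUE)
      if ((y1 > yi) != (y2 > yi)) {
        xint <- x1 + (yi - y1) * (x2 - x1) / (y2 - y1)
        if (xi < xint) inside <- !inside
      }
      j <- k
    }
    inside
  }, logical(1))
}

#' Read local-area polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features on planar (projected)
#' coordinates; each feature's \code{area}, \code{name} or \code{id}
#' property labels the area. Only the outer ring is used.
#'
#' @param path Path to a GeoJSON file.
#' @return Named list of two-column vertex matrices.
#' @export
readAreasGeoJSON <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(js$type, "FeatureCollection")) js$features else list(js)
  out <- list()
  for (i in seq_along(feats)) {
    ft <- feats[[i]]
    geom <- ft$geometry %||% ft
    if (!identical(geom$type, "Polygon"))
      stop("feature ", i, ": only Polygon geometries are supported")
    ring <- geom$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    label <- ft$properties$area %||% ft$properties$name %||% ft$properties$id %||%
      paste0("area", i)
    out[[as.character(label)]] <- m
  }
  out
}

#' Assign sampled individuals to local areas
#'
#' Point-in-polygon assignment (boundary inclusive). Individuals outside
#' every polygon -- and all inferred individuals, which carry no spatial
#' location -- remain unassigned (NA). A point claimed by two overlapping
#' polygons is an error listing the conflicts.
#'
#' @param net A \code{\link{FamilialNetwork}} (or an
#'   \code{\link{IndividualSet}}).
#' @param areas Named list of polygon matrices (see
#'   \code{\link{readAreasGeoJSON}}), or a named character vector of
#'   explicit area labels (id -> area) used as-is for sampled nodes.
#' @return Named character vector: node id -> area label (NA when
#'   unassigned).
#' @export
assignLocalAreas <- function(net, areas) {
  if (is(net, "FamilialNetwork")) {
    nd <- net@nodes
    ids <- nd$id; xs <- nd$x; ys <- nd$y; sampled <- nd$sampled
  } else if (is(net, "IndividualSet")) {
    ids <- net@info$individual_id; xs <- net@info$x; ys <- net@info$y
    sampled <- net@info$sampled
  } else stop("net must be a FamilialNetwork or IndividualSet")

  memb <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (is.character(areas) && !is.list(areas)) {
    hit <- intersect(names(areas), ids[sampled])
    memb[hit] <- unname(areas[hit])
    return(memb)
  }
  stopifnot(is.list(areas), !is.null(names(areas)))
  conflicts <- character(0)
  hits <- matrix(FALSE, length(ids), length(areas))
  for (a in seq_along(areas))
    hits[, a] <- sampled & pointInPolygon(xs, ys, areas[[a]])
  multi <- rowSums(hits) > 1L
  if (any(multi)) {
    for (i in which(multi))
      conflicts <- c(conflicts, paste0(ids[i], " in {",
                                       paste(names(areas)[hits[i, ]], collapse = ", "), "}"))
    stop("overlapping polygons claim the same point(s): ",
         paste(conflicts, collapse = "; "))
  }
  one <- rowSums(hits) == 1L
  memb[one] <- names(areas)[apply(hits[one, , drop = FALSE], 1, which)]
  memb
}

areaMemberIds <- function(net, membership, areaId) {
  nd <- net@nodes
  ids <- names(membership)[!is.na(membership) & membership == areaId]
  intersect(ids, nd$id[nd$sampled])
}

#' Edge-to-node ratio of a local area
#'
#' Internal cohesion index: the number of parent-offspring edges with both
#' endpoints inside the area, divided by the number of sampled individuals
#' in the area. Because every internal edge is an in-edge of some member
#' and in-degree is capped at 2, the ratio never exceeds 2.
#'
#' @param net A \code{\link{FamilialNetwork}}.
#' @param membership Node id -> area label (see
#'   \code{\link{assignLocalAreas}}).
#' @param areaId Area label.
#' @return List with \code{n_nodes}, \code{n_edges}, \code{ratio}
#'   (2-decimal reporting is applied by \code{\link{areaReports}}).
#' @export
edgeToNodeRatio <- function(net, membership, areaId) {
  stopifnot(is(net, "FamilialNetwork"))
  members <- areaMemberIds(net, membership, areaId)
  if (!length(members)) {
    warning("area ", areaId, " has no members; ratio undefined")
    return(list(n_nodes = 0L, n_edges = 0L, ratio = NA_real_))
  }
  el <- igraph::as_edgelist(net@graph)
  E <- sum(el[, 1] %in% members & el[, 2] %in% members)
  r <- E / length(members)
  stopifnot(r <= 2)
  list(n_nodes = length(members), n_edges = as.integer(E), ratio = r)
}

#' First-neighbor expansion of a local area
#'
#' Expands the area's member set by every in- and out-neighbor (one edge
#' away in either direction) -- since inferred parents have no spatial
#' location, this is how they enter the spatial analysis -- then reports
#' the expanded subnetwork's edge-to-node ratio and the share of the
#' area's own members lying in its largest weak component.
#'
#' @inheritParams edgeToNodeRatio
#' @return List with \code{n_nodes}, \code{n_edges}, \code{ratio} (area
#'   internal), \code{expanded_nodes}, \code{expanded_edges},
#'   \code{expanded_ratio}, \code{pct_members_in_largest_cluster}.
#' @export
firstNeighborExpansion <- function(net, membership, areaId) {
  stopifnot(is(net, "FamilialNetwork"))
  base <- edgeToNodeRatio(net, membership, areaId)
  members <- areaMemberIds(net, membership, areaId)
  if (!length(members))
    return(c(base, list(expanded_nodes = 0L, expanded_edges = 0L,
                        expanded_ratio = NA_real_,
                        pct_members_in_largest_cluster = NA_real_)))
  g <- net@graph
  nb <- unique(unlist(lapply(
    igraph::neighborhood(g, order = 1, nodes = members, mode = "all"),
    function(v) igraph::V(g)$name[v])))
  expanded <- union(members, nb)
  sub <- igraph::induced_subgraph(g, vids = expanded)
  cl <- igraph::components(sub, mode = "weak")
  big <- which.max(cl$csize)
  inBig <- igraph::V(sub)$name[cl$membership == big]
  pct <- roundHalfUp(100 * length(intersect(members, inBig)) / length(members), 1)
  c(base, list(expanded_nodes = igraph::vcount(sub),
               expanded_edges = igraph::ecount(sub),
               expanded_ratio = igraph::ecount(sub) / igraph::vcount(sub),
               pct_members_in_largest_cluster = pct))
}

#' Per-area cohesion report
#'
#' One row per local area: member count, internal edges, edge-to-node ratio
#' (2 decimals), first-neighbor expansion summary, and a high/low/none
#' group label for the \code{k} highest- and lowest-ratio areas.
#'
#' @param net A \code{\link{FamilialNetwork}}.
#' @param membership Node id -> area label.
#' @param k Number of areas labelled per extreme group (default 4).
#' @return An \code{AreaReport} data.frame.
#' @export
areaReports <- function(net, membership, k = 4L) {
  areas <- sort(unique(stats::na.omit(membership)))
  rows <- lapply(areas, function(a) {
    e <- firstNeighborExpansion(net, membership, a)
    data.frame(area = a, n_nodes = e$n_nodes, n_edges = e$n_edges,
               ratio = roundHalfUp(e$ratio, 2),
               expanded_nodes = e$expanded_nodes,
               expanded_edges = e$expanded_edges,
               expanded_ratio = roundHalfUp(e$expanded_ratio, 2),
               pct_members_in_largest_cluster = e$pct_members_in_largest_cluster,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$group <- "none"
  defined <- which(!is.na(out$ratio))
  k <- min(k, floor(length(defined) / 2))
  if (k >= 1L) {
    ord <- defined[order(out$ratio[defined], out$area[defined])]
    out$group[utils::tail(ord, k)] <- "high"
    out$group[utils::head(ord, k)] <- "low"
  }
  out
}

#' Compare centrality profiles of high- and low-ratio area groups
#'
#' Labels the \code{k} highest- and lowest-ratio areas, summarizes each
#' centrality measure's distribution (mean, median, quartiles) over member
#' nodes per group, and reports the Pearson correlation between area ratio
#' and the area mean of each measure across all areas. No hypothesis tests
#' are performed. A measure constant across areas (or constant ratios)
#' yields an NA correlation, flagged rather than silently zero.
#'
#' @param centralities A \code{CentralityTable}.
#' @param membership Node id -> area label.
#' @param reports An \code{AreaReport} from \code{\link{areaReports}}.
#' @param k Areas per extreme group (default 4).
#' @param measures Measures to compare.
#' @return List with \code{groups} (area -> high/low), \code{summaries}
#'   (long data.frame: group x measure stats), \code{correlations}
#'   (data.frame measure / r), \code{undefined} (measures with undefined
#'   correlation).
#' @export
compareAreaGroups <- function(centralities, membership, reports, k = 4L,
                              measures = centralityMeasures) {
  stopifnot(all(measures %in% colnames(centralities)))
  defined <- reports[!is.na(reports$ratio), , drop = FALSE]
  if (nrow(defined) < 2L * k)
    stop("need at least 2k areas with defined ratios (got ",
         nrow(defined), ", k = ", k, ")")
  ord <- order(defined$ratio, defined$area)
  lowAreas <- defined$area[utils::head(ord, k)]
  highAreas <- defined$area[utils::tail(ord, k)]
  groups <- c(stats::setNames(rep("high", k), highAreas),
              stats::setNames(rep("low", k), lowAreas))

  nodeGroup <- stats::setNames(rep(NA_character_, nrow(centralities)),
                               centralities$id)
  memb <- membership[centralities$id]
  nodeGroup[!is.na(memb) & memb %in% highAreas] <- "high"
  nodeGroup[!is.na(memb) & memb %in% lowAreas] <- "low"

  summaries <- do.call(rbind, lapply(c("high", "low"), function(gr) {
    rows <- which(nodeGroup == gr)
    do.call(rbind, lapply(measures, function(m) {
      v <- centralities[[m]][rows]
      data.frame(group = gr, measure = m, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 q25 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
                 median = if (length(v)) stats::median(v) else NA_real_,
                 q75 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))

  # area-level ratio vs area-mean centrality, across all defined areas
  areaMeans <- sapply(measures, function(m) {
    vapply(defined$area, function(a) {
      ids <- names(membership)[!is.na(membership) & membership == a]
      v <- centralities[[m]][centralities$id %in% ids]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  })
  undefined <- character(0)
  rvals <- vapply(measures, function(m) {
    x <- defined$ratio; y <- areaMeans[, m]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      undefined <<- c(undefined, m)
      return(NA_real_)
    }
    stats::cor(x[ok], y[ok])
  }, numeric(1))
  if (length(undefined))
    warning("ratio-centrality correlation undefined for: ",
            paste(undefined, collapse = ", "))

  list(groups = groups,
       summaries = summaries,
       correlations = data.frame(measure = measures, r = unname(rvals),
                                 stringsAsFactors = FALSE),
       undefined = undefined)
}
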