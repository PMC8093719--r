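# Directed familial network: nodes are individuals, edges run parent ->
# offspring; component structure reporting.

#' Build the directed familial network from a pedigree
#'
#' Node set = all sampled individuals plus all inferred parents appearing in
#' the pedigree; every pedigree row contributes two directed edges (dam ->
#' offspring, sire -> offspring). Inferred parents are full nodes without
#' coordinates: they take part in the topology but have no spatial
#' location. A cycle in the pedigree is an error naming the cycle.
#'
#' @param ped A \code{PedigreeTable} (offspring_id, dam_id, sire_id,
#'   dam_sampled, sire_sampled).
#' @param individuals An \code{\link{IndividualSet}} supplying node
#'   attributes for sampled individuals; inferred sexes are taken from the
#'   pedigree slots.
#' @param membership Optional named vector (individual id -> local-area
#'   label) stored as the node \code{area} attribute.
#' @return A \code{\link{FamilialNetwork}}.
#' @export
buildFamilialNetwork <- function(ped, individuals, membership = NULL) {
  stopifnot(is(individuals, "IndividualSet"))
  info <- individuals@info
  sampledIds <- info$individual_id
  parentIds <- unique(c(ped$dam_id, ped$sire_id))
  inferredIds <- setdiff(parentIds, sampledIds)
  allIds <- c(sampledIds, inferredIds)

  inferredSex <- stats::setNames(rep("unknown", length(inferredIds)), inferredIds)
  if (nrow(ped)) {
    inferredSex[intersect(inferredIds, ped$dam_id)] <- "F"
    inferredSex[intersect(inferredIds, ped$sire_id)] <- "M"
  }
  nodes <- data.frame(
    id = allIds,
    sampled = allIds %in% sampledIds,
    sex = c(info$sex, unname(inferredSex)),
    x = c(info$x, rep(NA_real_, length(inferredIds))),
    y = c(info$y, rep(NA_real_, length(inferredIds))),
    area = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(membership)) {
    hit <- intersect(names(membership), nodes$id)
    nodes$area[match(hit, nodes$id)] <- unname(membership[hit])
  }

  edges <- if (nrow(ped)) {
    data.frame(from = c(ped$dam_id, ped$sire_id),
               to = c(ped$offspring_id, ped$offspring_id),
               stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0))

  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes["id"])
  if (igraph::ecount(g) && !igraph::is_dag(g)) {
    sc <- igraph::components(g, mode = "strong")
    cyc <- names(sc$membership)[sc$membership %in% which(sc$csize > 1L)]
    stop("pedigree contains a cycle involving: ", paste(cyc, collapse = ", "))
  }
  for (col in c("sampled", "sex", "x", "y", "area"))
    g <- igraph::set_vertex_attr(g, col, value = nodes[[col]])
  new("FamilialNetwork", graph = g, nodes = nodes)
}

#' Component structure report from component sizes
#'
#' @param sizes Integer vector of weak-component sizes.
#' @return Object of class \code{ComponentReport}: list with \code{count},
#'   \code{sizes} (descending), \code{total} and \code{largest_share_pct}
#'   (largest / total x 100, 1 decimal).
#' @export
componentReport <- function(sizes) {
  sizes <- sort(as.integer(sizes), decreasing = TRUE)
  total <- sum(sizes)
  structure(list(count = length(sizes), sizes = sizes, total = total,
                 largest_share_pct = if (total > 0)
                   roundHalfUp(100 * sizes[1] / total, 1) else NA_real_),
            class = "ComponentReport")
}

#' @export
print.ComponentReport <- function(x, ...) {
  cat(sprintf("ComponentReport: %d component(s), %d nodes total\n",
              x$count, x$total))
  if (x$count)
    cat(sprintf("  sizes: %s; largest holds %.1f%% of nodes\n",
                paste(utils::head(x$sizes, 10), collapse = ", "),
                x$largest_share_pct))
  invisible(x)
}

#' Weakly connected components of a familial network
#'
#' Connectivity ignores edge direction. Returns sizes in descending order
#' and the share of all nodes held by the largest component.
#'
#' @param net A \code{\link{FamilialNetwork}}.
#' @return A \code{ComponentReport} (see \code{\link{componentReport}});
#'   attribute \code{membership} maps node id -> component rank (1 =
#'   largest).
#' @export
connectedComponents <- function(net) {
  stopifnot(is(net, "FamilialNetwork"))
  g <- net@graph
  if (igraph::vcount(g) == 0L) return(componentReport(integer(0)))
  cl <- igraph::components(g, mode = "weak")
  rep <- componentReport(cl$csize)
  rank <- rank(-cl$csize, ties.method = "first")
  attr(rep, "membership") <- stats::setNames(rank[cl$membership],
                                             igraph::V(g)$name)
  rep
}

#' Largest-component subnetwork
#'
#' The primary network used for centrality profiling: nodes outside the
#' largest weak component are dropped.
#'
#' @param net A \code{\link{FamilialNetwork}}.
#' @return A \code{\link{FamilialNetwork}} restricted to the largest weak
#'   component.
#' @export
primaryNetwork <- function(net) {
  stopifnot(is(net, "FamilialNetwork"))
  comp <- connectedComponents(net)
  memb <- attr(comp, "membership")
  keep <- names(memb)[memb == 1L]
  subNetwork(net, keep)
}

# Induced subnetwork on a set of node ids (internal; also used by spatial).
subNetwork <- function(net, ids) {
  g <- igraph::induced_subgraph(net@graph, vids = ids)
  nodes <- net@nodes[match(igraph::V(g)$name, net@nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  new("FamilialNetwork", graph = g, nodes = nodes)
}
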