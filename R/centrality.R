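# Node centrality profiles: alpha centrality and degree respect edge
# direction; betweenness, harmonic (Latora) closeness and eccentricity are
# computed on the undirected view, where a pedigree's shortest-path
# structure is meaningful for disconnected, mostly mutually unreachable
# directed pairs.

#' Alpha centrality
#'
#' Solves \code{x = alpha * t(A) x + e}, i.e. each node's score is its
#' exogenous input plus \code{alpha} times the summed scores of its
#' parents. On an acyclic pedigree the adjacency matrix is nilpotent, so
#' the system is solvable for every \code{alpha} (the default 1).
#'
#' @param net A \code{\link{FamilialNetwork}}.
#' @param alpha Attenuation parameter (default 1).
#' @param exo Exogenous input: scalar or per-node vector (default 1).
#' @return Named numeric vector of alpha centralities.
#' @export
alphaCentrality <- function(net, alpha = 1, exo = 1) {
  stopifnot(is(net, "FamilialNetwork"))
  g <- net@graph
  n <- igraph::vcount(g)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  if (length(exo) == 1L) exo <- rep(exo, n)
  stopifnot(length(exo) == n, all(is.finite(exo)), is.finite(alpha))
  x <- tryCatch(
    igraph::alpha_centrality(g, alpha = alpha, exo = exo, sparse = FALSE,
                             tol = 1e-10),
    error = function(e) stop("alpha-centrality system is singular ",
                             "(cyclic input with alpha at/above the spectral bound): ",
                             conditionMessage(e)))
  stats::setNames(x, igraph::V(g)$name)
}

#' Shortest-path centralities: betweenness, harmonic closeness, eccentricity
#'
#' All three are computed on the undirected view of the network.
#' Betweenness counts unordered node pairs (endpoints excluded), splitting
#' fractionally across tied shortest paths. Harmonic (Latora) closeness is
#' the raw sum of reciprocal distances to reachable nodes -- well defined in
#' disconnected networks (pass \code{normalized = TRUE} to divide by n-1).
#' Eccentricity is the maximum finite shortest-path distance (0 for an
#' isolated node); larger values mark peripheral individuals.
#'
#' @param net A \code{\link{FamilialNetwork}}.
#' @param normalized Normalize harmonic closeness by n-1 (default FALSE).
#' @return data.frame with columns \code{id}, \code{betweenness},
#'   \code{closeness}, \code{eccentricity}.
#' @export
pathCentralities <- function(net, normalized = FALSE) {
  stopifnot(is(net, "FamilialNetwork"))
  g <- igraph::as_undirected(net@graph, mode = "collapse")
  n <- igraph::vcount(g)
  if (n == 0L)
    return(data.frame(id = character(0), betweenness = numeric(0),
                      closeness = numeric(0), eccentricity = numeric(0)))
  btw <- igraph::betweenness(g, directed = FALSE)
  clo <- igraph::harmonic_centrality(g, mode = "all", normalized = FALSE)
  if (normalized && n > 1L) clo <- clo / (n - 1)
  ecc <- igraph::eccentricity(g, mode = "all")
  data.frame(id = igraph::V(g)$name, betweenness = unname(btw),
             closeness = unname(clo), eccentricity = unname(ecc),
             stringsAsFactors = FALSE)
}

#' Edge betweenness on the undirected view
#'
#' Each unordered node pair contributes 1/sigma_st to every edge crossed by
#' each of its sigma_st shortest paths.
#'
#' @param net A \code{\link{FamilialNetwork}}.
#' @return data.frame with columns \code{from}, \code{to}, \code{score}.
#' @export
edgeBetweenness <- function(net) {
  stopifnot(is(net, "FamilialNetwork"))
  g <- igraph::as_undirected(net@graph, mode = "collapse")
  if (igraph::ecount(g) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      score = numeric(0)))
  eb <- igraph::edge_betweenness(g, directed = FALSE)
  ends <- igraph::as_edgelist(g)
  data.frame(from = ends[, 1], to = ends[, 2], score = eb,
             stringsAsFactors = FALSE)
}

#' Degree centrality (in, out, total)
#'
#' In-degree counts edges directed toward the node (its assigned parents:
#' always 2 for sampled individuals in a full assignment, 0 for inferred
#' ones); out-degree counts edges leaving it (its offspring, i.e. fitness).
#'
#' @param net A \code{\link{FamilialNetwork}}.
#' @return data.frame with columns \code{id}, \code{degree_in},
#'   \code{degree_out}, \code{degree}.
#' @export
degreeCentrality <- function(net) {
  stopifnot(is(net, "FamilialNetwork"))
  g <- net@graph
  data.frame(id = igraph::V(g)$name,
             degree_in = unname(igraph::degree(g, mode = "in")),
             degree_out = unname(igraph::degree(g, mode = "out")),
             degree = unname(igraph::degree(g, mode = "all")),
             stringsAsFactors = FALSE)
}

#' Full per-node centrality table
#'
#' Assembles the five study measures (alpha, betweenness, harmonic
#' closeness, degree, eccentricity) plus in-/out-degree.
#'
#' @param net A \code{\link{FamilialNetwork}}.
#' @param alpha,exo Passed to \code{\link{alphaCentrality}}.
#' @return A \code{CentralityTable} data.frame: \code{id}, \code{alpha},
#'   \code{betweenness}, \code{closeness}, \code{eccentricity},
#'   \code{degree_in}, \code{degree_out}, \code{degree}.
#' @export
centralityTable <- function(net, alpha = 1, exo = 1) {
  a <- alphaCentrality(net, alpha = alpha, exo = exo)
  p <- pathCentralities(net)
  d <- degreeCentrality(net)
  out <- data.frame(id = p$id, alpha = unname(a[p$id]),
                    betweenness = p$betweenness, closeness = p$closeness,
                    eccentricity = p$eccentricity,
                    stringsAsFactors = FALSE)
  out <- merge(out, d, by = "id", sort = TRUE)
  stopifnot(out$degree == out$degree_in + out$degree_out)
  out
}

centralityMeasures <- c("alpha", "betweenness", "closeness", "degree",
                        "eccentricity")

#' Pearson correlation matrix between centrality measures
#'
#' Symmetric with unit diagonal. A measure with zero variance yields NA
#' entries, flagged via the \code{undefined} attribute (never silently 0).
#'
#' @param tab A \code{CentralityTable}.
#' @param measures Columns to correlate (default the five study measures).
#' @return Correlation matrix with attribute \code{undefined} (character
#'   vector of zero-variance measures).
#' @export
centralityCorrelations <- function(tab, measures = centralityMeasures) {
  stopifnot(all(measures %in% colnames(tab)), nrow(tab) >= 3L)
  X <- as.matrix(tab[, measures, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  flat <- measures[sds == 0]
  if (length(flat))
    warning("zero-variance measure(s), correlations undefined: ",
            paste(flat, collapse = ", "))
  cm <- suppressWarnings(stats::cor(X))
  diag(cm) <- 1
  attr(cm, "undefined") <- flat
  cm
}

#' PCA contributions of centrality measures
#'
#' Measures are standardized (zero mean, unit variance) and decomposed by
#' PCA. The contribution of measure j to component k is its squared loading
#' as a share of that component's loading norm, x 100 (so each component's
#' contributions sum to 100). The reference line is the expected average
#' contribution 100/p for p measures; a measure is "selected" when it
#' exceeds the reference on any of the first \code{nComponents} components.
#'
#' @param tab A \code{CentralityTable}.
#' @param measures Columns to decompose (default the five study measures).
#' @param nComponents Number of leading components to report (default 3).
#' @return List with \code{contributions} (measures x components, percent),
#'   \code{varianceExplained} (percent per component), \code{expectedAvg}
#'   (100/p) and \code{selected} (character vector of measures).
#' @export
pcaContributions <- function(tab, measures = centralityMeasures,
                             nComponents = 3L) {
  stopifnot(all(measures %in% colnames(tab)))
  X <- as.matrix(tab[, measures, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  if (sum(sds > 0) < 2L)
    stop("need at least two measures with positive variance")
  if (any(sds == 0)) {
    warning("dropping zero-variance measure(s): ",
            paste(measures[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    measures <- measures[sds > 0]
  }
  if (nrow(X) < ncol(X))
    warning("fewer nodes than measures; components truncated")
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  k <- min(nComponents, ncol(pr$rotation))
  contrib <- 100 * sweep(pr$rotation[, seq_len(k), drop = FALSE]^2, 2,
                         colSums(pr$rotation[, seq_len(k), drop = FALSE]^2),
                         "/")
  varExp <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  expected <- 100 / length(measures)
  selected <- rownames(contrib)[apply(contrib > expected, 1, any)]
  list(contributions = contrib, varianceExplained = varExp[seq_len(k)],
       expectedAvg = expected, selected = selected)
}
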