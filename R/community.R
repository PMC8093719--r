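# Edge-betweenness distribution reporting and Girvan-Newman style edge
# removal to probe the cohesion of the familial network.

#' Tabulate the edge-betweenness score distribution
#'
#' Scores are binned at \code{binPrecision} (fractional scores arise from
#' tied shortest paths) and tabulated as score -> edge count.
#'
#' @param net A \code{\link{FamilialNetwork}}.
#' @param binPrecision Rounding unit for non-integer scores (default 1e-6).
#' @return A \code{BetweennessDistribution} data.frame with columns
#'   \code{score} (ascending) and \code{count}.
#' @export
betweennessDistribution <- function(net, binPrecision = 1e-6) {
  eb <- edgeBetweenness(net)
  if (nrow(eb) == 0L)
    return(data.frame(score = numeric(0), count = integer(0)))
  s <- round(eb$score / binPrecision) * binPrecision
  tb <- table(s)
  data.frame(score = as.numeric(names(tb)), count = as.integer(tb))
}

#' Summarize a betweenness distribution
#'
#' Reports (to 2 decimals) the percentage of edges sitting at the minimum
#' score and the percentage scoring strictly above \code{threshold} -- the
#' fraction that a static high-betweenness removal would delete.
#'
#' @param dist A \code{BetweennessDistribution} (data.frame score/count).
#' @param threshold Removal threshold.
#' @return List with \code{fraction_at_min_pct},
#'   \code{fraction_above_pct}, \code{min_score}, \code{total_edges}.
#' @export
distributionSummary <- function(dist, threshold) {
  stopifnot(nrow(dist) > 0L, all(dist$count >= 0))
  total <- sum(dist$count)
  minScore <- min(dist$score)
  atMin <- sum(dist$count[dist$score == minScore])
  above <- sum(dist$count[dist$score > threshold])
  list(fraction_at_min_pct = roundHalfUp(100 * atMin / total, 2),
       fraction_above_pct = roundHalfUp(100 * above / total, 2),
       min_score = minScore, total_edges = total)
}

#' Remove high-betweenness edges (Girvan-Newman style)
#'
#' Static mode computes edge betweenness once and removes every edge
#' scoring strictly above \code{threshold}. Recompute mode repeatedly
#' removes all edges tied at the current maximum and recomputes scores,
#' stopping once the maximum remaining score is at or below
#' \code{threshold} (the classic sequential algorithm). Removed edges are
#' ordered by endpoint ids within a step for reproducibility.
#'
#' @param net A \code{\link{FamilialNetwork}}.
#' @param threshold Stopping threshold (>= 0).
#' @param mode "static" or "recompute".
#' @return A \code{RemovalTrace} list: \code{removed} (data.frame with
#'   \code{step}, \code{from}, \code{to}, \code{score_at_removal}),
#'   \code{components_after} (list of \code{ComponentReport}s per step),
#'   \code{final} (final \code{ComponentReport}), \code{mode},
#'   \code{threshold}, \code{removed_fraction_pct} (2 decimals),
#'   \code{graph} (the final undirected igraph).
#' @export
removeHighBetweennessEdges <- function(net, threshold,
                                       mode = c("static", "recompute")) {
  stopifnot(is(net, "FamilialNetwork"), threshold >= 0)
  mode <- match.arg(mode)
  g <- igraph::as_undirected(net@graph, mode = "collapse")
  nEdges0 <- igraph::ecount(g)
  removed <- data.frame(step = integer(0), from = character(0),
                        to = character(0), score_at_removal = numeric(0),
                        stringsAsFactors = FALSE)
  compReports <- list()
  compOf <- function(gr) componentReport(igraph::components(gr, mode = "weak")$csize)

  step <- 0L
  repeat {
    if (igraph::ecount(g) == 0L) break
    eb <- igraph::edge_betweenness(g, directed = FALSE)
    ends <- igraph::as_edgelist(g)
    if (mode == "static") {
      hit <- which(eb > threshold)
      if (length(hit)) {
        step <- step + 1L
        ord <- hit[order(ends[hit, 1], ends[hit, 2])]
        removed <- rbind(removed, data.frame(
          step = step, from = ends[ord, 1], to = ends[ord, 2],
          score_at_removal = eb[ord], stringsAsFactors = FALSE))
        g <- igraph::delete_edges(g, ord)
        compReports[[step]] <- compOf(g)
      }
      break
    }
    mx <- max(eb)
    if (mx <= threshold) break
    hit <- which(eb == mx)
    step <- step + 1L
    ord <- hit[order(ends[hit, 1], ends[hit, 2])]
    removed <- rbind(removed, data.frame(
      step = step, from = ends[ord, 1], to = ends[ord, 2],
      score_at_removal = eb[ord], stringsAsFactors = FALSE))
    g <- igraph::delete_edges(g, ord)
    compReports[[step]] <- compOf(g)
  }

  structure(list(removed = removed, components_after = compReports,
                 final = compOf(g), mode = mode, threshold = threshold,
                 removed_fraction_pct = if (nEdges0 > 0)
                   roundHalfUp(100 * nrow(removed) / nEdges0, 2) else 0,
                 graph = g),
            class = "RemovalTrace")
}

#' @export
print.RemovalTrace <- function(x, ...) {
  cat(sprintf("RemovalTrace (%s, threshold %g): %d edge(s) removed (%.2f%%) in %d step(s)\n",
              x$mode, x$threshold, nrow(x$removed), x$removed_fraction_pct,
              length(x$components_after)))
  print(x$final)
  invisible(x)
}
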