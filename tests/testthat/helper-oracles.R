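# Independent brute-force oracles. These deliberately avoid igraph and the
# package's own code paths: distances and shortest-path counts come from
# exhaustive simple-path enumeration, alpha centrality from an explicit
# nilpotent power series.

edgeKey <- function(u, v) paste(sort(c(u, v)), collapse = "|")

# Exhaustive shortest-path statistics on the undirected view.
bruteGraphStats <- function(ids, edges) {
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (r in seq_len(nrow(edges))) {
    u <- edges$from[r]; v <- edges$to[r]
    adj[[u]] <- union(adj[[u]], v)
    adj[[v]] <- union(adj[[v]], u)
  }
  btw <- stats::setNames(numeric(length(ids)), ids)
  harm <- btw; ecc <- btw
  eb <- if (nrow(edges)) stats::setNames(numeric(nrow(edges)),
                                         mapply(edgeKey, edges$from, edges$to))
        else stats::setNames(numeric(0), character(0))
  allPaths <- function(s, t) {
    out <- list()
    rec <- function(path) {
      last <- path[length(path)]
      if (last == t) { out[[length(out) + 1L]] <<- path; return(invisible()) }
      for (nb in adj[[last]]) if (!(nb %in% path)) rec(c(path, nb))
    }
    rec(s)
    out
  }
  n <- length(ids)
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    s <- ids[i]; t <- ids[j]
    paths <- allPaths(s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1)) - 1L
    d <- min(lens)
    sp <- paths[lens == d]
    sig <- length(sp)
    harm[s] <- harm[s] + 1 / d
    harm[t] <- harm[t] + 1 / d
    ecc[s] <- max(ecc[s], d)
    ecc[t] <- max(ecc[t], d)
    for (p in sp) {
      if (length(p) > 2L)
        for (v in p[2:(length(p) - 1L)]) btw[v] <- btw[v] + 1 / sig
      for (q in seq_len(length(p) - 1L))
        eb[edgeKey(p[q], p[q + 1L])] <- eb[edgeKey(p[q], p[q + 1L])] + 1 / sig
    }
  }
  list(betweenness = btw, harmonic = harm, eccentricity = ecc, edge = eb)
}

# Alpha centrality by truncated power series: x = sum_k alpha^k (A^T)^k e,
# exact once k exceeds the DAG's longest path (nilpotency).
alphaSeriesOracle <- function(ids, edges, alpha = 1, e = 1) {
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) A[edges$from[r], edges$to[r]] <- 1
  if (length(e) == 1L) e <- rep(e, n)
  x <- e
  term <- e
  At <- t(A)
  for (k in seq_len(n + 1L)) {
    term <- alpha * (At %*% term)
    x <- x + term
    if (all(term == 0)) break
  }
  stats::setNames(as.numeric(x), ids)
}

netEdges <- function(net) {
  el <- igraph::as_edgelist(famnet::asGraph(net))
  data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
}

# Check one network's centralities + edge betweenness against the oracles;
# returns TRUE when everything agrees within tol.
oracleAgrees <- function(net, tol = 1e-9) {
  ids <- nodeData(net)$id
  edges <- netEdges(net)
  or <- bruteGraphStats(ids, edges)
  pc <- pathCentralities(net)
  rownames(pc) <- pc$id
  dg <- degreeCentrality(net)
  al <- alphaCentrality(net)
  alOr <- alphaSeriesOracle(ids, edges)
  ebTab <- edgeBetweenness(net)
  ok <- TRUE
  ok <- ok && all(abs(pc[ids, "betweenness"] - or$betweenness[ids]) < tol)
  ok <- ok && all(abs(pc[ids, "closeness"] - or$harmonic[ids]) < tol)
  ok <- ok && all(pc[ids, "eccentricity"] == or$eccentricity[ids])
  ok <- ok && all(abs(al[ids] - alOr[ids]) < tol)
  inDeg <- vapply(ids, function(v) sum(edges$to == v), numeric(1))
  outDeg <- vapply(ids, function(v) sum(edges$from == v), numeric(1))
  rownames(dg) <- dg$id
  ok <- ok && all(dg[ids, "degree_in"] == inDeg) &&
    all(dg[ids, "degree_out"] == outDeg) &&
    all(dg[ids, "degree"] == inDeg + outDeg)
  if (nrow(ebTab)) {
    keys <- mapply(edgeKey, ebTab$from, ebTab$to)
    ok <- ok && all(abs(ebTab$score - or$edge[keys]) < tol)
  }
  ok
}
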