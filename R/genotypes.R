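# Sample consolidation into unique individuals, and genotyping QC:
# per-stratum success rates plus dropout / false-allele rates estimated from
# re-amplification replicates.

#' Consolidate genotype samples into unique individuals
#'
#' Samples typed at fewer than \code{minLoci} loci are excluded (and
#' reported). The remaining samples are grouped by single linkage on the
#' mismatch graph: two samples are linked when they have at least one
#' comparable locus (typed in both) and disagree at no more than
#' \code{maxMismatch} comparable loci. Each connected group becomes one
#' individual whose consensus genotype is the per-locus majority call over
#' member samples, with ties resolved toward the heterozygote (allelic
#' dropout produces false homozygotes, so the heterozygous call is the more
#' credible one). Sex is the member majority; a conflict yields "unknown"
#' with a warning. Representative coordinates and stratum come from the
#' lexicographically first member sample.
#'
#' @param samples A \code{\link{GenotypeSamples}} object.
#' @param maxMismatch Maximum number of disagreeing comparable loci for two
#'   samples to be considered the same individual (default 2, tolerant of
#'   dropout artifacts).
#' @param minLoci Minimum typed loci for a sample to be retained (default 5).
#' @return An \code{\link{IndividualSet}}. Attributes: \code{mapping}
#'   (named character vector, sample id -> individual id, total over
#'   retained samples), \code{excluded} (sample ids dropped for too few
#'   typed loci), \code{singletons} (individual ids represented by a single
#'   sample, flagged for re-amplification review).
#' @export
consolidateIndividuals <- function(samples, maxMismatch = 2L, minLoci = 5L) {
  stopifnot(is(samples, "GenotypeSamples"))
  if (minLoci < 1L) stop("minLoci must be >= 1")
  info <- samples@info
  if (anyDuplicated(info$sample_id)) {
    dup <- unique(info$sample_id[duplicated(info$sample_id)])
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  }
  geno <- samples@geno
  loci <- lociNames(samples)
  typed <- typedLociCount(geno)
  excluded <- info$sample_id[typed < minLoci]
  keep <- typed >= minLoci
  info <- info[keep, , drop = FALSE]
  geno <- geno[keep, , drop = FALSE]
  n <- nrow(info)
  if (n == 0L) {
    out <- new("IndividualSet",
               info = data.frame(individual_id = character(0), sex = character(0),
                                 sampled = logical(0), stratum = character(0),
                                 x = numeric(0), y = numeric(0),
                                 n_samples = integer(0), stringsAsFactors = FALSE),
               geno = emptyGenoMatrix(0, loci), members = list())
    attr(out, "mapping") <- stats::setNames(character(0), character(0))
    attr(out, "excluded") <- excluded
    attr(out, "singletons") <- character(0)
    return(out)
  }

  gs <- genoStrings(geno)
  comp <- !is.na(gs)
  # pairwise mismatch counts over comparable loci; linked when comparable
  # loci exist and mismatches <= maxMismatch
  adj <- matrix(FALSE, n, n)
  nComp <- matrix(0L, n, n)
  mism <- matrix(0L, n, n)
  for (l in seq_along(loci)) {
    cl <- outer(comp[, l], comp[, l], "&")
    nComp <- nComp + cl
    dif <- outer(gs[, l], gs[, l], "!=")
    dif[!cl] <- FALSE
    mism <- mism + dif
  }
  adj <- nComp > 0L & mism <= maxMismatch
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  memb <- igraph::components(g)$membership

  # deterministic individual ids ordered by each group's smallest sample id
  firstId <- tapply(info$sample_id, memb, function(x) min(sort(x)))
  ord <- order(unname(firstId))
  rank <- stats::setNames(seq_along(ord), names(firstId)[ord])
  indIds <- sprintf("I%04d", rank[as.character(memb)])

  groups <- split(seq_len(n), indIds)
  uid <- names(groups)
  cgeno <- emptyGenoMatrix(length(uid), loci)
  cinfo <- data.frame(individual_id = uid, sex = NA_character_, sampled = TRUE,
                      stratum = NA_character_, x = NA_real_, y = NA_real_,
                      n_samples = lengths(groups), stringsAsFactors = FALSE)
  members <- vector("list", length(uid))
  names(members) <- uid
  sexConflicts <- character(0)

  for (k in seq_along(uid)) {
    rows <- groups[[k]]
    ids <- sort(info$sample_id[rows])
    members[[k]] <- ids
    rep1 <- rows[order(info$sample_id[rows])][1]
    cinfo$stratum[k] <- info$stratum[rep1]
    cinfo$x[k] <- info$x[rep1]
    cinfo$y[k] <- info$y[rep1]
    # sex consensus: majority; conflict between F and M -> unknown
    sx <- info$sex[rows]
    sx <- sx[sx != "unknown"]
    if (!length(sx)) cinfo$sex[k] <- "unknown"
    else {
      tb <- sort(table(sx), decreasing = TRUE)
      if (length(tb) > 1L && tb[1] == tb[2]) {
        cinfo$sex[k] <- "unknown"
        sexConflicts <- c(sexConflicts, uid[k])
      } else cinfo$sex[k] <- names(tb)[1]
    }
    # consensus genotype: per-locus majority, ties toward heterozygote then
    # lexicographic
    for (l in seq_along(loci)) {
      calls <- gs[rows, l]
      calls <- calls[!is.na(calls)]
      if (!length(calls)) next
      tb <- table(calls)
      best <- names(tb)[tb == max(tb)]
      if (length(best) > 1L) {
        isHet <- vapply(strsplit(best, "/", fixed = TRUE),
                        function(p) p[1] != p[2], logical(1))
        if (any(isHet)) best <- best[isHet]
        best <- sort(best)[1]
      }
      cgeno[k, locusCols(l)] <- as.integer(strsplit(best, "/", fixed = TRUE)[[1]])
    }
  }
  if (length(sexConflicts))
    warning("sex conflict within individual(s): ",
            paste(sexConflicts, collapse = ", "), "; set to unknown")

  rownames(cgeno) <- uid
  out <- new("IndividualSet", info = cinfo,
             geno = normalizeGenotypes(cgeno), members = members)
  mapping <- stats::setNames(indIds, info$sample_id)
  attr(out, "mapping") <- mapping
  attr(out, "excluded") <- excluded
  attr(out, "singletons") <- uid[lengths(groups) == 1L]
  out
}

#' Per-stratum genotyping success from raw counts
#'
#' Arithmetic core of the QC report: success \% = scored / collected x 100
#' per stratum (1 decimal), plus the unweighted mean of the per-stratum
#' percentages. A stratum with zero collected samples has undefined (NA)
#' success rather than 0.
#'
#' @param strata data.frame with columns \code{stratum}, \code{collected},
#'   \code{scored}, and optionally \code{unique_genotypes}.
#' @return Object of class \code{QCReport}: list with \code{strata} (the
#'   input plus \code{success_pct}) and \code{overall} (totals plus
#'   \code{mean_success_pct}, the unweighted stratum mean).
#' @export
qcFromCounts <- function(strata) {
  stopifnot(all(c("stratum", "collected", "scored") %in% colnames(strata)))
  if (any(strata$scored > strata$collected))
    stop("scored cannot exceed collected")
  succ <- ifelse(strata$collected > 0,
                 roundHalfUp(100 * strata$scored / strata$collected, 1),
                 NA_real_)
  strata$success_pct <- succ
  overall <- list(collected = sum(strata$collected),
                  scored = sum(strata$scored),
                  mean_success_pct = roundHalfUp(mean(succ, na.rm = TRUE), 1))
  if ("unique_genotypes" %in% colnames(strata))
    overall$unique_genotypes <- sum(strata$unique_genotypes)
  structure(list(strata = strata, overall = overall), class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat("Genotyping QC report\n")
  print(x$strata, row.names = FALSE)
  cat(sprintf("Overall: %d collected, %d scored; unweighted mean success %.1f%%\n",
              x$overall$collected, x$overall$scored, x$overall$mean_success_pct))
  if (!is.null(x$overall$dropout_rate))
    cat(sprintf("Replicate-based error rates: dropout %.4g, false allele %.4g\n",
                x$overall$dropout_rate, x$overall$false_allele_rate))
  invisible(x)
}

#' Genotyping QC summary from samples and re-amplification replicates
#'
#' Computes per-stratum collected/scored counts and success percentages,
#' and, when replicate pairs are supplied, per-allele dropout and
#' false-allele rates from re-amplification discordances. For each replicate
#' pair and comparable locus: a heterozygote in one replicate called as a
#' matching homozygote in the other counts one dropout event (denominator:
#' two allele observations per heterozygous genotype observation); any other
#' novel-allele discordance counts toward the false-allele rate
#' (denominator: all replicated allele observations).
#'
#' @param samples A \code{\link{GenotypeSamples}} object.
#' @param scoredFlags Optional named logical vector (sample id -> scored).
#'   Defaults to "typed at >= \code{minLoci} loci".
#' @param replicatePairs Optional data.frame with columns \code{sample1},
#'   \code{sample2}; each row must reference two samples of the same
#'   individual.
#' @param mapping Optional sample -> individual mapping (as produced by
#'   \code{\link{consolidateIndividuals}}); adds unique-genotype counts and
#'   validates replicate pairs.
#' @param minLoci Scoring threshold when \code{scoredFlags} is absent.
#' @return A \code{QCReport} (see \code{\link{qcFromCounts}}) whose
#'   \code{overall} element additionally carries \code{dropout_rate} and
#'   \code{false_allele_rate} when replicate pairs are given.
#' @export
qcSummary <- function(samples, scoredFlags = NULL, replicatePairs = NULL,
                      mapping = NULL, minLoci = 5L) {
  stopifnot(is(samples, "GenotypeSamples"))
  info <- samples@info
  if (is.null(scoredFlags)) {
    scoredFlags <- stats::setNames(typedLociCount(samples@geno) >= minLoci,
                                   info$sample_id)
  }
  scored <- scoredFlags[info$sample_id]
  strata <- unique(info$stratum)
  tab <- data.frame(stratum = strata,
                    collected = vapply(strata, function(s) sum(info$stratum == s), integer(1)),
                    scored = vapply(strata, function(s)
                      sum(scored[info$stratum == s], na.rm = TRUE), integer(1)),
                    stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    tab$unique_genotypes <- vapply(strata, function(s) {
      ids <- info$sample_id[info$stratum == s]
      length(unique(stats::na.omit(mapping[ids])))
    }, integer(1))
  }
  rep <- qcFromCounts(tab)

  if (!is.null(replicatePairs) && nrow(replicatePairs)) {
    if (!is.null(mapping)) {
      m1 <- mapping[as.character(replicatePairs$sample1)]
      m2 <- mapping[as.character(replicatePairs$sample2)]
      bad <- !is.na(m1) & !is.na(m2) & m1 != m2
      if (any(bad))
        stop("replicate pair(s) reference different individuals: ",
             paste(replicatePairs$sample1[bad], replicatePairs$sample2[bad],
                   sep = "/", collapse = ", "))
    }
    er <- replicateErrorRates(samples, replicatePairs)
    rep$overall$dropout_rate <- er["dropout_rate"]
    rep$overall$false_allele_rate <- er["false_allele_rate"]
    rep$overall$dropout_events <- er["dropout_events"]
    rep$overall$false_allele_events <- er["false_allele_events"]
  }
  rep
}

# Dropout / false-allele rates from replicate pair discordances.
replicateErrorRates <- function(samples, pairs) {
  geno <- samples@geno
  ids <- samples@info$sample_id
  nl <- ncol(geno) %/% 2L
  hetObs <- 0L; alleleObs <- 0L; dropEvents <- 0L; faEvents <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- match(as.character(pairs$sample1[r]), ids)
    j <- match(as.character(pairs$sample2[r]), ids)
    if (is.na(i) || is.na(j)) stop("replicate pair references unknown sample id")
    for (l in seq_len(nl)) {
      cc <- locusCols(l)
      g1 <- unname(geno[i, cc]); g2 <- unname(geno[j, cc])
      if (anyNA(g1) || anyNA(g2)) next
      h1 <- g1[1] != g1[2]; h2 <- g2[1] != g2[2]
      alleleObs <- alleleObs + 4L
      hetObs <- hetObs + 2L * (h1 + h2)
      if (identical(unname(g1), unname(g2))) next
      dropoutPattern <- (h1 && !h2 && g2[1] %in% g1) ||
                        (h2 && !h1 && g1[1] %in% g2)
      if (dropoutPattern) dropEvents <- dropEvents + 1L
      else faEvents <- faEvents + length(union(setdiff(g1, g2), setdiff(g2, g1)))
    }
  }
  c(dropout_rate = if (hetObs > 0) dropEvents / hetObs else NA_real_,
    false_allele_rate = if (alleleObs > 0) faEvents / alleleObs else NA_real_,
    dropout_events = dropEvents, false_allele_events = faEvents)
}
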