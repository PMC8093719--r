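# Parentage assignment: Mendelian exclusion pre-filter plus a pairwise
# transmission likelihood with a per-locus error mixture, a 50% prior on a
# true parent being among the candidates, inferred placeholders for
# unsampled parents, greedy sib-grouping of placeholders into shared
# inferred parents, and offspring-count fitness.

#' Parentage configuration
#'
#' @param errorRate Per-locus genotyping error weight \code{eps} in the
#'   likelihood mixture (default 0.01, the order of observed dropout /
#'   false-allele rates).
#' @param maxExclusions Number of mismatching (allele-sharing-free) loci
#'   tolerated before a candidate is excluded (default 1, tolerating one
#'   dropout-induced mismatch).
#' @param probParentSampled Prior probability that a true parent is present
#'   among the sampled candidates (default 0.5).
#' @param allowPolygamy Individuals may appear as parents in several
#'   offspring rows (default TRUE). Kept for interface symmetry; assignment
#'   is per-offspring, so polygamous use of a parent is never blocked.
#' @param inbreedingAvoidance If TRUE, candidate dam-sire pairs that are
#'   themselves genotype-compatible as parent and offspring (zero mutual
#'   exclusions) are skipped (default FALSE, matching a mating system
#'   without inbreeding avoidance).
#' @return A validated list of class \code{ParentageConfig}.
#' @export
parentageConfig <- function(errorRate = 0.01, maxExclusions = 1L,
                            probParentSampled = 0.5, allowPolygamy = TRUE,
                            inbreedingAvoidance = FALSE) {
  if (errorRate < 0 || errorRate > 1 || probParentSampled < 0 || probParentSampled > 1)
    stop("invalid argument: probabilities must lie in [0, 1]")
  if (maxExclusions < 0) stop("invalid argument: maxExclusions must be >= 0")
  structure(list(errorRate = errorRate, maxExclusions = as.integer(maxExclusions),
                 probParentSampled = probParentSampled,
                 allowPolygamy = isTRUE(allowPolygamy),
                 inbreedingAvoidance = isTRUE(inbreedingAvoidance)),
            class = "ParentageConfig")
}

#' Count Mendelian exclusions between an offspring and a candidate parent
#'
#' The number of comparable loci (typed in both) at which the candidate
#' shares no allele with the offspring. A true parent transmits one allele
#' per locus, so barring genotyping error its exclusion count is 0.
#'
#' @param offspring,candidate Genotype vectors (two entries per locus, the
#'   matrix-row layout used throughout the package).
#' @return Integer exclusion count. If the two genotypes have no comparable
#'   locus the count is 0 and the result carries attribute
#'   \code{noComparableLoci = TRUE} (with a warning).
#' @export
locusExclusions <- function(offspring, candidate) {
  nl <- length(offspring) %/% 2L
  stopifnot(length(candidate) == length(offspring))
  cnt <- 0L
  comparable <- 0L
  for (l in seq_len(nl)) {
    cc <- locusCols(l)
    o <- offspring[cc]; p <- candidate[cc]
    if (anyNA(o) || anyNA(p)) next
    comparable <- comparable + 1L
    if (!any(o %in% p)) cnt <- cnt + 1L
  }
  if (comparable == 0L) {
    warning("no comparable loci between offspring and candidate")
    attr(cnt, "noComparableLoci") <- TRUE
  }
  cnt
}

# Per-locus likelihood of an observed offspring genotype given parent
# genotypes (either may be NULL = unsampled, marginalized over HWE), with a
# per-locus error mixture: with probability 1 - eps the genotype follows
# Mendelian transmission, with probability eps it is an error drawn from the
# HWE genotype distribution.
locusLikelihood <- function(o, d, s, f, eps, genoTab) {
  hw <- hweProb(o[1], o[2], f)
  mendel <-
    if (!is.null(d) && !is.null(s)) {
      transmissionProb(o[1], o[2], d[1], d[2], s[1], s[2])
    } else if (!is.null(d) || !is.null(s)) {
      p <- if (is.null(d)) s else d
      tot <- 0
      for (r in seq_len(nrow(genoTab))) {
        tot <- tot + genoTab$p[r] *
          transmissionProb(o[1], o[2], p[1], p[2], genoTab$a1[r], genoTab$a2[r])
      }
      tot
    } else hw
  (1 - eps) * mendel + eps * hw
}

#' Log-likelihood of a parent configuration for one offspring
#'
#' Per locus, the likelihood is the Mendelian transmission probability of
#' the offspring genotype given the stated parent genotypes, mixed with a
#' Hardy-Weinberg error term of weight \code{eps}; an unknown parent is
#' marginalized over Hardy-Weinberg genotype probabilities. Loci multiply
#' (logs add); loci missing in the offspring (or in a stated parent) are
#' skipped / marginalized. With \code{eps = 0} a hard Mendelian
#' impossibility yields \code{-Inf}.
#'
#' @param offspring Offspring genotype vector (two entries per locus).
#' @param dam,sire Parent genotype vectors, or \code{NULL} for an unsampled
#'   (unknown) parent.
#' @param freqs A \code{\link{FrequencyTable}} covering all observed alleles.
#' @param eps Per-locus error probability.
#' @return Log-likelihood (natural log), possibly \code{-Inf}.
#' @export
parentageLikelihood <- function(offspring, dam = NULL, sire = NULL, freqs,
                                eps = 0.01) {
  stopifnot(is(freqs, "FrequencyTable"))
  loci <- lociNames(freqs)
  nl <- length(loci)
  stopifnot(length(offspring) == 2L * nl)
  genoTabs <- lapply(freqs@freqs, enumerateGenotypes)
  ll <- 0
  for (l in seq_len(nl)) {
    cc <- locusCols(l)
    o <- offspring[cc]
    if (anyNA(o)) next
    d <- if (is.null(dam)) NULL else dam[cc]
    s <- if (is.null(sire)) NULL else sire[cc]
    if (!is.null(d) && anyNA(d)) d <- NULL   # parent untyped here: marginalize
    if (!is.null(s) && anyNA(s)) s <- NULL
    f <- freqs@freqs[[l]]
    L <- locusLikelihood(o, d, s, f, eps, genoTabs[[l]])
    if (L <= 0) return(-Inf)
    ll <- ll + log(L)
  }
  ll
}

#' Assign a dam and sire to every individual
#'
#' Every sampled individual is treated as a potential offspring; all sampled
#' females are candidate dams and all sampled males candidate sires (self
#' excluded). Candidates failing the exclusion filter
#' (\code{maxExclusions}) are dropped; the remaining (dam, sire)
#' configurations -- both sampled, dam only, sire only, neither -- are
#' scored by \code{\link{parentageLikelihood}} plus a prior of
#' \code{probParentSampled} per sampled slot (and its complement per
#' unsampled slot), and the maximum-posterior configuration is kept.
#' Unassigned slots receive inferred-parent placeholders, so every
#' offspring ends with exactly one dam and one sire. Because no age data
#' orient the relationships, reciprocal assignments can create cycles;
#' these are broken post hoc by discarding the lowest-confidence edge
#' inside each strongly connected component (with a warning), the freed
#' slot reverting to a placeholder.
#'
#' @param individuals An \code{\link{IndividualSet}} (sampled individuals
#'   with sex labels).
#' @param freqs A \code{\link{FrequencyTable}}.
#' @param config A \code{\link{parentageConfig}}.
#' @param maxPairs Cap on (dam, sire) pairs evaluated per offspring; when
#'   exceeded, candidates are pre-ranked by single-parent likelihood.
#' @return A \code{PedigreeTable} data.frame: \code{offspring_id},
#'   \code{dam_id}, \code{sire_id}, \code{dam_sampled}, \code{sire_sampled},
#'   \code{confidence} (log-likelihood gap between best and runner-up
#'   configuration). Attribute \code{skipped} lists individuals with no
#'   typed loci (excluded, with report entry).
#' @export
assignParentage <- function(individuals, freqs, config = parentageConfig(),
                            maxPairs = 20000L) {
  stopifnot(is(individuals, "IndividualSet"), is(freqs, "FrequencyTable"),
            inherits(config, "ParentageConfig"))
  info <- individuals@info
  geno <- individuals@geno
  ids <- info$individual_id
  loci <- lociNames(freqs)
  nl <- length(loci)
  eps <- config$errorRate
  p <- config$probParentSampled
  genoTabs <- lapply(freqs@freqs, enumerateGenotypes)
  logp <- function(q) if (q <= 0) -Inf else log(q)

  typed <- typedLociCount(geno)
  skipped <- ids[typed == 0L]
  offIdx <- which(typed > 0L)

  damIdx <- which(info$sex == "F")
  sireIdx <- which(info$sex == "M")

  # exclusion counts offspring x candidate, vectorized per locus
  exclCounts <- function(candIdx) {
    out <- matrix(0L, nrow(info), length(candIdx))
    for (l in seq_len(nl)) {
      cc <- locusCols(l)
      o1 <- geno[, cc[1]]; o2 <- geno[, cc[2]]
      c1 <- geno[candIdx, cc[1]]; c2 <- geno[candIdx, cc[2]]
      share <- outer(o1, c1, "==") | outer(o1, c2, "==") |
               outer(o2, c1, "==") | outer(o2, c2, "==")
      comp <- outer(!is.na(o1), !is.na(c1), "&")
      out <- out + (comp & !share)
    }
    out
  }
  exD <- if (length(damIdx)) exclCounts(damIdx) else matrix(0L, nrow(info), 0)
  exS <- if (length(sireIdx)) exclCounts(sireIdx) else matrix(0L, nrow(info), 0)

  llCache <- new.env(parent = emptyenv())
  pairLL <- function(oi, di, si) {
    key <- paste(oi, if (is.null(di)) "-" else di, if (is.null(si)) "-" else si)
    got <- llCache[[key]]
    if (!is.null(got)) return(got)
    val <- parentageLikelihoodFast(geno[oi, ],
                                   if (is.null(di)) NULL else geno[di, ],
                                   if (is.null(si)) NULL else geno[si, ],
                                   freqs, eps, genoTabs)
    llCache[[key]] <- val
    val
  }

  res <- data.frame(offspring_id = ids[offIdx], dam_id = NA_character_,
                    sire_id = NA_character_, dam_sampled = FALSE,
                    sire_sampled = FALSE, confidence = NA_real_,
                    stringsAsFactors = FALSE)

  for (r in seq_along(offIdx)) {
    oi <- offIdx[r]
    dCand <- damIdx[exD[oi, ] <= config$maxExclusions & damIdx != oi]
    sCand <- sireIdx[exS[oi, ] <= config$maxExclusions & sireIdx != oi]

    llD <- vapply(dCand, function(di) pairLL(oi, di, NULL), numeric(1))
    llS <- vapply(sCand, function(si) pairLL(oi, NULL, si), numeric(1))
    dCand <- dCand[is.finite(llD)]; llD <- llD[is.finite(llD)]
    sCand <- sCand[is.finite(llS)]; llS <- llS[is.finite(llS)]

    if (length(dCand) * length(sCand) > maxPairs) {
      keepN <- max(1L, floor(sqrt(maxPairs)))
      oD <- order(llD, decreasing = TRUE)[seq_len(min(keepN, length(dCand)))]
      oS <- order(llS, decreasing = TRUE)[seq_len(min(keepN, length(sCand)))]
      dCand <- dCand[oD]; llD <- llD[oD]
      sCand <- sCand[oS]; llS <- llS[oS]
    }

    # candidate configurations: score = log prior + log likelihood
    scores <- c(none = 2 * logp(1 - p) + pairLL(oi, NULL, NULL))
    cfgDam <- c(NA_integer_); cfgSire <- c(NA_integer_)
    if (length(dCand)) {
      scores <- c(scores, stats::setNames(logp(p) + logp(1 - p) + llD,
                                          paste0("d", dCand)))
      cfgDam <- c(cfgDam, dCand); cfgSire <- c(cfgSire, rep(NA_integer_, length(dCand)))
    }
    if (length(sCand)) {
      scores <- c(scores, stats::setNames(logp(p) + logp(1 - p) + llS,
                                          paste0("s", sCand)))
      cfgDam <- c(cfgDam, rep(NA_integer_, length(sCand))); cfgSire <- c(cfgSire, sCand)
    }
    for (di in dCand) for (si in sCand) {
      if (config$inbreedingAvoidance) {
        mutual <- locusExclusionsIdx(geno, di, si, nl)
        if (mutual == 0L) next   # plausible parent-offspring pair: avoid
      }
      scores <- c(scores, stats::setNames(2 * logp(p) + pairLL(oi, di, si),
                                          paste0("p", di, ".", si)))
      cfgDam <- c(cfgDam, di); cfgSire <- c(cfgSire, si)
    }

    best <- which.max(scores)
    ord <- order(scores, decreasing = TRUE)
    conf <- if (length(scores) > 1L) scores[ord[1]] - scores[ord[2]] else Inf
    bd <- cfgDam[best]; bs <- cfgSire[best]
    res$dam_id[r] <- if (!is.na(bd)) ids[bd] else paste0("U.F.", ids[oi])
    res$sire_id[r] <- if (!is.na(bs)) ids[bs] else paste0("U.M.", ids[oi])
    res$dam_sampled[r] <- !is.na(bd)
    res$sire_sampled[r] <- !is.na(bs)
    res$confidence[r] <- conf
  }

  res <- breakCycles(res)
  attr(res, "skipped") <- skipped
  res
}

locusExclusionsIdx <- function(geno, i, j, nl) {
  cnt <- 0L
  for (l in seq_len(nl)) {
    cc <- locusCols(l)
    o <- geno[i, cc]; q <- geno[j, cc]
    if (anyNA(o) || anyNA(q)) next
    if (!any(o %in% q)) cnt <- cnt + 1L
  }
  cnt
}

# parentageLikelihood with precomputed genotype enumeration tables.
parentageLikelihoodFast <- function(offspring, dam, sire, freqs, eps, genoTabs) {
  nl <- length(genoTabs)
  ll <- 0
  for (l in seq_len(nl)) {
    cc <- locusCols(l)
    o <- offspring[cc]
    if (anyNA(o)) next
    d <- if (is.null(dam)) NULL else dam[cc]
    s <- if (is.null(sire)) NULL else sire[cc]
    if (!is.null(d) && anyNA(d)) d <- NULL
    if (!is.null(s) && anyNA(s)) s <- NULL
    L <- locusLikelihood(o, d, s, freqs@freqs[[l]], eps, genoTabs[[l]])
    if (L <= 0) return(-Inf)
    ll <- ll + log(L)
  }
  ll
}

# Cycles can arise because assignment is symmetric in the absence of ages:
# drop the lowest-confidence assignment edge inside each strongly connected
# component until the parent->offspring graph is a DAG.
breakCycles <- function(ped) {
  repeat {
    edges <- rbind(
      data.frame(from = ped$dam_id[ped$dam_sampled],
                 to = ped$offspring_id[ped$dam_sampled],
                 row = which(ped$dam_sampled),
                 slot = rep("dam", sum(ped$dam_sampled)),
                 stringsAsFactors = FALSE),
      data.frame(from = ped$sire_id[ped$sire_sampled],
                 to = ped$offspring_id[ped$sire_sampled],
                 row = which(ped$sire_sampled),
                 slot = rep("sire", sum(ped$sire_sampled)),
                 stringsAsFactors = FALSE))
    if (!nrow(edges)) return(ped)
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = TRUE)
    if (igraph::is_dag(g)) return(ped)
    sc <- igraph::components(g, mode = "strong")
    cyc <- names(sc$membership)[sc$membership %in% which(sc$csize > 1L)]
    inCyc <- edges$from %in% cyc & edges$to %in% cyc
    cand <- edges[inCyc, , drop = FALSE]
    conf <- ped$confidence[cand$row]
    worst <- cand[order(conf, cand$row)[1], ]
    warning(sprintf("cycle detected; dropping %s -> %s (%s edge, confidence %.3g)",
                    worst$from, worst$to, worst$slot, ped$confidence[worst$row]))
    if (worst$slot == "dam") {
      ped$dam_id[worst$row] <- paste0("U.F.", ped$offspring_id[worst$row])
      ped$dam_sampled[worst$row] <- FALSE
    } else {
      ped$sire_id[worst$row] <- paste0("U.M.", ped$offspring_id[worst$row])
      ped$sire_sampled[worst$row] <- FALSE
    }
  }
}

#' Merge inferred-parent placeholders into shared unsampled parents
#'
#' Offspring whose dam (resp. sire) slot is an inferred placeholder are
#' greedily grouped: a group is feasible when, at every locus comparable
#' across members, a single parental genotype (at most two alleles, one
#' transmitted to each member) exists that shares an allele with every
#' member. Candidates are processed in lexicographic id order; each joins
#' the feasible group with the highest compatibility score (number of loci
#' at which the candidate shares an allele with every current member), ties
#' to the earliest group. Each group's placeholders are replaced by one
#' inferred individual (ids \code{IF...} / \code{IM...}), sex-typed by slot.
#'
#' @param ped A \code{PedigreeTable} from \code{\link{assignParentage}}.
#' @param individuals The \code{\link{IndividualSet}} used for assignment.
#' @param freqs A \code{\link{FrequencyTable}} (interface completeness;
#'   grouping is purely allele-set based).
#' @param config A \code{\link{parentageConfig}}.
#' @return The updated \code{PedigreeTable}, with attribute
#'   \code{inferredParents}: data.frame of inferred ids, sex and the
#'   offspring grouped under each.
#' @export
reconstructUnsampledParents <- function(ped, individuals, freqs = NULL,
                                        config = parentageConfig()) {
  stopifnot(is(individuals, "IndividualSet"))
  geno <- individuals@geno
  ids <- individuals@info$individual_id
  nl <- ncol(geno) %/% 2L

  alleleSets <- function(offId) {
    g <- geno[match(offId, ids), ]
    lapply(seq_len(nl), function(l) {
      v <- g[locusCols(l)]
      if (anyNA(v)) NULL else unique(unname(v))
    })
  }
  # is there a <=2-allele parental genotype hitting every member's allele set?
  feasible <- function(sets) {
    sets <- Filter(Negate(is.null), sets)
    if (length(sets) <= 1L) return(TRUE)
    common <- Reduce(intersect, sets)
    if (length(common)) return(TRUE)
    U <- unique(unlist(sets))
    if (length(U) < 2L) return(FALSE)
    for (i in seq_len(length(U) - 1L)) for (j in (i + 1L):length(U)) {
      pairOk <- all(vapply(sets, function(s) U[i] %in% s || U[j] %in% s,
                           logical(1)))
      if (pairOk) return(TRUE)
    }
    FALSE
  }

  groupSlot <- function(slotIds, prefix) {
    off <- sort(unique(slotIds$offspring_id))
    sets <- lapply(off, alleleSets)
    names(sets) <- off
    groups <- list()        # each: list(members, perLocus list of member sets)
    for (o in off) {
      best <- 0L; bestScore <- -1L
      for (k in seq_along(groups)) {
        merged <- lapply(seq_len(nl), function(l)
          c(groups[[k]]$perLocus[[l]], sets[[o]][l]))
        ok <- all(vapply(seq_len(nl), function(l) feasible(merged[[l]]),
                         logical(1)))
        if (!ok) next
        score <- sum(vapply(seq_len(nl), function(l) {
          ms <- Filter(Negate(is.null), groups[[k]]$perLocus[[l]])
          s0 <- sets[[o]][[l]]
          if (is.null(s0) || !length(ms)) return(FALSE)
          length(Reduce(intersect, c(ms, list(s0)))) > 0
        }, logical(1)))
        if (score > bestScore) { bestScore <- score; best <- k }
      }
      if (best == 0L) {
        groups[[length(groups) + 1L]] <-
          list(members = o, perLocus = lapply(seq_len(nl), function(l) sets[[o]][l]))
      } else {
        groups[[best]]$members <- c(groups[[best]]$members, o)
        groups[[best]]$perLocus <- lapply(seq_len(nl), function(l)
          c(groups[[best]]$perLocus[[l]], sets[[o]][l]))
      }
    }
    data.frame(offspring_id = unlist(lapply(groups, `[[`, "members")),
               parent_id = rep(sprintf("%s%03d", prefix, seq_along(groups)),
                               vapply(groups, function(g) length(g$members), integer(1))),
               stringsAsFactors = FALSE)
  }

  inferredTab <- data.frame(parent_id = character(0), sex = character(0),
                            offspring = character(0), stringsAsFactors = FALSE)
  damSlots <- ped[!ped$dam_sampled, , drop = FALSE]
  if (nrow(damSlots)) {
    gm <- groupSlot(damSlots, "IF")
    ped$dam_id[match(gm$offspring_id, ped$offspring_id)] <- gm$parent_id
    inferredTab <- rbind(inferredTab,
                         data.frame(parent_id = unique(gm$parent_id), sex = "F",
                                    offspring = vapply(unique(gm$parent_id), function(p)
                                      paste(gm$offspring_id[gm$parent_id == p],
                                            collapse = ";"), character(1)),
                                    stringsAsFactors = FALSE))
  }
  sireSlots <- ped[!ped$sire_sampled, , drop = FALSE]
  if (nrow(sireSlots)) {
    gm <- groupSlot(sireSlots, "IM")
    ped$sire_id[match(gm$offspring_id, ped$offspring_id)] <- gm$parent_id
    inferredTab <- rbind(inferredTab,
                         data.frame(parent_id = unique(gm$parent_id), sex = "M",
                                    offspring = vapply(unique(gm$parent_id), function(p)
                                      paste(gm$offspring_id[gm$parent_id == p],
                                            collapse = ";"), character(1)),
                                    stringsAsFactors = FALSE))
  }
  attr(ped, "inferredParents") <- inferredTab
  attr(ped, "skipped") <- attr(ped, "skipped")
  ped
}

#' Offspring counts (fitness) per individual
#'
#' Fitness of an individual is the number of pedigree rows naming it as dam
#' or sire. The sum over all individuals is therefore twice the number of
#' offspring rows.
#'
#' @param ped A \code{PedigreeTable}.
#' @param ids Optional ids to report (zero-filled); defaults to every id
#'   appearing in the pedigree.
#' @return Named integer vector of offspring counts.
#' @export
fitnessCounts <- function(ped, ids = NULL) {
  parents <- c(ped$dam_id, ped$sire_id)
  tb <- table(parents)
  if (is.null(ids))
    ids <- sort(unique(c(ped$offspring_id, ped$dam_id, ped$sire_id)))
  out <- stats::setNames(integer(length(ids)), ids)
  hit <- intersect(ids, names(tb))
  out[hit] <- as.integer(tb[hit])
  out
}
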