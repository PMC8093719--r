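# Simulation experiments used to validate the pipeline against known truth:
# pedigree recovery under complete error-free sampling, recovery of an
# injected dropout rate, and the spatial philopatry contrast.

#' Build an IndividualSet directly from simulator truth
#'
#' Bypasses sampling, genotyping error and consolidation: every simulated
#' individual becomes one sampled individual with its true genotype. Used
#' to study downstream stages in isolation.
#'
#' @param pop A \code{\link{TruePopulation}}.
#' @return An \code{\link{IndividualSet}}.
#' @export
individualsFromTruth <- function(pop) {
  stopifnot(is(pop, "TruePopulation"))
  ind <- pop@individuals
  info <- data.frame(individual_id = ind$id, sex = ind$sex, sampled = TRUE,
                     stratum = ind$area, x = ind$x, y = ind$y,
                     n_samples = 1L, stringsAsFactors = FALSE)
  new("IndividualSet", info = info, geno = pop@geno,
      members = stats::setNames(as.list(ind$id), ind$id))
}

#' Pedigree recovery under complete, error-free sampling
#'
#' For each seed: simulate a population, sample every individual without
#' genotyping error, consolidate, assign parentage with error weight 0, and
#' score the assignment against the true pedigree's sampled-to-sampled
#' edges (\code{\link{comparePedigrees}}).
#'
#' @param nSeeds Number of replicate simulations.
#' @param baseSeed Seed offset; replicate i uses \code{baseSeed + i}.
#' @param nFounders,nGenerations Population size knobs.
#' @return data.frame with one row per seed: \code{seed}, \code{recall},
#'   \code{precision}, \code{n_true_edges}.
#' @export
parentageRecoveryExperiment <- function(nSeeds = 20, baseSeed = 0,
                                        nFounders = 16, nGenerations = 3) {
  rows <- lapply(seq_len(nSeeds), function(i) {
    cfg <- simulationConfig(nFounders = nFounders, nGenerations = nGenerations,
                            samplingFraction = 1, dropoutRate = 0,
                            falseAlleleRate = 0, locusFailureRate = 0,
                            replicateFraction = 0, seed = baseSeed + i)
    pop <- simulatePopulation(cfg)
    samples <- applySamplingAndError(pop, cfg)
    individuals <- suppressWarnings(consolidateIndividuals(samples))
    ped <- suppressWarnings(assignParentage(individuals, pop@freqs,
                                            parentageConfig(errorRate = 0)))
    cmp <- comparePedigrees(pop@pedigree, ped, trueIdMap(samples, individuals))
    data.frame(seed = baseSeed + i, recall = cmp$recall,
               precision = cmp$precision, n_true_edges = cmp$n_true_edges)
  })
  do.call(rbind, rows)
}

#' Recovery of an injected allelic-dropout rate
#'
#' Simulates one population and repeatedly re-samples it (full sampling,
#' dropout only) until at least \code{minTrials} per-allele dropout trials
#' at truly heterozygous loci have been observed, then compares the
#' empirical dropout frequency with the exact binomial 95\% interval around
#' the injected rate.
#'
#' @param rate Injected per-allele dropout probability.
#' @param minTrials Minimum number of per-allele trials (two per
#'   heterozygous locus observation).
#' @param seed Base seed.
#' @param nFounders,nGenerations Population size knobs.
#' @return List with \code{rate_hat}, \code{events}, \code{trials},
#'   \code{ci_low}, \code{ci_high} (binomial interval around \code{rate})
#'   and \code{inside} (logical).
#' @export
dropoutRecoveryExperiment <- function(rate = 0.0077, minTrials = 2e5,
                                      seed = 1, nFounders = 400,
                                      nGenerations = 3) {
  cfg <- simulationConfig(nFounders = nFounders, nGenerations = nGenerations,
                          samplingFraction = 1, dropoutRate = rate,
                          falseAlleleRate = 0, locusFailureRate = 0,
                          replicateFraction = 0, seed = seed)
  pop <- simulatePopulation(cfg)
  gTrue <- pop@geno
  nl <- nLoci(pop)
  events <- 0L; trials <- 0L
  pass <- 0L
  while (trials < minTrials) {
    pass <- pass + 1L
    s <- applySamplingAndError(pop, cfg, seed = seed + pass)
    map <- attr(s, "trueIndividual")
    gObs <- genotypes(s)
    gT <- gTrue[map[rownames(gObs)], , drop = FALSE]
    for (l in seq_len(nl)) {
      cc <- locusCols(l)
      het <- gT[, cc[1]] != gT[, cc[2]]
      oA <- gObs[het, cc[1]]; oB <- gObs[het, cc[2]]
      trials <- trials + 2L * sum(het)
      miss <- is.na(oA)                 # both alleles dropped
      hom <- !miss & oA == oB           # one allele dropped
      events <- events + 2L * sum(miss) + sum(hom)
    }
  }
  ciLow <- stats::qbinom(0.025, trials, rate) / trials
  ciHigh <- stats::qbinom(0.975, trials, rate) / trials
  rateHat <- events / trials
  list(rate_hat = rateHat, events = events, trials = trials,
       ci_low = ciLow, ci_high = ciHigh,
       inside = rateHat >= ciLow && rateHat <= ciHigh)
}

#' Philopatry contrast experiment
#'
#' For each seed, simulates a population under the default layout (three
#' strongly philopatric clusters, three dispersal-prone clusters), applies
#' the study-like partial sampling (20\%, error-free) and runs the full
#' reconstruction pipeline -- consolidation, parentage assignment,
#' sib-grouping of inferred parents, network construction. It then
#' compares edge-to-node ratios between philopatric and dispersing areas,
#' and reports the sign of the Pearson correlation between area ratio and
#' area-mean eccentricity (computed on the primary network). Partial
#' sampling matters here: it is what leaves dispersers weakly connected
#' and hence peripheral, as in real monitoring data.
#'
#' @param nSeeds Number of replicate simulations.
#' @param baseSeed Seed offset.
#' @param nFounders,nGenerations Population size knobs.
#' @return data.frame per seed: \code{seed}, \code{mean_ratio_philopatric},
#'   \code{mean_ratio_dispersing}, \code{philopatric_higher} (logical),
#'   \code{ecc_correlation} (may be NA when degenerate),
#'   \code{largest_share_pct}.
#' @export
philopatryContrastExperiment <- function(nSeeds = 20, baseSeed = 100,
                                         nFounders = 200, nGenerations = 4) {
  layout <- defaultAreaLayout()
  philAreas <- layout$area[layout$philopatry >= 0.5]
  dispAreas <- layout$area[layout$philopatry < 0.5]
  rows <- lapply(seq_len(nSeeds), function(i) {
    cfg <- simulationConfig(nFounders = nFounders, nGenerations = nGenerations,
                            dropoutRate = 0, falseAlleleRate = 0,
                            locusFailureRate = 0, replicateFraction = 0,
                            seed = baseSeed + i)
    pop <- simulatePopulation(cfg)
    samples <- applySamplingAndError(pop, cfg)
    individuals <- suppressWarnings(consolidateIndividuals(samples))
    ped <- suppressWarnings(assignParentage(individuals, pop@freqs,
                                            parentageConfig(errorRate = 0)))
    ped <- reconstructUnsampledParents(ped, individuals)
    memb <- stats::setNames(individuals@info$stratum,
                            individuals@info$individual_id)
    net <- buildFamilialNetwork(ped, individuals, membership = memb)
    reports <- areaReports(net, memb, k = 3)
    ratios <- stats::setNames(reports$ratio, reports$area)
    mp <- mean(ratios[intersect(philAreas, names(ratios))], na.rm = TRUE)
    md <- mean(ratios[intersect(dispAreas, names(ratios))], na.rm = TRUE)
    ecc <- NA_real_
    if (sum(!is.na(reports$ratio)) >= 4) {
      tab <- centralityTable(primaryNetwork(net))
      cmp <- tryCatch(
        suppressWarnings(compareAreaGroups(tab, memb, reports, k = 2)),
        error = function(e) NULL)
      if (!is.null(cmp))
        ecc <- cmp$correlations$r[cmp$correlations$measure == "eccentricity"]
    }
    data.frame(seed = baseSeed + i, mean_ratio_philopatric = mp,
               mean_ratio_dispersing = md, philopatric_higher = mp > md,
               ecc_correlation = ecc,
               largest_share_pct = connectedComponents(net)$largest_share_pct)
  })
  do.call(rbind, rows)
}
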