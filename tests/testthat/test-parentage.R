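# Exclusion counting, transmission likelihood, assignment, sib-grouping of
# inferred parents, and fitness.

test_that("locus exclusions count loci sharing no allele", {
  # one locus: offspring {1,2} vs candidate {2,3} share allele 2
  expect_equal(locusExclusions(c(1L, 2L), c(2L, 3L)), 0L)
  # offspring {1,1} vs candidate {2,3}: no shared allele
  expect_equal(locusExclusions(c(1L, 1L), c(2L, 3L)), 1L)
  # empty comparable set -> 0 with a warning
  expect_warning(z <- locusExclusions(c(NA, NA), c(1L, 2L)), "comparable")
  expect_equal(as.integer(z), 0L)
})

test_that("15-locus exclusions equal an independent per-locus loop", {
  set.seed(42)
  for (rep in 1:20) {
    o <- as.integer(sample(1:6, 30, replace = TRUE))
    p <- as.integer(sample(1:6, 30, replace = TRUE))
    o[sample(30, 4)] <- NA  # scatter missing alleles
    om <- normalizeGenotypes(matrix(o, 1))[1, ]
    pm <- normalizeGenotypes(matrix(p, 1))[1, ]
    brute <- 0L
    for (l in 1:15) {
      oo <- om[c(2 * l - 1, 2 * l)]; pp <- pm[c(2 * l - 1, 2 * l)]
      if (anyNA(oo) || anyNA(pp)) next
      if (!(oo[1] %in% pp || oo[2] %in% pp)) brute <- brute + 1L
    }
    expect_equal(suppressWarnings(as.integer(locusExclusions(om, pm))), brute)
  }
})

test_that("forced transmission has likelihood 1 and exclusions -Inf at eps 0", {
  f <- uniformFreqs(1, c(1L, 2L))
  # offspring {1,2}, dam {1,1}, sire {2,2}: transmission forced
  expect_equal(parentageLikelihood(c(1L, 2L), c(1L, 1L), c(2L, 2L), f, eps = 0), 0)
  # offspring allele 3 absent from both parents -> impossible
  f3 <- uniformFreqs(1, c(1L, 2L, 3L))
  expect_identical(parentageLikelihood(c(3L, 3L), c(1L, 1L), c(2L, 2L), f3, eps = 0),
                   -Inf)
})

test_that("unknown-parent likelihood equals brute-force HWE enumeration", {
  set.seed(7)
  alleles <- c(1L, 2L, 3L, 4L)
  fr <- rgamma(4, 1); fr <- fr / sum(fr)
  f <- FrequencyTable(list(L01 = stats::setNames(fr, alleles)))
  for (rep in 1:10) {
    off <- sort(sample(alleles, 2, replace = TRUE))
    dam <- sort(sample(alleles, 2, replace = TRUE))
    eps <- sample(c(0, 0.01, 0.1), 1)
    got <- parentageLikelihood(off, dam, NULL, f, eps = eps)
    # independent enumeration of all 10 unordered sire genotypes
    tot <- 0
    hwe <- function(a, b) if (a == b) fr[a] * fr[b] else 2 * fr[a] * fr[b]
    trans <- function(o, d, s) {
      p <- 0
      for (u in d) for (v in s)
        if (identical(sort(c(u, v)), sort(o))) p <- p + 0.25
      p
    }
    for (i in 1:4) for (j in i:4)
      tot <- tot + hwe(i, j) * trans(off, dam, c(alleles[i], alleles[j]))
    expected <- log((1 - eps) * tot + eps * hwe(off[1], off[2]))
    if (is.infinite(got)) expect_identical(expected, -Inf)
    else expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("likelihood is symmetric under swapping dam and sire genotypes", {
  f <- drawAlleleFrequencies(3, 4, seed = 2)
  g <- normalizeGenotypes(matrix(sample(seq(101L, 107L, 2L), 18, replace = TRUE), 3))
  ll1 <- parentageLikelihood(g[1, ], g[2, ], g[3, ], f, eps = 0.02)
  ll2 <- parentageLikelihood(g[1, ], g[3, ], g[2, ], f, eps = 0.02)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("error-free informative loci select the true parent pair", {
  # 15 loci; offspring shares exactly one allele per locus with each true
  # parent; a decoy shares nothing
  nl <- 15
  dam <- rep(c(1L, 1L), nl)
  sire <- rep(c(2L, 2L), nl)
  off <- rep(c(1L, 2L), nl)
  decoyF <- rep(c(3L, 4L), nl)
  decoyM <- rep(c(3L, 4L), nl)
  geno <- toyGeno(list(off, dam, sire, decoyF, decoyM))
  ind <- toyIndividuals(geno, ids = c("OFF", "DAM", "SIRE", "DF", "DM"),
                        sex = c("F", "F", "M", "F", "M"))
  f <- uniformFreqs(nl, c(1L, 2L, 3L, 4L))
  ped <- suppressWarnings(assignParentage(ind, f, parentageConfig(errorRate = 0,
                                                                  maxExclusions = 0)))
  row <- ped[ped$offspring_id == "OFF", ]
  expect_equal(row$dam_id, "DAM")
  expect_equal(row$sire_id, "SIRE")
  expect_true(row$dam_sampled && row$sire_sampled)
})

test_that("an empty candidate set yields two inferred placeholders", {
  nl <- 6
  geno <- toyGeno(list(rep(c(1L, 2L), nl), rep(c(3L, 4L), nl)))
  ind <- toyIndividuals(geno, ids = c("OFF", "OTHER"), sex = c("unknown", "F"))
  f <- uniformFreqs(nl, c(1L, 2L, 3L, 4L))
  ped <- assignParentage(ind, f, parentageConfig(errorRate = 0, maxExclusions = 0))
  row <- ped[ped$offspring_id == "OFF", ]
  expect_false(row$dam_sampled)
  expect_false(row$sire_sampled)
  expect_match(row$dam_id, "^U\\.F\\.")
  expect_match(row$sire_id, "^U\\.M\\.")
})

test_that("every offspring ends with exactly one dam and one sire", {
  cfg <- simulationConfig(nFounders = 16, nGenerations = 3, samplingFraction = 1,
                          dropoutRate = 0, falseAlleleRate = 0,
                          locusFailureRate = 0, replicateFraction = 0, seed = 19)
  out <- simulateConsolidated(cfg)
  ped <- suppressWarnings(assignParentage(out$individuals, out$pop@freqs,
                                          parentageConfig(errorRate = 0)))
  expect_equal(anyDuplicated(ped$offspring_id), 0)
  expect_true(all(!is.na(ped$dam_id) & !is.na(ped$sire_id)))
  ped2 <- reconstructUnsampledParents(ped, out$individuals)
  expect_true(all(!is.na(ped2$dam_id) & !is.na(ped2$sire_id)))
  # dam ids and sire ids never collide
  expect_length(intersect(ped2$dam_id, ped2$sire_id), 0)
})

test_that("compatible maternal half-sibs merge under one inferred dam", {
  nl <- 4
  # both offspring carry allele 1 at every locus -> a single dam {1, .} works
  o1 <- rep(c(1L, 2L), nl)
  o2 <- rep(c(1L, 3L), nl)
  geno <- toyGeno(list(o1, o2))
  ind <- toyIndividuals(geno, ids = c("K1", "K2"), sex = c("unknown", "unknown"))
  ped <- data.frame(offspring_id = c("K1", "K2"),
                    dam_id = c("U.F.K1", "U.F.K2"),
                    sire_id = c("U.M.K1", "U.M.K2"),
                    dam_sampled = FALSE, sire_sampled = FALSE,
                    confidence = NA_real_, stringsAsFactors = FALSE)
  ped2 <- reconstructUnsampledParents(ped, ind)
  expect_equal(ped2$dam_id[1], ped2$dam_id[2])
  expect_match(ped2$dam_id[1], "^IF")
})

test_that("offspring needing more than two parental alleles cannot all share a parent", {
  nl <- 4
  # locus 1 allele sets {1,2}, {3,4}, {5,6} are pairwise disjoint: no
  # two-allele parental genotype can transmit to all three, so at least two
  # distinct inferred dams must remain (any two can still share, e.g. {1,3})
  o1 <- c(1L, 2L, rep(c(1L, 2L), nl - 1))
  o2 <- c(3L, 4L, rep(c(1L, 2L), nl - 1))
  o3 <- c(5L, 6L, rep(c(1L, 2L), nl - 1))
  geno <- toyGeno(list(o1, o2, o3))
  ind <- toyIndividuals(geno, ids = c("K1", "K2", "K3"),
                        sex = c("unknown", "unknown", "unknown"))
  ped <- data.frame(offspring_id = c("K1", "K2", "K3"),
                    dam_id = paste0("U.F.K", 1:3),
                    sire_id = paste0("U.M.K", 1:3),
                    dam_sampled = FALSE, sire_sampled = FALSE,
                    confidence = NA_real_, stringsAsFactors = FALSE)
  ped2 <- reconstructUnsampledParents(ped, ind)
  expect_gte(length(unique(ped2$dam_id)), 2)
})

test_that("maternal sib recovery under one inferred dam is reported vs truth", {
  # unsampled mothers: drop all generation-0 females from the candidate set
  cfg <- simulationConfig(nFounders = 14, nGenerations = 2, samplingFraction = 1,
                          dropoutRate = 0, falseAlleleRate = 0,
                          locusFailureRate = 0, replicateFraction = 0,
                          meanOffspringPerFemale = 3, seed = 27)
  pop <- simulatePopulation(cfg)
  ind <- sampleInfo(pop)
  keep <- !(ind$generation == 0 & ind$sex == "F")
  info <- data.frame(individual_id = ind$id[keep], sex = ind$sex[keep],
                     sampled = TRUE, stratum = ind$area[keep],
                     x = ind$x[keep], y = ind$y[keep], n_samples = 1L,
                     stringsAsFactors = FALSE)
  g <- genotypes(pop)[keep, , drop = FALSE]
  iset <- methods::new("IndividualSet", info = info, geno = g,
                       members = stats::setNames(as.list(info$individual_id),
                                                 info$individual_id))
  ped <- suppressWarnings(assignParentage(iset, pop@freqs,
                                          parentageConfig(errorRate = 0)))
  ped <- reconstructUnsampledParents(ped, iset)
  # true maternal sib pairs among offspring with inferred dams
  tp <- pedigree(pop)
  offIds <- ped$offspring_id[grepl("^IF", ped$dam_id)]
  truedam <- stats::setNames(tp$dam_id, tp$offspring_id)
  pairsTotal <- 0; pairsTogether <- 0
  if (length(offIds) >= 2) {
    cmb <- utils::combn(offIds, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      if (is.na(truedam[a]) || is.na(truedam[b])) next
      if (truedam[a] == truedam[b]) {
        pairsTotal <- pairsTotal + 1
        same <- ped$dam_id[ped$offspring_id == a] ==
          ped$dam_id[ped$offspring_id == b]
        pairsTogether <- pairsTogether + same
      }
    }
  }
  expect_gt(pairsTotal, 0)
  # reported fraction is a valid proportion; grouping recovers at least some
  expect_gte(pairsTogether / pairsTotal, 0)
  expect_lte(pairsTogether / pairsTotal, 1)
})

test_that("fitness counts offspring rows naming each individual", {
  ped <- data.frame(offspring_id = sprintf("O%d", 1:5),
                    dam_id = c("D1", "D1", "D1", "D1", "D1"),
                    sire_id = c("S1", "S1", "S2", "S2", "S3"),
                    stringsAsFactors = FALSE)
  fit <- fitnessCounts(ped, ids = c("D1", "S1", "S2", "S3", "NOBODY"))
  expect_equal(unname(fit["D1"]), 5L)
  expect_equal(unname(fit["S1"]), 2L)
  expect_equal(unname(fit["NOBODY"]), 0L)
  expect_equal(sum(fitnessCounts(ped)), 2L * nrow(ped))
})
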