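# Consolidation of samples into unique individuals, and QC arithmetic.

test_that("identical profiles consolidate into one individual", {
  g <- toyGeno(list(c(1L, 2L, 3L, 3L, 5L, 6L, 7L, 8L, 1L, 1L),
                    c(1L, 2L, 3L, 3L, 5L, 6L, 7L, 8L, 1L, 1L)))
  ind <- consolidateIndividuals(toySamples(g), minLoci = 5)
  expect_equal(nrow(sampleInfo(ind)), 1)
  expect_equal(sampleInfo(ind)$n_samples, 2)
  expect_setequal(memberSamples(ind)[[1]], c("S01", "S02"))
  expect_equal(attr(ind, "singletons"), character(0))
})

test_that("profiles beyond the mismatch threshold stay separate", {
  # 5 loci, maxMismatch = 1 -> differing at 2 comparable loci must split
  g <- toyGeno(list(c(1L, 2L, 3L, 3L, 5L, 6L, 7L, 8L, 1L, 1L),
                    c(1L, 2L, 3L, 4L, 5L, 5L, 7L, 8L, 1L, 1L)))
  ind <- consolidateIndividuals(toySamples(g), maxMismatch = 1, minLoci = 5)
  expect_equal(nrow(sampleInfo(ind)), 2)
  # and with maxMismatch = 2 they merge
  ind2 <- consolidateIndividuals(toySamples(g), maxMismatch = 2, minLoci = 5)
  expect_equal(nrow(sampleInfo(ind2)), 1)
})

test_that("missing loci are not counted as mismatches", {
  g <- toyGeno(list(c(1L, 2L, 3L, 3L, 5L, 6L, 7L, 8L, 1L, 1L, 2L, 2L),
                    c(1L, 2L, 3L, 3L, 5L, 6L, 7L, 8L, 1L, 1L, NA, NA)))
  ind <- consolidateIndividuals(toySamples(g), maxMismatch = 0, minLoci = 5)
  expect_equal(nrow(sampleInfo(ind)), 1)
  # consensus keeps the typed call at the locus missing in one sample
  expect_equal(unname(genotypes(ind)[1, c("L06_a1", "L06_a2")]), c(2L, 2L))
})

test_that("samples typed below minLoci are excluded and reported", {
  g <- toyGeno(list(c(1L, 2L, 3L, 3L, 5L, 6L, 7L, 8L, 1L, 1L),
                    c(1L, 2L, 3L, 3L, NA, NA, NA, NA, NA, NA)))
  ind <- consolidateIndividuals(toySamples(g), minLoci = 5)
  expect_equal(attr(ind, "excluded"), "S02")
  expect_equal(nrow(sampleInfo(ind)), 1)
  mapping <- attr(ind, "mapping")
  expect_named(mapping, "S01")
})

test_that("duplicate sample ids raise an error naming the duplicates", {
  g <- toyGeno(list(c(1L, 2L, 3L, 3L, 5L, 6L, 7L, 8L, 1L, 1L),
                    c(1L, 2L, 3L, 3L, 5L, 6L, 7L, 8L, 1L, 1L)))
  info <- data.frame(sample_id = c("DUP", "DUP"), stratum = "all",
                     sex = "unknown", x = 0, y = 0, stringsAsFactors = FALSE)
  expect_error(methods::new("GenotypeSamples", info = info,
                            geno = {rownames(g) <- c("DUP", "DUP"); g}),
               "DUP")
})

test_that("consolidation is invariant to input order up to relabelling", {
  cfg <- simulationConfig(nFounders = 20, nGenerations = 3, samplingFraction = 1,
                          replicateFraction = 0.5, seed = 31)
  pop <- simulatePopulation(cfg)
  s <- applySamplingAndError(pop, cfg)
  perm <- rev(seq_len(nrow(sampleInfo(s))))
  s2 <- GenotypeSamples(sampleInfo(s)[perm, ], genotypes(s)[perm, ])
  i1 <- suppressWarnings(consolidateIndividuals(s))
  i2 <- suppressWarnings(consolidateIndividuals(s2))
  groups1 <- lapply(memberSamples(i1), sort)
  groups2 <- lapply(memberSamples(i2), sort)
  expect_setequal(unname(vapply(groups1, paste, character(1), collapse = ",")),
                  unname(vapply(groups2, paste, character(1), collapse = ",")))
})

test_that("mapping is total over retained samples and single-valued", {
  cfg <- simulationConfig(nFounders = 20, nGenerations = 3, samplingFraction = 1,
                          replicateFraction = 0.5, seed = 13)
  out <- simulateConsolidated(cfg)
  mapping <- attr(out$individuals, "mapping")
  retained <- setdiff(sampleInfo(out$samples)$sample_id,
                      attr(out$individuals, "excluded"))
  expect_setequal(names(mapping), retained)
  expect_true(all(unname(mapping) %in% sampleInfo(out$individuals)$individual_id))
})

test_that("consensus ties resolve toward the heterozygote", {
  g <- toyGeno(list(c(1L, 1L, 3L, 3L, 5L, 6L, 7L, 8L, 1L, 1L),
                    c(1L, 2L, 3L, 3L, 5L, 6L, 7L, 8L, 1L, 1L)))
  ind <- consolidateIndividuals(toySamples(g), minLoci = 5)
  expect_equal(nrow(sampleInfo(ind)), 1)
  expect_equal(unname(genotypes(ind)[1, c("L01_a1", "L01_a2")]), c(1L, 2L))
})

test_that("sex conflicts yield unknown with a warning", {
  g <- toyGeno(list(c(1L, 2L, 3L, 3L, 5L, 6L, 7L, 8L, 1L, 1L),
                    c(1L, 2L, 3L, 3L, 5L, 6L, 7L, 8L, 1L, 1L)))
  s <- toySamples(g, sex = c("F", "M"))
  expect_warning(ind <- consolidateIndividuals(s, minLoci = 5), "conflict")
  expect_equal(sampleInfo(ind)$sex, "unknown")
})

test_that("success percentages follow the published-table arithmetic", {
  counts <- data.frame(stratum = "Flin Flon", collected = 336, scored = 320)
  rep <- qcFromCounts(counts)
  expect_equal(rep$strata$success_pct, 95.2)

  seven <- data.frame(stratum = paste0("s", 1:7),
                      collected = rep(1000, 7),
                      scored = c(952, 811, 963, 905, 821, 990, 955))
  expect_equal(qcFromCounts(seven)$overall$mean_success_pct,
               famnet:::roundHalfUp(mean(c(95.2, 81.1, 96.3, 90.5, 82.1, 99, 95.5)), 1))

  zero <- qcFromCounts(data.frame(stratum = "z", collected = 10, scored = 0))
  expect_equal(zero$strata$success_pct, 0)
  undef <- qcFromCounts(data.frame(stratum = "e", collected = 0, scored = 0))
  expect_true(is.na(undef$strata$success_pct))
  expect_error(qcFromCounts(data.frame(stratum = "bad", collected = 5, scored = 6)),
               "exceed")
})

test_that("replicate-based error rates recover injected dropout (smoke scale)", {
  cfg <- simulationConfig(nFounders = 150, nGenerations = 3, samplingFraction = 1,
                          dropoutRate = 0.05, falseAlleleRate = 0,
                          locusFailureRate = 0, replicateFraction = 1, seed = 17)
  pop <- simulatePopulation(cfg)
  s <- applySamplingAndError(pop, cfg)
  ids <- sampleInfo(s)$sample_id
  base <- sub("_S[0-9]+$", "", ids)
  dup <- names(which(table(base) == 2))
  pairs <- data.frame(sample1 = paste0(dup, "_S1"), sample2 = paste0(dup, "_S2"))
  rep <- qcSummary(s, replicatePairs = pairs)
  # each pair-locus comparison sees two independently degraded replicates;
  # a single dropout in either shows up as one discordance
  expect_gt(rep$overall$dropout_rate, 0.02)
  expect_lt(rep$overall$dropout_rate, 0.09)
  expect_lt(rep$overall$false_allele_rate, 0.01)
})

test_that("QC percentages recomputed from counts match to one decimal", {
  cfg <- simulationConfig(nFounders = 40, nGenerations = 3, seed = 21,
                          samplingFraction = 0.8)
  out <- simulateConsolidated(cfg)
  qc <- qcSummary(out$samples, mapping = attr(out$individuals, "mapping"))
  with(qc$strata, expect_equal(success_pct,
                               famnet:::roundHalfUp(100 * scored / collected, 1)))
  expect_true(all(qc$strata$scored <= qc$strata$collected))
  expect_true(all(qc$strata$success_pct >= 0 & qc$strata$success_pct <= 100))
})
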