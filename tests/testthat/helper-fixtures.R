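# Fixture builders shared across test files.

# Build a FamilialNetwork directly from node ids and a parent->offspring
# edge table (all nodes sampled unless stated).
makeNet <- function(ids, edges = data.frame(from = character(0), to = character(0)),
                    sampled = rep(TRUE, length(ids)),
                    x = rep(NA_real_, length(ids)),
                    y = rep(NA_real_, length(ids)),
                    area = rep(NA_character_, length(ids)),
                    sex = rep("unknown", length(ids))) {
  nodes <- data.frame(id = ids, sampled = sampled, sex = sex,
                      x = x, y = y, area = area, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes["id"])
  methods::new("FamilialNetwork", graph = g, nodes = nodes)
}

# Random pedigree-shaped DAG: node i may take up to 2 parents among earlier
# nodes, giving in-degree <= 2 and acyclicity by construction.
randomFamNet <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  from <- character(0); to <- character(0)
  for (i in seq_len(n)[-1]) {
    k <- sample(0:min(2L, i - 1L), 1)
    if (k > 0) {
      par <- sample(ids[seq_len(i - 1L)], k)
      from <- c(from, par); to <- c(to, rep(ids[i], k))
    }
  }
  makeNet(ids, data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

# Genotype matrix from a list of per-sample integer vectors (2 per locus).
toyGeno <- function(rows, loci = sprintf("L%02d", seq_len(length(rows[[1]]) / 2))) {
  m <- do.call(rbind, rows)
  colnames(m) <- as.vector(rbind(paste0(loci, "_a1"), paste0(loci, "_a2")))
  storage.mode(m) <- "integer"
  m
}

toySamples <- function(geno, ids = sprintf("S%02d", seq_len(nrow(geno))),
                       stratum = "all", sex = "unknown",
                       x = 0, y = 0) {
  info <- data.frame(sample_id = ids, stratum = stratum, sex = sex,
                     x = x, y = y, stringsAsFactors = FALSE)
  GenotypeSamples(info, geno)
}

# IndividualSet built directly (bypassing consolidation) for parentage tests.
toyIndividuals <- function(geno, ids = sprintf("I%02d", seq_len(nrow(geno))),
                           sex, stratum = "all", x = 0, y = 0) {
  info <- data.frame(individual_id = ids, sex = sex, sampled = TRUE,
                     stratum = stratum, x = x, y = y,
                     n_samples = 1L, stringsAsFactors = FALSE)
  g <- famnet::normalizeGenotypes(geno)
  rownames(g) <- ids
  methods::new("IndividualSet", info = info, geno = g,
               members = stats::setNames(as.list(ids), ids))
}

# Uniform frequency table over allele codes `alleles` at `nl` loci.
uniformFreqs <- function(nl = 1, alleles = c(1L, 2L)) {
  f <- stats::setNames(rep(1 / length(alleles), length(alleles)),
                       as.character(alleles))
  FrequencyTable(stats::setNames(rep(list(f), nl), sprintf("L%02d", seq_len(nl))))
}

# End-to-end: simulate, sample, consolidate; returns all the pieces.
simulateConsolidated <- function(cfg) {
  pop <- simulatePopulation(cfg)
  samples <- applySamplingAndError(pop, cfg)
  individuals <- suppressWarnings(consolidateIndividuals(samples))
  list(pop = pop, samples = samples, individuals = individuals)
}
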