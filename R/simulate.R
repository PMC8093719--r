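# Spatial population simulator with known truth: multi-generation polygamous
# demography, spatially clustered families with sex-specific dispersal,
# multilocus microsatellite genotypes, and the noninvasive-sampling error
# processes (allelic dropout, false alleles, locus amplification failure).

#' Default spatial cluster layout
#'
#' Six labelled clusters on a planar grid; half are strongly philopatric
#' (offspring settle close to the dam), half are dispersal-prone, emulating
#' the contrast between tight family areas and areas occupied by loosely
#' related individuals.
#'
#' @param spacing Distance between neighbouring cluster centres (map units).
#' @return data.frame with columns \code{area}, \code{x}, \code{y},
#'   \code{spread} (founder scatter SD) and \code{philopatry} in [0, 1]
#'   (1 = offspring settle exactly at the dam's location).
#' @export
defaultAreaLayout <- function(spacing = 100) {
  data.frame(
    area = c("A1", "A2", "A3", "B1", "B2", "B3"),
    x = spacing * c(0, 1, 2, 0, 1, 2),
    y = spacing * c(0, 0, 0, 1, 1, 1),
    spread = 10,
    philopatry = c(0.8, 0.8, 0.8, 0.1, 0.1, 0.1),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles and validates all simulator parameters. The defaults describe the
#' study-like conditions: 15 microsatellite loci, partial (20\%) sampling,
#' small per-allele genotyping error rates, female philopatry and
#' longer-range male dispersal.
#'
#' @param nFounders Number of founder individuals (generation 0).
#' @param nGenerations Total number of generations including founders.
#' @param meanOffspringPerFemale Poisson mean litter size per female.
#' @param polygamy If TRUE (default) each offspring's sire is drawn
#'   independently, so individuals can have several mates.
#' @param nLoci,allelesPerLocus Microsatellite panel dimensions.
#' @param dispersalScaleFemale,dispersalScaleMale SD (map units) of the
#'   isotropic Gaussian offspring settlement displacement from the dam,
#'   before philopatry scaling. Scales are meaningful only relative to the
#'   layout's cluster spacing (default 100): a disperser must move about
#'   half the spacing to settle in a different area, so the male default
#'   (80) lets dispersal-prone offspring routinely leave their natal
#'   cluster while the female default (20) rarely does.
#' @param matingScale SD of the Gaussian distance kernel used to pick sires.
#' @param areaLayout data.frame of labelled clusters, see
#'   \code{\link{defaultAreaLayout}}.
#' @param samplingFraction Bernoulli probability that an individual is
#'   sampled at all.
#' @param dropoutRate Per-allele allelic dropout probability at
#'   heterozygous loci.
#' @param falseAlleleRate Per-allele probability of a spurious allele call.
#' @param locusFailureRate Per-locus probability that a locus fails to
#'   amplify in a sample (yields a missing locus).
#' @param replicateFraction Fraction of sampled individuals re-amplified as
#'   a second, independent sample (enables dropout/false-allele QC).
#' @param seed Integer seed; identical configurations reproduce identical
#'   populations byte for byte.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nFounders = 60, nGenerations = 4,
                             meanOffspringPerFemale = 2, polygamy = TRUE,
                             nLoci = 15, allelesPerLocus = 8,
                             dispersalScaleFemale = 20, dispersalScaleMale = 80,
                             matingScale = 50, areaLayout = defaultAreaLayout(),
                             samplingFraction = 0.20, dropoutRate = 0.0077,
                             falseAlleleRate = 0.032, locusFailureRate = 0.02,
                             replicateFraction = 0.2, seed = 1L) {
  probs <- c(samplingFraction = samplingFraction, dropoutRate = dropoutRate,
             falseAlleleRate = falseAlleleRate, locusFailureRate = locusFailureRate,
             replicateFraction = replicateFraction)
  if (any(probs < 0 | probs > 1))
    stop("invalid argument: probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  counts <- c(nFounders = nFounders, nGenerations = nGenerations,
              nLoci = nLoci, allelesPerLocus = allelesPerLocus)
  if (any(counts < 1))
    stop("invalid argument: counts must be >= 1: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  if (meanOffspringPerFemale <= 0)
    stop("invalid argument: meanOffspringPerFemale must be > 0")
  stopifnot(is.data.frame(areaLayout),
            all(c("area", "x", "y", "spread", "philopatry") %in% colnames(areaLayout)))
  if (any(areaLayout$philopatry < 0 | areaLayout$philopatry > 1))
    stop("invalid argument: philopatry levels must lie in [0, 1]")
  cfg <- list(nFounders = as.integer(nFounders),
              nGenerations = as.integer(nGenerations),
              meanOffspringPerFemale = meanOffspringPerFemale,
              polygamy = isTRUE(polygamy),
              nLoci = as.integer(nLoci),
              allelesPerLocus = as.integer(allelesPerLocus),
              dispersalScaleFemale = dispersalScaleFemale,
              dispersalScaleMale = dispersalScaleMale,
              matingScale = matingScale, areaLayout = areaLayout,
              samplingFraction = samplingFraction, dropoutRate = dropoutRate,
              falseAlleleRate = falseAlleleRate,
              locusFailureRate = locusFailureRate,
              replicateFraction = replicateFraction, seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Draw per-locus allele frequencies
#'
#' Frequencies at each locus are drawn from a symmetric Dirichlet(1), which
#' keeps loci exchangeable. Allele labels mimic fragment sizes (101, 103,
#' ...), shared across loci.
#'
#' @param nLoci Number of loci (>= 1).
#' @param allelesPerLocus Number of alleles per locus (>= 1).
#' @param seed Integer seed; the draw is deterministic per seed.
#' @return A \code{\link{FrequencyTable}}.
#' @export
drawAlleleFrequencies <- function(nLoci = 15, allelesPerLocus = 8, seed = 1L) {
  if (nLoci < 1 || allelesPerLocus < 1)
    stop("invalid argument: nLoci and allelesPerLocus must be >= 1")
  set.seed(as.integer(seed))
  alleles <- as.character(101L + 2L * (seq_len(allelesPerLocus) - 1L))
  loci <- sprintf("L%02d", seq_len(nLoci))
  freqs <- lapply(loci, function(l) {
    repeat {
      g <- rgamma(allelesPerLocus, shape = 1, rate = 1)
      if (all(g > 0)) break
    }
    stats::setNames(g / sum(g), alleles)
  })
  names(freqs) <- loci
  FrequencyTable(freqs)
}

nearestArea <- function(x, y, layout) {
  d2 <- outer(x, layout$x, "-")^2 + outer(y, layout$y, "-")^2
  layout$area[max.col(-d2, ties.method = "first")]
}

#' Simulate a spatial population with known pedigree
#'
#' Discrete non-overlapping generations. Founders are scattered around the
#' layout's cluster centres and genotyped by Hardy-Weinberg draws from a
#' Dirichlet-drawn frequency table. Each female produces a Poisson number of
#' offspring; sires are chosen among same-generation males with a Gaussian
#' distance kernel (independently per offspring under polygamy, one mate per
#' female otherwise). Offspring inherit one allele per locus from each
#' parent and settle at the dam's location plus an isotropic Gaussian
#' displacement whose SD is the sex-specific dispersal scale shrunk by the
#' natal area's philopatry level.
#'
#' If some generation has no females or no males, reproduction stops and the
#' returned population carries an \code{emptyGeneration} attribute naming
#' the first empty generation instead of crashing.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return A \code{\link{TruePopulation}}.
#' @export
simulatePopulation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  freqs <- drawAlleleFrequencies(config$nLoci, config$allelesPerLocus,
                                 seed = config$seed)
  set.seed(config$seed + 1L)
  layout <- config$areaLayout
  loci <- lociNames(freqs)
  phil <- stats::setNames(layout$philopatry, layout$area)

  n0 <- config$nFounders
  id <- sprintf("IND%05d", seq_len(n0))
  sex <- sample(c("F", "M"), n0, replace = TRUE)
  area0 <- sample(layout$area, n0, replace = TRUE)
  ctr <- match(area0, layout$area)
  x <- layout$x[ctr] + rnorm(n0, 0, layout$spread[ctr])
  y <- layout$y[ctr] + rnorm(n0, 0, layout$spread[ctr])
  geno <- emptyGenoMatrix(n0, loci)
  drawAlleles <- function(al, f, n) al[sample.int(length(al), n, TRUE, prob = f)]
  for (l in seq_along(loci)) {
    f <- freqs@freqs[[l]]
    al <- as.integer(names(f))
    geno[, locusCols(l)] <- cbind(drawAlleles(al, f, n0), drawAlleles(al, f, n0))
  }

  ind <- data.frame(id = id, sex = sex, generation = 0L, x = x, y = y,
                    area = nearestArea(x, y, layout), stringsAsFactors = FALSE)
  ped <- data.frame(offspring_id = character(0), dam_id = character(0),
                    sire_id = character(0), generation = integer(0),
                    stringsAsFactors = FALSE)
  nextId <- n0 + 1L
  emptyGen <- NA_integer_

  for (g in seq_len(config$nGenerations - 1L)) {
    prev <- ind[ind$generation == g - 1L, ]
    fem <- prev[prev$sex == "F", ]
    mal <- prev[prev$sex == "M", ]
    if (nrow(fem) == 0L || nrow(mal) == 0L) { emptyGen <- g; break }

    nOff <- rpois(nrow(fem), config$meanOffspringPerFemale)
    damRows <- rep(seq_len(nrow(fem)), nOff)
    nTot <- length(damRows)
    if (nTot == 0L) { emptyGen <- g; break }

    # sire choice: Gaussian distance kernel around each dam
    kern <- function(di) {
      w <- exp(-0.5 * ((fem$x[di] - mal$x)^2 + (fem$y[di] - mal$y)^2) /
                 config$matingScale^2)
      if (sum(w) <= 0) w <- rep(1, nrow(mal))
      w
    }
    if (config$polygamy) {
      sireRows <- vapply(damRows, function(di)
        sample.int(nrow(mal), 1L, prob = kern(di)), integer(1))
    } else {
      # monogamy: each breeding female keeps a single mate, chosen without
      # replacement; females left without an available male do not breed
      mate <- rep(NA_integer_, nrow(fem))
      avail <- seq_len(nrow(mal))
      for (di in sample.int(nrow(fem))) {
        if (!length(avail)) break
        w <- kern(di)[avail]
        pick <- if (length(avail) == 1L) avail else
          avail[sample.int(length(avail), 1L, prob = w)]
        mate[di] <- pick
        avail <- setdiff(avail, pick)
      }
      keep <- !is.na(mate[damRows])
      damRows <- damRows[keep]
      sireRows <- mate[damRows]
      nTot <- length(damRows)
      if (nTot == 0L) { emptyGen <- g; break }
    }

    offId <- sprintf("IND%05d", seq.int(nextId, length.out = nTot))
    nextId <- nextId + nTot
    offSex <- sample(c("F", "M"), nTot, replace = TRUE)

    offGeno <- emptyGenoMatrix(nTot, loci)
    damG <- geno[match(fem$id[damRows], ind$id), , drop = FALSE]
    sireG <- geno[match(mal$id[sireRows], ind$id), , drop = FALSE]
    for (l in seq_along(loci)) {
      cc <- locusCols(l)
      fromDam <- ifelse(runif(nTot) < 0.5, damG[, cc[1]], damG[, cc[2]])
      fromSire <- ifelse(runif(nTot) < 0.5, sireG[, cc[1]], sireG[, cc[2]])
      offGeno[, cc] <- cbind(fromDam, fromSire)
    }

    sexScale <- ifelse(offSex == "F", config$dispersalScaleFemale,
                       config$dispersalScaleMale)
    sigma <- sexScale * (1 - phil[fem$area[damRows]])
    offX <- fem$x[damRows] + rnorm(nTot, 0, sigma)
    offY <- fem$y[damRows] + rnorm(nTot, 0, sigma)

    ind <- rbind(ind, data.frame(
      id = offId, sex = offSex, generation = g, x = offX, y = offY,
      area = nearestArea(offX, offY, layout), stringsAsFactors = FALSE))
    geno <- rbind(geno, offGeno)
    ped <- rbind(ped, data.frame(
      offspring_id = offId, dam_id = fem$id[damRows],
      sire_id = mal$id[sireRows], generation = g, stringsAsFactors = FALSE))
  }

  rownames(geno) <- ind$id
  pop <- new("TruePopulation", individuals = ind, pedigree = ped,
             geno = normalizeGenotypes(geno), freqs = freqs)
  attr(pop, "emptyGeneration") <- emptyGen
  pop
}

#' Apply partial sampling and genotyping error to a true population
#'
#' Individuals are sampled independently with probability
#' \code{samplingFraction}; a fraction of sampled individuals yields a
#' second, independent replicate sample. Each sample's observed genotype is
#' the true genotype degraded by (i) whole-locus amplification failure,
#' (ii) allelic dropout -- at a heterozygous locus each allele is lost with
#' the stated per-allele probability, turning the genotype into a false
#' homozygote (both lost: missing locus) -- and (iii) false alleles, where
#' an allele call is replaced by a uniformly chosen different allele of that
#' locus.
#'
#' @param pop A \code{\link{TruePopulation}}.
#' @param config The \code{\link{simulationConfig}} holding the rates.
#' @param seed Seed for the sampling/error draws; defaults to
#'   \code{config$seed + 1}.
#' @return A \code{\link{GenotypeSamples}} object. Attribute
#'   \code{trueIndividual} maps each sample id to the underlying true
#'   individual id.
#' @export
applySamplingAndError <- function(pop, config, seed = config$seed + 1L) {
  stopifnot(is(pop, "TruePopulation"), inherits(config, "SimulationConfig"))
  rates <- c(config$dropoutRate, config$falseAlleleRate,
             config$locusFailureRate, config$samplingFraction,
             config$replicateFraction)
  if (any(rates < 0 | rates > 1))
    stop("invalid argument: rates must lie in [0, 1]")
  set.seed(as.integer(seed))

  ind <- pop@individuals
  take <- runif(nrow(ind)) < config$samplingFraction
  sampled <- ind[take, , drop = FALSE]
  nS <- nrow(sampled)
  loci <- lociNames(pop)
  if (nS == 0L) {
    emptyInfo <- data.frame(sample_id = character(0), stratum = character(0),
                            year = integer(0), source = character(0),
                            sex = character(0), x = numeric(0), y = numeric(0),
                            stringsAsFactors = FALSE)
    out <- GenotypeSamples(emptyInfo, emptyGenoMatrix(0, loci))
    attr(out, "trueIndividual") <- stats::setNames(character(0), character(0))
    return(out)
  }

  reps <- 1L + as.integer(runif(nS) < config$replicateFraction)
  rowIdx <- rep(seq_len(nS), reps)
  repNo <- unlist(lapply(reps, seq_len))
  trueId <- sampled$id[rowIdx]
  sampleId <- paste0(trueId, "_S", repNo)

  geno <- pop@geno[match(trueId, ind$id), , drop = FALSE]
  n <- nrow(geno)
  alleleSets <- lapply(pop@freqs@freqs, function(f) as.integer(names(f)))

  for (l in seq_along(loci)) {
    cc <- locusCols(l)
    a <- geno[, cc[1]]
    b <- geno[, cc[2]]
    fail <- runif(n) < config$locusFailureRate
    a[fail] <- NA_integer_; b[fail] <- NA_integer_

    het <- !is.na(a) & a != b
    d1 <- het & (runif(n) < config$dropoutRate)
    d2 <- het & (runif(n) < config$dropoutRate)
    both <- d1 & d2
    a[d1 & !both] <- b[d1 & !both]   # first allele lost -> homozygote of b
    b[d2 & !both] <- a[d2 & !both]
    a[both] <- NA_integer_; b[both] <- NA_integer_

    al <- alleleSets[[l]]
    if (length(al) > 1L) {
      swapOther <- function(v) {
        hit <- !is.na(v) & (runif(n) < config$falseAlleleRate)
        for (i in which(hit)) {
          others <- al[al != v[i]]
          v[i] <- others[sample.int(length(others), 1L)]
        }
        v
      }
      a <- swapOther(a)
      b <- swapOther(b)
    }
    geno[, cc[1]] <- a
    geno[, cc[2]] <- b
  }

  info <- data.frame(sample_id = sampleId, stratum = sampled$area[rowIdx],
                     year = 2000L + sampled$generation[rowIdx],
                     source = "synthetic", sex = sampled$sex[rowIdx],
                     x = sampled$x[rowIdx], y = sampled$y[rowIdx],
                     stringsAsFactors = FALSE)
  out <- GenotypeSamples(info, geno)
  attr(out, "trueIndividual") <- stats::setNames(trueId, sampleId)
  out
}
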