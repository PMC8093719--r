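# Accessors and show() methods.

lociFromGeno <- function(geno) {
  cn <- colnames(geno)
  unique(sub("_a[12]$", "", cn))
}

#' @rdname lociNames
#' @export
setMethod("lociNames", "FrequencyTable", function(x) names(x@freqs))
#' @rdname lociNames
#' @export
setMethod("lociNames", "GenotypeSamples", function(x) lociFromGeno(x@geno))
#' @rdname lociNames
#' @export
setMethod("lociNames", "IndividualSet", function(x) lociFromGeno(x@geno))
#' @rdname lociNames
#' @export
setMethod("lociNames", "TruePopulation", function(x) lociFromGeno(x@geno))

#' @rdname nLoci
#' @export
setMethod("nLoci", "FrequencyTable", function(x) length(x@freqs))
#' @rdname nLoci
#' @export
setMethod("nLoci", "GenotypeSamples", function(x) ncol(x@geno) %/% 2L)
#' @rdname nLoci
#' @export
setMethod("nLoci", "IndividualSet", function(x) ncol(x@geno) %/% 2L)
#' @rdname nLoci
#' @export
setMethod("nLoci", "TruePopulation", function(x) ncol(x@geno) %/% 2L)

#' @rdname genotypes
#' @export
setMethod("genotypes", "GenotypeSamples", function(x) x@geno)
#' @rdname genotypes
#' @export
setMethod("genotypes", "IndividualSet", function(x) x@geno)
#' @rdname genotypes
#' @export
setMethod("genotypes", "TruePopulation", function(x) x@geno)

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "GenotypeSamples", function(x) x@info)
#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "IndividualSet", function(x) x@info)
#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "TruePopulation", function(x) x@individuals)

#' @rdname pedigree
#' @export
setMethod("pedigree", "TruePopulation", function(x) x@pedigree)

#' @rdname asGraph
#' @export
setMethod("asGraph", "FamilialNetwork", function(x) x@graph)

#' @rdname nodeData
#' @export
setMethod("nodeData", "FamilialNetwork", function(x) x@nodes)

#' Allele frequencies at one locus
#' @param x A \code{FrequencyTable}.
#' @param locus Locus name.
#' @return Named numeric vector of allele frequencies.
#' @export
alleleFreqs <- function(x, locus) {
  stopifnot(is(x, "FrequencyTable"))
  if (!locus %in% names(x@freqs)) stop("unknown locus: ", locus)
  x@freqs[[locus]]
}

#' Member samples of consolidated individuals
#' @param x An \code{IndividualSet}.
#' @return Named list, individual id -> member sample ids.
#' @export
memberSamples <- function(x) {
  stopifnot(is(x, "IndividualSet"))
  x@members
}

setMethod("show", "FrequencyTable", function(object) {
  k <- lengths(object@freqs)
  cat(sprintf("FrequencyTable: %d loci, %d-%d alleles per locus\n",
              length(object@freqs), min(k), max(k)))
})

setMethod("show", "GenotypeSamples", function(object) {
  typed <- typedLociCount(object@geno)
  cat(sprintf("GenotypeSamples: %d samples x %d loci (%d strata)\n",
              nrow(object@info), ncol(object@geno) %/% 2L,
              length(unique(object@info$stratum))))
  if (nrow(object@info))
    cat(sprintf("  typed loci per sample: median %.0f [%d-%d]\n",
                stats::median(typed), min(typed), max(typed)))
})

setMethod("show", "IndividualSet", function(object) {
  cat(sprintf("IndividualSet: %d individuals (%d sampled, %d inferred)\n",
              nrow(object@info), sum(object@info$sampled),
              sum(!object@info$sampled)))
})

setMethod("show", "TruePopulation", function(object) {
  gens <- range(object@individuals$generation)
  cat(sprintf("TruePopulation: %d individuals, generations %d-%d, %d pedigree rows\n",
              nrow(object@individuals), gens[1], gens[2], nrow(object@pedigree)))
})

setMethod("show", "FamilialNetwork", function(object) {
  cat(sprintf("FamilialNetwork: %d nodes (%d sampled, %d inferred), %d parent->offspring edges\n",
              nrow(object@nodes), sum(object@nodes$sampled),
              sum(!object@nodes$sampled), igraph::ecount(object@graph)))
})
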