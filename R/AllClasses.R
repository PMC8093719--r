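#' @import methods
#' @importFrom stats rbinom rgamma rnorm rpois runif sd quantile median cor prcomp complete.cases
#' @importFrom utils read.csv write.csv head
NULL

#' FrequencyTable: per-locus allele frequencies
#'
#' Holds, for each microsatellite locus, a named numeric vector of allele
#' frequencies. Allele names are character labels (typically fragment sizes);
#' frequencies at each locus are strictly positive and sum to one.
#'
#' @slot freqs Named list; one named numeric vector per locus.
#' @export
setClass("FrequencyTable", representation(freqs = "list"))

setValidity("FrequencyTable", function(object) {
  f <- object@freqs
  if (length(f) == 0L) return("at least one locus is required")
  if (is.null(names(f)) || anyDuplicated(names(f)))
    return("loci must have unique names")
  for (l in names(f)) {
    v <- f[[l]]
    if (!is.numeric(v) || length(v) == 0L || is.null(names(v)))
      return(sprintf("locus %s: frequencies must be a named numeric vector", l))
    if (any(v <= 0)) return(sprintf("locus %s: all frequencies must be > 0", l))
    if (abs(sum(v) - 1) > 1e-9)
      return(sprintf("locus %s: frequencies must sum to 1 (got %.12f)", l, sum(v)))
  }
  TRUE
})

#' Construct a FrequencyTable
#'
#' @param freqs Named list of named numeric vectors (allele -> frequency),
#'   one element per locus.
#' @return A \code{FrequencyTable} object.
#' @export
FrequencyTable <- function(freqs) new("FrequencyTable", freqs = freqs)

#' GenotypeSamples: a collection of genotyped field/lab samples
#'
#' Tabular container pairing per-sample metadata with a genotype matrix.
#' The genotype matrix has two integer columns per locus
#' (\code{<locus>_a1}, \code{<locus>_a2}); allele pairs are unordered and
#' stored sorted; a missing locus has both entries \code{NA}.
#'
#' @slot info data.frame with columns \code{sample_id}, \code{stratum},
#'   \code{sex} ("F", "M" or "unknown"), \code{x}, \code{y} (may be NA).
#' @slot geno Integer matrix, rows aligned with \code{info}, rownames =
#'   sample ids.
#' @export
setClass("GenotypeSamples", representation(info = "data.frame", geno = "matrix"))

setValidity("GenotypeSamples", function(object) {
  needed <- c("sample_id", "stratum", "sex", "x", "y")
  miss <- setdiff(needed, colnames(object@info))
  if (length(miss)) return(paste("info lacks columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(object@info$sample_id)) {
    dup <- unique(object@info$sample_id[duplicated(object@info$sample_id)])
    return(paste("duplicate sample ids:", paste(dup, collapse = ", ")))
  }
  if (nrow(object@geno) != nrow(object@info))
    return("geno and info row counts differ")
  if (nrow(object@geno) > 0 && !identical(rownames(object@geno),
                                          as.character(object@info$sample_id)))
    return("geno rownames must equal info$sample_id")
  if (ncol(object@geno) %% 2L != 0L)
    return("geno must have two columns per locus")
  if (!all(object@info$sex %in% c("F", "M", "unknown")))
    return("sex must be F, M or unknown")
  TRUE
})

#' Construct a GenotypeSamples object
#'
#' @param info Sample metadata data.frame (see class docs).
#' @param geno Genotype matrix, two columns per locus; allele pairs are
#'   normalized (sorted, half-missing pairs set fully missing).
#' @return A \code{GenotypeSamples} object.
#' @export
GenotypeSamples <- function(info, geno) {
  info$sample_id <- as.character(info$sample_id)
  geno <- normalizeGenotypes(geno)
  rownames(geno) <- info$sample_id
  rownames(info) <- NULL
  new("GenotypeSamples", info = info, geno = geno)
}

#' IndividualSet: consolidated unique individuals
#'
#' Each row is one individual: a consensus multilocus genotype plus sex,
#' representative coordinates and stratum, a sampled/inferred flag, and the
#' ids of the member samples it was consolidated from.
#'
#' @slot info data.frame with columns \code{individual_id}, \code{sex},
#'   \code{sampled}, \code{stratum}, \code{x}, \code{y}, \code{n_samples}.
#' @slot geno Consensus genotype matrix (same layout as
#'   \code{GenotypeSamples}).
#' @slot members Named list: individual id -> character vector of member
#'   sample ids.
#' @export
setClass("IndividualSet",
         representation(info = "data.frame", geno = "matrix", members = "list"))

setValidity("IndividualSet", function(object) {
  needed <- c("individual_id", "sex", "sampled", "stratum", "x", "y", "n_samples")
  miss <- setdiff(needed, colnames(object@info))
  if (length(miss)) return(paste("info lacks columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(object@info$individual_id)) return("duplicate individual ids")
  if (nrow(object@geno) != nrow(object@info)) return("geno and info row counts differ")
  samp <- object@info$sampled
  n <- object@info$n_samples
  if (any(samp & n < 1L)) return("sampled individuals need >= 1 member sample")
  TRUE
})

#' TruePopulation: simulated population with known truth
#'
#' Ground-truth output of the simulator: every individual's true genotype,
#' sex, birth generation, coordinates and natal/settlement area, plus the
#' true pedigree (one dam and one sire per non-founder).
#'
#' @slot individuals data.frame: \code{id}, \code{sex}, \code{generation},
#'   \code{x}, \code{y}, \code{area}.
#' @slot pedigree data.frame: \code{offspring_id}, \code{dam_id},
#'   \code{sire_id}, \code{generation}.
#' @slot geno True genotype matrix (no errors, no missing loci).
#' @slot freqs The \code{FrequencyTable} the founders were drawn from.
#' @export
setClass("TruePopulation",
         representation(individuals = "data.frame", pedigree = "data.frame",
                        geno = "matrix", freqs = "FrequencyTable"))

setValidity("TruePopulation", function(object) {
  ind <- object@individuals
  ped <- object@pedigree
  if (anyDuplicated(ind$id)) return("duplicate individual ids")
  if (nrow(ped)) {
    if (anyDuplicated(ped$offspring_id)) return("offspring listed twice in pedigree")
    if (!all(ped$offspring_id %in% ind$id)) return("pedigree references unknown offspring")
    if (!all(c(ped$dam_id, ped$sire_id) %in% ind$id))
      return("pedigree references unknown parents")
    sex <- stats::setNames(ind$sex, ind$id)
    if (!all(sex[ped$dam_id] == "F")) return("a dam is not female")
    if (!all(sex[ped$sire_id] == "M")) return("a sire is not male")
    gen <- stats::setNames(ind$generation, ind$id)
    if (!all(gen[ped$dam_id] < gen[ped$offspring_id] &
             gen[ped$sire_id] < gen[ped$offspring_id]))
      return("parents must be born before offspring (pedigree must be acyclic)")
  }
  TRUE
})

#' FamilialNetwork: directed parent-to-offspring graph
#'
#' The central object of the pipeline. Nodes are individuals (sampled or
#' inferred); each directed edge runs from a parent to one of its offspring.
#' The graph is simple and acyclic; in-degree is at most 2 (one dam, one
#' sire) and inferred individuals always have in-degree 0, since their own
#' parents cannot be inferred.
#'
#' @slot graph An \code{igraph} directed graph.
#' @slot nodes data.frame of node attributes: \code{id}, \code{sampled},
#'   \code{sex}, \code{x}, \code{y}, \code{area} (coordinates/area NA for
#'   inferred individuals).
#' @export
setClass("FamilialNetwork", representation(graph = "ANY", nodes = "data.frame"))

setValidity("FamilialNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (!igraph::is_directed(g)) return("graph must be directed")
  nd <- object@nodes
  if (!identical(sort(nd$id), sort(igraph::V(g)$name)))
    return("node table and graph vertices disagree")
  if (igraph::ecount(g) > 0) {
    if (igraph::any_loop(g)) return("self-loops are impossible in a pedigree")
    if (igraph::any_multiple(g)) return("parallel edges are impossible in a pedigree")
    if (!igraph::is_dag(g)) return("familial network must be acyclic")
    indeg <- igraph::degree(g, mode = "in")
    if (any(indeg > 2L)) return("in-degree cannot exceed 2 (one dam, one sire)")
    inferred <- nd$id[!nd$sampled]
    if (length(inferred) && any(indeg[inferred] > 0L))
      return("inferred individuals must have in-degree 0")
  }
  TRUE
})
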