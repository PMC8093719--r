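# Generics shared across the package's S4 classes.

#' Locus names of an object
#' @param x An object carrying per-locus genotype data.
#' @return Character vector of locus names.
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' Number of loci
#' @param x An object carrying per-locus genotype data.
#' @return Integer count of loci.
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' Genotype matrix of an object
#' @param x An object carrying genotypes.
#' @return Integer matrix with two columns per locus.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' Sample or individual metadata table
#' @param x A container with a metadata table.
#' @return A data.frame.
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' Pedigree table of an object
#' @param x An object holding a pedigree.
#' @return data.frame of offspring/dam/sire rows.
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' Underlying igraph graph
#' @param x An object wrapping a graph.
#' @return An igraph object.
#' @export
setGeneric("asGraph", function(x) standardGeneric("asGraph"))

#' Node attribute table of a network
#' @param x A network object.
#' @return data.frame of node attributes.
#' @export
setGeneric("nodeData", function(x) standardGeneric("nodeData"))
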