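# Helpers for validating reconstruction against simulator truth.

#' Map consolidated individuals back to true simulated individuals
#'
#' Composes the sample -> true-individual map recorded by
#' \code{\link{applySamplingAndError}} with the sample -> individual map
#' from \code{\link{consolidateIndividuals}}. An individual consolidated
#' from samples of several true individuals (an over-merge) maps to NA.
#'
#' @param samples The \code{\link{GenotypeSamples}} carrying the
#'   \code{trueIndividual} attribute.
#' @param individuals The \code{\link{IndividualSet}} carrying the
#'   \code{mapping} attribute.
#' @return Named character vector: individual id -> true id (NA on
#'   over-merge).
#' @export
trueIdMap <- function(samples, individuals) {
  s2t <- attr(samples, "trueIndividual")
  s2i <- attr(individuals, "mapping")
  if (is.null(s2t) || is.null(s2i))
    stop("inputs lack the trueIndividual / mapping attributes")
  common <- intersect(names(s2t), names(s2i))
  tapplyRes <- tapply(s2t[common], s2i[common], function(x) {
    u <- unique(x)
    if (length(u) == 1L) u else NA_character_
  })
  stats::setNames(as.character(tapplyRes), names(tapplyRes))
}

#' Compare an assigned pedigree with the simulator truth
#'
#' Scores the assignment's sampled-parent edges (parent -> offspring)
#' against the true pedigree's edges between sampled individuals: recall is
#' the fraction of true sampled-to-sampled edges recovered, precision the
#' fraction of assigned sampled-parent edges that are true.
#'
#' @param truePed True pedigree data.frame (\code{offspring_id},
#'   \code{dam_id}, \code{sire_id}) in true ids.
#' @param ped Assigned \code{PedigreeTable} in consolidated ids.
#' @param indToTrue Named map from consolidated to true ids (see
#'   \code{\link{trueIdMap}}).
#' @return List with \code{recall}, \code{precision}, \code{n_true_edges},
#'   \code{n_assigned_edges}.
#' @export
comparePedigrees <- function(truePed, ped, indToTrue) {
  sampledTrue <- stats::na.omit(unname(indToTrue))
  trueEdges <- c(
    with(truePed, paste(dam_id, offspring_id))[
      truePed$dam_id %in% sampledTrue & truePed$offspring_id %in% sampledTrue],
    with(truePed, paste(sire_id, offspring_id))[
      truePed$sire_id %in% sampledTrue & truePed$offspring_id %in% sampledTrue])

  off <- indToTrue[ped$offspring_id]
  dam <- ifelse(ped$dam_sampled, indToTrue[ped$dam_id], NA)
  sire <- ifelse(ped$sire_sampled, indToTrue[ped$sire_id], NA)
  assigned <- c(paste(dam, off)[!is.na(dam) & !is.na(off)],
                paste(sire, off)[!is.na(sire) & !is.na(off)])

  hits <- length(intersect(assigned, trueEdges))
  # duplicates cannot arise (one dam/sire slot per offspring), so set
  # intersection is exact
  list(recall = if (length(trueEdges)) hits / length(trueEdges) else NA_real_,
       precision = if (length(assigned)) hits / length(assigned) else NA_real_,
       n_true_edges = length(trueEdges),
       n_assigned_edges = length(assigned))
}
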