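#' Published summary counts from the Saskatchewan boreal caribou program
#'
#' Small plain-text tables shipped with the package: per-stratum sample
#' counts from the caribou noninvasive genotyping program ("qc"), the
#' published edge-betweenness score distribution of its full familial
#' network ("edge_betweenness"), and the headline network accounting
#' ("network_summary": sampled and inferred individual counts, component
#' sizes). They serve as worked-example inputs for the report arithmetic;
#' the underlying genotype data are not distributed here.
#'
#' @param which One of "qc", "edge_betweenness", "network_summary".
#' @return A data.frame.
#' @export
publishedCounts <- function(which = c("qc", "edge_betweenness",
                                      "network_summary")) {
  which <- match.arg(which)
  f <- switch(which,
              qc = "caribou_qc_counts.csv",
              edge_betweenness = "caribou_edge_betweenness_counts.csv",
              network_summary = "caribou_network_summary.csv")
  path <- system.file("extdata", f, package = "famnet", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
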