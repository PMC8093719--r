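# Readers and writers for the pipeline's plain-text formats: genotype CSV
# (two allele columns per locus; empty cell = missing allele), pedigree CSV,
# allele-frequency CSV, GraphML and edge-list/node-table CSV.

#' Write genotype samples to CSV
#'
#' Schema: sample_id, area, year, source, sex, x, y, then per locus two
#' columns (\code{<locus>_a1}, \code{<locus>_a2}); a missing allele is an
#' empty cell.
#'
#' @param samples A \code{\link{GenotypeSamples}} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypesCSV <- function(samples, path) {
  stopifnot(is(samples, "GenotypeSamples"))
  info <- samples@info
  df <- data.frame(sample_id = info$sample_id, area = info$stratum,
                   year = info$year %||% NA_integer_,
                   source = info$source %||% NA_character_,
                   sex = info$sex, x = info$x, y = info$y,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(samples@geno))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read genotype samples from CSV
#'
#' Accepts the schema written by \code{\link{writeGenotypesCSV}}; locus
#' columns are any pair named \code{<locus>_a1} / \code{<locus>_a2}.
#'
#' @param path Input file path.
#' @return A \code{\link{GenotypeSamples}} object.
#' @export
readGenotypesCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  locusCols <- grep("_a[12]$", colnames(df), value = TRUE)
  if (!length(locusCols)) stop("no locus columns (<locus>_a1/_a2) found")
  loci <- unique(sub("_a[12]$", "", locusCols))
  want <- genoColNames(loci)
  miss <- setdiff(want, colnames(df))
  if (length(miss)) stop("incomplete locus columns: ", paste(miss, collapse = ", "))
  geno <- as.matrix(df[, want, drop = FALSE])
  storage.mode(geno) <- "integer"
  sex <- as.character(df$sex %||% "unknown")
  sex[!(sex %in% c("F", "M"))] <- "unknown"
  info <- data.frame(sample_id = as.character(df$sample_id),
                     stratum = as.character(df$area %||% "all"),
                     year = df$year %||% NA_integer_,
                     source = df$source %||% NA_character_,
                     sex = sex,
                     x = as.numeric(df$x %||% NA_real_),
                     y = as.numeric(df$y %||% NA_real_),
                     stringsAsFactors = FALSE)
  GenotypeSamples(info, geno)
}

#' Write a pedigree table to CSV
#' @param ped A \code{PedigreeTable} data.frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writePedigreeCSV <- function(ped, path) {
  write.csv(ped, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a pedigree table from CSV
#' @param path Input file path (columns offspring_id, dam_id, sire_id;
#'   optional dam_sampled, sire_sampled, confidence).
#' @return A \code{PedigreeTable} data.frame.
#' @export
readPedigreeCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("offspring_id", "dam_id", "sire_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("pedigree CSV lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(df$dam_sampled)) df$dam_sampled <- !grepl("^(U\\.F\\.|IF)", df$dam_id)
  if (is.null(df$sire_sampled)) df$sire_sampled <- !grepl("^(U\\.M\\.|IM)", df$sire_id)
  if (is.null(df$confidence)) df$confidence <- NA_real_
  df
}

#' Write an allele-frequency table to CSV (locus, allele, frequency)
#' @param freqs A \code{\link{FrequencyTable}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeFrequencyCSV <- function(freqs, path) {
  stopifnot(is(freqs, "FrequencyTable"))
  rows <- do.call(rbind, lapply(names(freqs@freqs), function(l)
    data.frame(locus = l, allele = names(freqs@freqs[[l]]),
               frequency = unname(freqs@freqs[[l]]), stringsAsFactors = FALSE)))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read an allele-frequency table from CSV
#' @param path Input file path (columns locus, allele, frequency).
#' @return A \code{\link{FrequencyTable}}.
#' @export
readFrequencyCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  FrequencyTable(lapply(split(df, df$locus), function(d)
    stats::setNames(d$frequency, as.character(d$allele))))
}

#' Export a familial network to GraphML
#' @param net A \code{\link{FamilialNetwork}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeGraphML <- function(net, path) {
  stopifnot(is(net, "FamilialNetwork"))
  g <- net@graph
  # GraphML writers reject NA/character mixes poorly; stringify coordinates
  g <- igraph::set_vertex_attr(g, "area",
                               value = ifelse(is.na(igraph::V(g)$area), "",
                                              igraph::V(g)$area))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write the network's edge list (parent_id, offspring_id) to CSV
#' @param net A \code{\link{FamilialNetwork}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeEdgeListCSV <- function(net, path) {
  stopifnot(is(net, "FamilialNetwork"))
  el <- igraph::as_edgelist(net@graph)
  write.csv(data.frame(parent_id = el[, 1], offspring_id = el[, 2],
                       stringsAsFactors = FALSE),
            path, row.names = FALSE)
  invisible(path)
}

#' Write the network's node attribute table to CSV
#' @param net A \code{\link{FamilialNetwork}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeNodeTableCSV <- function(net, path) {
  stopifnot(is(net, "FamilialNetwork"))
  write.csv(net@nodes, path, row.names = FALSE, na = "")
  invisible(path)
}
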