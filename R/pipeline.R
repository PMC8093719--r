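# End-to-end orchestration: simulate or ingest genotypes, QC, consolidate,
# assign parentage, build the network, profile centralities, probe cohesion,
# report local areas; every artifact lands in one output directory with a
# content-hash manifest and a parameter log.

#' Pipeline configuration
#'
#' @param outDir Output directory (created if absent).
#' @param seed Integer seed governing every stochastic stage.
#' @param simulate A \code{\link{simulationConfig}}, or NULL to ingest
#'   \code{genotypesCsv} instead.
#' @param genotypesCsv Path to a genotype CSV (required when
#'   \code{simulate} is NULL).
#' @param pedigreeCsv Optional precomputed pedigree CSV; skips the
#'   parentage stage.
#' @param areasGeoJSON Optional GeoJSON file of local-area polygons; when
#'   absent, the samples' stratum labels serve as area labels.
#' @param stages Character vector of stages to run, in pipeline order.
#' @param maxMismatch,minLoci Consolidation parameters.
#' @param parentage A \code{\link{parentageConfig}}.
#' @param alpha,exo Alpha-centrality parameters.
#' @param removalThreshold,removalMode Edge-removal parameters.
#' @param k Areas per extreme group in the spatial comparison.
#' @return A validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(outDir, seed = 1L, simulate = simulationConfig(seed = seed),
                           genotypesCsv = NULL, pedigreeCsv = NULL,
                           areasGeoJSON = NULL,
                           stages = c("input", "consolidate", "qc", "parentage",
                                      "network", "centrality", "community",
                                      "spatial"),
                           maxMismatch = 2L, minLoci = 5L,
                           parentage = parentageConfig(),
                           alpha = 1, exo = 1,
                           removalThreshold = 4, removalMode = "recompute",
                           k = 4L) {
  if (is.null(simulate) && is.null(genotypesCsv))
    stop("invalid config: either a simulation config or genotypesCsv is required")
  for (p in c(genotypesCsv, pedigreeCsv, areasGeoJSON))
    if (!is.null(p) && !file.exists(p))
      stop("invalid config: input file does not exist: ", p)
  structure(list(outDir = outDir, seed = as.integer(seed), simulate = simulate,
                 genotypesCsv = genotypesCsv, pedigreeCsv = pedigreeCsv,
                 areasGeoJSON = areasGeoJSON, stages = stages,
                 maxMismatch = as.integer(maxMismatch),
                 minLoci = as.integer(minLoci), parentage = parentage,
                 alpha = alpha, exo = exo,
                 removalThreshold = removalThreshold,
                 removalMode = removalMode, k = as.integer(k)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Scalar keys mirror the \code{\link{pipelineConfig}} arguments; keys
#' under \code{simulate:} and \code{parentage:} feed the respective
#' constructors.
#'
#' @param path YAML file path.
#' @param outDir Override for the output directory (optional).
#' @return A \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path, outDir = NULL) {
  y <- yaml::read_yaml(path)
  simArgs <- y$simulate
  sim <- if (is.null(simArgs)) NULL else do.call(simulationConfig, simArgs)
  parArgs <- y$parentage %||% list()
  args <- y[setdiff(names(y), c("simulate", "parentage"))]
  args$simulate <- sim
  args$parentage <- do.call(parentageConfig, parArgs)
  if (!is.null(outDir)) args$outDir <- outDir
  do.call(pipelineConfig, args)
}

#' Run the familial-network pipeline
#'
#' Executes the enabled stages in order and writes every artifact beneath
#' \code{config$outDir}. Identical configurations (including seed) yield
#' byte-identical artifacts. A failing stage leaves a partial manifest with
#' a failure record rather than discarding completed artifacts.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @return Invisibly, a manifest data.frame (\code{artifact}, \code{file},
#'   \code{md5}), also written to \code{manifest.csv}; attribute
#'   \code{failure} records a failed stage, if any.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(artifact = character(0), file = character(0),
                         md5 = character(0), stringsAsFactors = FALSE)
  failure <- NULL
  logLines <- c(sprintf("seed: %d", config$seed),
                sprintf("stages: %s", paste(config$stages, collapse = ",")))
  emit <- function(name, file) {
    manifest <<- rbind(manifest, data.frame(
      artifact = name, file = basename(file),
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE))
  }
  on.exit({
    mpath <- file.path(config$outDir, "manifest.csv")
    write.csv(manifest, mpath, row.names = FALSE)
    writeLines(logLines, file.path(config$outDir, "run_log.txt"))
  })

  result <- list()
  run <- function(stage, fn) {
    if (!(stage %in% config$stages) || !is.null(failure)) return(invisible())
    ok <- tryCatch({ fn(); TRUE },
                   error = function(e) {
                     failure <<- list(stage = stage, message = conditionMessage(e))
                     logLines <<- c(logLines, sprintf("FAILED %s: %s", stage,
                                                      conditionMessage(e)))
                     FALSE
                   })
    if (ok) logLines <<- c(logLines, sprintf("completed %s", stage))
    invisible(ok)
  }

  run("input", function() {
    if (!is.null(config$simulate)) {
      pop <- simulatePopulation(config$simulate)
      result$pop <<- pop
      result$freqs <<- pop@freqs
      result$samples <<- applySamplingAndError(pop, config$simulate)
      tp <- file.path(config$outDir, "true_pedigree.csv")
      write.csv(pop@pedigree, tp, row.names = FALSE)
      emit("true_pedigree", tp)
      logLines <<- c(logLines, sprintf("simulated %d individuals (seed %d)",
                                       nrow(pop@individuals), config$simulate$seed))
    } else {
      result$samples <<- readGenotypesCSV(config$genotypesCsv)
      result$freqs <<- empiricalFrequencies(result$samples)
    }
    gp <- file.path(config$outDir, "genotypes.csv")
    writeGenotypesCSV(result$samples, gp)
    emit("genotypes", gp)
    fp <- file.path(config$outDir, "allele_frequencies.csv")
    writeFrequencyCSV(result$freqs, fp)
    emit("allele_frequencies", fp)
  })

  run("consolidate", function() {
    result$individuals <<- consolidateIndividuals(result$samples,
                                                  maxMismatch = config$maxMismatch,
                                                  minLoci = config$minLoci)
    ip <- file.path(config$outDir, "individuals.csv")
    write.csv(result$individuals@info, ip, row.names = FALSE, na = "")
    emit("individuals", ip)
    ap <- file.path(config$outDir, "consolidation_audit.csv")
    mapping <- attr(result$individuals, "mapping")
    write.csv(data.frame(sample_id = names(mapping),
                         individual_id = unname(mapping),
                         stringsAsFactors = FALSE), ap, row.names = FALSE)
    emit("consolidation_audit", ap)
  })

  run("qc", function() {
    mapping <- if (!is.null(result$individuals)) attr(result$individuals, "mapping")
    qc <- qcSummary(result$samples, mapping = mapping, minLoci = config$minLoci)
    qp <- file.path(config$outDir, "qc_report.csv")
    write.csv(qc$strata, qp, row.names = FALSE)
    emit("qc_report", qp)
    result$qc <<- qc
  })

  run("parentage", function() {
    if (!is.null(config$pedigreeCsv)) {
      result$ped <<- readPedigreeCSV(config$pedigreeCsv)
    } else {
      ped <- assignParentage(result$individuals, result$freqs,
                             config = config$parentage)
      ped <- reconstructUnsampledParents(ped, result$individuals,
                                         result$freqs, config$parentage)
      result$ped <<- ped
    }
    pp <- file.path(config$outDir, "pedigree.csv")
    writePedigreeCSV(result$ped, pp)
    emit("pedigree", pp)
    fit <- fitnessCounts(result$ped)
    fp <- file.path(config$outDir, "fitness.csv")
    write.csv(data.frame(individual_id = names(fit), offspring = unname(fit),
                         stringsAsFactors = FALSE), fp, row.names = FALSE)
    emit("fitness", fp)
  })

  run("network", function() {
    memb <- if (!is.null(config$areasGeoJSON)) NULL else
      stats::setNames(result$individuals@info$stratum,
                      result$individuals@info$individual_id)
    result$net <<- buildFamilialNetwork(result$ped, result$individuals,
                                        membership = memb)
    if (!is.null(config$areasGeoJSON)) {
      areas <- readAreasGeoJSON(config$areasGeoJSON)
      result$membership <<- assignLocalAreas(result$net, areas)
    } else {
      result$membership <<- memb
    }
    writeGraphML(result$net, file.path(config$outDir, "network.graphml"))
    emit("network_graphml", file.path(config$outDir, "network.graphml"))
    writeEdgeListCSV(result$net, file.path(config$outDir, "edges.csv"))
    emit("edges", file.path(config$outDir, "edges.csv"))
    writeNodeTableCSV(result$net, file.path(config$outDir, "nodes.csv"))
    emit("nodes", file.path(config$outDir, "nodes.csv"))
    comp <- connectedComponents(result$net)
    cp <- file.path(config$outDir, "components.csv")
    write.csv(data.frame(component = seq_along(comp$sizes), size = comp$sizes),
              cp, row.names = FALSE)
    emit("components", cp)
    result$components <<- comp
  })

  run("centrality", function() {
    prim <- primaryNetwork(result$net)
    result$primary <<- prim
    tab <- centralityTable(prim, alpha = config$alpha, exo = config$exo)
    result$centrality <<- tab
    tp <- file.path(config$outDir, "centrality.csv")
    write.csv(tab, tp, row.names = FALSE)
    emit("centrality", tp)
    if (nrow(tab) >= 3L) {
      cm <- centralityCorrelations(tab)
      cp <- file.path(config$outDir, "centrality_correlations.csv")
      write.csv(as.data.frame(cm), cp, row.names = TRUE)
      emit("centrality_correlations", cp)
      pc <- pcaContributions(tab)
      pp <- file.path(config$outDir, "pca_contributions.csv")
      write.csv(as.data.frame(pc$contributions), pp, row.names = TRUE)
      emit("pca_contributions", pp)
    }
  })

  run("community", function() {
    dist <- betweennessDistribution(result$net)
    dp <- file.path(config$outDir, "edge_betweenness_distribution.csv")
    write.csv(dist, dp, row.names = FALSE)
    emit("edge_betweenness_distribution", dp)
    trace <- removeHighBetweennessEdges(result$net, config$removalThreshold,
                                        mode = config$removalMode)
    tp <- file.path(config$outDir, "removal_trace.csv")
    write.csv(trace$removed, tp, row.names = FALSE)
    emit("removal_trace", tp)
    memb <- igraph::components(trace$graph, mode = "weak")$membership
    pp <- file.path(config$outDir, "removal_partition.csv")
    write.csv(data.frame(id = names(memb), component = unname(memb),
                         stringsAsFactors = FALSE), pp, row.names = FALSE)
    emit("removal_partition", pp)
    result$removal <<- trace
  })

  run("spatial", function() {
    rep <- areaReports(result$net, result$membership, k = config$k)
    ap <- file.path(config$outDir, "area_reports.csv")
    write.csv(rep, ap, row.names = FALSE)
    emit("area_reports", ap)
    result$areas <<- rep
    nDefined <- sum(!is.na(rep$ratio))
    kUse <- min(config$k, floor(nDefined / 2))
    if (kUse >= 1L && !is.null(result$centrality)) {
      cmpG <- compareAreaGroups(result$centrality, result$membership, rep,
                                k = kUse)
      gp <- file.path(config$outDir, "area_group_comparison.csv")
      write.csv(cmpG$summaries, gp, row.names = FALSE)
      emit("area_group_comparison", gp)
      jp <- file.path(config$outDir, "area_group_comparison.json")
      jsonlite::write_json(list(groups = as.list(cmpG$groups),
                                correlations = cmpG$correlations),
                           jp, auto_unbox = TRUE, digits = NA)
      emit("area_group_comparison_json", jp)
      result$areaComparison <<- cmpG
    }
  })

  if (!is.null(failure)) {
    manifest <- rbind(manifest, data.frame(
      artifact = paste0("FAILED:", failure$stage), file = "", md5 = "",
      stringsAsFactors = FALSE))
  }
  attr(manifest, "failure") <- failure
  attr(manifest, "result") <- result
  invisible(manifest)
}

#' Empirical allele frequencies from samples
#'
#' Allele counts over all typed loci, normalized per locus; used when
#' genotypes are ingested without a supplied frequency table.
#'
#' @param samples A \code{\link{GenotypeSamples}} or
#'   \code{\link{IndividualSet}}.
#' @return A \code{\link{FrequencyTable}}.
#' @export
empiricalFrequencies <- function(samples) {
  geno <- if (is(samples, "GenotypeSamples") || is(samples, "IndividualSet"))
    genotypes(samples) else stop("unsupported input")
  loci <- lociFromGeno(geno)
  freqs <- lapply(seq_along(loci), function(l) {
    v <- as.vector(geno[, locusCols(l)])
    v <- v[!is.na(v)]
    if (!length(v)) stop("locus ", loci[l], " has no observed alleles")
    tb <- table(v)
    stats::setNames(as.numeric(tb) / sum(tb), names(tb))
  })
  names(freqs) <- loci
  FrequencyTable(freqs)
}
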