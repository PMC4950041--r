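## End-to-end pipeline over synthetic data: simulate -> marker QC ->
## physical assignment -> per-population linkage maps -> consensus ->
## ordination and segment detection, with per-stage count accounting.

#' Pipeline configuration
#'
#' @param seed global integer seed; all stage sub-streams derive from it.
#' @param nChromosomes,chromosomeLength,nMarkers,nPositions ground-truth map
#'   shape.
#' @param populations named integer vector: DH lines per mapping population.
#' @param panelGroups named integer vector: accessions per panel group.
#' @param sim a [simConfig()] (its `seed` is overridden by `seed`).
#' @param qc a [qcConfig()].
#' @param map a [mapConfig()].
#' @param introgression optional list `accessions` (count), `chromosome`,
#'   `span`, `donorCode` describing a block to implant in the panel.
#' @param minBins,carriersMin segment-caller thresholds.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(seed = 1L,
                           nChromosomes = 3, chromosomeLength = 120,
                           nMarkers = 200, nPositions = 75,
                           populations = c(AxC = 130, SxR = 64, SxO = 60),
                           panelGroups = c(elite = 40, landrace = 20),
                           sim = simConfig(), qc = qcConfig(),
                           map = mapConfig(),
                           introgression = list(accessions = 3,
                                                chromosome = NULL,
                                                span = c(40, 80),
                                                donorCode = "BB"),
                           minBins = 4L, carriersMin = 2L) {
  list(seed = as.integer(seed), nChromosomes = nChromosomes,
       chromosomeLength = chromosomeLength, nMarkers = nMarkers,
       nPositions = nPositions, populations = populations,
       panelGroups = panelGroups, sim = sim, qc = qc, map = map,
       introgression = introgression, minBins = as.integer(minBins),
       carriersMin = as.integer(carriersMin))
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipelineConfig()] arguments; `sim`, `qc` and
#' `map` sub-maps mirror [simConfig()], [qcConfig()] and [mapConfig()].
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a [pipelineConfig()] list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sub in c("sim", "qc", "map")) {
    if (!is.null(raw[[sub]])) {
      ctor <- switch(sub, sim = simConfig, qc = qcConfig, map = mapConfig)
      badSub <- setdiff(names(raw[[sub]]), names(formals(ctor)))
      if (length(badSub))
        stop("unknown ", sub, " key(s): ", paste(badSub, collapse = ", "))
      if (sub == "sim" && !is.null(raw$sim$classMix))
        raw$sim$classMix <- unlist(raw$sim$classMix)
      raw[[sub]] <- do.call(ctor, raw[[sub]])
    }
  }
  for (vec in c("populations", "panelGroups"))
    if (!is.null(raw[[vec]])) raw[[vec]] <- unlist(raw[[vec]])
  if (!is.null(raw$introgression))
    raw$introgression$span <- unlist(raw$introgression$span)
  do.call(pipelineConfig, raw)
}

#' Run the full synthetic-data pipeline
#'
#' Simulates the ground truth, the accession panel (with an optional
#' implanted introgression) and the aneuploid screen; classifies markers;
#' assigns chromosomes from the aneuploid stocks; builds one genetic map
#' per DH population; merges them into a consensus map; and runs the
#' ordination and the segment caller. Every stage logs its input/output
#' counts. Re-running with the same seed reproduces every artifact.
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional directory: artifacts are written as CSV/TSV/JSON.
#' @return list with `truth`, `qc`, `physical`, `maps`, `consensus`,
#'   `mds`, `segments` and a `log` data.frame of stage counts.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  log <- list()
  note <- function(stage, ...) {
    cnt <- list(...)
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, quantity = names(cnt), count = as.numeric(cnt))
  }
  cfg <- config$sim
  cfg$seed <- config$seed
  lens <- stats::setNames(rep(config$chromosomeLength, config$nChromosomes),
                          wheatChromosomes(config$nChromosomes))
  trueMap <- makeTrueMap(lens, config$nMarkers, config$nPositions,
                         seed = config$seed)
  note("simulate", markers = config$nMarkers,
       positions = config$nPositions)

  ## panel + optional introgression
  groups <- data.frame(
    accession = sprintf("ACC%03d", seq_len(sum(config$panelGroups))),
    group = rep(names(config$panelGroups), config$panelGroups))
  panelSim <- simulatePanel(trueMap, groups, cfg)
  panel <- panelSim$matrix
  segTruth <- NULL
  intro <- config$introgression
  if (!is.null(intro)) {
    chrom <- intro$chromosome %||% names(lens)[1]
    carriers <- utils::head(groups$accession, intro$accessions)
    panel <- injectIntrogression(panel, carriers, chrom, intro$span,
                                 intro$donorCode %||% "BB", trueMap)
    segTruth <- list(accessions = carriers, chromosome = chrom,
                     span = intro$span)
  }

  ## QC
  qcSum <- summarizeCategories(panel, config$qc)
  note("qc", markers = sum(qcSum$categoryCounts),
       useful = qcSum$usefulCount)

  ## aneuploid screen covering every chromosome
  aneu <- aneuploidPanel(stock = paste0("N", names(lens)),
                         kind = "nulli_tetra", chromosome = names(lens))
  aneuMat <- simulateAneuploids(trueMap, aneu, seed = config$seed)
  phys <- assignByNulliTetra(aneuMat, aneu,
                             euploidRefs = grep("^EUPLOID",
                                                accessionNames(aneuMat),
                                                value = TRUE))
  note("assign", assigned = sum(!is.na(phys$chromosome)))

  ## per-population maps
  maps <- list()
  for (p in names(config$populations)) {
    pcfg <- cfg
    pcfg$nLines <- config$populations[[p]]
    pcfg$seed <- deriveSeed(config$seed, match(p, names(config$populations)))
    pop <- simulateDhPopulation(trueMap, pcfg)$pop
    built <- buildMap(pop, config$map, evidence = phys)
    maps[[p]] <- built
    note(paste0("map_", p), frame = built$summary$counts$frameMapped,
         mapped = built$summary$counts$totalMapped,
         unlinked = built$summary$counts$unlinked)
  }

  ## consensus
  merged <- mergeMaps(lapply(maps, `[[`, "map"), seed = config$seed)
  note("consensus", markers = nrow(mapTable(merged$map)),
       deletedEdges = merged$deletedEdges)

  ## structure + segments on the panel along the consensus map
  sim <- similarityMatrix(panel)
  mds <- classicalMds(sim)
  ## below-threshold markers carry no usable signal for the segment caller
  coded <- recodeGenotypes(panel)
  notCrbt <- qcSum$classes$marker[qcSum$classes$category != "CRBT"]
  segs <- detectSegments(coded[intersect(rownames(coded), notCrbt), ,
                               drop = FALSE],
                         merged$map, minBins = config$minBins,
                         carriersMin = config$carriersMin)
  note("introgress", segments = nrow(segs))

  out <- list(truth = list(trueMap = trueMap, classes = panelSim$truth,
                           segment = segTruth),
              panel = panel, qc = qcSum, physical = phys, maps = maps,
              consensus = merged, mds = mds, segments = segs,
              log = do.call(rbind, log))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeGenotypeCsv(panel, file.path(outDir, "panel_genotypes.csv"))
    utils::write.table(qcSum$classes, file.path(outDir, "marker_qc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(phys, file.path(outDir, "physical_assignment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (p in names(maps))
      writeMapTsv(maps[[p]]$map,
                  file.path(outDir, paste0("map_", p, ".tsv")))
    writeMapTsv(merged$map, file.path(outDir, "consensus_map.tsv"))
    utils::write.table(segs, file.path(outDir, "segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out$log, file.path(outDir, "run_log.json"))
  }
  out
}
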