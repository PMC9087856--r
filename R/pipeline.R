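## End-to-end orchestration: regions -> k sweep -> distances ->
## tree/network -> core k-mers -> feature mapping -> repeat enrichment,
## with per-stage artefacts and a hash manifest for reproducibility.

.stageLog <- function(run, stage, fmt, ...) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                  stage, sprintf(fmt, ...))
  message(line)
  cat(line, "\n", file = file.path(run, "pipeline.log"), append = TRUE)
}

.hashOutputs <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(as.vector(h), basename(paths))
}

#' Run the full alignment-free phylogenomics pipeline
#'
#' Executes every stage on a genome collection: region curation (and
#' per-genome region-size report), optional word-length sweep, D2S
#' distance matrices, neighbour-joining tree (rooted at the outgroup
#' when given, compared to a reference topology when given),
#' relatedness network with threshold breakpoints, core k-mers of a
#' target group with per-node tree annotation, core-k-mer feature
#' classification on a reference genome, and the repeat-type
#' enrichment screen. Each stage writes its artefacts under `outDir`
#' and is recorded in `manifest.json` with parameter echo and MD5
#' hashes, so a rerun with the same inputs and seed reproduces
#' identical hashes for deterministic stages. Validation (group
#' membership, reference ids) happens before any stage runs.
#'
#' @param genomes named list of [GenomeRecord-class] objects.
#' @param outDir output directory (created; reused if existing).
#' @param regions region kinds to analyse (subset of WGS, rmWGS, CDS,
#'   intron, repeat, protein).
#' @param k word length used for distances when no `kGrid` is given.
#' @param kGrid optional integer grid; when supplied, a sweep chooses
#'   the representative k per region.
#' @param canonical canonical k-mer counting flag.
#' @param metadata optional metadata data.frame (genome_id, species,
#'   isolate, lifestyle); defaults to the records' own fields.
#' @param outgroup optional outgroup leaf labels for rooting.
#' @param referenceTree optional [ape::phylo] reference topology for
#'   the normalised RF comparison.
#' @param speciesMap optional leaf -> species map for isolate
#'   collapsing in that comparison.
#' @param coreGroup genome ids for core-k-mer discovery (default: all).
#' @param mappingReference genome id whose annotation classifies the
#'   core k-mers (default: none).
#' @param enrichmentGroups optional list with elements `A` and `B` of
#'   genome ids for the repeat enrichment screen.
#' @param alpha significance level for the screen.
#' @param seed seed recorded in the manifest (stages are deterministic
#'   given inputs; the seed namespaces any future stochastic stage).
#' @return (invisibly) a list with the per-stage results and the
#'   manifest, whose `outDir` holds all artefacts.
#' @export
runPipeline <- function(genomes, outDir,
                        regions = "WGS", k = 23L, kGrid = NULL,
                        canonical = FALSE, metadata = NULL,
                        outgroup = NULL, referenceTree = NULL,
                        speciesMap = NULL, coreGroup = NULL,
                        mappingReference = NULL,
                        enrichmentGroups = NULL, alpha = 0.05,
                        seed = 1L) {
  ids <- vapply(genomes, genomeId, "")
  names(genomes) <- ids
  bad <- setdiff(regions, .REGION_KINDS)
  if (length(bad))
    .stopf("unknown region kind(s): %s", paste(bad, collapse = ", "))
  for (grp in list(outgroup, coreGroup, mappingReference,
                   enrichmentGroups$A, enrichmentGroups$B)) {
    miss <- setdiff(grp, ids)
    if (length(miss))
      .stopf("configuration references unknown genome(s): %s",
             paste(miss, collapse = ", "))
  }
  if (is.null(metadata))
    metadata <- data.frame(
      genome_id = ids,
      species = vapply(genomes, function(g) g@species, ""),
      isolate = vapply(genomes, function(g) g@isolate, ""),
      lifestyle = vapply(genomes, function(g) g@lifestyle, ""),
      stringsAsFactors = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = list())
  results <- list()
  addStage <- function(name, params, outputs) {
    manifest$stages[[name]] <<- list(name = name, params = params,
                                     outputs = .hashOutputs(outputs))
  }
  t0 <- proc.time()[["elapsed"]]

  ## regions
  regionSets <- list()
  regionFiles <- character()
  for (kind in regions) {
    regionSets[[kind]] <- lapply(genomes, function(g) {
      switch(kind,
             WGS = extractWGS(g),
             rmWGS = extractRmWGS(g),
             CDS = extractCDS(g),
             intron = extractIntrons(g),
             `repeat` = extractRepeats(g),
             protein = translateCDS(extractCDS(g)))
    })
    for (rs in regionSets[[kind]]) {
      f <- file.path(outDir, sprintf("%s_%s.fasta", genomeId(rs), kind))
      writeFasta(rs, f)
      regionFiles <- c(regionFiles, f)
    }
  }
  reportPath <- file.path(outDir, "region_sizes.tsv")
  results$regionReport <- regionSizeReport(unlist(regionSets,
                                                  recursive = FALSE),
                                           reportPath)
  addStage("regions", list(regions = regions),
           c(regionFiles, reportPath))
  .stageLog(outDir, "regions", "%d region set(s) in %.1fs",
            length(regions) * length(genomes),
            proc.time()[["elapsed"]] - t0)

  ## per-region analysis
  results$byRegion <- list()
  for (kind in regions) {
    t1 <- proc.time()[["elapsed"]]
    rs <- regionSets[[kind]]
    kUse <- as.integer(k)
    if (!is.null(kGrid)) {
      sweep <- sweepK(rs, kGrid, canonical = canonical)
      sweepPath <- file.path(outDir, sprintf("sweep_%s.tsv", kind))
      utils::write.table(sweep$table, sweepPath, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      kUse <- sweep$chosen_k
      addStage(paste0("sweep-k:", kind),
               list(grid = kGrid, chosen_k = kUse), sweepPath)
      results$byRegion[[kind]]$sweep <- sweep
    }
    profiles <- lapply(rs, countKmers, k = kUse, canonical = canonical)
    dm <- distanceMatrix(profiles, regionSets = rs)
    dmPath <- file.path(outDir, sprintf("distances_%s.phylip", kind))
    writePhylipDistance(dm, dmPath)
    addStage(paste0("distances:", kind), list(k = kUse), dmPath)

    tree <- neighborJoining(dm)
    if (!is.null(outgroup)) tree <- rootWithOutgroup(tree, outgroup)
    treePath <- file.path(outDir, sprintf("tree_%s.nwk", kind))
    writeNewick(tree, treePath)
    rf <- NULL
    if (!is.null(referenceTree))
      rf <- normalizedRF(tree, referenceTree, speciesMap)
    addStage(paste0("tree:", kind),
             list(outgroup = outgroup, normalized_rf = rf), treePath)

    net <- buildNetwork(dm, metadata)
    netPath <- file.path(outDir, sprintf("network_%s.json", kind))
    writeNetworkJSON(net, netPath)
    bp <- networkBreakpoints(net)
    bpPath <- file.path(outDir, sprintf("network_breakpoints_%s.tsv",
                                        kind))
    utils::write.table(bp, bpPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    addStage(paste0("network:", kind), list(), c(netPath, bpPath))

    results$byRegion[[kind]] <- c(results$byRegion[[kind]],
                                  list(k = kUse, profiles = profiles,
                                       distances = dm, tree = tree,
                                       normalizedRF = rf, network = net,
                                       breakpoints = bp))
    .stageLog(outDir, kind, "k=%d, tree + network in %.1fs", kUse,
              proc.time()[["elapsed"]] - t1)
  }

  ## core k-mers on the first region's profiles
  kindMain <- regions[[1L]]
  profiles <- results$byRegion[[kindMain]]$profiles
  if (is.null(coreGroup)) coreGroup <- ids
  core <- coreKmers(profiles, coreGroup)
  corePath <- file.path(outDir, "core_kmers.txt")
  writeKmerList(core, corePath)
  annTree <- annotateCoreCounts(
    if (!is.null(outgroup))
      results$byRegion[[kindMain]]$tree else
        rootWithOutgroup(results$byRegion[[kindMain]]$tree, ids[1L]),
    profiles)
  annPath <- file.path(outDir, "tree_core_counts.nwk")
  writeNewick(annTree, annPath)
  addStage("core-kmers", list(group = coreGroup, n = length(core$words)),
           c(corePath, annPath))
  results$core <- core
  .stageLog(outDir, "core-kmers", "%d core %d-mers", length(core$words),
            core$k)

  ## feature mapping
  if (!is.null(mappingReference) && length(core$words)) {
    ref <- genomes[[mappingReference]]
    hits <- locateKmers(core$words, ref)
    cls <- classifyHits(hits, genomeFeatures(ref), strandSpecific = TRUE)
    venn <- vennCounts(cls, allWords = core$words)
    bedPath <- file.path(outDir, "core_kmer_hits.bed")
    writeKmerHitsBed(hits, bedPath)
    vennPath <- file.path(outDir, "core_kmer_venn.tsv")
    utils::write.table(
      data.frame(cell = names(venn$cells), count = venn$cells),
      vennPath, sep = "\t", quote = FALSE, row.names = FALSE)
    addStage("map-kmers", list(reference = mappingReference),
             c(bedPath, vennPath))
    results$mapping <- list(hits = hits, classifications = cls,
                            venn = venn)
    .stageLog(outDir, "map-kmers", "%d hits, %d classified words",
              nrow(hits), nrow(cls))
  }

  ## repeat enrichment
  if (!is.null(enrichmentGroups)) {
    tab <- repeatTypeTable(genomes)
    res <- rbind(
      enrichmentTest(tab, enrichmentGroups$A, enrichmentGroups$B,
                     metric = "proportion", alpha = alpha),
      enrichmentTest(tab, enrichmentGroups$A, enrichmentGroups$B,
                     metric = "kimura", alpha = alpha))
    resPath <- file.path(outDir, "repeat_enrichment.tsv")
    utils::write.table(res, resPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    addStage("repeat-enrichment",
             list(alpha = alpha, groupA = enrichmentGroups$A,
                  groupB = enrichmentGroups$B), resPath)
    results$enrichment <- res
    results$enrichmentSummary <- summariseByClass(res)
    .stageLog(outDir, "repeat-enrichment", "%d significant type(s)",
              length(unique(res$repeat_type[res$significant])))
  }

  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, null = "null")
  results$manifest <- manifest
  results$outDir <- outDir
  .stageLog(outDir, "done", "total %.1fs",
            proc.time()[["elapsed"]] - t0)
  invisible(results)
}
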