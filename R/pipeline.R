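## End-to-end seeded demo pipeline with an output manifest.

.DEFAULT_RUN <- list(
  sim = list(genomeLength = 5e5, nPairs = 20000, nAnchoredPairs = 2000,
             oddsRatio = 3, p1 = 0.3, p2 = 0.3,
             tadBoundaries = c(1e5, 2e5, 3e5, 4e5),
             compartmentBin = 50000),
  spikein = list(nCalls = 20000, epsilon = 0.02),
  pileup = list(minCov = 5, minCovMerged = 10),
  singlemol = list(window = 100, minSep = 1000, maxSep = Inf, k = 4,
                   minCalls = 1, threshold = 0.5),
  hic = list(binSize = 1000, insulationFlank = 25000,
             boundaryQuantile = 0.90, boundarySpan = 2000,
             compartmentBin = 50000, strengthMinSep = 150000,
             promoterWindow = 5000, assocMinDist = 5000,
             assocMaxDist = 2e6))

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      .mergeConfig(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' Run the full pipeline end-to-end on synthetic data
#'
#' Executes the stages in dependency order -- simulate, fend assignment
#' and deduplication, pileup and conversion QC, single-molecule
#' co-accessibility, contact statistics -- writing every intermediate in
#' its text format, the effective configuration, and a manifest JSON
#' listing every output with its md5 checksum. All randomness derives
#' from \code{seed}, so reruns are byte-identical.
#'
#' @param outdir output directory (created if missing).
#' @param seed master seed.
#' @param config nested list (or YAML path) overriding the bundled demo
#'   configuration.
#' @param quiet suppress progress messages.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(outdir, seed = 1L, config = list(),
                        quiet = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- read_yaml(config)
  cfg <- .mergeConfig(.DEFAULT_RUN, config)
  if (cfg$singlemol$window <= 0) stop("window must be > 0")
  if (cfg$hic$binSize <= 0) stop("binSize must be > 0")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  pth <- function(f) file.path(outdir, f)
  outputs <- character(0)
  emit <- function(f) outputs <<- c(outputs, pth(f))

  ## effective configuration echo (includes every analysis constant)
  cfg$seed <- as.integer(seed)
  write_yaml(cfg, pth("effective_config.yaml"))
  emit("effective_config.yaml")

  say("stage simulate")
  simCfg <- do.call(simConfig, c(cfg$sim, list(seed = as.integer(seed))))
  genome <- simulateGenome(simCfg)
  sim <- simulateContactPairs(simCfg)
  calls <- simulateReadMethCalls(simCfg, sim$pairs, sim$truth, genome)
  spike <- rbind(
    methCalls(simulateSpikein(cfg$spikein$nCalls, cfg$spikein$epsilon,
                              methylated = FALSE,
                              seed = .substream(seed, 404L))),
    methCalls(simulateSpikein(cfg$spikein$nCalls, cfg$spikein$epsilon,
                              methylated = TRUE,
                              seed = .substream(seed, 505L))))
  allCalls <- MethCallTable(rbind(methCalls(calls), spike))
  writeXStringSet(genome, pth("genome.fa"))
  writeMethCalls(allCalls, pth("calls.tsv"))
  anchors <- GRanges(simCfg@anchorFeatures$chrom,
                     IRanges(start = simCfg@anchorFeatures$pos + 1L,
                             width = 1L),
                     strand = simCfg@anchorFeatures$strand,
                     label = simCfg@anchorFeatures$label)
  writeFeaturesBed(anchors, pth("anchors.bed"))
  write_json(sim$truth[c("joint", "tadBoundaries", "compartmentLabels",
                         "compartmentBin")],
             pth("truth.json"), auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  emit("genome.fa"); emit("calls.tsv"); emit("anchors.bed")
  emit("truth.json")

  say("stage fends")
  index <- buildFragmentIndex(genome, simCfg@restrictionMotif)
  writeFragmentIndexBed(index, pth("fends.bed"))
  dedup <- dedupContactPairs(assignFends(sim$pairs, index))
  writePairs(dedup, pth("pairs.pairs"))
  emit("fends.bed"); emit("pairs.pairs")

  say("stage tracks")
  gchPile <- pileupCalls(calls, "GCH", minCov = cfg$pileup$minCov)
  hcgPile <- pileupCalls(calls, "HCG", minCov = cfg$pileup$minCov)
  writeBedGraph(data.frame(chrom = gchPile$chrom, start = gchPile$pos,
                           end = gchPile$pos + 1L,
                           score = gchPile$fraction),
                pth("accessibility.bedGraph"))
  writeBedGraph(data.frame(chrom = hcgPile$chrom, start = hcgPile$pos,
                           end = hcgPile$pos + 1L,
                           score = hcgPile$fraction),
                pth("methylation.bedGraph"))
  qc <- conversionQC(MethCallTable(spike))
  write_json(qc, pth("conversion_qc.json"), auto_unbox = TRUE,
             digits = NA, pretty = TRUE)
  emit("accessibility.bedGraph"); emit("methylation.bedGraph")
  emit("conversion_qc.json")

  say("stage singlemol")
  aIdx <- grepl("^A", mcols(anchors)$label)
  res <- coAccessibility(calls, anchors[aIdx], anchors[!aIdx],
                         window = cfg$singlemol$window,
                         minSep = cfg$singlemol$minSep,
                         maxSep = cfg$singlemol$maxSep,
                         k = cfg$singlemol$k,
                         seed = .substream(seed, 606L),
                         minCalls = cfg$singlemol$minCalls,
                         threshold = cfg$singlemol$threshold)
  coAccessibilityStats(res, pth("coaccessibility.json"))
  obs <- observations(res)
  if (length(clusterAssignments(res)))
    obs$cluster <- clusterAssignments(res)
  write.table(obs, pth("observations.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  emit("coaccessibility.json"); emit("observations.tsv")

  say("stage hic")
  mats <- binContacts(dedup, cfg$hic$binSize,
                      setNames(rep(simCfg@genomeLength, simCfg@nChroms),
                               paste0("chr", seq_len(simCfg@nChroms))))
  ins <- do.call(rbind, lapply(mats, insulationScore,
                               flank = cfg$hic$insulationFlank))
  writeBedGraph(ins, pth("insulation.bedGraph"))
  bounds <- callBoundaries(ins, cfg$hic$boundaryQuantile,
                           cfg$hic$boundarySpan)
  write.table(bounds[, c("chrom", "start", "end")],
              pth("boundaries.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cmats <- binContacts(dedup, cfg$hic$compartmentBin,
                       setNames(rep(simCfg@genomeLength, simCfg@nChroms),
                                paste0("chr", seq_len(simCfg@nChroms))))
  comp <- do.call(rbind, lapply(cmats, compartmentEigenvector))
  writeBedGraph(comp, pth("compartments.bedGraph"), scoreCol = "value")
  strength <- tryCatch(
    compartmentStrength(cmats[[1]], comp$label[comp$chrom == names(cmats)[1]],
                        minSep = cfg$hic$strengthMinSep),
    error = function(e) NA_real_)
  decay <- contactDecay(dedup, minDist = simCfg@minDistance)
  write.table(decay, pth("decay.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_json(list(compartment_strength = strength,
                  n_boundaries = nrow(bounds),
                  decay_slope = fitDecaySlope(
                    decay, c(2 * simCfg@minDistance,
                             simCfg@maxDistance / 2))),
             pth("hic_summary.json"), auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  emit("insulation.bedGraph"); emit("boundaries.bed")
  emit("compartments.bedGraph"); emit("decay.tsv")
  emit("hic_summary.json")

  say("writing manifest")
  manifest <- list(
    seed = as.integer(seed),
    outputs = lapply(setNames(outputs, basename(outputs)), function(f)
      list(path = basename(f), md5 = unname(md5sum(f)),
           bytes = file.size(f))))
  write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
             digits = NA, pretty = TRUE)
  invisible(manifest)
}
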