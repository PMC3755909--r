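# End-to-end driver: simulate -> map -> build -> profile -> cluster.

#' Run the full gene-build pipeline on a simulated dataset
#'
#' Convenience driver chaining the package's modules on one simulation:
#' genome and library simulation, transcript-to-genome mapping, gene-set
#' partitioning, transcript feature annotation, expression profiling,
#' tissue-specificity calling and cluster detection.
#'
#' @param config a [SimulationConfig-class].
#' @param thresholds a [MappingThresholds-class].
#' @param minCopies,minFraction tissue-call thresholds, see
#'   [callTissueSpecific()].
#' @param clusterGap cluster chaining gap (bp), see [detectClusters()].
#' @return list with elements `sim` ([GenomeSimulation-class]),
#'   `transcripts` ([TranscriptSet-class]), `alignments`
#'   ([SplicedAlignmentSet-class]), `geneSets` ([GeneLocusSet-class]),
#'   `features` (transcript ORF/poly-A table), `profile` (loci x tissue
#'   EST matrix), `calls` (tissue calls), `callTable` (calls with
#'   coordinates), `clusters`, and `chromLengths`.
#' @examples
#' \dontrun{
#' res <- runPipeline(simulationConfig(seed = 1))
#' res$geneSets
#' }
#' @export
runPipeline <- function(config = simulationConfig(),
                        thresholds = MappingThresholds(),
                        minCopies = 3L, minFraction = 0.9,
                        clusterGap = 100000L) {
  sim <- simulateGenome(config)
  transcripts <- simulateLibraries(sim)
  alignments <- mapTranscripts(transcripts, simGenome(sim), thresholds)
  geneSets <- buildGeneSets(alignments, transcripts,
                            models = simulatedModels(sim))
  flc <- transcripts[mcols(transcripts)$type == "FLC"]
  features <- transcriptFeatures(flc)
  profile <- countEstSupport(geneSets, transcripts, config@libraries)
  calls <- callTissueSpecific(profile, minCopies, minFraction)
  callTable <- tissueCallTable(geneSets, calls)
  clusters <- detectClusters(callTable, clusterGap)
  list(sim = sim, transcripts = transcripts, alignments = alignments,
       geneSets = geneSets, features = features, profile = profile,
       calls = calls, callTable = callTable, clusters = clusters,
       chromLengths = setNames(Biostrings::width(simGenome(sim)),
                               names(simGenome(sim))))
}

#' Match built loci to planted truth genes
#'
#' Links each class-A/B locus to the planted gene whose exons overlap its
#' exon union on the same strand (first overlap wins; loci built from one
#' gene's evidence overlap exactly one planted gene in practice).
#'
#' @param geneSets a [GeneLocusSet-class].
#' @param truth a [GroundTruth-class] or [GenomeSimulation-class].
#' @return data.frame `locus_id`, `gene_id` (`NA` where no overlap).
#' @export
matchLociToTruth <- function(geneSets, truth) {
  if (is(truth, "GenomeSimulation")) truth <- simTruth(truth)
  ex <- locusExons(geneSets)
  lo <- lociTable(geneSets)
  te <- truthExons(truth)
  uT <- unlist(te, use.names = FALSE)
  ownerT <- rep(names(te), lengths(te))
  geneOf <- rep(NA_character_, nrow(lo))
  nonEmpty <- which(lengths(ex) > 0L)
  if (length(nonEmpty)) {
    uL <- unlist(ex[nonEmpty], use.names = FALSE)
    ownerL <- rep(nonEmpty, lengths(ex[nonEmpty]))
    hits <- GenomicRanges::findOverlaps(uL, uT, ignore.strand = FALSE)
    if (length(hits)) {
      li <- ownerL[S4Vectors::queryHits(hits)]
      gi <- ownerT[S4Vectors::subjectHits(hits)]
      first <- !duplicated(li)
      geneOf[li[first]] <- gi[first]
    }
  }
  data.frame(locus_id = lo$locus_id, gene_id = geneOf,
             stringsAsFactors = FALSE)
}
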