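# Shared, lazily computed pipeline runs. The reference run uses the
# package's default study conditions (200 genes, six libraries, planted
# ovary/midgut clusters, 5% chimeras) and takes several minutes, so it is
# computed once per test session and reused by every test that needs it.

.runCache <- new.env(parent = emptyenv())

referenceRun <- function() {
  if (is.null(.runCache$ref))
    .runCache$ref <- runPipeline(simulationConfig(seed = 20130901))
  .runCache$ref
}

smallRun <- function() {
  if (is.null(.runCache$small))
    .runCache$small <- runPipeline(smallConfig())
  .runCache$small
}

# truth lookup joined onto calls for a pipeline run
callsWithTruth <- function(res) {
  m2t <- matchLociToTruth(res$geneSets, res$sim)
  tg <- truthGenes(res$sim)
  calls <- as.data.frame(res$calls)
  calls$gene_id <- m2t$gene_id[match(calls$locus_id, m2t$locus_id)]
  calls$truth_tissue <- tg$tissue[match(calls$gene_id, tg$gene_id)]
  calls
}
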