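# Synthetic genome / transcriptome generator.
#
# The generator plants gene structures with known coordinates on a small
# multi-chromosome genome and emits transcript libraries with the artifacts
# the downstream analyses must tolerate (5' truncation, sequencing error,
# poly-A tails, chimeric clones, transposon-filled introns). Every random
# choice derives from the configuration seed, so identical configurations
# reproduce byte-identical outputs.

# tissue label assignment shared by simulateGenome() and simulateLocusCalls().
# Labels are drawn per gene: specific with probability `specificFraction`,
# then a tissue uniformly -- except that on the Z-like chromosome (index 1)
# the testis probability is raised so that the *density* of testis-specific
# genes on Z is `zEnrichment` times the genome-wide average (genes are
# placed uniformly per bp, so the required conditional probability has a
# closed form).
assignTissueLabels <- function(chromIdx, chromLens, tissues,
                               specificFraction, zEnrichment) {
  n <- length(chromIdx)
  labels <- rep("broad", n)
  specific <- runif(n) < specificFraction
  if (!any(specific)) return(labels)
  Tn <- length(tissues)
  pA <- 1 / Tn
  L <- sum(as.numeric(chromLens))
  lZ <- as.numeric(chromLens[1])
  qZ <- pA
  if ("testis" %in% tissues && zEnrichment != 1 && length(chromLens) > 1L) {
    qZ <- zEnrichment * pA * (L - lZ) / (L - zEnrichment * lZ)
    if (qZ >= 1 || qZ <= 0)
      stop("testisZEnrichment = ", zEnrichment,
           " is not attainable with these chromosome lengths")
  }
  other <- setdiff(tissues, "testis")
  for (i in which(specific)) {
    if ("testis" %in% tissues && chromIdx[i] == 1L) {
      if (runif(1) < qZ) labels[i] <- "testis"
      else labels[i] <- sample(other, 1L)
    } else {
      labels[i] <- sample(tissues, 1L)
    }
  }
  labels
}

# intron/exon structure for one gene; returns list(exonLens, intronLens)
drawGeneStructure <- function(config, intronMean = config@intronLengthMean) {
  nEx <- 1L + rpois(1L, max(0, config@exonCountMean - 1))
  exLens <- rShiftedGeom(nEx, config@exonLengthMean, config@exonLengthMin)
  inLens <- if (nEx > 1L)
    rShiftedGeom(nEx - 1L, intronMean, config@intronLengthMin)
  else integer(0)
  list(exonLens = exLens, intronLens = inLens)
}

# exonic (mature-transcript) sequence with a planted ORF:
# [5' UTR] ATG [non-stop codons] TAA [3' UTR]
makeExonicSeq <- function(totalLen) {
  bases <- randomBases(totalLen)
  if (totalLen >= 150L) {
    u5 <- min(60L, totalLen %/% 10L)
    ncodTotal <- (totalLen - u5) %/% 3L
    ncod <- max(35L, floor(ncodTotal * 0.8))
    codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L, paste0,
                    collapse = "")
    codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
    body <- sample(codons, ncod - 2L, replace = TRUE)
    cds <- unlist(strsplit(c("ATG", body, "TAA"), ""), use.names = FALSE)
    bases[(u5 + 1L):(u5 + length(cds))] <- cds
  }
  bases
}

# transposon-like motif library: a handful of fixed 200-500 bp sequences
makeTeLibrary <- function() {
  lens <- sample(200:500, 4L, replace = TRUE)
  lapply(lens, randomBases)
}

# random background of length `len` with ~teFraction of positions covered by
# mutated copies of the TE motifs
fillWithTE <- function(len, teFraction, teLib) {
  bg <- randomBases(len)
  if (teFraction <= 0 || len < 250L) return(bg)
  target <- teFraction * len
  placed <- 0
  guard <- 0L
  while (placed < target && guard < 10000L) {
    guard <- guard + 1L
    motif <- teLib[[sample(length(teLib), 1L)]]
    lm <- length(motif)
    if (lm >= len) break
    s <- sample(len - lm + 1L, 1L)
    bg[s:(s + lm - 1L)] <- mutateAtRate(motif, 0.02)
    placed <- placed + lm
  }
  bg
}

# Given per-junction exon sequences (transcript order), remove splice-shift
# ambiguity so the planted junction is the unique optimum: no GT two bases
# into the exon upstream of a donor, no AG two bases into the exon
# downstream of an acceptor.
guardExonBoundaries <- function(exonSeqs) {
  n <- length(exonSeqs)
  if (n == 0L) return(exonSeqs)
  if (n >= 2L) for (k in seq_len(n - 1L)) {
    up <- exonSeqs[[k]]
    lu <- length(up)
    if (lu >= 2L && up[lu - 1L] == "G" && up[lu] == "T") up[lu] <- "A"
    exonSeqs[[k]] <- up
    dn <- exonSeqs[[k + 1L]]
    if (length(dn) >= 2L && dn[1L] == "A" && dn[2L] == "G") dn[1L] <- "C"
    exonSeqs[[k + 1L]] <- dn
  }
  # a transcript must not end in A, so an appended poly-A tail remains
  # distinguishable from the terminal exon
  lastEx <- exonSeqs[[n]]
  if (length(lastEx) && lastEx[length(lastEx)] == "A")
    lastEx[length(lastEx)] <- "C"
  exonSeqs[[n]] <- lastEx
  exonSeqs
}

#' Simulate a genome with planted gene structures
#'
#' Generates chromosome sequences and a [GroundTruth-class]: gene
#' coordinates, exon structures with canonical GT...AG splice sites,
#' transposon-filled introns and intergenic space, per-gene tissue labels
#' (with testis-specific genes enriched on the Z-like chromosome 1 at the
#' configured density ratio), planted tissue-specific gene clusters with
#' tandem-duplication families, and the mature transcript of every gene.
#'
#' Genes are placed without overlap; a configuration whose genes cannot be
#' placed raises an error naming the first offending gene index.
#'
#' @param config a [SimulationConfig-class], see [simulationConfig()].
#' @return a [GenomeSimulation-class].
#' @examples
#' sim <- simulateGenome(simulationConfig(seed = 7, nGenes = 5,
#'   chromosomeLength = 200000L,
#'   clusterPlantSpec = data.frame(tissue = character(), chromosome = integer(),
#'                                 span = integer(), n_genes = integer())))
#' sim
#' @export
simulateGenome <- function(config) {
  validObject(config)
  set.seed(config@seed)
  nC <- config@nChromosomes
  chromNames <- if (nC == 1L) "chrZ" else c("chrZ", paste0("chr", 2:nC))
  chromLens <- setNames(rep(config@chromosomeLength, nC), chromNames)
  teLib <- makeTeLibrary()
  nG <- config@nGenes

  emptyTruth <- function() {
    g <- GRanges()
    mcols(g) <- DataFrame(gene_id = character(), tissue = character(),
                          cluster_id = character(), family_id = character(),
                          n_exons = integer(), has_model = logical())
    new("GroundTruth", genes = g, exons = GRangesList(),
        matureSeq = DNAStringSet())
  }

  if (nG == 0L) {
    seqs <- DNAStringSet(vapply(chromNames, function(cn)
      paste(fillWithTE(chromLens[[cn]], config@teFraction, teLib),
            collapse = ""), character(1)))
    names(seqs) <- chromNames
    return(new("GenomeSimulation", genome = seqs, truth = emptyTruth(),
               config = config))
  }

  cps <- config@clusterPlantSpec
  nClusterGenes <- if (nrow(cps)) sum(cps$n_genes) else 0L
  if (nClusterGenes > nG)
    stop("planted clusters require more genes than nGenes")

  # ---- gene bookkeeping ----
  geneId <- sprintf("Gene%04d", seq_len(nG))
  chromIdx <- integer(nG)
  clusterId <- rep(NA_character_, nG)
  familyId <- rep(NA_character_, nG)
  inCluster <- logical(nG)
  clusterOf <- rep(NA_integer_, nG)
  idx <- 1L
  if (nrow(cps)) for (k in seq_len(nrow(cps))) {
    nk <- cps$n_genes[k]
    sel <- idx:(idx + nk - 1L)
    chromIdx[sel] <- cps$chromosome[k]
    clusterId[sel] <- paste0("pc", k)
    inCluster[sel] <- TRUE
    clusterOf[sel] <- k
    nDup <- round(config@clusterDupFraction * nk)
    if (nDup >= 2L) familyId[sel[seq_len(nDup)]] <- paste0("fam", k)
    idx <- idx + nk
  }
  free <- idx <= nG
  freeIdx <- if (idx <= nG) idx:nG else integer(0)
  if (length(freeIdx))
    chromIdx[freeIdx] <- sample(nC, length(freeIdx), replace = TRUE,
                                prob = chromLens)

  # tissue labels: cluster genes take their cluster's tissue; free genes are
  # drawn with the Z-density enrichment
  tissue <- rep("broad", nG)
  if (nrow(cps)) tissue[inCluster] <- cps$tissue[clusterOf[inCluster]]
  if (length(freeIdx))
    tissue[freeIdx] <- assignTissueLabels(chromIdx[freeIdx], chromLens,
                                          config@tissues,
                                          config@tissueSpecificFraction,
                                          config@testisZEnrichment)

  # ---- structures ----
  exonLens <- vector("list", nG)
  intronLens <- vector("list", nG)
  founderOf <- rep(NA_integer_, nG)
  for (i in seq_len(nG)) {
    if (!is.na(familyId[i])) {
      prev <- which(familyId == familyId[i])
      prev <- prev[prev < i]
      if (length(prev)) { # duplicate: copy the founder's structure
        founderOf[i] <- prev[1L]
        exonLens[[i]] <- exonLens[[prev[1L]]]
        intronLens[[i]] <- intronLens[[prev[1L]]]
        next
      }
    }
    if (inCluster[i]) {
      k <- clusterOf[i]
      budget <- floor(0.7 * cps$span[k] / cps$n_genes[k])
      st <- drawGeneStructure(config, intronMean = config@intronLengthMean)
      nIn <- length(st$intronLens)
      if (nIn > 0L) {
        adjMean <- max(config@intronLengthMin + 1,
                       (budget - sum(st$exonLens)) / nIn)
        st$intronLens <- rShiftedGeom(nIn, adjMean, config@intronLengthMin)
      }
      exonLens[[i]] <- st$exonLens
      intronLens[[i]] <- st$intronLens
    } else {
      st <- drawGeneStructure(config)
      exonLens[[i]] <- st$exonLens
      intronLens[[i]] <- st$intronLens
    }
  }
  # shrink planted-cluster introns deterministically until the block fits
  if (nrow(cps)) for (k in seq_len(nrow(cps))) {
    sel <- which(clusterOf == k)
    repeat {
      tot <- sum(vapply(sel, function(i)
        sum(exonLens[[i]]) + sum(intronLens[[i]]), numeric(1)))
      if (tot <= 0.9 * cps$span[k]) break
      for (i in sel)
        intronLens[[i]] <- pmax(config@intronLengthMin,
                                as.integer(floor(intronLens[[i]] * 0.8)))
      if (all(vapply(sel, function(i)
        all(intronLens[[i]] == config@intronLengthMin), logical(1)))) break
    }
  }
  geneLen <- vapply(seq_len(nG), function(i)
    sum(exonLens[[i]]) + sum(intronLens[[i]]), numeric(1))
  strandOf <- sample(c("+", "-"), nG, replace = TRUE)

  # ---- sequences (transcript orientation) ----
  exonSeqList <- vector("list", nG)
  for (i in seq_len(nG)) {
    if (!is.na(founderOf[i])) {
      ex <- lapply(exonSeqList[[founderOf[i]]], mutateAtRate, rate = 0.02)
    } else {
      whole <- makeExonicSeq(sum(exonLens[[i]]))
      ends <- cumsum(exonLens[[i]])
      starts <- c(1L, head(ends, -1L) + 1L)
      ex <- Map(function(s, e) whole[s:e], starts, ends)
    }
    exonSeqList[[i]] <- guardExonBoundaries(ex)
  }
  mature <- vapply(exonSeqList, function(ex)
    paste(unlist(ex, use.names = FALSE), collapse = ""), character(1))

  # genomic region per gene (plus orientation first, revcomp if minus)
  regionOf <- vector("list", nG)
  exonStartsInRegion <- vector("list", nG)
  for (i in seq_len(nG)) {
    ex <- exonSeqList[[i]]
    nEx <- length(ex)
    pieces <- vector("list", 2L * nEx - 1L)
    offs <- integer(nEx)
    pos <- 0L
    for (k in seq_len(nEx)) {
      offs[k] <- pos + 1L
      pieces[[2L * k - 1L]] <- ex[[k]]
      pos <- pos + length(ex[[k]])
      if (k < nEx) {
        il <- intronLens[[i]][k]
        intr <- fillWithTE(il, config@teFraction, teLib)
        intr[1L] <- "G"; intr[2L] <- "T"
        intr[il - 1L] <- "A"; intr[il] <- "G"
        if (il >= 8L) { # junction-shift guards
          if (intr[3L] == "G" && intr[4L] == "T") intr[4L] <- "C"
          if (intr[il - 3L] == "A" && intr[il - 2L] == "G") intr[il - 3L] <- "C"
        }
        pieces[[2L * k]] <- intr
        pos <- pos + il
      }
    }
    region <- unlist(pieces, use.names = FALSE)
    exw <- lengths(ex)
    if (strandOf[i] == "-") {
      L <- length(region)
      region <- revcompChar(region)
      offs <- L - (offs + exw - 1L) + 1L # genomic starts after revcomp
    }
    regionOf[[i]] <- region
    exonStartsInRegion[[i]] <- sort(offs)
    exonLens[[i]] <- if (strandOf[i] == "-") rev(exw) else exw # genomic order
  }

  # ---- placement ----
  geneStart <- integer(nG)
  chromSeq <- setNames(vector("list", nC), chromNames)
  for (ci in seq_len(nC)) {
    clHere <- if (nrow(cps)) which(cps$chromosome == ci) else integer(0)
    freeHere <- which(chromIdx == ci & !inCluster)
    # items: each planted cluster is one block; each free gene is one item
    items <- c(lapply(clHere, function(k) list(kind = "cluster", k = k)),
               lapply(freeHere, function(i) list(kind = "gene", i = i)))
    itemLen <- vapply(items, function(it)
      if (it$kind == "cluster") as.numeric(cps$span[it$k])
      else geneLen[it$i], numeric(1))
    minGap <- 8L
    F <- chromLens[[ci]] - sum(itemLen) - minGap * (length(items) + 1L)
    if (F < 0) {
      bad <- if (length(freeHere)) freeHere[1L]
             else which(clusterOf %in% clHere)[1L]
      stop("cannot place gene ", bad, " on ", chromNames[ci],
           ": chromosome too short for the configured genes")
    }
    if (length(items)) {
      items <- items[sample(length(items))]
      itemLen <- vapply(items, function(it)
        if (it$kind == "cluster") as.numeric(cps$span[it$k])
        else geneLen[it$i], numeric(1))
      w <- runif(length(items) + 1L)
      gaps <- floor(F * w / sum(w)) + minGap
      pos <- 1L
      pieces <- list()
      np <- 0L
      push <- function(x) { np <<- np + 1L; pieces[[np]] <<- x }
      for (j in seq_along(items)) {
        g <- fillWithTE(gaps[j], config@teFraction, teLib)
        push(g); pos <- pos + gaps[j]
        it <- items[[j]]
        if (it$kind == "gene") {
          i <- it$i
          geneStart[i] <- pos
          push(regionOf[[i]])
          push(c("C", "G", "C", "G")) # 3' extension guard
          pos <- pos + geneLen[i] + 4L
        } else {
          k <- it$k
          sel <- which(clusterOf == k)
          blockLen <- cps$span[k]
          totG <- sum(geneLen[sel]) + 4L * length(sel)
          slack <- blockLen - totG
          wi <- runif(length(sel) + 1L)
          gi <- floor(slack * wi / sum(wi))
          bpos <- pos
          for (m in seq_along(sel)) {
            i <- sel[m]
            push(fillWithTE(gi[m], config@teFraction, teLib))
            bpos <- bpos + gi[m]
            geneStart[i] <- bpos
            push(regionOf[[i]])
            push(c("C", "G", "C", "G"))
            bpos <- bpos + geneLen[i] + 4L
          }
          lastGap <- blockLen - (bpos - pos)
          if (lastGap > 0L) push(fillWithTE(lastGap, config@teFraction, teLib))
          pos <- pos + blockLen
        }
      }
      tailLen <- chromLens[[ci]] - (pos - 1L)
      if (tailLen > 0L) push(fillWithTE(tailLen, config@teFraction, teLib))
      chromSeq[[ci]] <- paste(unlist(pieces, use.names = FALSE), collapse = "")
    } else {
      chromSeq[[ci]] <- paste(fillWithTE(chromLens[[ci]], config@teFraction,
                                         teLib), collapse = "")
    }
  }
  genome <- DNAStringSet(unlist(chromSeq))
  names(genome) <- chromNames

  hasModel <- runif(nG) < config@modelFraction

  genes <- GRanges(factor(chromNames[chromIdx], levels = chromNames),
                   IRanges(geneStart, geneStart + as.integer(geneLen) - 1L),
                   strand = strandOf,
                   gene_id = geneId, tissue = tissue, cluster_id = clusterId,
                   family_id = familyId,
                   n_exons = lengths(exonLens), has_model = hasModel)
  seqlengths(genes) <- chromLens

  exonsGRL <- GRangesList(lapply(seq_len(nG), function(i) {
    s <- geneStart[i] + exonStartsInRegion[[i]] - 1L
    gr <- GRanges(factor(chromNames[chromIdx[i]], levels = chromNames),
                  IRanges(s, s + exonLens[[i]] - 1L),
                  strand = strandOf[i])
    seqlengths(gr) <- chromLens
    gr
  }))
  names(exonsGRL) <- geneId
  matureSet <- DNAStringSet(mature)
  names(matureSet) <- geneId

  truth <- new("GroundTruth", genes = genes, exons = exonsGRL,
               matureSeq = matureSet)
  new("GenomeSimulation", genome = genome, truth = truth, config = config)
}

#' Predicted gene models of a simulation
#'
#' Returns the planted exon structures of the genes flagged as covered by a
#' gene predictor (fraction `modelFraction` of genes), as a `GRangesList`
#' named by model id (`"model_<gene>"`). These stand in for an external
#' GFF3 of predictions in the gene build.
#'
#' @param sim a [GenomeSimulation-class].
#' @return `GRangesList` of exons per model.
#' @export
simulatedModels <- function(sim) {
  stopifnot(is(sim, "GenomeSimulation"))
  g <- truthGenes(sim)
  sel <- which(g$has_model)
  mods <- truthExons(sim)[sel]
  names(mods) <- paste0("model_", g$gene_id[sel])
  mods
}

#' Simulate transcript libraries from a simulated genome
#'
#' Emits, per the configuration: 5' ESTs (5'-anchored, truncated,
#' error-mutated copies of the mature transcript, drawn per library with
#' tissue-specific genes expressed almost exclusively in their own
#' tissue), one poly-A-tailed FL-cDNA clone per gene, public-mRNA style
#' records for a fraction of genes, and chimeric FL-cDNA clones formed by
#' fusing the 5' half of one transcript to the 3' half of another
#' (partner genes on different chromosomes or > 250 kb apart, mature-length
#' ratio at most 3).
#'
#' Randomness derives from `seed(config) + 1`, so a simulation and its
#' libraries are jointly reproducible.
#'
#' @param sim a [GenomeSimulation-class].
#' @return a [TranscriptSet-class] with truth metadata columns.
#' @export
simulateLibraries <- function(sim) {
  stopifnot(is(sim, "GenomeSimulation"))
  config <- sim@config
  set.seed(config@seed + 1L)
  truth <- sim@truth
  genes <- truth@genes
  nG <- length(genes)
  mature <- as.character(truth@matureSeq)
  tissues <- config@tissues
  Tn <- length(tissues)
  lib <- config@libraries
  if (nrow(lib) && !all(lib$tissue %in% tissues))
    stop("library manifest names unknown tissue(s): ",
         paste(setdiff(lib$tissue, tissues), collapse = ", "))

  seqs <- character(0)
  meta <- list()
  addRec <- function(seq, clone, library, tissueOf, type, g1, g2, chim, off) {
    seqs[[length(seqs) + 1L]] <<- seq
    meta[[length(meta) + 1L]] <<- data.frame(
      clone_id = clone, library = library, tissue = tissueOf, type = type,
      source_gene = g1, source_gene2 = g2, is_chimera = chim,
      trunc_offset = off, stringsAsFactors = FALSE)
  }

  if (nG > 0L) {
    # expression weights gene x tissue
    leak <- config@specificityLeak
    W <- matrix(1, nrow = nG, ncol = Tn, dimnames = list(genes$gene_id, tissues))
    spec <- genes$tissue != "broad"
    for (i in which(spec)) {
      W[i, ] <- Tn * leak / max(1L, Tn - 1L)
      W[i, genes$tissue[i]] <- Tn * (1 - leak)
    }

    # ---- ESTs ----
    if (nrow(lib)) for (r in seq_len(nrow(lib))) {
      tis <- lib$tissue[r]
      nE <- lib$n_ests[r]
      if (nE <= 0L) next
      counts <- as.integer(rmultinom(1L, nE, prob = W[, tis]))
      eid <- 0L
      for (g in which(counts > 0L)) {
        for (j in seq_len(counts[g])) {
          eid <- eid + 1L
          mlen <- nchar(mature[g])
          off <- rShiftedGeom(1L, config@estTruncationMean, 0L)
          off <- min(off, max(0L, mlen - 100L))
          readLen <- min(config@estReadLength, mlen - off)
          bases <- strsplit(substr(mature[g], off + 1L, off + readLen), "")[[1]]
          bases <- mutateAtRate(bases, config@estErrorRate)
          addRec(paste(bases, collapse = ""),
                 sprintf("%s_%05d", lib$library[r], eid),
                 lib$library[r], tis, "EST", genes$gene_id[g], NA_character_,
                 FALSE, off)
        }
      }
    }

    polyaTail <- function() {
      len <- config@polyaMin +
        rpois(1L, max(0, config@polyaMean - config@polyaMin))
      strrep("A", len)
    }
    pickLibrary <- function(g) {
      if (!nrow(lib)) return(c(NA_character_, NA_character_))
      tis <- sample(tissues, 1L, prob = W[g, ])
      rows <- which(lib$tissue == tis)
      if (!length(rows)) rows <- seq_len(nrow(lib))
      r <- if (length(rows) == 1L) rows else
        sample(rows, 1L, prob = lib$n_ests[rows])
      c(lib$library[r], lib$tissue[r])
    }

    # ---- proper FL-cDNAs, one per gene ----
    for (g in seq_len(nG)) {
      lt <- pickLibrary(g)
      addRec(paste0(mature[g], polyaTail()), sprintf("FLC%04d", g),
             lt[1L], lt[2L], "FLC", genes$gene_id[g], NA_character_, FALSE, 0L)
    }

    # ---- chimeric FL-cDNAs ----
    rate <- config@chimeraRate
    nChim <- if (rate > 0 && nG >= 2L)
      rbinom(1L, nG, rate / (1 - rate)) else 0L
    chrOf <- as.character(seqnames(genes))
    made <- 0L
    tries <- 0L
    while (made < nChim && tries < 200L * nChim) {
      tries <- tries + 1L
      pair <- sample(nG, 2L)
      a <- pair[1L]; b <- pair[2L]
      farApart <- chrOf[a] != chrOf[b] ||
        (min(abs(start(genes)[a] - end(genes)[b]),
             abs(start(genes)[b] - end(genes)[a])) > 250000L)
      la <- nchar(mature[a]); lb <- nchar(mature[b])
      if (!farApart || max(la, lb) > 3L * min(la, lb)) next
      made <- made + 1L
      h5 <- substr(mature[a], 1L, la %/% 2L)
      h3 <- substr(mature[b], lb %/% 2L + 1L, lb)
      lt <- pickLibrary(a)
      addRec(paste0(h5, h3, polyaTail()), sprintf("CHI%03d", made),
             lt[1L], lt[2L], "FLC", genes$gene_id[a], genes$gene_id[b],
             TRUE, 0L)
    }

    # ---- public-mRNA style records ----
    nM <- floor(config@mrnaFraction * nG)
    if (nM > 0L) {
      sel <- sort(sample(nG, nM))
      for (g in sel)
        addRec(mature[g], sprintf("MRN%04d", g), NA_character_, NA_character_,
               "mRNA", genes$gene_id[g], NA_character_, FALSE, 0L)
    }
  }

  md <- if (length(meta)) do.call(rbind, meta) else
    data.frame(clone_id = character(), library = character(),
               tissue = character(), type = character(),
               source_gene = character(), source_gene2 = character(),
               is_chimera = logical(), trunc_offset = integer(),
               stringsAsFactors = FALSE)
  ts <- DNAStringSet(unlist(seqs, use.names = FALSE))
  names(ts) <- md$clone_id
  mcols(ts) <- DataFrame(md)
  new("TranscriptSet", ts)
}

#' Simulate gene positions and tissue calls only
#'
#' A lightweight companion to [simulateGenome()] that draws only locus
#' coordinates and tissue-specificity labels (no sequences), using the same
#' label-assignment machinery, including the Z-chromosome testis-density
#' enrichment and optional planted clusters. Intended for statistical
#' calibration runs (null replicates of the adjacency test, density-ratio
#' recovery) where sequence-level simulation would add nothing.
#'
#' @param seed integer seed.
#' @param nLoci number of loci.
#' @param nChromosomes,chromosomeLength genome frame.
#' @param tissues tissue names.
#' @param specificFraction probability a locus is tissue-specific.
#' @param testisZEnrichment target testis density ratio on chromosome 1.
#' @param clusterPlant optional data.frame (`tissue`, `chromosome`, `span`,
#'   `n_genes`) of planted clusters.
#' @param locusWidth mean locus width (bp), exponential-ish spread.
#' @return list with elements `calls` (data.frame `locus_id`, `chromosome`,
#'   `start`, `end`, `specific_tissue` with `NA` for broadly expressed
#'   loci) and `chromLengths` (named numeric).
#' @export
simulateLocusCalls <- function(seed, nLoci, nChromosomes = 4L,
                               chromosomeLength = 1200000L,
                               tissues = c("testis", "ovary", "midgut",
                                           "fat_body", "brain"),
                               specificFraction = 0.3,
                               testisZEnrichment = 1,
                               clusterPlant = NULL,
                               locusWidth = 3000L) {
  set.seed(seed)
  nC <- as.integer(nChromosomes)
  chromNames <- if (nC == 1L) "chrZ" else c("chrZ", paste0("chr", 2:nC))
  chromLens <- setNames(rep(as.numeric(chromosomeLength), nC), chromNames)
  nCl <- if (is.null(clusterPlant)) 0L else sum(clusterPlant$n_genes)
  if (nCl > nLoci) stop("planted clusters exceed nLoci")
  chromIdx <- integer(nLoci)
  start <- numeric(nLoci)
  tissueLab <- rep("broad", nLoci)
  idx <- 1L
  if (nCl > 0L) for (k in seq_len(nrow(clusterPlant))) {
    nk <- clusterPlant$n_genes[k]
    sel <- idx:(idx + nk - 1L)
    chromIdx[sel] <- clusterPlant$chromosome[k]
    s0 <- runif(1L, 1, chromLens[clusterPlant$chromosome[k]] -
                  clusterPlant$span[k])
    start[sel] <- sort(runif(nk, s0, s0 + clusterPlant$span[k] - locusWidth))
    tissueLab[sel] <- clusterPlant$tissue[k]
    idx <- idx + nk
  }
  if (idx <= nLoci) {
    sel <- idx:nLoci
    chromIdx[sel] <- sample(nC, length(sel), replace = TRUE, prob = chromLens)
    start[sel] <- runif(length(sel), 1, chromLens[chromIdx[sel]] - locusWidth)
    tissueLab[sel] <- assignTissueLabels(chromIdx[sel], chromLens, tissues,
                                         specificFraction, testisZEnrichment)
  }
  w <- pmax(200, rShiftedGeom(nLoci, locusWidth, 200L))
  calls <- data.frame(
    locus_id = sprintf("L%05d", seq_len(nLoci)),
    chromosome = chromNames[chromIdx],
    start = floor(start), end = floor(start) + w - 1,
    specific_tissue = ifelse(tissueLab == "broad", NA_character_, tissueLab),
    stringsAsFactors = FALSE)
  list(calls = calls, chromLengths = chromLens)
}

#' Write a simulation to disk
#'
#' Emits the standard plain-text fixture set: genome FASTA, truth
#' annotation GFF3 (gene/mRNA/exon features, 1-based inclusive), predicted
#' gene-model GFF3, per-gene truth TSV and, when a [TranscriptSet-class] is
#' supplied, a transcript FASTA (headers `clone_id|library|type`), the
#' library manifest TSV and a per-transcript truth TSV.
#'
#' @param sim a [GenomeSimulation-class].
#' @param dir output directory (created if needed).
#' @param transcripts optional [TranscriptSet-class].
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir, transcripts = NULL) {
  stopifnot(is(sim, "GenomeSimulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeXStringSet(sim@genome, file.path(dir, "genome.fasta"), width = 70L)

  g <- truthGenes(sim)
  ex <- truthExons(sim)
  feats <- c(
    GRanges(seqnames(g), IRanges(start(g), end(g)), strand = strand(g),
            type = "gene", ID = g$gene_id, Parent = NA_character_),
    GRanges(seqnames(g), IRanges(start(g), end(g)), strand = strand(g),
            type = "mRNA", ID = paste0(g$gene_id, ".t1"), Parent = g$gene_id))
  exu <- unlist(ex, use.names = TRUE)
  exf <- GRanges(seqnames(exu), IRanges(start(exu), end(exu)),
                 strand = strand(exu), type = "exon",
                 ID = NA_character_, Parent = paste0(names(exu), ".t1"))
  feats <- sort(c(feats, exf), ignore.strand = TRUE)
  rtracklayer::export(feats, file.path(dir, "truth.gff3"), format = "gff3")

  mods <- simulatedModels(sim)
  if (length(mods)) {
    mu <- unlist(mods, use.names = TRUE)
    mf <- c(GRanges(seqnames(mu), IRanges(start(mu), end(mu)),
                    strand = strand(mu), type = "match_part",
                    ID = NA_character_, Parent = names(mu)))
    rtracklayer::export(sort(mf, ignore.strand = TRUE),
                        file.path(dir, "models.gff3"), format = "gff3")
  }

  gt <- data.frame(gene_id = g$gene_id, chromosome = as.character(seqnames(g)),
                   start = start(g), end = end(g),
                   strand = as.character(strand(g)), tissue = g$tissue,
                   cluster_id = g$cluster_id, family_id = g$family_id,
                   n_exons = g$n_exons)
  write.table(gt, file.path(dir, "truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  if (!is.null(transcripts)) {
    stopifnot(is(transcripts, "TranscriptSet"))
    md <- as.data.frame(mcols(transcripts))
    out <- DNAStringSet(unname(as.character(transcripts)))
    names(out) <- paste(md$clone_id,
                        ifelse(is.na(md$library), ".", md$library),
                        md$type, sep = "|")
    writeXStringSet(out, file.path(dir, "transcripts.fasta"), width = 70L)
    write.table(simConfig(sim)@libraries, file.path(dir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(md, file.path(dir, "truth_transcripts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
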