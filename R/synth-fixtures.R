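# Layout constants of the synthetic protein backbone: five conserved-region
# windows (width 12) separated by fixed-length linkers. All generated
# proteins share this 220-aa frame, so their coding sequences align without
# gaps and the canonical intron positions fall on fixed columns.
.FIX <- list(
  linkerLens = c(20L, 30L, 30L, 30L, 30L, 20L),
  regionWidth = 12L,
  proteinLen = 220L)

#' @noRd
linkerPositions <- function() {
  lens <- .FIX$linkerLens; w <- .FIX$regionWidth
  pos <- integer(); at <- 0L
  for (i in seq_along(lens)) {
    pos <- c(pos, at + seq_len(lens[i]))
    at <- at + lens[i] + if (i < length(lens)) w else 0L
  }
  pos  # 1-based indices of linker residues
}

# residue frequencies used for linkers: charged residues common enough that
# greedy K/R <-> D/E swapping can reach any pI target in (3, 12)
.LINKER_FREQ <- c(A = 0.09, G = 0.08, L = 0.08, S = 0.08, T = 0.07,
                  V = 0.07, N = 0.06, Q = 0.06, I = 0.06, F = 0.05,
                  P = 0.05, M = 0.02, W = 0.01, Y = 0.02, H = 0.02,
                  C = 0.01, K = 0.08, R = 0.08, D = 0.08, E = 0.08)

# deterministic 220-aa backbone: exemplar windows joined by random linkers
#' @noRd
buildBackbone <- function(seed, panel) {
  withSeed(seed, {
    pieces <- character()
    lens <- .FIX$linkerLens
    regions <- panel@regions
    for (i in seq_along(lens)) {
      pieces <- c(pieces, paste(sample(names(.LINKER_FREQ), lens[i],
                                       replace = TRUE, prob = .LINKER_FREQ),
                                collapse = ""))
      if (i <= length(regions)) {
        w <- regions[[i]]$windows
        pieces <- c(pieces, w[sample.int(length(w), 1L)])
      }
    }
    res <- strsplit(paste(pieces, collapse = ""), "")[[1]]
    res[1] <- "M"  # initiator methionine, so the CDS is ATG-anchored
    res
  })
}

#' Generate a synthetic T2-RNase-like protein with a target pI
#'
#' Builds a 220-residue backbone by concatenating one exemplar window per
#' conserved region (so all five regions are recovered by
#' [scanConservedRegions()]) with random linkers, then greedily swaps
#' K/R <-> D/E at linker positions until the Bjellqvist isoelectric point is
#' within 0.3 pH of the target. Deterministic for a given seed.
#'
#' When `backboneSeed` is supplied, the initial backbone is derived from
#' that seed instead of `seed`, and `mutationRate` of the linker positions
#' are then mutated under `seed`. Records sharing a `backboneSeed` thus form
#' a coherent sequence family (within-group similarity far above
#' between-group similarity), emulating the clade structure of a real gene
#' family — this is what makes nearest-reference classification
#' informative on synthetic panels.
#'
#' @param classLabel `"I"`, `"II"` or `"III"` (recorded as provenance).
#' @param pITarget target isoelectric point, in (3, 12).
#' @param seed integer seed.
#' @param id record identifier.
#' @param panel a [MotifPanel-class] supplying the exemplar windows.
#' @param maxSwaps swap budget before giving up.
#' @param backboneSeed optional seed of a shared family backbone.
#' @param mutationRate fraction of linker positions mutated away from the
#'   shared backbone (only used with `backboneSeed`).
#' @return a [ProteinRecord-class].
#' @export
makeProtein <- function(classLabel, pITarget, seed,
                        id = sprintf("%s_pi%.1f_s%d", classLabel, pITarget,
                                     seed),
                        panel = defaultMotifPanel(), maxSwaps = 500L,
                        backboneSeed = NULL, mutationRate = 0.15) {
  stopifnot(pITarget > 3, pITarget < 12)
  res <- buildBackbone(if (is.null(backboneSeed)) seed else backboneSeed,
                       panel)
  withSeed(seed + 1L, {
    lp <- setdiff(linkerPositions(), 1L)  # keep the initiator Met
    if (!is.null(backboneSeed) && mutationRate > 0) {
      nMut <- round(mutationRate * length(lp))
      at <- sample(lp, nMut)
      res[at] <- sample(names(.LINKER_FREQ), nMut, replace = TRUE,
                        prob = .LINKER_FREQ)
    }
    for (swap in seq_len(maxSwaps + 1L)) {
      cur <- isoelectricPoint(paste(res, collapse = ""), digits = NA)
      if (abs(cur - pITarget) <= 0.3) break
      if (swap > maxSwaps)
        stop("pI target ", pITarget, " unreachable within ", maxSwaps,
             " swaps", call. = FALSE)
      if (cur < pITarget) {
        from <- lp[res[lp] %in% c("D", "E")]
        if (length(from) == 0L) from <- lp[!res[lp] %in% c("K", "R", "H")]
        res[from[sample.int(length(from), 1L)]] <- sample(c("K", "R"), 1L)
      } else {
        from <- lp[res[lp] %in% c("K", "R")]
        if (length(from) == 0L) from <- lp[!res[lp] %in% c("D", "E")]
        res[from[sample.int(length(from), 1L)]] <- sample(c("D", "E"), 1L)
      }
    }
    ProteinRecord(id, paste(res, collapse = ""),
                  source = paste0("synthetic class ", classLabel))
  })
}

#' Realize a synthetic gene structure for a canonical intron pattern
#'
#' Back-translates the protein with a fixed codon table, appends a stop
#' codon, and inserts `GT..AG` introns at the coding offsets of the
#' pattern's canonical positions (correct phases by construction). Emits
#' the gene structure on a small contig fragment together with the
#' (ungapped) aligned CDS row of the package's reference frame.
#'
#' @param protein a [ProteinRecord-class] or amino-acid string.
#' @param patternName a [patternCatalog()] name, or `"no-intron"`.
#' @param seed integer seed (intron lengths/sequences, flanks).
#' @param strand strand on which the gene is planted.
#' @param flankNt random flanking sequence on each side of the gene.
#' @return list with `gene` ([GeneStructure-class]), `contig` (fragment
#'   sequence), `alignedRow` (gapless CDS row in the reference frame),
#'   `positions` (canonical intron positions realized), `cds`.
#' @export
makeGene <- function(protein, patternName, seed, strand = "+",
                     flankNt = 50L) {
  prot <- if (is(protein, "ProteinRecord")) protein@seq else protein
  pid <- if (is(protein, "ProteinRecord")) protein@id else "gene"
  positions <- if (patternName == "no-intron") integer()
  else {
    cat <- patternCatalog()
    if (!patternName %in% names(cat))
      stop("unknown pattern: ", patternName, call. = FALSE)
    cat[[patternName]]$positions
  }
  cds <- paste0(backTranslate(prot), "TAA")
  ref <- canonicalIntronTable()
  offsets <- sort(ref$refColumn[match(positions, ref$position)])
  if (any(offsets >= nchar(cds)))
    stop("pattern positions beyond CDS length", call. = FALSE)
  withSeed(seed, {
    cuts <- c(0L, offsets, nchar(cds))
    exonSeqs <- substring(cds, cuts[-length(cuts)] + 1L, cuts[-1])
    introns <- vapply(seq_along(offsets), function(i)
      paste0("GT", paste(sample(c("A", "C", "G", "T"),
                                sample(36:76, 1L), replace = TRUE),
                         collapse = ""), "AG"), "")
    flank5 <- paste(sample(c("A", "C", "G", "T"), flankNt, TRUE),
                    collapse = "")
    flank3 <- paste(sample(c("A", "C", "G", "T"), flankNt, TRUE),
                    collapse = "")
    gene <- character(2 * length(exonSeqs) - 1L)
    gene[seq(1L, length(gene), by = 2L)] <- exonSeqs
    if (length(introns)) gene[seq(2L, length(gene), by = 2L)] <- introns
    frag <- paste0(flank5, paste(gene, collapse = ""), flank3)
    # exon coordinates on the (plus-strand) fragment
    at <- flankNt
    starts <- integer(length(exonSeqs)); ends <- integer(length(exonSeqs))
    for (i in seq_along(exonSeqs)) {
      starts[i] <- at
      at <- at + nchar(exonSeqs[i])
      ends[i] <- at
      if (i <= length(introns)) at <- at + nchar(introns[i])
    }
    if (strand == "-") {
      frag <- revcompString(frag)
      n <- nchar(frag)
      newStarts <- n - ends; newEnds <- n - starts
      ord <- order(newStarts)
      starts <- newStarts[ord]; ends <- newEnds[ord]
    }
    contigId <- paste0("ctg_", pid)
    list(gene = GeneStructure(pid, contigId, strand, starts, ends,
                              contigSeq = frag),
         contig = frag, contigId = contigId, alignedRow = cds,
         positions = positions, cds = cds)
  })
}

#' Generate a labeled panel of synthetic proteins and gene structures
#'
#' Emulates the class structure of the land-plant T2/S-RNase family:
#' per-class isoelectric-point distributions (class I acidic around 5.0,
#' class II around 5.9, class III basic around 8.8, mirroring the published
#' class medians) and class-specific intron patterns drawn with the
#' family's modal frequencies (I-D and III-C dominant, class II invariant).
#'
#' Per-class pI targets are truncated normals: the swap-based generator
#' tunes charge in integer residue steps, so isoelectric points in the
#' sparsely ionizable band around neutrality (roughly 6.8-8.1) are not
#' finely reachable and the class ranges are clipped away from it — class
#' I/II draws stay acidic, class III draws stay basic, matching the
#' published class-wise distributions.
#'
#' @param nPerClass records per class.
#' @param seed integer seed.
#' @param piMeans,piSds named per-class pI target distributions.
#' @param piRanges named list of per-class truncation bounds `c(lo, hi)`.
#' @param backboneSeeds named per-class backbone seeds; members of a class
#'   are mutated copies of one shared backbone (the same backbones the
#'   bundled reference panel was drawn from), emulating within-clade
#'   similarity.
#' @param mutationRate linker mutation rate away from the class backbone.
#' @param panel a [MotifPanel-class].
#' @return list with `seqs` (named protein strings), `genes` (named list of
#'   [GeneStructure-class]), `alignment` (named gapless CDS rows), and
#'   `truth` (data.frame: id, class, pattern, piTarget, pI).
#' @export
makeClassPanel <- function(nPerClass = 10L, seed = 1L,
                           piMeans = c(I = 5.0, II = 5.9, III = 8.8),
                           piSds = c(I = 0.8, II = 0.8, III = 0.7),
                           piRanges = list(I = c(3.9, 6.1), II = c(4.3, 6.1),
                                           III = c(8.4, 9.9)),
                           backboneSeeds = c(I = 101L, II = 202L, III = 303L),
                           mutationRate = 0.15,
                           panel = defaultMotifPanel()) {
  patternsByClass <- list(
    I = c("I-D", "I-C", "I-A", "I-B"),
    II = "II",
    III = c("III-C", "III-D", "III-A", "III-B*"))
  patternProb <- list(I = c(0.6, 0.25, 0.075, 0.075), II = 1,
                      III = c(0.6, 0.2, 0.15, 0.05))
  draws <- withSeed(seed, {
    lapply(c("I", "II", "III"), function(cl) {
      data.frame(
        class = cl,
        pattern = sample(patternsByClass[[cl]], nPerClass, replace = TRUE,
                         prob = patternProb[[cl]]),
        piTarget = pmin(piRanges[[cl]][2],
                        pmax(piRanges[[cl]][1],
                             stats::rnorm(nPerClass, piMeans[[cl]],
                                          piSds[[cl]]))),
        seed = sample.int(2^30, nPerClass),
        stringsAsFactors = FALSE)
    })
  })
  truth <- do.call(rbind, draws)
  truth$id <- sprintf("syn_%s_%02d", truth$class,
                      unlist(lapply(draws, function(d) seq_len(nrow(d)))))
  seqs <- character(); genes <- list(); aln <- character()
  pIs <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    rec <- makeProtein(truth$class[i], truth$piTarget[i], truth$seed[i],
                       id = truth$id[i], panel = panel,
                       backboneSeed = backboneSeeds[[truth$class[i]]],
                       mutationRate = mutationRate)
    g <- makeGene(rec, truth$pattern[i], truth$seed[i] + 1L)
    seqs[truth$id[i]] <- rec@seq
    genes[[truth$id[i]]] <- g$gene
    aln[truth$id[i]] <- g$alignedRow
    pIs[i] <- isoelectricPoint(rec@seq)
  }
  truth$pI <- pIs
  list(seqs = seqs, genes = genes, alignment = aln,
       truth = truth[, c("id", "class", "pattern", "piTarget", "pI")])
}

# all-frame stop pad: its own reverse complement, contains a stop codon in
# every frame on both strands, so planted features never fuse with the
# random background
.STOP_PAD <- "TTAATTAATTAA"

#' Generate a 2-Mb haplotype contig with planted, known-truth features
#'
#' Plants RNase gene(s) (synthetic class exemplars with their class-typical
#' intron pattern), intact F-box ORFs (ATG..stop, lengths uniform over the
#' canonical 900-1800 nt window), and stop-disrupted F-box copies (one
#' internal codon replaced by a stop) at random non-overlapping positions
#' on an i.i.d. uniform background. Every feature is padded with a short
#' all-frame stop block so the planted coordinates are exactly the
#' coordinates an ORF scan recovers. Optional decoy F-box-like sequences
#' outside the 900-1800 nt bounds exercise the scanner's length filter.
#'
#' @param seed integer seed.
#' @param contigLength background length in nucleotides.
#' @param rnaseClasses character vector of RNase loci to plant (one gene
#'   per entry; `"I"`, `"II"` or `"III"`).
#' @param nFboxIntact,nFboxDisrupted planted F-box counts.
#' @param nDecoyShort,nDecoyLong F-box-like decoys below/above the length
#'   bounds.
#' @param rnaseRegion,fboxRegion optional `c(lo, hi)` placement windows
#'   (0-based contig coordinates) for RNase loci and F-box loci.
#' @param fboxRefs exemplar panel, see [fboxReferences()].
#' @param panel a [MotifPanel-class].
#' @return list with `contig` (sequence) and `truth` (data.frame: type,
#'   start, end, strand, classLabel).
#' @export
makeHaplotype <- function(seed, contigLength = 2e6L, rnaseClasses = "III",
                          nFboxIntact = 6L, nFboxDisrupted = 2L,
                          nDecoyShort = 0L, nDecoyLong = 0L,
                          rnaseRegion = NULL, fboxRegion = NULL,
                          fboxRefs = fboxReferences(),
                          panel = defaultMotifPanel()) {
  contigLength <- as.integer(contigLength)
  withSeed(seed, {
    background <- paste(sample(c("A", "C", "G", "T"), contigLength,
                               replace = TRUE), collapse = "")
    occupied <- data.frame(start = integer(), end = integer())
    pieces <- list()
    truth <- list()
    place <- function(fragment, region) {
      fragLen <- nchar(fragment) + 2L * nchar(.STOP_PAD)
      lo <- max(0L, as.integer(region[1]))
      hi <- min(contigLength - fragLen, as.integer(region[2]) - fragLen)
      if (hi < lo) stop("placement region too small", call. = FALSE)
      for (try in 1:1000) {
        at <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        clash <- nrow(occupied) > 0L &&
          any(occupied$start < at + fragLen & occupied$end > at)
        if (!clash) {
          occupied <<- rbind(occupied,
                             data.frame(start = at, end = at + fragLen))
          pieces[[length(pieces) + 1L]] <<- list(at = at, frag = fragment)
          return(at + nchar(.STOP_PAD))  # start of the feature proper
        }
      }
      stop("could not place feature without overlap", call. = FALSE)
    }
    padded <- function(x) paste0(.STOP_PAD, x, .STOP_PAD)
    rnRegion <- if (is.null(rnaseRegion))
      c(floor(contigLength * 0.4), floor(contigLength * 0.6))
    else rnaseRegion
    fbRegion <- if (is.null(fboxRegion)) c(0L, contigLength) else fboxRegion
    classPattern <- c(I = "I-D", II = "II", III = "III-C")
    classPi <- c(I = 5.0, II = 5.9, III = 9.0)
    for (ci in seq_along(rnaseClasses)) {
      cl <- rnaseClasses[ci]
      rec <- makeProtein(cl, classPi[[cl]], sample.int(2^30, 1L),
                         panel = panel)
      g <- makeGene(rec, classPattern[[cl]], sample.int(2^30, 1L))
      at <- place(padded(g$contig), rnRegion)
      truth[[length(truth) + 1L]] <- data.frame(
        type = "rnase", start = at, end = at + nchar(g$contig),
        strand = "+", classLabel = cl, stringsAsFactors = FALSE)
    }
    plantFbox <- function(aaLen, disrupt) {
      ref <- fboxRefs[[sample.int(length(fboxRefs), 1L)]]
      aaLen <- min(aaLen, nchar(ref))
      codons <- substring(backTranslate(substr(ref, 1L, aaLen)),
                          seq(1L, 3L * aaLen, by = 3L),
                          seq(3L, 3L * aaLen, by = 3L))
      if (disrupt) codons[ceiling(aaLen / 2)] <- "TGA"
      cdsNt <- paste0("ATG", paste(codons, collapse = ""), "TAA")
      strand <- sample(c("+", "-"), 1L)
      frag <- if (strand == "+") cdsNt else revcompString(cdsNt)
      at <- place(padded(frag), fbRegion)
      data.frame(type = if (disrupt) "fbox_disrupted" else "fbox_intact",
                 start = at, end = at + nchar(frag), strand = strand,
                 classLabel = NA_character_, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nFboxIntact))
      truth[[length(truth) + 1L]] <- plantFbox(sample(298:598, 1L), FALSE)
    for (i in seq_len(nFboxDisrupted))
      truth[[length(truth) + 1L]] <- plantFbox(sample(420:520, 1L), TRUE)
    for (i in seq_len(nDecoyShort)) {
      d <- plantFbox(sample(120:280, 1L), FALSE); d$type <- "decoy_short"
      truth[[length(truth) + 1L]] <- d
    }
    for (i in seq_len(nDecoyLong)) {
      ref <- fboxRefs[[sample.int(length(fboxRefs), 1L)]]
      prot <- paste0(ref, substr(ref, 1L, 120L))  # > 1.8 kb once coded
      cdsNt <- paste0("ATG", backTranslate(prot), "TAA")
      strand <- sample(c("+", "-"), 1L)
      frag <- if (strand == "+") cdsNt else revcompString(cdsNt)
      at <- place(padded(frag), fbRegion)
      truth[[length(truth) + 1L]] <- data.frame(
        type = "decoy_long", start = at, end = at + nchar(frag),
        strand = strand, classLabel = NA_character_, stringsAsFactors = FALSE)
    }
    contig <- background
    for (p in pieces) {
      substr(contig, p$at + 1L, p$at + nchar(p$frag)) <- p$frag
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(contig = contig, truth = truth)
  })
}
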