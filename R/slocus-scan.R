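#' Find open reading frames on both strands of a contig
#'
#' An ORF is an `ATG..stop` stretch (stop codon included in the length) with
#' no internal stop, scanned in all three frames of both strands. One ORF is
#' reported per (strand, frame, stop): the one anchored at the 5'-most ATG
#' after the previous in-frame stop, i.e. the longest ORF ending at that
#' stop. Codons containing `N` translate to `X` and never count as stops.
#' Runs of `minNRun` or more `N`s break the scan (ORFs never span assembly
#' gaps). Length bounds are inclusive.
#'
#' @param contig nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param minNt,maxNt inclusive ORF length bounds in nucleotides (defaults
#'   900 and 1800, the canonical S-locus F-box gene size window).
#' @param minNRun N-run length treated as an assembly gap.
#' @return data.frame with one row per ORF: `start`, `end` (0-based
#'   half-open contig coordinates), `strand`, `frame` (0-2 on its strand),
#'   `ntLength`, `protein` (translated, stop codon dropped).
#' @export
findOrfs <- function(contig, minNt = 900L, maxNt = 1800L, minNRun = 10L) {
  contig <- toupper(contig)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      ntLength = integer(), protein = character(),
                      stringsAsFactors = FALSE)
  segs <- contigSegments(contig, minNRun)
  out <- list(empty)
  for (seg in segs) {
    segLen <- seg$end - seg$start
    if (segLen < minNt) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seg$seq else revcompString(seg$seq)
      for (f in 0:2) {
        if (segLen - f < 3L) next
        at <- seq(f + 1L, segLen - 2L, by = 3L)
        codons <- substring(s, at, at + 2L)
        stops <- which(codons %in% STOP_CODONS)
        if (length(stops) == 0L) next
        atgs <- which(codons == "ATG")
        if (length(atgs) == 0L) next
        prev <- c(0L, stops[-length(stops)])
        j <- findInterval(prev, atgs) + 1L
        valid <- j <= length(atgs)
        j <- j[valid]; st <- stops[valid]
        valid2 <- atgs[j] < st
        a <- atgs[j[valid2]]; st <- st[valid2]
        if (length(a) == 0L) next
        len <- 3L * (st - a + 1L)
        keep <- len >= minNt & len <= maxNt
        if (!any(keep)) next
        a <- a[keep]; st <- st[keep]; len <- len[keep]
        # coordinates on the oriented segment
        oStart <- f + 3L * (a - 1L)
        cStart <- if (strand == "+") seg$start + oStart
        else seg$start + (segLen - (oStart + len))
        prot <- vapply(seq_along(a), function(i)
          paste(translateCodons(codons[a[i]:(st[i] - 1L)]), collapse = ""),
          "")
        out[[length(out) + 1L]] <- data.frame(
          start = cStart, end = cStart + len, strand = strand, frame = f,
          ntLength = len, protein = prot, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# split a contig at runs of >= minNRun Ns; returns list of
# list(start (0-based), end (exclusive), seq)
#' @noRd
contigSegments <- function(contig, minNRun = 10L) {
  n <- nchar(contig)
  m <- gregexpr(paste0("N{", minNRun, ",}"), contig)[[1]]
  if (m[1] == -1L) return(list(list(start = 0L, end = n, seq = contig)))
  gapStart <- as.integer(m) - 1L
  gapEnd <- gapStart + attr(m, "match.length")
  segStart <- c(0L, gapEnd)
  segEnd <- c(gapStart, n)
  keep <- segEnd > segStart
  mapply(function(s, e) list(start = s, end = e,
                             seq = substring(contig, s + 1L, e)),
         segStart[keep], segEnd[keep], SIMPLIFY = FALSE)
}

#' Bundled F-box exemplar panel (synthetic)
#'
#' Exemplar F-box-gene protein sequences used to score candidate ORFs. The
#' bundled panel (`inst/extdata/fbox_refs_synthetic.fasta`) is a synthetic
#' construction emitted by the package's fixture machinery, sized like
#' S-locus F-box proteins; replace it with curated SLF/SFB sequences for
#' real scans.
#'
#' @return named character vector of exemplar proteins.
#' @export
fboxReferences <- function() {
  if (is.null(.pkgCache$fboxRefs)) {
    fa <- system.file("extdata", "fbox_refs_synthetic.fasta",
                      package = "rnaseScout", mustWork = TRUE)
    .pkgCache$fboxRefs <- readFastaRecords(fa)
  }
  .pkgCache$fboxRefs
}

#' Score a protein against the F-box exemplar panel
#'
#' `score = max over refs of S(protein, ref) / S(ref, ref)` using the
#' global alignment score; the protein is called an F-box when the score
#' reaches `tau`.
#'
#' @param protein amino-acid string.
#' @param fboxRefs exemplar panel, see [fboxReferences()].
#' @param tau decision threshold (default 0.25).
#' @return list with `score` and `isFbox`.
#' @export
scoreFbox <- function(protein, fboxRefs = fboxReferences(), tau = 0.25) {
  protein <- gsub("\\*", "X", toupper(protein))
  sc <- max(vapply(fboxRefs, function(ref)
    globalAlignScore(protein, ref) / globalAlignScore(ref, ref),
    numeric(1)))
  list(score = sc, isFbox = sc >= tau)
}

# six-frame translation of a segment, through stops (stop -> "*")
#' @noRd
frameTranslations <- function(seq) {
  n <- nchar(seq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcompString(seq)
    for (f in 0:2) {
      if (n - f < 3L) next
      at <- seq(f + 1L, n - 2L, by = 3L)
      res[[paste0(strand, f)]] <- list(
        strand = strand, frame = f,
        aa = translateCodons(substring(s, at, at + 2L)))
    }
  }
  res
}

#' Find stop-disrupted F-box copies in a contig
#'
#' Relict S-haplotypes retain F-box loci broken by in-frame stop codons;
#' such copies are invisible to [findOrfs()]. This scan translates all six
#' frames straight through stop codons and locates regions resembling the
#' exemplar panel by exact amino-acid `seedWidth`-mer seeding: seed matches
#' closer than `maxSeedGap` (in residues) are chained, and the seed-covered
#' span is scored against the panel with the same normalized global
#' alignment as [scoreFbox()]. A span is reported as a disrupted F-box
#' when it scores at least `tau` and contains at least one stop strictly
#' inside the seed-covered span (a terminal stop is an intact gene's own
#' stop codon, not a disruption). Runs of `minNRun` Ns break the scan.
#'
#' @param contig nucleotide string.
#' @param fboxRefs exemplar panel, see [fboxReferences()].
#' @param tau score threshold (default 0.25).
#' @param seedWidth exact-match seed width in residues.
#' @param maxSeedGap maximum chaining gap between seeds, residues.
#' @param minNt minimum reported span, nucleotides.
#' @param minNRun N-run length treated as an assembly gap.
#' @return data.frame: `start`, `end` (0-based half-open contig coords),
#'   `strand`, `frame`, `ntLength`, `score`, `nStops`, `disrupted`
#'   (always `TRUE`).
#' @export
findDisruptedFbox <- function(contig, fboxRefs = fboxReferences(),
                              tau = 0.25, seedWidth = 6L, maxSeedGap = 400L,
                              minNt = 300L, minNRun = 10L) {
  contig <- toupper(contig)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      ntLength = integer(), score = numeric(),
                      nStops = integer(), disrupted = logical(),
                      stringsAsFactors = FALSE)
  seeds <- unique(unlist(lapply(fboxRefs, function(r) {
    if (nchar(r) < seedWidth) return(character())
    substring(r, seq_len(nchar(r) - seedWidth + 1L),
              seq_len(nchar(r) - seedWidth + 1L) + seedWidth - 1L)
  })))
  seeds <- seeds[!grepl("X", seeds)]
  out <- list(empty)
  for (seg in contigSegments(contig, minNRun)) {
    segLen <- seg$end - seg$start
    if (segLen < minNt) next
    for (tr in frameTranslations(seg$seq)) {
      nAA <- length(tr$aa)
      if (nAA < seedWidth) next
      aaStr <- paste(tr$aa, collapse = "")
      at <- seq_len(nAA - seedWidth + 1L)
      st <- which(substring(aaStr, at, at + seedWidth - 1L) %in% seeds)
      if (length(st) == 0L) next
      # chain seeds into clusters
      brk <- c(0L, which(diff(st) > maxSeedGap), length(st))
      for (ci in seq_len(length(brk) - 1L)) {
        cl <- st[(brk[ci] + 1L):brk[ci + 1L]]
        aaFrom <- min(cl); aaTo <- max(cl) + seedWidth - 1L  # 1-based, incl.
        span <- aaTo - aaFrom + 1L
        if (3L * span < minNt) next
        inner <- tr$aa[(aaFrom + 1L):(aaTo - 1L)]
        nStops <- sum(inner == "*")
        if (nStops < 1L) next
        prot <- paste(tr$aa[aaFrom:aaTo], collapse = "")
        sc <- max(vapply(fboxRefs, function(ref)
          globalAlignScore(prot, ref) / globalAlignScore(ref, ref),
          numeric(1)))
        if (sc < tau) next
        oStart <- tr$frame + 3L * (aaFrom - 1L)
        len <- 3L * span
        cStart <- if (tr$strand == "+") seg$start + oStart
        else seg$start + (segLen - (oStart + len))
        out[[length(out) + 1L]] <- data.frame(
          start = cStart, end = cStart + len, strand = tr$strand,
          frame = tr$frame, ntLength = len, score = sc, nStops = nStops,
          disrupted = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Scan a genomic haplotype for a putative (possibly relict) S-locus
#'
#' Collects intact F-box ORFs ([findOrfs()] filtered by [scoreFbox()]) and
#' stop-disrupted F-box copies ([findDisruptedFbox()]) within `flankNt` of
#' each supplied RNase locus, and reports the region in the style of
#' published S-haplotype diagrams. The region is an S-locus candidate when
#' at least one *class III* RNase locus has at least `minFbox` F-box loci
#' (intact + disrupted) in its flank; class I/II loci with nearby F-boxes
#' are reported with a note but never promote candidacy. The ambiguous-base
#' (N) fraction of each flank is reported, since poorly resolved assemblies
#' can hide F-box loci.
#'
#' @param contig nucleotide string.
#' @param rnaseLoci data.frame with columns `start`, `end` (0-based
#'   half-open) and `classLabel` (`"I"`, `"II"`, `"III"`); loci must not
#'   overlap.
#' @param flankNt flank size on each side of an RNase locus (default 2 Mb).
#' @param minFbox minimum F-box loci in a class III flank for candidacy
#'   (default 4, operationalizing "more than a few").
#' @param fboxRefs exemplar panel, see [fboxReferences()].
#' @param tau F-box score threshold.
#' @param minNt,maxNt intact ORF length bounds, nucleotides.
#' @param contigId identifier recorded in the report.
#' @return a [HaplotypeReport-class].
#' @export
scanHaplotype <- function(contig, rnaseLoci, flankNt = 2e6L, minFbox = 4L,
                          fboxRefs = fboxReferences(), tau = 0.25,
                          minNt = 900L, maxNt = 1800L, contigId = "contig") {
  contig <- toupper(contig)
  stopifnot(is.data.frame(rnaseLoci),
            all(c("start", "end", "classLabel") %in% names(rnaseLoci)))
  rl <- rnaseLoci[order(rnaseLoci$start), , drop = FALSE]
  if (nrow(rl) > 1L && any(rl$start[-1] < rl$end[-nrow(rl)]))
    stop("overlapping RNase loci", call. = FALSE)
  orfs <- findOrfs(contig, minNt = minNt, maxNt = maxNt)
  orfScores <- vapply(orfs$protein, function(p)
    scoreFbox(p, fboxRefs, tau)$score, numeric(1))
  intact <- orfs[orfScores >= tau, , drop = FALSE]
  intactScores <- orfScores[orfScores >= tau]
  disrupted <- findDisruptedFbox(contig, fboxRefs, tau = tau)
  fb <- rbind(
    if (nrow(intact)) data.frame(start = intact$start, end = intact$end,
                                 strand = intact$strand,
                                 frame = intact$frame,
                                 ntLength = intact$ntLength,
                                 score = unname(intactScores),
                                 disrupted = FALSE,
                                 stringsAsFactors = FALSE),
    if (nrow(disrupted)) data.frame(start = disrupted$start,
                                    end = disrupted$end,
                                    strand = disrupted$strand,
                                    frame = disrupted$frame,
                                    ntLength = disrupted$ntLength,
                                    score = disrupted$score,
                                    disrupted = TRUE,
                                    stringsAsFactors = FALSE))
  if (is.null(fb)) fb <- data.frame(start = integer(), end = integer(),
                                    strand = character(), frame = integer(),
                                    ntLength = integer(), score = numeric(),
                                    disrupted = logical())
  # drop intact/disrupted duplicates of the same span (a disrupted call
  # overlapping an intact ORF keeps the intact interpretation)
  if (nrow(fb) > 1L) {
    keep <- rep(TRUE, nrow(fb))
    for (i in which(fb$disrupted)) {
      ov <- !fb$disrupted & fb$start < fb$end[i] & fb$end > fb$start[i] &
        fb$strand == fb$strand[i]
      if (any(ov)) keep[i] <- FALSE
    }
    fb <- fb[keep, , drop = FALSE]
  }
  nContig <- nchar(contig)
  inFlank <- function(locusStart, locusEnd) {
    lo <- max(0L, locusStart - flankNt); hi <- min(nContig, locusEnd + flankNt)
    fb$start < hi & fb$end > lo
  }
  rl$nFboxInFlank <- vapply(seq_len(nrow(rl)), function(i)
    sum(inFlank(rl$start[i], rl$end[i])), integer(1))
  rl$flankNFraction <- vapply(seq_len(nrow(rl)), function(i) {
    lo <- max(0L, rl$start[i] - flankNt); hi <- min(nContig, rl$end[i] + flankNt)
    win <- substring(contig, lo + 1L, hi)
    lengths(regmatches(win, gregexpr("N", win))) / nchar(win)
  }, numeric(1))
  anyFlank <- Reduce(`|`, lapply(seq_len(nrow(rl)), function(i)
    inFlank(rl$start[i], rl$end[i])), accumulate = FALSE,
    init = rep(FALSE, nrow(fb)))
  fb <- fb[anyFlank, , drop = FALSE]
  candidate <- any(rl$classLabel == "III" & rl$nFboxInFlank >= minFbox)
  notes <- character()
  nonIII <- rl$classLabel != "III" & rl$nFboxInFlank >= minFbox
  if (any(nonIII))
    notes <- c(notes, sprintf(
      "class %s RNase locus at %d with %d flanking F-box loci: not an S-locus candidate (class III required)",
      rl$classLabel[nonIII], rl$start[nonIII], rl$nFboxInFlank[nonIII]))
  if (any(rl$flankNFraction > 0.4))
    notes <- c(notes, "a flank is >40% ambiguous characters; F-box loci may be hidden")
  new("HaplotypeReport", contigId = contigId, rnaseLoci = rl,
      fboxLoci = fb, candidate = candidate, notes = notes,
      params = list(flankNt = flankNt, minFbox = minFbox, tau = tau,
                    minNt = minNt, maxNt = maxNt))
}
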