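#' ProteinRecord: an amino-acid sequence with optional signal-peptide boundary
#'
#' Holds one protein sequence over the 20 canonical residues plus `X`,
#' an optional signal-peptide boundary (0-based exclusive index into the
#' sequence: residues `[0, signalPeptideEnd)` are the signal peptide), and a
#' free-text provenance tag. Signal peptides are excluded from isoelectric
#' point computation by [matureSequence()].
#'
#' @slot id single character identifier.
#' @slot seq amino-acid sequence (uppercase; 20 canonical letters + X).
#' @slot signalPeptideEnd integer, 0-based exclusive end of the signal
#'   peptide, or `NA_integer_` when no boundary is known.
#' @slot source free-text provenance.
#' @export
setClass("ProteinRecord",
  representation(id = "character", seq = "character",
                 signalPeptideEnd = "integer", source = "character"),
  prototype(signalPeptideEnd = NA_integer_, source = ""))

setValidity("ProteinRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (length(object@seq) != 1L || nchar(object@seq) == 0L)
    msg <- c(msg, "seq must be a single non-empty string")
  else {
    bad <- setdiff(unique(strsplit(object@seq, "")[[1]]), c(AA20, "X"))
    if (length(bad) > 0L)
      msg <- c(msg, paste0("seq has non-canonical residues: ",
                           paste(bad, collapse = ",")))
  }
  spe <- object@signalPeptideEnd
  if (!is.na(spe) && (spe < 0L || spe >= nchar(object@seq)))
    msg <- c(msg, "signalPeptideEnd must satisfy 0 <= end < nchar(seq)")
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinRecord
#'
#' @param id sequence identifier.
#' @param seq amino-acid sequence; lowercase input is uppercased. Ambiguity
#'   letters other than `X` are rejected.
#' @param signalPeptideEnd optional 0-based exclusive signal-peptide boundary.
#' @param source free-text provenance.
#' @return A [ProteinRecord-class] object.
#' @examples
#' ProteinRecord("p1", "MKLHGLWPA", signalPeptideEnd = 3)
#' @export
ProteinRecord <- function(id, seq, signalPeptideEnd = NA, source = "") {
  new("ProteinRecord", id = as.character(id), seq = toupper(seq),
      signalPeptideEnd = as.integer(signalPeptideEnd),
      source = as.character(source))
}

#' @describeIn ProteinRecord-class display a short summary
#' @param object a `ProteinRecord`
#' @export
setMethod("show", "ProteinRecord", function(object) {
  cat("ProteinRecord", object@id, "(", nchar(object@seq), "aa",
      if (!is.na(object@signalPeptideEnd))
        paste0(", signal peptide 0..", object@signalPeptideEnd) else "",
      ")\n", sep = " ")
})

#' GeneStructure: ordered exon coordinates and the derived coding sequence
#'
#' Exon coordinates are stored internally as 0-based half-open intervals on
#' the contig, sorted by start and non-overlapping. The coding sequence (when
#' the contig sequence was available) is given 5'->3' along the transcript;
#' minus-strand exons are reverse-complemented. `intronOffsets` are the
#' counts of coding nucleotides 5' of each intron, which makes intron
#' placement independent of strand and contig coordinates.
#'
#' @slot geneId gene identifier.
#' @slot contigId contig the exons live on.
#' @slot strand `"+"` or `"-"`.
#' @slot exonStarts,exonEnds integer vectors, 0-based half-open.
#' @slot cds derived coding nucleotide string (may be `NA` when no contig
#'   sequence was supplied).
#' @slot intronOffsets integer vector, one per intron (`n_exons - 1`).
#' @export
setClass("GeneStructure",
  representation(geneId = "character", contigId = "character",
                 strand = "character", exonStarts = "integer",
                 exonEnds = "integer", cds = "character",
                 intronOffsets = "integer"))

setValidity("GeneStructure", function(object) {
  msg <- character()
  s <- object@exonStarts; e <- object@exonEnds
  if (length(s) != length(e) || length(s) == 0L)
    msg <- c(msg, "need at least one exon with matching starts/ends")
  else {
    if (any(e <= s)) msg <- c(msg, "exon end must exceed exon start")
    if (is.unsorted(s, strictly = TRUE) && length(s) > 1L)
      msg <- c(msg, "exons must be sorted by start")
    if (length(s) > 1L && any(s[-1] < e[-length(e)]))
      msg <- c(msg, "exons must not overlap")
  }
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(object@intronOffsets) != max(length(s) - 1L, 0L))
    msg <- c(msg, "number of introns must be number of exons - 1")
  total <- sum(e - s)
  if (!is.na(object@cds) && nchar(object@cds) != total)
    msg <- c(msg, "cds length must equal total exon length")
  if (length(object@intronOffsets) &&
      (any(object@intronOffsets <= 0L) || any(object@intronOffsets >= total)))
    msg <- c(msg, "intron offsets must lie strictly inside the CDS")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneStructure
#'
#' @param geneId,contigId identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exonStarts,exonEnds exon coordinates, 0-based half-open on the
#'   contig, sorted by start.
#' @param contigSeq optional contig nucleotide sequence used to derive the
#'   CDS (minus-strand genes are reverse-complemented).
#' @return A [GeneStructure-class] object with `intronOffsets` derived from
#'   the exon lengths (in transcript order).
#' @examples
#' GeneStructure("g", "c", "+", c(0, 6), c(3, 9), contigSeq = "ATGCCCTAAGGG")
#' @export
GeneStructure <- function(geneId, contigId, strand, exonStarts, exonEnds,
                          contigSeq = NULL) {
  ord <- order(exonStarts)
  exonStarts <- as.integer(exonStarts[ord]); exonEnds <- as.integer(exonEnds[ord])
  widths <- exonEnds - exonStarts
  # transcript order: plus strand = genomic order, minus strand = reversed
  txWidths <- if (strand == "-") rev(widths) else widths
  offsets <- if (length(txWidths) > 1L)
    as.integer(cumsum(txWidths[-length(txWidths)])) else integer()
  cds <- NA_character_
  if (!is.null(contigSeq)) {
    if (any(exonEnds > nchar(contigSeq)))
      stop("exon outside contig bounds for gene ", geneId, call. = FALSE)
    pieces <- substring(contigSeq, exonStarts + 1L, exonEnds)
    cds <- paste(pieces, collapse = "")
    if (strand == "-") cds <- revcompString(cds)
  }
  new("GeneStructure", geneId = as.character(geneId),
      contigId = as.character(contigId), strand = strand,
      exonStarts = exonStarts, exonEnds = exonEnds,
      cds = cds, intronOffsets = offsets)
}

#' @describeIn GeneStructure-class display a short summary
#' @param object a `GeneStructure`
#' @export
setMethod("show", "GeneStructure", function(object) {
  cat("GeneStructure", object@geneId, "on", object@contigId,
      paste0("(", object@strand, ")"), length(object@exonStarts), "exon(s),",
      length(object@intronOffsets), "intron(s)\n")
})

#' @rdname GeneStructure-class
#' @param x a `GeneStructure`
#' @export
geneId <- function(x) x@geneId

#' @rdname GeneStructure-class
#' @export
intronOffsets <- function(x) x@intronOffsets

#' @rdname GeneStructure-class
#' @export
cdsSequence <- function(x) x@cds

#' @rdname GeneStructure-class
#' @export
exonRanges <- function(x) {
  data.frame(start = x@exonStarts, end = x@exonEnds)
}

#' MotifPanel: exemplar windows for the five conserved T2-RNase regions
#'
#' Each region carries a set of equal-length exemplar windows, a similarity
#' threshold, and (for the two catalytic active-site regions CAS I and
#' CAS II) the 0-based offset of the catalytic histidine within the window.
#'
#' @slot regions named list (C1..C5 in N->C order); each element a list with
#'   `windows` (character vector), `casOffset` (integer or NA) and
#'   `threshold` (numeric).
#' @export
setClass("MotifPanel", representation(regions = "list"))

setValidity("MotifPanel", function(object) {
  msg <- character()
  for (rn in names(object@regions)) {
    r <- object@regions[[rn]]
    w <- r$windows
    if (length(w) == 0L || length(unique(nchar(w))) != 1L || nchar(w[1]) < 4L)
      msg <- c(msg, paste0(rn, ": exemplar windows must share a length >= 4"))
    if (!is.na(r$casOffset) &&
        (r$casOffset < 0L || r$casOffset >= nchar(w[1])))
      msg <- c(msg, paste0(rn, ": casOffset outside window"))
    if (!is.numeric(r$threshold) || r$threshold <= 0 || r$threshold > 1)
      msg <- c(msg, paste0(rn, ": threshold must be in (0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MotifPanel-class display a summary
#' @param object a `MotifPanel`
#' @export
setMethod("show", "MotifPanel", function(object) {
  cat("MotifPanel with", length(object@regions), "regions:\n")
  for (rn in names(object@regions)) {
    r <- object@regions[[rn]]
    cat(" ", rn, ": ", length(r$windows), " exemplar(s) of width ",
        nchar(r$windows[1]),
        if (!is.na(r$casOffset)) paste0(", catalytic His at offset ",
                                        r$casOffset) else "",
        ", threshold ", r$threshold, "\n", sep = "")
  }
})

#' HaplotypeReport: a genomic window's RNase and F-box loci
#'
#' The result of [scanHaplotype()]: all RNase loci with their class labels,
#' every intact or stop-disrupted F-box locus found within the flanking
#' window of at least one RNase locus, inter-locus distances, the ambiguous
#' (N) fraction of each flank, and the S-locus candidacy verdict. A region is
#' an S-locus candidate when at least one class III RNase locus has at least
#' `minFbox` F-box loci within its flank; class I/II loci with nearby F-boxes
#' are reported but never promote candidacy.
#'
#' @slot contigId contig identifier.
#' @slot rnaseLoci data.frame: start, end (0-based half-open), classLabel,
#'   nFboxInFlank, flankNFraction.
#' @slot fboxLoci data.frame: start, end, strand, frame, ntLength, score,
#'   disrupted.
#' @slot candidate logical S-locus candidacy verdict.
#' @slot notes character vector of free-text annotations.
#' @slot params list of scan parameters (flankNt, minFbox, tau, bounds).
#' @export
setClass("HaplotypeReport",
  representation(contigId = "character", rnaseLoci = "data.frame",
                 fboxLoci = "data.frame", candidate = "logical",
                 notes = "character", params = "list"))

#' @describeIn HaplotypeReport-class print a Fig.5-style locus table
#' @param object a `HaplotypeReport`
#' @export
setMethod("show", "HaplotypeReport", function(object) {
  cat("HaplotypeReport for contig", object@contigId, "\n")
  cat("  S-locus candidate:", object@candidate,
      sprintf("(flank %.1f kb, minFbox %d)\n",
              object@params$flankNt / 1000, object@params$minFbox))
  tab <- reportTable(object)
  if (nrow(tab)) print(tab, row.names = FALSE)
  for (n in object@notes) cat("  note:", n, "\n")
})

#' @rdname HaplotypeReport-class
#' @param x a `HaplotypeReport`
#' @export
isCandidate <- function(x) x@candidate

#' @rdname HaplotypeReport-class
#' @export
fboxLoci <- function(x) x@fboxLoci

#' @rdname HaplotypeReport-class
#' @export
rnaseLoci <- function(x) x@rnaseLoci

#' Tabulate a haplotype report
#'
#' One row per locus (RNase or F-box) sorted by coordinate, with the
#' distance to the previous locus in kb, mirroring the published style of
#' S-haplotype diagrams.
#'
#' @param x a [HaplotypeReport-class].
#' @return data.frame with columns locus, type, start, end, strand,
#'   disrupted, distanceToPrevKb.
#' @export
reportTable <- function(x) {
  rn <- x@rnaseLoci; fb <- x@fboxLoci
  rows <- rbind(
    if (nrow(rn)) data.frame(
      locus = paste0("RNase_", seq_len(nrow(rn))),
      type = paste("RNase class", rn$classLabel),
      start = rn$start, end = rn$end,
      strand = if ("strand" %in% names(rn)) rn$strand else "+",
      disrupted = FALSE, stringsAsFactors = FALSE),
    if (nrow(fb)) data.frame(
      locus = paste0("Fbox_", seq_len(nrow(fb))),
      type = "F-box", start = fb$start, end = fb$end, strand = fb$strand,
      disrupted = fb$disrupted, stringsAsFactors = FALSE))
  if (is.null(rows) || nrow(rows) == 0L)
    return(data.frame(locus = character(), type = character(),
                      start = integer(), end = integer(),
                      strand = character(), disrupted = logical(),
                      distanceToPrevKb = numeric()))
  rows <- rows[order(rows$start), , drop = FALSE]
  gaps <- c(NA, (rows$start[-1] - rows$end[-nrow(rows)]) / 1000)
  rows$distanceToPrevKb <- round(gaps, 1)
  rows
}
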