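#' Read a FASTA file into a named character vector
#'
#' Identifiers are the first whitespace-delimited token of each header line;
#' sequences are uppercased and line wrapping is concatenated away. Record
#' order is preserved.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences, in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a desc", "AC", "GT"), f)
#' readFastaRecords(f)
#' @export
readFastaRecords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not valid FASTA: ", path, " (",
                                           conditionMessage(e), ")",
                                           call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFastaRecords <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene structures from a GFF3-subset exon table
#'
#' Consumes the exon features of a GFF3 file (1-based inclusive coordinates
#' per the GFF3 standard), groups them by gene, and converts to the internal
#' 0-based half-open convention. The gene identifier is taken from the
#' `gene_id`, `Parent` or `ID` attribute, in that order of preference. When
#' contig sequences are supplied, each gene's CDS is derived (minus-strand
#' genes reverse-complemented, exons ordered 5'->3' along the transcript).
#'
#' @param path path to a GFF3 file containing exon features.
#' @param contigs optional named character vector (or `DNAStringSet`) of
#'   contig sequences used to derive the CDS and check exon bounds.
#' @return list of [GeneStructure-class] objects, named by gene id.
#' @export
readExonTable <- function(path, contigs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path, call. = FALSE)
  mc <- S4Vectors::mcols(gr)
  pickId <- function(i) {
    for (key in c("gene_id", "Parent", "ID")) {
      v <- mc[[key]]
      if (!is.null(v)) {
        vi <- if (is(v, "List") || is.list(v)) unlist(v[i])[1] else v[i]
        if (length(vi) == 1L && !is.na(vi) && nzchar(vi)) return(as.character(vi))
      }
    }
    NA_character_
  }
  gid <- vapply(seq_along(gr), pickId, "")
  if (anyNA(gid)) stop("exon feature without gene_id/Parent/ID attribute",
                       call. = FALSE)
  if (!is.null(contigs)) contigs <- stats::setNames(
    toupper(as.character(contigs)), names(contigs))
  out <- lapply(split(seq_along(gr), gid), function(idx) {
    sub <- gr[idx]
    contig <- as.character(GenomeInfoDb::seqnames(sub))[1]
    strand <- as.character(BiocGenerics::strand(sub))[1]
    if (!strand %in% c("+", "-"))
      stop("exon without explicit strand for gene ", gid[idx[1]],
           call. = FALSE)
    # GFF3 1-based inclusive -> 0-based half-open
    starts0 <- BiocGenerics::start(sub) - 1L
    ends0 <- BiocGenerics::end(sub)
    ord <- order(starts0)
    starts0 <- starts0[ord]; ends0 <- ends0[ord]
    if (length(starts0) > 1L && any(starts0[-1] < ends0[-length(ends0)]))
      stop("overlapping exons in gene ", gid[idx[1]], call. = FALSE)
    cseq <- if (!is.null(contigs)) {
      if (!contig %in% names(contigs))
        stop("contig ", contig, " not supplied", call. = FALSE)
      contigs[[contig]]
    } else NULL
    GeneStructure(gid[idx[1]], contig, strand, starts0, ends0,
                  contigSeq = cseq)
  })
  out[unique(gid)]
}

#' Write gene structures to a GFF3-subset exon table
#'
#' Inverse of [readExonTable()]: internal 0-based half-open exon coordinates
#' are emitted as 1-based inclusive GFF3 exon features with a `gene_id`
#' attribute.
#'
#' @param genes list of [GeneStructure-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExonTable <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (g in genes) {
    n <- length(g@exonStarts)
    lines <- c(lines, sprintf(
      "%s\trnaseScout\texon\t%d\t%d\t.\t%s\t.\tgene_id=%s",
      g@contigId, g@exonStarts + 1L, g@exonEnds, g@strand, g@geneId))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Map ungapped positions of an aligned row to alignment columns
#'
#' @param alignedRow one gapped row of an alignment; gap character `"-"`.
#' @return integer vector `m` with `m[i + 1]` the 0-based alignment column
#'   of the i-th (0-based) non-gap symbol; length equals the number of
#'   non-gap symbols. The map is strictly increasing.
#' @examples
#' columnMap("A-CG")  # 0, 2, 3
#' @export
columnMap <- function(alignedRow) {
  chars <- strsplit(alignedRow, "")[[1]]
  which(chars != "-") - 1L
}
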