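#' Needleman-Wunsch global alignment score
#'
#' Deterministic global (end-to-end) alignment score with affine gap costs:
#' a gap of length L costs `gapOpen + L * gapExtend`. Set `gapOpen = 0` for
#' linear gap costs.
#'
#' @param a,b non-empty sequences (amino-acid strings by default).
#' @param matrix substitution matrix; default BLOSUM62.
#' @param gapOpen,gapExtend nonnegative gap penalties (subtracted).
#' @return the optimal global alignment score.
#' @examples
#' globalAlignScore("HGLWP", "HGLWP")  # self-score under BLOSUM62
#' @export
globalAlignScore <- function(a, b, matrix = blosum62(),
                             gapOpen = 10, gapExtend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gapOpen, gapExtension = gapExtend, scoreOnly = TRUE)
}

#' Bundled class exemplar panel (synthetic)
#'
#' Labeled class I/II/III exemplar proteins used by [nearestReference()].
#' The exemplars are synthetic constructions emitted by the package's own
#' fixture generator (frozen under
#' `inst/extdata/class_refs_synthetic.fasta` + `.tsv`), not curated natural
#' sequences; swap in a curated panel via the same two-file format
#' (FASTA + TSV with columns `id`, `class`).
#'
#' @return list with `seqs` (named character vector) and `classes` (named
#'   character vector of `"I"`, `"II"`, `"III"` labels).
#' @export
referencePanel <- function() {
  if (is.null(.pkgCache$refPanel)) {
    fa <- system.file("extdata", "class_refs_synthetic.fasta",
                      package = "rnaseScout", mustWork = TRUE)
    tsv <- system.file("extdata", "class_refs_synthetic.tsv",
                       package = "rnaseScout", mustWork = TRUE)
    seqs <- readFastaRecords(fa)
    meta <- utils::read.delim(tsv, stringsAsFactors = FALSE)
    .pkgCache$refPanel <- list(
      seqs = seqs, classes = stats::setNames(meta$class, meta$id)[names(seqs)])
  }
  .pkgCache$refPanel
}

#' Nearest-reference class vote
#'
#' Alignment distance to each labeled exemplar,
#' `d(a, b) = 1 - S(a, b) / min(S(a, a), S(b, b))`, followed by a majority
#' vote among the k nearest exemplars. Vote ties are broken by the smaller
#' mean distance; an unresolved tie, or all distances >= `maxDistance`,
#' yields `"unclassified"`.
#'
#' @param protein amino-acid string.
#' @param refs labeled exemplar panel, see [referencePanel()].
#' @param k number of neighbours (default 3).
#' @param maxDistance distance at which exemplars stop counting as evidence.
#' @return list with `class` (label or `"unclassified"`) and `distance`
#'   (mean distance of the winning neighbours).
#' @export
nearestReference <- function(protein, refs = referencePanel(), k = 3L,
                             maxDistance = 0.95) {
  stopifnot(length(refs$seqs) > 0L)
  selfA <- globalAlignScore(protein, protein)
  d <- vapply(names(refs$seqs), function(id) {
    ref <- refs$seqs[[id]]
    1 - globalAlignScore(protein, ref) /
      min(selfA, globalAlignScore(ref, ref))
  }, numeric(1))
  if (all(d >= maxDistance))
    return(list(class = "unclassified", distance = min(d)))
  k <- min(k, length(d))
  nn <- order(d)[seq_len(k)]
  votes <- table(refs$classes[nn])
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    means <- vapply(top, function(cl)
      mean(d[nn][refs$classes[nn] == cl]), numeric(1))
    best <- which(means == min(means))
    if (length(best) > 1L)
      return(list(class = "unclassified", distance = min(d)))
    top <- top[best]
  }
  list(class = top, distance = min(d[nn][refs$classes[nn] == top]))
}

#' Classify one feature vector into class I, II or III
#'
#' Decision ladder over the three lines of evidence (intron pattern,
#' isoelectric point, nearest labeled exemplar):
#'
#' 1. An intron pattern matching catalog entries of exactly one class fixes
#'    that class (confidence `pattern-exact`).
#' 2. Otherwise (ambiguous single-intron-at-5 pattern, novel or undetermined
#'    pattern) the class votes are tallied: the pattern's compatible classes
#'    (if any), the pI side (acidic, below `acidBasicThreshold`, supports
#'    classes I and II; basic supports class III), and the nearest-reference
#'    class. The class with most supporting lines wins; agreement of at
#'    least two lines gives confidence `multi-line`, one line `single-line`,
#'    unresolved ties `unclassified`.
#'
#' S-RNase candidacy requires class III, pI at or above `sCandidateMinPI`
#' (functional S-RNases rarely display pI < 8.0), an intron pattern that is
#' III-C (\{5\}), III-D (\{1,5\}) or undetermined (cDNA input; the weaker
#' evidence is reflected in the confidence, and pattern III-A \{5,9\} is
#' excluded because known S-RNases lack position 9), CAS II histidine not
#' absent, and at least three conserved regions hit.
#'
#' @param fv list with components `id`, `pI`, `regionsHit`, `cas2His`
#'   (tristate), `intronPattern` (integer vector of canonical position ids,
#'   or `NULL`/`NA` when undetermined; `integer(0)` for intronless), and
#'   optionally `nnClass` (label from [nearestReference()]).
#' @param acidBasicThreshold pI threshold of the acidic/basic vote.
#' @param sCandidateMinPI minimum pI of an S-RNase candidate.
#' @param catalog pattern catalog, see [patternCatalog()].
#' @return list (class call) with `id`, `classLabel` (`"I"`, `"II"`,
#'   `"III"`, `"unclassified"`), `sRnaseCandidate`, `confidence`
#'   (`"pattern-exact"`, `"multi-line"`, `"single-line"`,
#'   `"unclassified"`), `patternNames`, `evidence` (named character vector
#'   of criterion verdicts).
#' @export
classifySequence <- function(fv, acidBasicThreshold = 7.0,
                             sCandidateMinPI = 8.0,
                             catalog = patternCatalog()) {
  undetermined <- is.null(fv$intronPattern) ||
    (length(fv$intronPattern) == 1L && is.na(fv$intronPattern))
  if (!undetermined)
    fv$intronPattern <- sort(unique(as.integer(fv$intronPattern)))
  patternNames <- if (undetermined) character()
  else assignPattern(fv$intronPattern, catalog)
  patternClasses <- unique(vapply(
    patternNames[patternNames %in% names(catalog)],
    function(n) catalog[[n]]$class, ""))
  evidence <- character()
  classLabel <- NULL; confidence <- NULL
  if (length(patternClasses) == 1L) {
    classLabel <- patternClasses
    confidence <- "pattern-exact"
    evidence["pattern"] <- paste0("{", paste(sort(fv$intronPattern),
                                             collapse = ","), "} => ",
                                  paste(patternNames, collapse = "/"))
  } else {
    piClasses <- if (is.na(fv$pI)) character()
    else if (fv$pI < acidBasicThreshold) c("I", "II") else "III"
    nnClass <- if (!is.null(fv$nnClass) &&
                   fv$nnClass %in% c("I", "II", "III")) fv$nnClass
    else character()
    lines <- vapply(c("I", "II", "III"), function(cl)
      (cl %in% patternClasses) + (cl %in% piClasses) + (cl %in% nnClass),
      numeric(1))
    evidence["pattern"] <- if (undetermined) "undetermined"
    else paste0("{", paste(sort(fv$intronPattern), collapse = ","),
                "} compatible with ",
                if (length(patternClasses)) paste(patternClasses,
                                                  collapse = "/") else "none")
    evidence["pI"] <- if (is.na(fv$pI)) "unavailable" else
      paste0(fv$pI, if (fv$pI < acidBasicThreshold) " acidic => I/II"
             else " basic => III")
    evidence["nearest-reference"] <- if (length(nnClass)) nnClass else "none"
    mx <- max(lines)
    top <- names(lines)[lines == mx]
    if (mx == 0 || length(top) > 1L) {
      # an unresolved tie falls back to the nearest-reference line alone
      if (length(nnClass) && nnClass %in% top) {
        classLabel <- nnClass; confidence <- "single-line"
      } else {
        classLabel <- "unclassified"; confidence <- "unclassified"
      }
    } else {
      classLabel <- top
      confidence <- if (mx >= 2) "multi-line" else "single-line"
    }
  }
  patternOk <- undetermined ||
    identical(sort(fv$intronPattern), 5L) ||
    identical(sort(fv$intronPattern), c(1L, 5L))
  candidate <- identical(classLabel, "III") &&
    !is.na(fv$pI) && fv$pI >= sCandidateMinPI &&
    patternOk &&
    !identical(fv$cas2His, "absent") &&
    !is.null(fv$regionsHit) && fv$regionsHit >= 3L
  evidence["s-candidate"] <- if (candidate) "class III, basic pI, S-type intron pattern, CAS II intact"
  else "not all candidacy criteria met"
  list(id = fv$id, classLabel = classLabel, sRnaseCandidate = candidate,
       confidence = confidence, patternNames = patternNames,
       evidence = evidence)
}

# translate the longest ATG..stop open reading frame across all 6 frames;
# NULL when none exists
#' @noRd
longestOrfProtein <- function(nt) {
  nt <- toupper(nt)
  best <- NULL; bestLen <- 0L
  for (s in list(nt, revcompString(nt))) {
    n <- nchar(s)
    for (f in 0:2) {
      startsAt <- seq(f + 1L, n - 2L, by = 3L)
      if (length(startsAt) == 0L) next
      codons <- substring(s, startsAt, startsAt + 2L)
      stops <- which(codons %in% STOP_CODONS)
      atgs <- which(codons == "ATG")
      bounds <- c(0L, stops, length(codons) + 1L)
      for (bi in seq_len(length(bounds) - 1L)) {
        lo <- bounds[bi]; hi <- bounds[bi + 1L]
        a <- atgs[atgs > lo & atgs < hi]
        if (length(a) == 0L) next
        len <- hi - a[1]
        if (len > bestLen) {
          bestLen <- len
          best <- paste(translateCodons(codons[a[1]:(hi - 1L)]),
                        collapse = "")
        }
      }
    }
  }
  best
}

#' Classify a set of sequences end to end
#'
#' Orchestrates the full pipeline per record: nucleotide inputs are
#' translated after longest-ORF extraction, motif and catalytic-histidine
#' evidence is collected, the isoelectric point computed, the intron
#' pattern derived when a gene structure and aligned row are available, the
#' nearest labeled exemplar found, and the classification ladder applied.
#' A record that cannot be processed (e.g. untranslatable nucleotide input)
#' yields an error row; the run continues.
#'
#' @param seqs named character vector of protein or nucleotide sequences,
#'   or a path to a FASTA file.
#' @param genes optional named list of [GeneStructure-class] objects (names
#'   matching `seqs`).
#' @param alignment optional named character vector of gapped CDS rows for
#'   the genes in `genes`.
#' @param refs labeled exemplar panel, see [referencePanel()]; `NULL` to
#'   skip the nearest-reference line.
#' @param panel a [MotifPanel-class].
#' @param signalEnds optional named 0-based exclusive signal-peptide
#'   boundaries (applied before pI computation).
#' @param ... passed to [classifySequence()].
#' @return data.frame with one row per input: id, class, confidence, pI,
#'   pattern, regionsHit, cas2His, candidate, error.
#' @export
classifyFasta <- function(seqs, genes = NULL, alignment = NULL,
                          refs = referencePanel(), panel = defaultMotifPanel(),
                          signalEnds = NULL, ...) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- readFastaRecords(seqs)
  if (length(seqs) == 0L)
    return(data.frame(id = character(), class = character(),
                      confidence = character(), pI = numeric(),
                      pattern = character(), regionsHit = integer(),
                      cas2His = character(), candidate = logical(),
                      error = character()))
  reference <- canonicalIntronTable()
  rows <- lapply(names(seqs), function(id) {
    errRow <- function(msg) data.frame(
      id = id, class = NA_character_, confidence = NA_character_,
      pI = NA_real_, pattern = NA_character_, regionsHit = NA_integer_,
      cas2His = NA_character_, candidate = NA, error = msg,
      stringsAsFactors = FALSE)
    s <- toupper(seqs[[id]])
    letters <- unique(strsplit(s, "")[[1]])
    isNt <- all(letters %in% c("A", "C", "G", "T", "U", "N"))
    cdsLen <- NA_integer_
    if (isNt) {
      s <- gsub("U", "T", s)
      cdsLen <- nchar(s)
      prot <- longestOrfProtein(s)
      if (is.null(prot))
        return(errRow("no open reading frame found in nucleotide input"))
      prot <- sub("\\*$", "", prot)
      if (!nzchar(prot)) return(errRow("empty translation"))
    } else prot <- s
    ok <- tryCatch({ assertProteinAlphabet(prot, id); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(errRow(ok))
    if (is.na(cdsLen)) cdsLen <- 3L * (nchar(prot) + 1L)
    hits <- scanConservedRegions(prot, panel)
    cas <- catalyticHistidines(hits, panel)
    matureProt <- if (!is.null(signalEnds) && id %in% names(signalEnds))
      substring(prot, signalEnds[[id]] + 1L) else prot
    pI <- isoelectricPoint(matureProt)
    pattern <- NULL
    if (!is.null(genes) && id %in% names(genes)) {
      g <- genes[[id]]
      cm <- if (!is.null(alignment) && id %in% names(alignment))
        columnMap(alignment[[id]]) else NULL
      sites <- intronSites(g, cm)
      if (is.null(cm)) {
        # no alignment row: anchor by CDS offset in the reference frame
        sites$column <- sites$cdsOffset
      }
      if (nrow(sites) == 0L) pattern <- integer() else {
        cl <- clusterIntronPositions(sites)
        cl$positions <- canonicalPositionIds(cl$positions, reference)
        pattern <- sort(cl$positions$canonicalId)
      }
    }
    nn <- if (!is.null(refs)) nearestReference(prot, refs) else NULL
    fv <- list(id = id, pI = pI, regionsHit = length(unique(hits$region)),
               cas2His = cas$cas2His, intronPattern = pattern,
               nnClass = if (!is.null(nn)) nn$class else NULL)
    call <- classifySequence(fv, ...)
    data.frame(
      id = id, class = call$classLabel, confidence = call$confidence,
      pI = pI,
      pattern = if (is.null(pattern)) "U"
      else if (length(pattern) == 0L) "no-intron"
      else paste(pattern, collapse = ","),
      regionsHit = length(unique(hits$region)), cas2His = cas$cas2His,
      candidate = call$sRnaseCandidate, error = NA_character_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
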