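#' Bundled exemplar panel for the five conserved T2-RNase regions
#'
#' The five conserved regions (C1..C5, N->C order) of the T2/S-RNase family
#' are represented by small sets of equal-length exemplar windows bundled
#' with the package (`inst/extdata/motif_panel_synthetic.*`). The two
#' catalytic active-site regions carry the offset of their catalytic
#' histidine: CAS I lives in region C2 (an `HGLWP`-like core) and CAS II in
#' region C4. The exemplars are synthetic, package-chosen stand-ins for the
#' family consensus (the positions and cores follow the canonical RNase T2
#' active-site architecture); the panel is data, not code, and can be
#' replaced via [readMotifPanel()].
#'
#' @return a [MotifPanel-class].
#' @export
defaultMotifPanel <- function() {
  if (is.null(.pkgCache$motifPanel)) {
    fa <- system.file("extdata", "motif_panel_synthetic.fasta",
                      package = "rnaseScout", mustWork = TRUE)
    tsv <- system.file("extdata", "motif_panel_synthetic.tsv",
                       package = "rnaseScout", mustWork = TRUE)
    .pkgCache$motifPanel <- readMotifPanel(fa, tsv)
  }
  .pkgCache$motifPanel
}

#' Read a motif panel from FASTA + TSV
#'
#' @param fastaPath FASTA of exemplar windows; record ids are
#'   `<region>_<n>` (e.g. `C2_1`).
#' @param tsvPath TSV with header `region  casOffset  threshold`; `casOffset`
#'   is the 0-based catalytic-histidine offset within the window (`NA` for
#'   regions without an active-site histidine).
#' @return a [MotifPanel-class].
#' @export
readMotifPanel <- function(fastaPath, tsvPath) {
  seqs <- readFastaRecords(fastaPath)
  meta <- utils::read.delim(tsvPath, stringsAsFactors = FALSE)
  regions <- list()
  for (i in seq_len(nrow(meta))) {
    rn <- meta$region[i]
    w <- unname(seqs[grep(paste0("^", rn, "_"), names(seqs))])
    regions[[rn]] <- list(windows = w,
                          casOffset = as.integer(meta$casOffset[i]),
                          threshold = as.numeric(meta$threshold[i]))
  }
  new("MotifPanel", regions = regions)
}

# normalized best-exemplar similarity of every window start for one region;
# returns data.frame(start0, score) sorted by score (best first)
#' @noRd
regionWindowScores <- function(resVec, region) {
  w <- nchar(region$windows[1])
  nS <- length(resVec) - w + 1L
  if (nS < 1L) return(data.frame(start0 = integer(), score = numeric()))
  B <- blosum62()
  best <- rep(-Inf, nS)
  for (ex in region$windows) {
    e <- strsplit(ex, "")[[1]]
    self <- sum(B[cbind(e, e)])
    m <- vapply(seq_len(w), function(i) B[e[i], resVec[seq_len(nS) + i - 1L]],
                numeric(nS))
    sc <- if (nS == 1L) sum(m) else rowSums(m)
    best <- pmax(best, sc / self)
  }
  ord <- order(best, decreasing = TRUE)
  data.frame(start0 = ord - 1L, score = best[ord])
}

#' Scan a protein for the five conserved T2-RNase regions
#'
#' Every window of each region's width is scored against the region's
#' exemplars (substitution-matrix sum over the ungapped window, normalized
#' by the exemplar self-score; best exemplar wins). Windows at or above the
#' region threshold are candidate hits. Because the five regions are
#' positionally ordered in all described family members, the reported hits
#' are the best *collinear* subset: one hit per region at most, appearing in
#' panel order along the sequence without overlap, chosen to maximize first
#' the number of regions hit and then the total score.
#'
#' @param protein amino-acid string.
#' @param panel a [MotifPanel-class]; default [defaultMotifPanel()].
#' @param maxCandidatesPerRegion cap on threshold-passing windows considered
#'   per region during collinear selection.
#' @return data.frame with one row per reported hit: `region`, `start`
#'   (0-based), `score`, `histidinePresent` (`NA` for regions without a
#'   catalytic-histidine offset). Proteins shorter than every window yield
#'   zero rows.
#' @export
scanConservedRegions <- function(protein, panel = defaultMotifPanel(),
                                 maxCandidatesPerRegion = 10L) {
  protein <- toupper(protein)
  assertProteinAlphabet(protein, "protein")
  resVec <- strsplit(protein, "")[[1]]
  regions <- panel@regions
  cands <- lapply(regions, function(r) {
    sc <- regionWindowScores(resVec, r)
    sc <- sc[sc$score >= r$threshold, , drop = FALSE]
    utils::head(sc, maxCandidatesPerRegion)
  })
  # dynamic best-collinear-subset: states are (nextFreePos, count, score, hits)
  states <- list(list(free = 0L, count = 0L, score = 0, hits = NULL))
  for (ri in seq_along(regions)) {
    rn <- names(regions)[ri]
    w <- nchar(regions[[ri]]$windows[1])
    cc <- cands[[ri]]
    grown <- states  # skipping this region is always allowed
    if (nrow(cc) > 0L) {
      for (st in states) {
        ok <- cc$start0 >= st$free
        if (!any(ok)) next
        for (j in which(ok)) {
          grown[[length(grown) + 1L]] <- list(
            free = cc$start0[j] + w, count = st$count + 1L,
            score = st$score + cc$score[j],
            hits = rbind(st$hits, data.frame(region = rn,
                                             start = cc$start0[j],
                                             score = cc$score[j])))
        }
      }
    }
    # prune dominated states: keep, per achievable (count), the frontier of
    # (score, free) pairs not beaten on both by another state
    keep <- rep(TRUE, length(grown))
    for (a in seq_along(grown)) for (b in seq_along(grown)) {
      if (a != b && keep[a] &&
          grown[[b]]$count >= grown[[a]]$count &&
          grown[[b]]$score >= grown[[a]]$score &&
          grown[[b]]$free <= grown[[a]]$free &&
          (grown[[b]]$count > grown[[a]]$count ||
           grown[[b]]$score > grown[[a]]$score ||
           grown[[b]]$free < grown[[a]]$free)) keep[a] <- FALSE
    }
    states <- grown[keep]
  }
  scores <- vapply(states, function(s) s$score, numeric(1))
  counts <- vapply(states, function(s) s$count, numeric(1))
  best <- states[[order(-counts, -scores)[1]]]
  hits <- best$hits
  if (is.null(hits))
    return(data.frame(region = character(), start = integer(),
                      score = numeric(), histidinePresent = logical()))
  hits$histidinePresent <- vapply(seq_len(nrow(hits)), function(i) {
    off <- regions[[hits$region[i]]]$casOffset
    if (is.na(off)) NA else resVec[hits$start[i] + off + 1L] == "H"
  }, logical(1))
  rownames(hits) <- NULL
  hits
}

#' Dataset inclusion filter: CDS length and motif count
#'
#' A sequence is kept when its coding sequence is longer than 350 bp and at
#' least three of the five conserved regions were hit.
#'
#' @param cdsLength coding-sequence length in nucleotides.
#' @param hits hit table from [scanConservedRegions()].
#' @return `TRUE` when the sequence passes the inclusion filter.
#' @export
passesInclusionFilter <- function(cdsLength, hits) {
  cdsLength > 350 && length(unique(hits$region)) >= 3L
}

#' Catalytic-histidine status and inferred RNase competence
#'
#' The CAS II histidine is essential for ribonuclease activity; a protein
#' whose CAS II region is found without the histidine is inferred
#' non-functional. When the CAS II region was not found at all, functional
#' status is undetermined (no evidence either way).
#'
#' @param hits hit table from [scanConservedRegions()].
#' @param panel the [MotifPanel-class] used for the scan (identifies which
#'   regions are CAS I and CAS II).
#' @return list with tristates (`"present"`, `"absent"`, `"undetermined"`)
#'   `cas1His` and `cas2His`, and `inferredFunctional`
#'   (`"true"`, `"false"`, `"undetermined"`).
#' @export
catalyticHistidines <- function(hits, panel = defaultMotifPanel()) {
  casRegions <- names(panel@regions)[!vapply(panel@regions,
                                             function(r) is.na(r$casOffset),
                                             logical(1))]
  stateOf <- function(rn) {
    row <- hits[hits$region == rn, , drop = FALSE]
    if (nrow(row) == 0L) "undetermined"
    else if (isTRUE(row$histidinePresent[1])) "present" else "absent"
  }
  cas1 <- stateOf(casRegions[1])
  cas2 <- stateOf(casRegions[2])
  fun <- switch(cas2, absent = "false", undetermined = "undetermined",
                present = "true")
  list(cas1His = cas1, cas2His = cas2, inferredFunctional = fun)
}

#' Summarize motif evidence for a set of proteins
#'
#' @param seqs named character vector of protein sequences.
#' @param cdsLengths optional named integer vector of CDS lengths in
#'   nucleotides; defaults to `3 * (nchar + 1)` (coding length implied by
#'   the protein plus a stop codon).
#' @param panel a [MotifPanel-class].
#' @return data.frame: id, regionsHit, cas1His, cas2His, inferredFunctional,
#'   passesFilter.
#' @export
motifTable <- function(seqs, cdsLengths = NULL, panel = defaultMotifPanel()) {
  rows <- lapply(names(seqs), function(id) {
    hits <- scanConservedRegions(seqs[[id]], panel)
    cas <- catalyticHistidines(hits, panel)
    cdsLen <- if (!is.null(cdsLengths) && id %in% names(cdsLengths))
      cdsLengths[[id]] else 3L * (nchar(seqs[[id]]) + 1L)
    data.frame(id = id, regionsHit = length(unique(hits$region)),
               cas1His = cas$cas1His, cas2His = cas$cas2His,
               inferredFunctional = cas$inferredFunctional,
               passesFilter = passesInclusionFilter(cdsLen, hits),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
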