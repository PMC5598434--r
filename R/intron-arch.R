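#' Canonical land-plant intron positions of the T2/S-RNase family
#'
#' Eleven positionally homologous intron sites are observed across
#' land-plant T2/S-RNases. The bundled reference table anchors each
#' canonical position to a column of the package's reference alignment
#' frame and records its phase (introns at a given homologous position show
#' no phase variation across land plants). Phases at positions 3, 5, 8 and
#' 10 follow the published values; the remaining phases are package-chosen
#' constants of the synthetic reference frame.
#'
#' @return data.frame with columns `position` (1..11), `refColumn` (0-based
#'   alignment column of the first coding nucleotide 3' of the intron) and
#'   `phase` (0, 1 or 2).
#' @export
canonicalIntronTable <- function() {
  path <- system.file("extdata", "canonical_intron_positions.tsv",
                      package = "rnaseScout", mustWork = TRUE)
  utils::read.delim(path)
}

#' Catalog of canonical intron presence patterns
#'
#' The named intron patterns of the three land-plant T2/S-RNase classes:
#' class I patterns I-A \{2\}, I-B \{5\}, I-C \{2,5\}, I-D \{2,5,9\} (the
#' modal class I pattern); the invariant eight-intron class II pattern
#' \{3,4,5,6,7,8,10,11\}; and class III patterns III-A \{5,9\}, III-B*
#' \{9\} (provisional: predicted from genomic sequence only), III-C \{5\}
#' (the modal class III and S-RNase pattern) and III-D \{1,5\} (Prunus
#' S-RNases, with the extra intron at position 1). Patterns I-B and III-C
#' share the single-intron-at-5 set and are distinguishable only with class
#' context.
#'
#' @return named list; each entry has `class` (`"I"`, `"II"` or `"III"`),
#'   `positions` (integer vector) and `provisional` (logical).
#' @export
patternCatalog <- function() {
  list(
    "I-A"    = list(class = "I",   positions = 2L,                  provisional = FALSE),
    "I-B"    = list(class = "I",   positions = 5L,                  provisional = FALSE),
    "I-C"    = list(class = "I",   positions = c(2L, 5L),           provisional = FALSE),
    "I-D"    = list(class = "I",   positions = c(2L, 5L, 9L),       provisional = FALSE),
    "II"     = list(class = "II",  positions = c(3L, 4L, 5L, 6L, 7L, 8L, 10L, 11L),
                    provisional = FALSE),
    "III-A"  = list(class = "III", positions = c(5L, 9L),           provisional = FALSE),
    "III-B*" = list(class = "III", positions = 9L,                  provisional = TRUE),
    "III-C"  = list(class = "III", positions = 5L,                  provisional = FALSE),
    "III-D"  = list(class = "III", positions = c(1L, 5L),           provisional = FALSE))
}

#' Intron sites of a gene mapped onto its alignment row
#'
#' One site per intron: the count of coding nucleotides 5' of the intron,
#' its phase (`cdsOffset mod 3`: phase 0 introns fall before the first base
#' of a codon, phase 1 and 2 introns interrupt a codon after its first or
#' second base), and the alignment column of the first coding nucleotide 3'
#' of the intron.
#'
#' @param gene a [GeneStructure-class].
#' @param colmap integer column map of the gene's aligned CDS row, from
#'   [columnMap()]; `NULL` when the gene is not in the alignment (columns
#'   are then `NA`).
#' @return data.frame with columns geneId, cdsOffset, phase, column.
#' @export
intronSites <- function(gene, colmap = NULL) {
  offs <- gene@intronOffsets
  if (length(offs) == 0L)
    return(data.frame(geneId = character(), cdsOffset = integer(),
                      phase = integer(), column = integer()))
  cols <- if (is.null(colmap)) rep(NA_integer_, length(offs)) else {
    if (any(offs >= length(colmap)))
      stop("intron offset beyond the aligned row of gene ", gene@geneId,
           call. = FALSE)
    colmap[offs + 1L]
  }
  data.frame(geneId = gene@geneId, cdsOffset = offs,
             phase = offs %% 3L, column = cols)
}

#' Cluster intron sites into positionally homologous groups
#'
#' Introns are treated as homologous when their anchor columns overlap
#' within a seven-nucleotide window of the alignment: sites are linked when
#' both columns fit inside a `window`-column window (|column difference|
#' <= `window - 1`), and clusters are the single-linkage (transitive)
#' closure of that relation. Clusters are labeled 1..k in ascending column
#' order. Phase disagreement within a cluster is recorded, never silently
#' merged away.
#'
#' @param sites data.frame of intron sites (rows from [intronSites()]);
#'   rows with `NA` columns are ignored.
#' @param window homology window in alignment columns (default 7).
#' @return list with `positions` (data.frame: positionId, columnMin,
#'   columnMax, phase — `NA` under conflict —, phaseConflict, nSites) and
#'   `sites` (the input rows with a `positionId` column added).
#' @export
clusterIntronPositions <- function(sites, window = 7L) {
  sites <- sites[!is.na(sites$column), , drop = FALSE]
  if (nrow(sites) == 0L)
    return(list(positions = data.frame(positionId = integer(),
                                       columnMin = integer(),
                                       columnMax = integer(),
                                       phase = integer(),
                                       phaseConflict = logical(),
                                       nSites = integer()),
                sites = cbind(sites, positionId = integer())))
  ord <- order(sites$column, sites$geneId)
  sites <- sites[ord, , drop = FALSE]
  gap <- diff(sites$column)
  cl <- cumsum(c(1L, as.integer(gap > window - 1L)))
  sites$positionId <- cl
  pos <- do.call(rbind, lapply(split(sites, cl), function(s) {
    phases <- unique(s$phase)
    data.frame(positionId = s$positionId[1],
               columnMin = min(s$column), columnMax = max(s$column),
               phase = if (length(phases) == 1L) phases else NA_integer_,
               phaseConflict = length(phases) > 1L,
               nSites = nrow(s))
  }))
  rownames(pos) <- NULL
  rownames(sites) <- NULL
  list(positions = pos, sites = sites)
}

#' Label clusters with canonical position ids
#'
#' Clusters whose column span falls within the homology window of a
#' canonical reference column take that canonical id (1..11); novel
#' clusters get fresh labels above 11, in ascending column order.
#'
#' @param positions cluster table from [clusterIntronPositions()].
#' @param reference canonical site table, see [canonicalIntronTable()].
#' @param window homology window in alignment columns.
#' @return `positions` with a `canonicalId` column added.
#' @export
canonicalPositionIds <- function(positions, reference = canonicalIntronTable(),
                                 window = 7L) {
  nextNovel <- max(reference$position) + 1L
  ids <- integer(nrow(positions))
  for (i in seq_len(nrow(positions))) {
    d <- pmax(reference$refColumn - positions$columnMax[i],
              positions$columnMin[i] - reference$refColumn)
    d[d < 0] <- 0
    hit <- which(d <= window - 1L)
    if (length(hit) >= 1L) ids[i] <- reference$position[hit[1]]
    else { ids[i] <- nextNovel; nextNovel <- nextNovel + 1L }
  }
  positions$canonicalId <- ids
  positions
}

#' Intron presence/absence matrix with undetermined marks
#'
#' For every gene and homologous position: `"1"` when the gene has an
#' intron in the cluster, `"0"` when the gene's aligned row spans the
#' cluster's column range but carries no intron there, and `"U"` when the
#' gene does not span the position (cDNA record or truncated sequence).
#'
#' @param geneIds character vector of gene ids (row order of the matrix).
#' @param clustering result of [clusterIntronPositions()] (optionally after
#'   [canonicalPositionIds()]; the `canonicalId` column is used for column
#'   names when present).
#' @param spans named list mapping gene id to `c(minColumn, maxColumn)`
#'   covered by its aligned row; genes absent from `spans` are undetermined
#'   throughout.
#' @return character matrix genes x positions with entries "1", "0", "U".
#' @export
presenceMatrix <- function(geneIds, clustering, spans) {
  pos <- clustering$positions
  idCol <- if ("canonicalId" %in% names(pos)) pos$canonicalId else pos$positionId
  m <- matrix("U", nrow = length(geneIds), ncol = nrow(pos),
              dimnames = list(geneIds, as.character(idCol)))
  for (gi in seq_along(geneIds)) {
    g <- geneIds[gi]
    span <- spans[[g]]
    if (is.null(span) || anyNA(span)) next
    covered <- span[1] <= pos$columnMin & span[2] >= pos$columnMax
    m[gi, covered] <- "0"
    gs <- clustering$sites[clustering$sites$geneId == g, , drop = FALSE]
    if (nrow(gs) > 0L) {
      hitPos <- match(gs$positionId, pos$positionId)
      m[gi, hitPos] <- "1"
    }
  }
  m
}

#' Name an intron presence set against the pattern catalog
#'
#' @param present integer vector of canonical position ids with an intron.
#' @param catalog pattern catalog, see [patternCatalog()].
#' @return character vector of all catalog pattern names whose position set
#'   equals `present`; `"no-intron"` for the empty set; `"novel"` when no
#'   catalog entry matches.
#' @examples
#' assignPattern(c(2, 5, 9))  # "I-D"
#' assignPattern(5)           # "I-B" "III-C" (ambiguous without class)
#' @export
assignPattern <- function(present, catalog = patternCatalog()) {
  present <- sort(unique(as.integer(present)))
  if (length(present) == 0L) return("no-intron")
  hits <- names(catalog)[vapply(catalog, function(e)
    identical(sort(e$positions), present), logical(1))]
  if (length(hits) == 0L) "novel" else hits
}
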