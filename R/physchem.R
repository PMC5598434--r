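#' Default Bjellqvist dissociation-constant table
#'
#' pK values of the ionizable groups used in net-charge and isoelectric
#' point computation, in the Bjellqvist dialect popularized by the ExPASy
#' lineage of protein-analysis tools: side chains D 4.05, E 4.45, H 5.98,
#' C 9.00, Y 10.00, K 10.00, R 12.00; C-terminal default 3.55 with
#' terminal-residue overrides (D 4.55, E 4.75); N-terminal default 7.50 with
#' overrides (A 7.59, M 7.00, S 6.93, P 8.36, T 6.82, V 7.44, E 7.70).
#'
#' @return list with components `sideChain` (named numeric), `nTermDefault`,
#'   `nTermOverrides`, `cTermDefault`, `cTermOverrides`.
#' @export
defaultPkTable <- function() {
  list(
    sideChain = c(D = 4.05, E = 4.45, H = 5.98, C = 9.00,
                  Y = 10.00, K = 10.00, R = 12.00),
    nTermDefault = 7.50,
    nTermOverrides = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36,
                       T = 6.82, V = 7.44, E = 7.70),
    cTermDefault = 3.55,
    cTermOverrides = c(D = 4.55, E = 4.75))
}

#' Read a pK override table from a two-column TSV
#'
#' The file carries rows `group<TAB>pK` where `group` is a side-chain
#' residue (`D`, `E`, `H`, `C`, `Y`, `K`, `R`), `Nterm`, `Cterm`, or a
#' terminal override written `Nterm:X` / `Cterm:X`. Unlisted groups keep
#' their [defaultPkTable()] values.
#'
#' @param path path to the TSV.
#' @return a pK table list as from [defaultPkTable()].
#' @export
readPkTable <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, col.names = c("group", "pk"),
                           stringsAsFactors = FALSE, comment.char = "#")
  pk <- defaultPkTable()
  for (i in seq_len(nrow(tab))) {
    g <- tab$group[i]; v <- as.numeric(tab$pk[i])
    if (v <= 0 || v >= 14) stop("pK out of (0, 14): ", g, call. = FALSE)
    if (g == "Nterm") pk$nTermDefault <- v
    else if (g == "Cterm") pk$cTermDefault <- v
    else if (grepl("^Nterm:", g)) pk$nTermOverrides[sub("^Nterm:", "", g)] <- v
    else if (grepl("^Cterm:", g)) pk$cTermOverrides[sub("^Cterm:", "", g)] <- v
    else if (g %in% names(pk$sideChain)) pk$sideChain[g] <- v
    else stop("unknown pK group: ", g, call. = FALSE)
  }
  pk
}

#' Mature (signal-peptide-trimmed) sequence of a protein record
#'
#' Signal peptides are excluded from isoelectric point computation; this
#' returns the sequence downstream of the record's signal-peptide boundary,
#' or the full sequence when no boundary is recorded.
#'
#' @param rec a [ProteinRecord-class].
#' @return amino-acid string of the mature chain.
#' @export
matureSequence <- function(rec) {
  stopifnot(is(rec, "ProteinRecord"))
  spe <- rec@signalPeptideEnd
  if (is.na(spe)) return(rec@seq)
  if (spe >= nchar(rec@seq))
    stop("signal peptide boundary leaves an empty mature sequence",
         call. = FALSE)
  substring(rec@seq, spe + 1L)
}

# decompose a sequence into (pK, multiplicity) charge groups
#' @noRd
chargeProfile <- function(seq, pk = defaultPkTable()) {
  res <- strsplit(seq, "")[[1]]
  assertProteinAlphabet(seq)
  counts <- table(factor(res, levels = c(AA20, "X")))
  first <- res[1]; last <- res[length(res)]
  nt <- if (first %in% names(pk$nTermOverrides))
    pk$nTermOverrides[[first]] else pk$nTermDefault
  ct <- if (last %in% names(pk$cTermOverrides))
    pk$cTermOverrides[[last]] else pk$cTermDefault
  pos <- c(nt, unname(pk$sideChain[c("H", "K", "R")]))
  posMult <- c(1, counts[["H"]], counts[["K"]], counts[["R"]])
  neg <- c(ct, unname(pk$sideChain[c("D", "E", "C", "Y")]))
  negMult <- c(1, counts[["D"]], counts[["E"]], counts[["C"]], counts[["Y"]])
  keepP <- posMult > 0; keepN <- negMult > 0
  list(posPk = pos[keepP], posMult = posMult[keepP],
       negPk = neg[keepN], negMult = negMult[keepN])
}

#' @noRd
chargeAt <- function(profile, pH) {
  vapply(pH, function(h) {
    sum(profile$posMult / (1 + 10^(h - profile$posPk))) -
      sum(profile$negMult / (1 + 10^(profile$negPk - h)))
  }, numeric(1))
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch net charge
#' \deqn{Q(pH) = \sum_i \frac{m_i}{1 + 10^{pH - pK_i}}
#'             - \sum_j \frac{m_j}{1 + 10^{pK_j - pH}}}
#' with positive groups the N-terminus, H, K and R, and negative groups the
#' C-terminus, D, E, C and Y. `X` residues carry no charge. `Q` is strictly
#' decreasing in pH, so its root (the isoelectric point) is unique.
#'
#' @param seq amino-acid string (non-empty; 20 canonical letters + X).
#' @param pH pH value(s) at which to evaluate the charge.
#' @param pk pK table, see [defaultPkTable()].
#' @return numeric vector of net charges, one per pH.
#' @examples
#' netCharge("GG", 5.525)  # ~0: midpoint of the two terminal groups
#' @export
netCharge <- function(seq, pH, pk = defaultPkTable()) {
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  chargeAt(chargeProfile(seq, pk), pH)
}

#' Isoelectric point by bisection
#'
#' The isoelectric point is the pH at which the peptide, on average, carries
#' no net electric charge. The root of [netCharge()] is bracketed on
#' \[0, 14\] and bisected to within `tol`, then reported rounded to two
#' decimals (matching the precision customarily quoted for protein pI).
#'
#' @param seq amino-acid string, or a [ProteinRecord-class] (in which case
#'   the mature, signal-trimmed sequence is used).
#' @param pk pK table, see [defaultPkTable()].
#' @param tol bisection half-width in pH units.
#' @param digits decimals in the reported value; `NA` to skip rounding.
#' @return isoelectric point in pH units.
#' @examples
#' isoelectricPoint("GG")  # 5.52 or 5.53; the analytic root is 5.525
#' @export
isoelectricPoint <- function(seq, pk = defaultPkTable(), tol = 0.01,
                             digits = 2) {
  if (is(seq, "ProteinRecord")) seq <- matureSequence(seq)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  profile <- chargeProfile(seq, pk)
  lo <- 0; hi <- 14
  qlo <- chargeAt(profile, lo); qhi <- chargeAt(profile, hi)
  if (qlo < 0 || qhi > 0)
    stop("net charge has no sign change on [0, 14]", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (chargeAt(profile, mid) > 0) lo <- mid else hi <- mid
  }
  val <- (lo + hi) / 2
  if (is.na(digits)) val else round(val, digits)
}

#' Isoelectric points for a set of sequences
#'
#' @param seqs named character vector of protein sequences (e.g. from
#'   [readFastaRecords()]).
#' @param signalEnds optional named integer vector of 0-based exclusive
#'   signal-peptide boundaries; sequences present in this vector are trimmed
#'   before computation.
#' @param pk pK table.
#' @return data.frame with columns id, length, pI.
#' @export
isoelectricPointTable <- function(seqs, signalEnds = NULL,
                                  pk = defaultPkTable()) {
  ids <- names(seqs)
  pI <- vapply(ids, function(id) {
    s <- seqs[[id]]
    if (!is.null(signalEnds) && id %in% names(signalEnds))
      s <- substring(s, signalEnds[[id]] + 1L)
    isoelectricPoint(s, pk = pk)
  }, numeric(1))
  data.frame(id = ids, length = nchar(unname(seqs)), pI = unname(pI),
             stringsAsFactors = FALSE)
}
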