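# internal helpers shared across modules

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' @noRd
assertProteinAlphabet <- function(seq, what = "sequence") {
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c(AA20, "X"))
  if (length(bad) > 0L)
    stop(what, " contains residues outside the 20 canonical letters + X: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
#' @noRd
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# codon -> amino acid lookup; any codon containing a non-ACGT letter -> X
#' @noRd
codonTable <- function() {
  tab <- Biostrings::GENETIC_CODE
  names(tab) <- gsub("U", "T", names(tab))
  tab
}

# translate a character vector of codons; fuzzy codons -> X, stops -> "*"
#' @noRd
translateCodons <- function(codons) {
  tab <- codonTable()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' @noRd
revcompString <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# fixed codon per residue used by the deterministic back-translator
#' @noRd
backTranslationTable <- function() {
  c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
    Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
    L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
    S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT",
    X = "GCA")
}

#' @noRd
backTranslate <- function(protein) {
  tab <- backTranslationTable()
  res <- strsplit(protein, "")[[1]]
  bad <- setdiff(unique(res), names(tab))
  if (length(bad) > 0L)
    stop("cannot back-translate residues: ", paste(bad, collapse = ","),
         call. = FALSE)
  paste(tab[res], collapse = "")
}

# BLOSUM62 as shipped with Biostrings, fetched once per session
.pkgCache <- new.env(parent = emptyenv())

#' @noRd
blosum62 <- function() {
  if (is.null(.pkgCache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgCache$BLOSUM62 <- e$BLOSUM62
  }
  .pkgCache$BLOSUM62
}
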