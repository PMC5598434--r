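# Independent oracles used across the suite. These re-derive expected
# values by brute force / direct formula evaluation and never call the code
# paths they check.

AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I",
                "L","K","M","F","P","S","T","W","Y","V")

randomProtein <- function(n) paste(sample(AA_LETTERS, n, TRUE), collapse = "")

# --- pI oracle: dense-grid sign change of the Henderson-Hasselbalch charge
# (direct formula evaluation; Bjellqvist pK values restated independently)
gridRootPI <- function(seq, step = 1e-4) {
  res <- strsplit(seq, "")[[1]]
  side <- c(D = 4.05, E = 4.45, H = 5.98, C = 9.00, Y = 10.00,
            K = 10.00, R = 12.00)
  ntOver <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
              V = 7.44, E = 7.70)
  ctOver <- c(D = 4.55, E = 4.75)
  nt <- if (res[1] %in% names(ntOver)) ntOver[[res[1]]] else 7.50
  ct <- if (res[length(res)] %in% names(ctOver)) ctOver[[res[length(res)]]] else 3.55
  posPk <- c(nt, rep(side[["H"]], sum(res == "H")),
             rep(side[["K"]], sum(res == "K")),
             rep(side[["R"]], sum(res == "R")))
  negPk <- c(ct, rep(side[["D"]], sum(res == "D")),
             rep(side[["E"]], sum(res == "E")),
             rep(side[["C"]], sum(res == "C")),
             rep(side[["Y"]], sum(res == "Y")))
  pH <- seq(0, 14, by = step)
  Q <- colSums(1 / (1 + 10^outer(-posPk, pH, `+`))) -
    colSums(1 / (1 + 10^outer(negPk, -pH, `+`)))
  i <- which(Q[-length(Q)] > 0 & Q[-1] <= 0)[1]
  pH[i] + step / 2
}

# --- global alignment oracle: exhaustive enumeration of all alignments
# (monotone edit paths), scoring gap runs as open + len * extend
enumAlignScore <- function(a, b, sub, gapOpen, gapExtend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, sub[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    if (i <= length(av))   # gap in b
      best <- max(best,
                  -gapExtend - (if (last != "I") gapOpen else 0) +
                    rec(i + 1, j, "I"))
    if (j <= length(bv))   # gap in a
      best <- max(best,
                  -gapExtend - (if (last != "D") gapOpen else 0) +
                    rec(i, j + 1, "D"))
    best
  }
  rec(1, 1, "M")
}

# --- ORF oracle: enumerate every ATG, walk to the next in-frame stop,
# keep the longest ORF per stop, then filter by length bounds
bruteOrfs <- function(contig, minNt = 900, maxNt = 1800) {
  stopCodons <- c("TAA", "TAG", "TGA")
  rows <- list()
  n <- nchar(contig)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(contig)))
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else rc
    for (f in 0:2) {
      at <- seq(f + 1, n - 2, by = 3)
      codons <- substring(s, at, at + 2)
      perStop <- list()
      for (ai in which(codons == "ATG")) {
        k <- ai
        while (k <= length(codons) && !(codons[k] %in% stopCodons)) k <- k + 1
        if (k > length(codons)) next
        key <- as.character(k)
        if (is.null(perStop[[key]]) || perStop[[key]] > ai)
          perStop[[key]] <- ai
      }
      for (key in names(perStop)) {
        k <- as.integer(key); ai <- perStop[[key]]
        len <- 3L * (k - ai + 1L)
        if (len < minNt || len > maxNt) next
        oStart <- as.integer(f + 3L * (ai - 1L))
        start <- if (strand == "+") oStart else as.integer(n - (oStart + len))
        rows[[length(rows) + 1]] <- data.frame(
          start = start, end = start + len, strand = strand, frame = as.integer(f),
          ntLength = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      ntLength = integer()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# --- clustering oracle: transitive closure of the pairwise window relation
closureClusters <- function(columns, window = 7) {
  n <- length(columns)
  if (n == 0) return(integer())
  adj <- abs(outer(columns, columns, `-`)) <= window - 1
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0 | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n); label <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      label <- label + 1
      comp[reach[i, ]] <- label
    }
  }
  # relabel in ascending order of cluster minimum column
  mins <- tapply(columns, comp, min)
  newId <- rank(mins)
  as.integer(newId[comp])
}

# --- collinear motif subset oracle: enumerate every assignment of at most
# one candidate window per region, require ascending non-overlapping starts
bruteBestCollinear <- function(cands, width) {
  # cands: list per region of data.frame(start0, score)
  best <- list(count = 0, score = 0)
  nr <- length(cands)
  recurse <- function(ri, freePos, count, score) {
    if (ri > nr) {
      if (count > best$count ||
          (count == best$count && score > best$score))
        best <<- list(count = count, score = score)
      return(invisible())
    }
    recurse(ri + 1, freePos, count, score)   # skip region
    cc <- cands[[ri]]
    if (nrow(cc)) for (j in seq_len(nrow(cc))) {
      if (cc$start0[j] >= freePos)
        recurse(ri + 1, cc$start0[j] + width, count + 1, score + cc$score[j])
    }
  }
  recurse(1, 0, 0, 0)
  best
}

# simple match/mismatch substitution matrix over an alphabet
simpleSubMatrix <- function(match = 1, mismatch = -1,
                            alphabet = AA_LETTERS) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}
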