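randomContig <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                  collapse = "")

test_that("a planted in-bounds ORF is reported exactly once, exactly", {
  set.seed(61)
  # 1200 nt ORF: ATG + 398 sense codons + TAA, stop-padded both sides
  sense <- setdiff(names(rnaseScout:::backTranslationTable()), c("X", "M"))
  body <- paste(rnaseScout:::backTranslationTable()[
    sample(sense, 398, TRUE)], collapse = "")
  orf <- paste0("ATG", body, "TAA")
  pad <- "TTAATTAATTAA"
  contig <- paste0(randomContig(500), pad, orf, pad, randomContig(500))
  found <- findOrfs(contig, minNt = 900, maxNt = 1800)
  planted <- found[found$strand == "+" & found$ntLength == 1200, ]
  expect_identical(nrow(planted), 1L)
  expect_identical(planted$start, 512L)
  expect_identical(planted$end, 512L + 1200L)
  expect_identical(substr(planted$protein, 1, 1), "M")
})

test_that("ORFs outside the 900-1800 nt bounds are excluded", {
  set.seed(62)
  sense <- setdiff(names(rnaseScout:::backTranslationTable()), c("X", "M"))
  mk <- function(nCodons) paste0("ATG", paste(
    rnaseScout:::backTranslationTable()[sample(sense, nCodons, TRUE)],
    collapse = ""), "TAA")
  pad <- "TTAATTAATTAA"
  contig <- paste0(pad, mk(198), pad, mk(700), pad)  # 600 nt and 2106 nt
  expect_identical(nrow(findOrfs(contig, 900, 1800)), 0L)
  # both planted ORFs reappear when the bounds admit them
  wide <- findOrfs(contig, 600, 2200)
  expect_true(all(c(600L, 2106L) %in% wide$ntLength[wide$strand == "+"]))
})

test_that("findOrfs equals the exhaustive ATG-walk oracle on random contigs", {
  set.seed(63)
  for (i in 1:10) {
    contig <- randomContig(10000)
    mine <- findOrfs(contig, minNt = 90, maxNt = 600)
    oracle <- bruteOrfs(contig, minNt = 90, maxNt = 600)
    expect_identical(mine[, c("start", "end", "strand", "frame", "ntLength")],
                     oracle, info = paste("contig", i))
  }
})

test_that("reverse-complementing a contig mirrors ORF coordinates", {
  set.seed(64)
  contig <- randomContig(8000)
  n <- nchar(contig)
  fwd <- findOrfs(contig, minNt = 90, maxNt = 600)
  rev <- findOrfs(rnaseScout:::revcompString(contig), minNt = 90, maxNt = 600)
  expect_identical(nrow(fwd), nrow(rev))
  mirrored <- data.frame(start = n - rev$end, end = n - rev$start)
  expect_setequal(paste(mirrored$start, mirrored$end),
                  paste(fwd$start, fwd$end))
})

test_that("long N runs break ORFs", {
  sense <- setdiff(names(rnaseScout:::backTranslationTable()), c("X", "M"))
  set.seed(65)
  body <- paste(rnaseScout:::backTranslationTable()[
    sample(sense, 200, TRUE)], collapse = "")
  orf <- paste0("ATG", body, "TAA")  # 606 nt
  gap <- strrep("N", 12)
  broken <- paste0("ATG", substr(body, 1, 300), gap,
                   substr(body, 301, 600), "TAA")
  expect_identical(nrow(findOrfs(orf, 300, 900)), 1L)
  expect_identical(nrow(findOrfs(broken, 300, 900)), 0L)
})

test_that("F-box scoring: self-score 1, random nulls, graded degradation", {
  refs <- fboxReferences()
  expect_equal(scoreFbox(refs[[1]], refs)$score, 1, tolerance = 1e-9)
  expect_true(scoreFbox(refs[[1]], refs)$isFbox)
  set.seed(66)
  nullCalls <- vapply(1:20, function(i)
    scoreFbox(randomProtein(350), refs)$isFbox, logical(1))
  expect_identical(sum(nullCalls), 0L)
  # 10% point mutations: score strictly between random and identity
  mut <- strsplit(refs[[1]], "")[[1]]
  idx <- sample(length(mut), length(mut) %/% 10)
  mut[idx] <- sample(AA_LETTERS, length(idx), TRUE)
  sc <- scoreFbox(paste(mut, collapse = ""), refs)$score
  expect_lt(sc, 1)
  expect_gt(sc, max(vapply(1:5, function(i)
    scoreFbox(randomProtein(598), refs)$score, numeric(1))))
})

test_that("disrupted F-box copies are found; intact copies are not", {
  set.seed(67)
  refs <- fboxReferences()
  hap <- makeHaplotype(seed = 68, contigLength = 3e5, rnaseClasses = character(),
                       nFboxIntact = 1, nFboxDisrupted = 1)
  truthDis <- hap$truth[hap$truth$type == "fbox_disrupted", ]
  hits <- findDisruptedFbox(hap$contig, refs)
  expect_identical(nrow(hits), 1L)
  # the hit covers the planted disruption site
  expect_lte(hits$start, truthDis$start + 30)
  expect_gte(hits$end, truthDis$end - 30)
  expect_gte(hits$nStops, 1L)
  # a contig with only an intact copy yields no disrupted hits
  hap2 <- makeHaplotype(seed = 69, contigLength = 3e5,
                        rnaseClasses = character(),
                        nFboxIntact = 2, nFboxDisrupted = 0)
  expect_identical(nrow(findDisruptedFbox(hap2$contig, refs)), 0L)
  # and a bare random contig is clean
  expect_identical(nrow(findDisruptedFbox(randomContig(2e5), refs)), 0L)
})

test_that("haplotype scan recovers planted truth and applies the flank rule", {
  hap <- makeHaplotype(seed = 70, contigLength = 1e6, rnaseClasses = "III",
                       nFboxIntact = 6, nFboxDisrupted = 2)
  rn <- hap$truth[hap$truth$type == "rnase", ]
  rep <- scanHaplotype(hap$contig,
                       data.frame(start = rn$start, end = rn$end,
                                  classLabel = rn$classLabel))
  expect_true(isCandidate(rep))
  fb <- fboxLoci(rep)
  expect_identical(sum(!fb$disrupted), 6L)
  expect_gte(sum(fb$disrupted), 1L)
  # distances are consistent with coordinates
  tab <- reportTable(rep)
  expect_true(all(diff(tab$start) >= 0))
  expect_equal(tab$distanceToPrevKb[-1],
               (tab$start[-1] - tab$end[-nrow(tab)]) / 1000,
               tolerance = 0.05 + 1e-9)
})

test_that("F-boxes beyond the 2 Mb flank do not count", {
  hap <- makeHaplotype(seed = 71, contigLength = 5e6, rnaseClasses = "III",
                       nFboxIntact = 5, nFboxDisrupted = 0,
                       rnaseRegion = c(0, 1e5),
                       fboxRegion = c(2.5e6, 4.8e6))
  rn <- hap$truth[hap$truth$type == "rnase", ]
  rep <- scanHaplotype(hap$contig,
                       data.frame(start = rn$start, end = rn$end,
                                  classLabel = rn$classLabel))
  expect_false(isCandidate(rep))
  expect_identical(rnaseLoci(rep)$nFboxInFlank, 0L)
  expect_identical(nrow(fboxLoci(rep)), 0L)
})

test_that("class I loci with many flanking F-boxes are never candidates", {
  hap <- makeHaplotype(seed = 72, contigLength = 1e6, rnaseClasses = "I",
                       nFboxIntact = 7, nFboxDisrupted = 0)
  rn <- hap$truth[hap$truth$type == "rnase", ]
  rep <- scanHaplotype(hap$contig,
                       data.frame(start = rn$start, end = rn$end,
                                  classLabel = rn$classLabel))
  expect_false(isCandidate(rep))
  expect_gte(rnaseLoci(rep)$nFboxInFlank, 7L)
  expect_true(any(grepl("class I", rep@notes)))
})

test_that("the candidate flag is monotone in minFbox", {
  hap <- makeHaplotype(seed = 73, contigLength = 1e6, rnaseClasses = "III",
                       nFboxIntact = 4, nFboxDisrupted = 1)
  rn <- hap$truth[hap$truth$type == "rnase", ]
  loci <- data.frame(start = rn$start, end = rn$end,
                     classLabel = rn$classLabel)
  flags <- vapply(c(1, 3, 5, 6, 9), function(m)
    isCandidate(scanHaplotype(hap$contig, loci, minFbox = m)), logical(1))
  expect_false(is.unsorted(rev(flags)))  # TRUE..TRUE then FALSE..FALSE
  expect_error(scanHaplotype(hap$contig,
                             data.frame(start = c(0, 50), end = c(100, 150),
                                        classLabel = c("III", "III"))),
               "overlap")
})
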