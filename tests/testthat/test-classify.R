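test_that("identity alignment of a word is its diagonal self-score", {
  sub <- rnaseScout:::blosum62()
  w <- "HGLWP"
  self <- sum(diag(sub[strsplit(w, "")[[1]], strsplit(w, "")[[1]]]))
  expect_equal(globalAlignScore(w, w), self)
})

test_that("small alignments match exhaustive enumeration (linear gaps)", {
  sub <- simpleSubMatrix()
  # "ACGT" vs "ACG": 3 matches + one terminal gap = 3 - 2 = 1
  expect_equal(globalAlignScore("ACGT", "ACG", matrix = sub,
                                gapOpen = 0, gapExtend = 2), 1)
  # "A" vs "AAA": 1 match + gap of length 2 = 1 - 4 = -3
  expect_equal(globalAlignScore("A", "AAA", matrix = sub,
                                gapOpen = 0, gapExtend = 2), -3)
  expect_error(globalAlignScore("", "A"), "empty")
})

test_that("NW equals exhaustive alignment enumeration on random pairs", {
  set.seed(101)
  sub <- rnaseScout:::blosum62()[AA_LETTERS, AA_LETTERS]
  for (i in 1:40) {
    a <- randomProtein(sample(1:6, 1))
    b <- randomProtein(sample(1:6, 1))
    gapOpen <- sample(c(0, 2, 5), 1); gapExt <- sample(c(0.5, 1, 2), 1)
    expect_equal(globalAlignScore(a, b, matrix = sub,
                                  gapOpen = gapOpen, gapExtend = gapExt),
                 enumAlignScore(a, b, sub, gapOpen, gapExt),
                 info = paste(a, b, gapOpen, gapExt))
  }
})

test_that("nearest reference: self-distance is zero, label recovered", {
  refs <- referencePanel()
  id <- names(refs$seqs)[refs$classes == "II"][1]
  nn <- nearestReference(refs$seqs[[id]], refs)
  expect_identical(nn$class, "II")
  expect_equal(nn$distance, 0, tolerance = 1e-9)
})

test_that("nearest reference: k = 1 equidistant tie is unclassified", {
  refs <- list(seqs = c(r1 = "HGLWPAAK", r2 = "HGLWPAAD"),
               classes = c(r1 = "I", r2 = "III"))
  # query differs from r1 and r2 by symmetric K/D swaps at the same site
  nn <- nearestReference("HGLWPAAE", refs, k = 2)
  # E is closer to D (+2) than to K (+1) under BLOSUM62 -> not a tie
  expect_identical(nn$class, "III")
  nnTie <- nearestReference("HGLWPAAA", list(
    seqs = c(r1 = "HGLWPAAK", r2 = "HGLWPAAR"),
    classes = c(r1 = "I", r2 = "III")), k = 2)
  # A vs K and A vs R score identically under BLOSUM62: a true tie
  expect_identical(nnTie$class, "unclassified")
})

test_that("shuffling an exemplar increases its distance", {
  refs <- referencePanel()
  ref1 <- refs$seqs[[1]]
  base <- nearestReference(ref1, refs)$distance
  set.seed(55)
  worse <- sum(vapply(1:20, function(i) {
    shuf <- paste(sample(strsplit(ref1, "")[[1]]), collapse = "")
    nearestReference(shuf, refs)$distance > base
  }, logical(1)))
  expect_gte(worse, 19)
})

test_that("decision ladder: pattern-exact classes and S-candidacy", {
  # eight-intron pattern is uniquely class II
  callII <- classifySequence(list(id = "a", pI = 5.2, regionsHit = 5L,
                                  cas2His = "present",
                                  intronPattern = c(3, 4, 5, 6, 7, 8, 10, 11)))
  expect_identical(callII$classLabel, "II")
  expect_identical(callII$confidence, "pattern-exact")
  expect_false(callII$sRnaseCandidate)

  # ambiguous {5} + basic pI + nn III -> class III S-candidate
  callS <- classifySequence(list(id = "b", pI = 9.2, regionsHit = 5L,
                                 cas2His = "present", intronPattern = 5L,
                                 nnClass = "III"))
  expect_identical(callS$classLabel, "III")
  expect_identical(callS$confidence, "multi-line")
  expect_true(callS$sRnaseCandidate)

  # I-D pattern with acidic pI -> class I, never a candidate
  callI <- classifySequence(list(id = "c", pI = 5.0, regionsHit = 5L,
                                 cas2His = "present",
                                 intronPattern = c(2, 5, 9)))
  expect_identical(callI$classLabel, "I")
  expect_false(callI$sRnaseCandidate)
})

test_that("candidacy needs basic pI, S-type pattern, CAS II and 3 regions", {
  base <- list(id = "x", pI = 9.0, regionsHit = 5L, cas2His = "present",
               intronPattern = 5L, nnClass = "III")
  expect_true(classifySequence(base)$sRnaseCandidate)
  expect_false(classifySequence(modifyList(base, list(pI = 7.9)))$sRnaseCandidate)
  expect_false(classifySequence(modifyList(base, list(cas2His = "absent")))$sRnaseCandidate)
  expect_false(classifySequence(modifyList(base, list(regionsHit = 2L)))$sRnaseCandidate)
  # pattern III-A {5,9} is excluded: known S-RNases lack position 9
  expect_false(classifySequence(modifyList(base, list(intronPattern = c(5L, 9L))))$sRnaseCandidate)
  # undetermined pattern (cDNA input) stays eligible
  expect_true(classifySequence(modifyList(base, list(intronPattern = NULL)))$sRnaseCandidate)
  # Prunus-style {1,5} stays eligible
  expect_true(classifySequence(modifyList(base, list(intronPattern = c(1L, 5L))))$sRnaseCandidate)
})

test_that("candidates are always class III, over random feature vectors", {
  set.seed(202)
  for (i in 1:200) {
    fv <- list(id = "r", pI = runif(1, 3, 12),
               regionsHit = sample(0:5, 1),
               cas2His = sample(c("present", "absent", "undetermined"), 1),
               intronPattern = if (runif(1) < 0.2) NULL else
                 sort(sample(1:11, sample(0:4, 1))),
               nnClass = sample(c("I", "II", "III", "unclassified"), 1))
    call <- classifySequence(fv)
    if (call$sRnaseCandidate) expect_identical(call$classLabel, "III")
  }
})

test_that("a uniquely matching pattern never overrides a correct call", {
  # multi-line III call stays III when the exact III pattern is added
  noPat <- classifySequence(list(id = "m", pI = 9.0, regionsHit = 5L,
                                 cas2His = "present", intronPattern = NULL,
                                 nnClass = "III"))
  withPat <- classifySequence(list(id = "m", pI = 9.0, regionsHit = 5L,
                                   cas2His = "present",
                                   intronPattern = c(1L, 5L),
                                   nnClass = "III"))
  expect_identical(noPat$classLabel, "III")
  expect_identical(withPat$classLabel, "III")
  expect_identical(withPat$confidence, "pattern-exact")
})

test_that("classifyFasta orchestrates the full pipeline per record", {
  panel <- makeClassPanel(nPerClass = 2, seed = 3)
  tab <- classifyFasta(panel$seqs, genes = panel$genes,
                       alignment = panel$alignment)
  expect_identical(nrow(tab), 6L)
  expect_identical(tab$class, panel$truth$class)
  expect_true(all(is.na(tab$error)))
  # protein-only input: intron evidence undetermined, call still produced
  solo <- classifyFasta(panel$seqs[1])
  expect_identical(solo$pattern, "U")
  expect_false(is.na(solo$class))
  # empty input -> empty table
  expect_identical(nrow(classifyFasta(character())), 0L)
})

test_that("nucleotide inputs are translated via their longest ORF", {
  panel <- makeClassPanel(nPerClass = 1, seed = 8)
  id <- panel$truth$id[1]
  cds <- cdsSequence(panel$genes[[id]])
  tab <- classifyFasta(setNames(cds, id))
  expect_identical(tab$class, panel$truth$class[1])
  # untranslatable nucleotide input yields an error row, run continues
  both <- classifyFasta(c(bad = "ACGTACGTACG", setNames(cds, id)))
  expect_false(is.na(both$error[1]))
  expect_true(is.na(both$error[2]))
})
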