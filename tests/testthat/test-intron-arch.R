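toyGene <- function(offsets, len = 300) {
  # a gene whose CDS has introns at the given coding offsets
  starts <- c(0L, offsets + 100L * seq_along(offsets))
  ends <- c(offsets, len) + 100L * c(0L, seq_along(offsets))
  GeneStructure("toy", "ctg", "+", starts, ends)
}

test_that("intron phase follows the coding offset modulo 3", {
  g <- toyGene(c(3L, 4L, 5L))
  sites <- intronSites(g, colmap = 0:299)
  expect_identical(sites$phase, c(0L, 1L, 2L))
  expect_identical(sites$cdsOffset, c(3L, 4L, 5L))
})

test_that("single-exon genes yield no sites; gapped rows map columns", {
  expect_identical(nrow(intronSites(toyGene(integer()))), 0L)
  g <- toyGene(3L)
  cm <- columnMap(paste0("A-TG", strrep("C", 296)))
  sites <- intronSites(g, cm)
  expect_identical(sites$column, 4L)
  shortMap <- columnMap("A-TG")
  expect_error(intronSites(toyGene(250L), shortMap), "beyond")
})

test_that("seven-nucleotide window clustering follows single linkage", {
  mk <- function(cols) data.frame(geneId = sprintf("g%d", seq_along(cols)),
                                  cdsOffset = rep(3L, length(cols)),
                                  phase = rep(0L, length(cols)),
                                  column = cols)
  one <- clusterIntronPositions(mk(c(100L, 104L, 106L)))
  expect_identical(nrow(one$positions), 1L)  # 100-104 (d4), 104-106 (d2)
  two <- clusterIntronPositions(mk(c(100L, 107L)))
  expect_identical(nrow(two$positions), 2L)  # d7 > 6 cannot share a window
  expect_identical(nrow(clusterIntronPositions(mk(integer()))$positions), 0L)
})

test_that("clustering equals brute-force transitive closure and is invariant", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(2:15, 1)
    cols <- sort(sample.int(400, n))
    sites <- data.frame(geneId = paste0("g", seq_len(n)), cdsOffset = 3L,
                        phase = 0L, column = cols)
    res <- clusterIntronPositions(sites)
    oracle <- closureClusters(cols)
    expect_identical(res$sites$positionId[order(res$sites$column)],
                     oracle[order(cols)])
    # permutation invariance and idempotence of membership
    perm <- sites[sample.int(n), ]
    res2 <- clusterIntronPositions(perm)
    expect_identical(res2$positions, res$positions)
    expect_identical(sum(res$positions$nSites), n)
  }
})

test_that("phase conflicts are flagged, never merged away", {
  sites <- data.frame(geneId = c("a", "b"), cdsOffset = c(3L, 4L),
                      phase = c(0L, 1L), column = c(100L, 102L))
  res <- clusterIntronPositions(sites)
  expect_identical(nrow(res$positions), 1L)
  expect_true(res$positions$phaseConflict)
  expect_true(is.na(res$positions$phase))
})

test_that("canonical ids map clusters to the bundled reference frame", {
  ref <- canonicalIntronTable()
  expect_identical(ref$position, 1:11)
  expect_identical(ref$phase, ref$refColumn %% 3L)  # phases consistent
  pos <- data.frame(positionId = 1:2,
                    columnMin = c(ref$refColumn[5], 1000L),
                    columnMax = c(ref$refColumn[5] + 2L, 1001L),
                    phase = 0L, phaseConflict = FALSE, nSites = 1L)
  lab <- canonicalPositionIds(pos, ref)
  expect_identical(lab$canonicalId, c(5L, 12L))
})

test_that("presence matrix marks present, absent and undetermined", {
  ref <- canonicalIntronTable()
  # gene A spans everything and has introns at canonical 2, 5, 9
  cols <- ref$refColumn[c(2, 5, 9)]
  sites <- data.frame(geneId = "A", cdsOffset = cols, phase = cols %% 3L,
                      column = cols)
  cl <- clusterIntronPositions(sites)
  cl$positions <- canonicalPositionIds(cl$positions, ref)
  spans <- list(A = c(0L, 700L), B = c(0L, 700L),
                C = c(0L, ref$refColumn[9] - 50L))
  m <- presenceMatrix(c("A", "B", "C", "D"), cl, spans)
  expect_identical(unname(m["A", ]), c("1", "1", "1"))
  expect_identical(unname(m["B", ]), c("0", "0", "0"))
  expect_identical(unname(m["C", ]), c("0", "0", "U"))  # truncated before 9
  expect_identical(unname(m["D", ]), c("U", "U", "U"))  # cDNA record
  expect_identical(colnames(m), c("2", "5", "9"))
})

test_that("pattern naming matches the canonical catalog", {
  expect_identical(assignPattern(c(2, 5, 9)), "I-D")
  expect_identical(sort(assignPattern(5)), c("I-B", "III-C"))
  expect_identical(assignPattern(c(1, 5)), "III-D")
  expect_identical(assignPattern(c(3, 4, 5, 6, 7, 8, 10, 11)), "II")
  expect_identical(assignPattern(integer()), "no-intron")
  expect_identical(assignPattern(c(1, 2, 3)), "novel")
  expect_identical(assignPattern(9), "III-B*")
  # every canonical position appears in at least one catalog entry
  cat <- patternCatalog()
  expect_setequal(sort(unique(unlist(lapply(cat, `[[`, "positions")))), 1:11)
})

test_that("generated genes round-trip through the intron pipeline exactly", {
  panel <- makeClassPanel(nPerClass = 3, seed = 77)
  cat <- patternCatalog()
  allSites <- do.call(rbind, lapply(names(panel$genes), function(id)
    intronSites(panel$genes[[id]], columnMap(panel$alignment[[id]]))))
  cl <- clusterIntronPositions(allSites)
  cl$positions <- canonicalPositionIds(cl$positions)
  expect_false(any(cl$positions$phaseConflict))
  for (i in seq_len(nrow(panel$truth))) {
    id <- panel$truth$id[i]
    mine <- cl$sites[cl$sites$geneId == id, "positionId"]
    got <- sort(cl$positions$canonicalId[match(mine, cl$positions$positionId)])
    expect_identical(got, sort(cat[[panel$truth$pattern[i]]]$positions),
                     info = id)
  }
})
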