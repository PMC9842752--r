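## Build a HaplotypeArray from labels and intergenic gaps (1 kb genes).
mkArray <- function(labels, gaps = rep(2000, max(0, length(labels) - 1)),
                    pseudo = rep(FALSE, length(labels)), id = "hap") {
  geneLen <- 1000L
  start <- integer(length(labels))
  pos <- 0L
  for (i in seq_along(labels)) {
    start[i] <- pos
    pos <- pos + geneLen + if (i <= length(gaps)) as.integer(gaps[i]) else 0L
  }
  haplotypeArray(id, data.frame(label = labels,
                                strand = rep("+", length(labels)),
                                start = start, end = start + geneLen,
                                pseudogene = pseudo))
}

test_that("copy counting handles empty arrays and pseudogene flags", {
  expect_equal(countCopies(mkArray(character(0))), 0L)
  h <- mkArray(as.character(1:17), pseudo = c(rep(FALSE, 15), TRUE, TRUE))
  expect_equal(countCopies(h, includePseudogenes = TRUE), 17L)
  expect_equal(countCopies(h, includePseudogenes = FALSE), 15L)
  expect_equal(countCopies(h, TRUE) - countCopies(h, FALSE),
               sum(lociTable(h)$pseudogene))
})

test_that("pseudogene flagging detects stops, truncation and missing ORFs", {
  ## clean CDS: ATG + 59 codons + TAA, mature length 50
  set.seed(5)
  codons <- c("GCT", "GGA", "TGC", "AAA", "CCT", "GAT")
  cds <- paste0("ATG", paste(sample(codons, 59, TRUE), collapse = ""), "TAA")
  expect_false(flagPseudogene(cds, expectedMatureLength = 50,
                              matureOffset = 10)$pseudogene)

  withStop <- paste0("ATG", paste(sample(codons, 20, TRUE), collapse = ""),
                     "TAA",
                     paste(sample(codons, 38, TRUE), collapse = ""), "TAA")
  r <- flagPseudogene(withStop, 50, matureOffset = 10)
  expect_true(r$pseudogene)
  expect_equal(r$reason, "premature stop")

  ## truncated to 60% of the expected mature peptide
  short <- paste0("ATG", paste(sample(codons, 10 + 30, TRUE), collapse = ""),
                  "TAA")
  r2 <- flagPseudogene(short, 50, matureOffset = 10)
  expect_true(r2$pseudogene)
  expect_equal(r2$reason, "truncated")

  r3 <- flagPseudogene(sub("^ATG", "CCC", cds), 50)
  expect_true(r3$pseudogene)
  expect_equal(r3$reason, "no ORF")
})

test_that("tandem units resolve singlet, duplet and quadruplet repeats", {
  ## pure singlet repeat
  u <- detectTandemUnits(mkArray(c("6", "6", "6", "6")))
  expect_equal(nrow(u), 1L)
  expect_equal(u$unit, "6")
  expect_equal(u$count, 4L)

  ## duplet repeat
  u2 <- detectTandemUnits(mkArray(c("6", "20", "6", "20")))
  expect_equal(u2$unit, "6,20")
  expect_equal(u2$count, 2L)

  ## quadruplet duplication with periodic gaps
  u4 <- detectTandemUnits(mkArray(c("8", "6", "1", "6", "8", "6", "1", "6"),
                                  gaps = rep(c(1500, 2500, 1800, 3000), 2)))
  expect_equal(u4$unit, "8,6,1,6")
  expect_equal(u4$count, 2L)

  ## no repeat structure
  expect_equal(nrow(detectTandemUnits(mkArray(c("1", "2", "3")))), 0L)

  ## inconsistent gaps break the periodicity
  u5 <- detectTandemUnits(mkArray(c("6", "6", "6"), gaps = c(1000, 9000)))
  expect_equal(sum(u5$count), 2L)
})

test_that("tandem detection matches brute-force decomposition on small arrays", {
  set.seed(29)
  for (rep in 1:150) {
    n <- sample(2:10, 1)
    labels <- as.character(sample(1:3, n, replace = TRUE))
    gaps <- sample(c(1000, 1100, 5000), max(0, n - 1), replace = TRUE)
    got <- detectTandemUnits(mkArray(labels, gaps))
    oracle <- bruteForceTandemUnits(labels, gaps)
    expect_equal(nrow(got), nrow(oracle),
                 info = paste(labels, collapse = ","))
    if (nrow(got)) {
      expect_equal(got[, c("period", "count", "startIndex", "endIndex")],
                   oracle[, c("period", "count", "startIndex", "endIndex")],
                   ignore_attr = TRUE,
                   info = paste(paste(labels, collapse = ","), "|",
                                paste(gaps, collapse = ",")))
      ## reported units never overlap
      covered <- unlist(lapply(seq_len(nrow(got)), function(i) {
        got$startIndex[i]:got$endIndex[i]
      }))
      expect_false(any(duplicated(covered)))
    }
  }
})

test_that("block-edit comparison finds minimal duplication/deletion scripts", {
  expect_equal(compareHaplotypes(c("6"), c("6", "6"))$events, 1L)
  expect_equal(compareHaplotypes(c("8", "6", "1", "6"),
                                 c("8", "6", "1", "6", "8", "6", "1", "6"))$events,
               1L)
  expect_equal(compareHaplotypes(c("a", "b"), c("a", "b"))$events, 0L)

  ## independent iterative-deepening oracle on random small pairs
  set.seed(37)
  for (rep in 1:40) {
    a <- as.character(sample(1:3, sample(1:4, 1), replace = TRUE))
    b <- as.character(sample(1:3, sample(1:4, 1), replace = TRUE))
    got <- compareHaplotypes(a, b, maxEvents = 3)$events
    oracle <- iddfsBlockEdit(a, b, maxEvents = 3)
    expect_equal(got, oracle,
                 info = paste(paste(a, collapse = ","), "->",
                              paste(b, collapse = ",")))
  }
})

test_that("tandem expansions are invertible: k duplications imply a return path of <= k deletions", {
  ## a tandem duplication is undone by deleting the copied block, so a
  ## descendant built from k duplications is at most k events from its
  ## ancestor in the reverse direction (arbitrary deletions are not
  ## invertible by duplications, so the full relation is one-sided)
  set.seed(43)
  for (rep in 1:30) {
    a <- as.character(sample(1:3, sample(2:4, 1), replace = TRUE))
    b <- a
    k <- sample(1:2, 1)
    for (e in seq_len(k)) {
      n <- length(b)
      i <- sample(n, 1)
      j <- if (i == n) n else sample(i:n, 1)
      b <- append(b, b[i:j], after = j)
    }
    fwd <- compareHaplotypes(a, b, maxEvents = k)$events
    expect_lte(fwd, k)
    back <- compareHaplotypes(b, a, maxEvents = k)$events
    expect_lte(back, fwd)
  }
})

test_that("non-B scanner finds inverted repeats and homopolymer runs", {
  hits <- scanNonBMotifs("ACGTACTTTTGTACGT", minArm = 6, maxLoop = 100)
  ir <- hits[hits$type == "invertedRepeat", ]
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$start, 0L)
  expect_equal(ir$end, 16L)
  expect_equal(ir$armLength, 6L)
  expect_equal(ir$loop, 4L)

  seqG <- paste0("AAAA", strrep("G", 10), "AAAA")
  hg <- scanNonBMotifs(seqG, minGRun = 8)
  expect_equal(hg$type, "polyG")
  expect_equal(hg$start, 4L)
  expect_equal(hg$end, 14L)

  ## short runs are not reported
  expect_equal(nrow(scanNonBMotifs(paste0("AAAA", strrep("G", 7), "AAAA"),
                                   minGRun = 8)), 0L)
})

test_that("non-B scan matches the brute-force all-pairs oracle", {
  ## the oracle scans arm lengths up to 30 bp: in uniform-random sequence
  ## the longest maximal arm is far shorter, so the comparison is complete
  for (seed in 1:2) {
    seq <- randomDna(500, seed = 400 + seed)
    got <- scanNonBMotifs(seq, minArm = 6, maxLoop = 100, minGRun = 8)
    oracle <- bruteForceNonB(seq, minArm = 6, maxLoop = 100, minGRun = 8,
                             maxArm = 30)
    expect_equal(got, oracle, info = paste("seed", seed))
  }
})

test_that("non-B hits mirror on the reverse complement", {
  for (seed in 7:10) {
    seq <- randomDna(600, seed = 500 + seed)
    n <- nchar(seq)
    fwd <- scanNonBMotifs(seq)
    rev <- scanNonBMotifs(rcomp(seq))
    mirror <- data.frame(type = fwd$type,
                         start = n - fwd$end, end = n - fwd$start,
                         armLength = fwd$armLength, loop = fwd$loop)
    mirror$type[fwd$type == "polyG"] <- "polyC"
    mirror$type[fwd$type == "polyC"] <- "polyG"
    mirror <- mirror[order(mirror$start, mirror$end, mirror$type), ]
    rownames(mirror) <- NULL
    expect_equal(rev, mirror, info = paste("seed", seed))
  }
})

test_that("breakpoint context reports signed distances within the window", {
  hits <- data.frame(type = "invertedRepeat", start = 100L, end = 150L,
                     armLength = 10L, loop = 30L)
  ## breakpoint inside the motif
  ctx <- breakpointContext(120L, hits, window = 500)
  expect_equal(ctx$distance, 0L)
  ## motif ending 356 bp to the left
  ctx2 <- breakpointContext(506L, hits, window = 500)
  expect_equal(ctx2$distance, -356L)
  ## outside the window: empty report
  ctx3 <- breakpointContext(1000L, hits, window = 500)
  expect_equal(nrow(ctx3), 0L)
  expect_error(breakpointContext(5000L, hits, window = 500,
                                 seqLength = 2000L), "bounds")
})

test_that("locus arrays round-trip through the TSV reader", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(haplotype = rep(c("H1", "H2"), c(3, 2)),
                   label = c("8", "6", "1", "6", "6"),
                   strand = "+",
                   start = c(0, 3000, 6000, 0, 3000),
                   end = c(1000, 4000, 7000, 1000, 4000),
                   pseudogene = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  arrays <- readLocusArrays(f)
  expect_setequal(names(arrays), c("H1", "H2"))
  expect_equal(countCopies(arrays$H1), 3L)
  expect_equal(countCopies(arrays$H1, includePseudogenes = FALSE), 2L)
  expect_equal(intergenicGaps(arrays$H2), 2000)
  expect_equal(haplotypeLabels(arrays$H1), c("8", "6", "1"))
})
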