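test_that("amplicon filters partition rejections by reason", {
  seqs <- c(randomDna(250, 1), randomDna(300, 2), randomDna(400, 3),
            randomDna(500, 4), randomDna(501, 5))
  f <- filterAmplicons(seqs)
  expect_equal(length(f$retained), 3L)
  expect_equal(unname(f$tally),
               c(1L, 1L, 0L, 3L))
  expect_equal(sum(f$tally), length(seqs))

  withN <- paste0(substr(randomDna(400, 6), 1, 399), "N")
  f2 <- filterAmplicons(c(seqs, withN))
  expect_equal(unname(f2$tally["ambiguous"]), 1L)
  expect_false(withN %in% f2$retained)

  f3 <- filterAmplicons(character(0))
  expect_equal(length(f3$retained), 0L)
  expect_true(all(f3$tally == 0L))
})

test_that("primer trimming allows bounded mismatches and rejects otherwise", {
  fwd <- "ACGTACGTAC"; rev <- "GGTTGGTTGG"
  insert <- randomDna(100, 7)
  amp <- paste0(fwd, insert, rcomp(rev))
  tr <- trimPrimers(amp, fwd, rev)
  expect_equal(tr$trimmed, insert)
  expect_equal(tr$reason, "ok")

  fwd1 <- fwd; substr(fwd1, 3, 3) <- "T"
  amp1 <- paste0(fwd1, insert, rcomp(rev))
  expect_equal(trimPrimers(amp1, fwd, rev, maxMismatch = 1)$reason, "ok")
  expect_equal(trimPrimers(amp1, fwd, rev, maxMismatch = 0)$reason,
               "fwd_primer_not_found")

  expect_equal(trimPrimers(insert, fwd, rev)$reason, "fwd_primer_not_found")
})

test_that("subsampling is exact-depth, seed-stable and membership-preserving", {
  pool <- replicate(20000, NA_character_)
  pool <- paste0("read", seq_len(20000))
  s <- subsampleReads(pool, depth = 14800, seed = 9)
  expect_equal(s$status, "ok")
  expect_equal(length(s$reads), 14800L)
  expect_true(all(s$reads %in% pool))
  expect_false(any(duplicated(s$reads)))
  s2 <- subsampleReads(pool, depth = 14800, seed = 9)
  expect_identical(sort(s$reads), sort(s2$reads))

  short <- subsampleReads(pool[1:10000], depth = 14800, seed = 9)
  expect_equal(short$status, "excluded")
  expect_equal(short$available, 10000L)
})

test_that("variant calling applies the abundance AND prevalence rule", {
  counts <- rbind(ind1 = c(A = 150, B = 120, C = 80),
                  ind2 = c(A = 90, B = 0, C = 70))
  expect_equal(callVariants(counts), "A")
  ## strict reading requires the threshold in multiple individuals
  counts2 <- rbind(ind1 = c(A = 150, B = 110),
                   ind2 = c(A = 120, B = 5))
  expect_equal(callVariants(counts2, strict = TRUE), "A")
  expect_equal(callVariants(counts2, strict = FALSE), c("A", "B"))

  set.seed(13)
  for (rep in 1:100) {
    ni <- sample(2:8, 1); nv <- sample(2:10, 1)
    cm <- matrix(rpois(ni * nv, 40), ni, nv,
                 dimnames = list(paste0("i", 1:ni), paste0("v", 1:nv)))
    cm[sample(length(cm), length(cm) %/% 3)] <- 0
    cm[1, ] <- sample(c(0, 120, 90), nv, replace = TRUE)
    expect_equal(callVariants(cm), bruteForceCallVariants(cm))
  }
})

test_that("sample clustering uses Spearman distance with complete linkage", {
  ab <- rbind(s1 = c(0.5, 0.3, 0.2),
              s2 = c(0.5, 0.3, 0.2),
              s3 = c(0.2, 0.3, 0.5))
  cl <- clusterSamples(ab)
  expect_equal(cl$dist["s1", "s2"], 0)
  expect_equal(cl$dist["s1", "s3"], 2)  # exactly reversed ranks
  expect_equal(diag(cl$dist), rep(0, 3), ignore_attr = TRUE)

  set.seed(19)
  ab2 <- matrix(runif(20 * 6), 20, 6,
                dimnames = list(sprintf("s%02d", 1:20), paste0("v", 1:6)))
  ab2 <- ab2 / rowSums(ab2)
  cl2 <- clusterSamples(ab2)
  ## oracle: direct rank-correlation distances
  oracle <- 1 - cor(apply(ab2, 1, rank))
  expect_equal(cl2$dist, oracle[rownames(cl2$dist), colnames(cl2$dist)],
               tolerance = 1e-12)
  expect_equal(max(abs(cl2$dist - t(cl2$dist))), 0)
  ## dendrogram exports as valid Newick with all samples
  nw <- readNewick(cl2$newick)
  expect_setequal(nw$tip.label, rownames(ab2))

  abc <- rbind(s1 = c(0.5, 0.5), s2 = c(0.9, 0.1), s3 = c(0.2, 0.8))
  expect_warning(cl3 <- clusterSamples(abc), "constant")
  expect_equal(cl3$dist["s1", "s2"], 1)
})

test_that("core haplotypes are deduced by minimal exact cover", {
  mkCounts <- function(sets, universe) {
    m <- matrix(0L, length(sets), length(universe),
                dimnames = list(paste0("ind", seq_along(sets)), universe))
    for (i in seq_along(sets)) m[i, sets[[i]]] <- 150L
    m
  }
  ## worked example: {a,b}, {a,c} are cores; {a,b,c} is heterozygous
  m <- mkCounts(list(c("a", "b"), c("a", "c"), c("a", "b", "c")),
                c("a", "b", "c"))
  res <- inferCoreHaplotypes(m)
  expect_equal(length(res$cores), 2L)
  expect_setequal(vapply(res$cores, paste, character(1), collapse = "+"),
                  c("a+b", "a+c"))
  expect_equal(res$assignments$homozygous, c(TRUE, TRUE, FALSE))

  ## all individuals identical: one core, all homozygous
  m2 <- mkCounts(rep(list(c("x", "y", "z")), 4), c("x", "y", "z"))
  res2 <- inferCoreHaplotypes(m2)
  expect_equal(length(res2$cores), 1L)
  expect_true(all(res2$assignments$homozygous))
})

test_that("simulated populations recover the known haplotype pool exactly", {
  recovered <- 0L
  for (pop in 1:50) {
    set.seed(2000 + pop)
    nh <- sample(2:6, 1)
    universe <- paste0("v", 1:12)
    ## distinct haplotypes sharing one backbone variant
    pool <- lapply(seq_len(nh), function(h) {
      unique(c("v1", sample(universe[-1], sample(2:4, 1))))
    })
    keys <- vapply(pool, function(s) paste(sort(s), collapse = "|"),
                   character(1))
    if (anyDuplicated(keys)) next
    names(pool) <- paste0("hap", seq_len(nh))
    geno <- simulateLocusPopulation(names(pool), rep(1 / nh, nh),
                                    nIndividuals = max(60, 3 * nh),
                                    seed = 3000 + pop,
                                    ensureHomozygotes = TRUE)
    counts <- matrix(0L, nrow(geno), length(universe),
                     dimnames = list(geno$individual, universe))
    for (i in seq_len(nrow(geno))) {
      vs <- union(pool[[geno$hap1[i]]], pool[[geno$hap2[i]]])
      counts[i, vs] <- 200L
    }
    res <- inferCoreHaplotypes(counts)
    got <- sort(vapply(res$cores, function(s) paste(sort(s), collapse = "|"),
                       character(1)))
    if (identical(unname(got), sort(unname(keys)))) recovered <- recovered + 1L
  }
  expect_gte(recovered, 48L)  # a couple of pools may collide and be skipped
})

test_that("variant dropout keeps recovered cores supersets of the truth", {
  okSuperset <- 0L; total <- 0L
  for (pop in 1:30) {
    set.seed(5000 + pop)
    nh <- sample(2:4, 1)
    universe <- paste0("v", 1:10)
    pool <- lapply(seq_len(nh), function(h) {
      unique(c("v1", sample(universe[-1], sample(2:4, 1))))
    })
    keys <- vapply(pool, function(s) paste(sort(s), collapse = "|"),
                   character(1))
    if (anyDuplicated(keys)) next
    names(pool) <- paste0("hap", seq_len(nh))
    geno <- simulateLocusPopulation(names(pool), rep(1 / nh, nh),
                                    nIndividuals = 60, seed = 6000 + pop,
                                    ensureHomozygotes = TRUE)
    counts <- matrix(0L, nrow(geno), length(universe),
                     dimnames = list(geno$individual, universe))
    for (i in seq_len(nrow(geno))) {
      h1 <- pool[[geno$hap1[i]]]; h2 <- pool[[geno$hap2[i]]]
      vs <- union(h1, h2)
      ## 5% dropout of the low-abundance (half-dosage) variants
      lowAbundance <- setdiff(vs, intersect(h1, h2))
      dropped <- lowAbundance[runif(length(lowAbundance)) < 0.05]
      counts[i, setdiff(vs, dropped)] <- 200L
    }
    res <- inferCoreHaplotypes(counts)
    total <- total + 1L
    gotSets <- lapply(res$cores, sort)
    superset <- all(vapply(pool, function(truth) {
      any(vapply(gotSets, function(g) all(truth %in% g), logical(1)))
    }, logical(1)))
    if (superset) okSuperset <- okSuperset + 1L
  }
  expect_gte(okSuperset / total, 0.9)
})
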