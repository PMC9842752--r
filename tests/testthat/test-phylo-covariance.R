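test_that("ancestral states match closed forms and the dense GLS oracle", {
  tr <- readNewick("(A:1,B:1);")
  expect_equal(asrBM(c(A = 0, B = 2), tr)$estimate, 1)
  tr13 <- readNewick("(A:1,B:3);")
  expect_equal(asrBM(c(A = 0, B = 4), tr13)$estimate,
               (0 / 1 + 4 / 3) / (1 + 1 / 3))

  set.seed(5)
  for (rep in 1:25) {
    tr <- simulateTree(sample(4:10, 1), seed = 400 + rep)
    x <- setNames(rnorm(length(tr$tip.label)), tr$tip.label)
    est <- asrBM(x, tr)
    oracle <- denseAsrOracle(x, tr)
    expect_equal(est$estimate, unname(oracle[as.character(est$node)]),
                 tolerance = 1e-8)
    expect_true(all(est$estimate >= min(x) - 1e-9))
    expect_true(all(est$estimate <= max(x) + 1e-9))
  }
})

test_that("ancestral states agree with an independent comparative-methods package", {
  tr <- simulateTree(12, seed = 99)
  x <- simulateTraits(tr, "BM", list(sigma2 = 1, root = 0), seed = 98)
  est <- asrBM(x, tr)
  fa <- phytools::fastAnc(tr, x)
  expect_equal(est$estimate, unname(as.numeric(fa)), tolerance = 1e-6)
})

test_that("composition reconstruction clips and renormalizes per node", {
  tr <- readNewick("(A:1,B:1);")
  comp <- new("FamilyComposition",
              tpm = matrix(c(10, 0, 0, 10), 2,
                           dimnames = list(c("A", "B"), c("NaTx", "KTx3"))),
              fraction = matrix(c(1, 0, 0, 1), 2,
                                dimnames = list(c("A", "B"),
                                                c("NaTx", "KTx3"))),
              defined = c(TRUE, TRUE))
  anc <- asrComposition(comp, tr)
  expect_equal(unname(anc[1, ]), c(0.5, 0.5))

  ## identical tip compositions propagate unchanged, rows always sum to 1
  tr2 <- simulateTree(8, seed = 3)
  fr <- matrix(rep(c(0.7, 0.2, 0.1), each = 8), 8,
               dimnames = list(tr2$tip.label, c("NaTx", "KTx3", "NEP3")))
  comp2 <- new("FamilyComposition", tpm = fr * 100, fraction = fr,
               defined = rep(TRUE, 8))
  anc2 <- asrComposition(comp2, tr2)
  expect_equal(unname(anc2),
               matrix(rep(c(0.7, 0.2, 0.1), each = nrow(anc2)), nrow(anc2)),
               tolerance = 1e-9)
  expect_equal(rowSums(anc2), setNames(rep(1, nrow(anc2)), rownames(anc2)))
})

test_that("Pagel's lambda separates signal from noise", {
  ## identity: lambda = 1 likelihood equals the BM likelihood at the same
  ## profiled parameters
  tr <- simulateTree(32, seed = 21)
  x <- simulateTraits(tr, "BM", list(sigma2 = 1, root = 0), seed = 22)
  pl <- pagelLambda(x, tr)
  fb <- fitBM(x, tr)
  expect_equal(pl$logLik1, fb@logLik, tolerance = 1e-8)

  ## BM data: strong signal; iid data: no signal (reduced replicate counts,
  ## same conditions as the generator defaults)
  lamBM <- vapply(1:100, function(rep) {
    tr <- simulateTree(64, seed = 9000 + rep)
    x <- simulateTraits(tr, "BM", list(sigma2 = 1, root = 0),
                        seed = 9100 + rep)
    pagelLambda(x, tr)$lambda
  }, numeric(1))
  expect_gte(median(lamBM), 0.8)

  lamIID <- vapply(1:100, function(rep) {
    tr <- simulateTree(64, seed = 9300 + rep)
    x <- setNames(withr::with_seed(9400 + rep,
                                   rnorm(64)), tr$tip.label)
    pagelLambda(x, tr)$lambda
  }, numeric(1))
  ## the per-replicate probability of lambda-hat <= 0.1 is ~0.93 for iid
  ## data at this size, so the count is asserted at a threshold with
  ## negligible false-alarm probability, plus the sharper median property
  expect_gte(sum(lamIID <= 0.1), 85)
  expect_equal(median(lamIID), 0)
})

test_that("lambda estimate agrees with an independent implementation", {
  tr <- simulateTree(48, seed = 55)
  x <- simulateTraits(tr, "BM", list(sigma2 = 1, root = 0), seed = 56)
  pl <- pagelLambda(x, tr)
  ps <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(pl$lambda, ps$lambda, tolerance = 1e-3)
  expect_equal(pl$logLik, ps$logL, tolerance = 1e-4)
})

test_that("phylogenetic covariance reduces to the sample covariance on a star", {
  star <- readNewick("(A:1,B:1,C:1,D:1,E:1,F:1);")
  set.seed(31)
  X <- matrix(rnorm(6 * 2), 6, 2,
              dimnames = list(star$tip.label, c("u", "v")))
  res <- phyloCovariance(X, star, B = 50, seed = 1)
  expect_equal(covMatrix(res), cov(X), tolerance = 1e-9)
  expect_equal(rootMean(res), colMeans(X), tolerance = 1e-9)
})

test_that("phylogenetic covariance matches the dense GLS oracle on a worked tree", {
  tr <- readNewick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  set.seed(41)
  X <- matrix(rnorm(4 * 2), 4, 2,
              dimnames = list(tr$tip.label, c("u", "v")))
  res <- phyloCovariance(X, tr, B = 50, seed = 1)
  C <- bruteForceVcv(tr)
  iC <- solve(C)
  one <- rep(1, 4)
  a <- drop(solve(t(one) %*% iC %*% one) %*% t(one) %*% iC %*% X)
  Rhat <- t(X - one %*% t(a)) %*% iC %*% (X - one %*% t(a)) / 3
  expect_equal(covMatrix(res), Rhat, tolerance = 1e-9)
})

test_that("duplicated trait columns are flagged significant with correlation 1", {
  tr <- simulateTree(16, seed = 61)
  x <- simulateTraits(tr, "BM", list(sigma2 = 1, root = 0), seed = 62)
  X <- cbind(u = x, v = x, w = simulateTraits(tr, "BM",
                                              list(sigma2 = 1, root = 0),
                                              seed = 63))
  expect_warning(res <- phyloCovariance(X, tr, B = 100, seed = 2),
                 "rank-deficient")
  R <- covMatrix(res)
  expect_equal(R["u", "v"] / sqrt(R["u", "u"] * R["v", "v"]), 1,
               tolerance = 1e-9)
  expect_true(significantPairs(res)["u", "v"])
})

test_that("phylomorphospace PCA decomposes the evolutionary covariance", {
  ## variance fractions read off a diagonal covariance
  res <- new("PhyloCovarianceResult",
             cov = diag(c(4, 1)), rootMean = c(0, 0),
             lower = diag(2) * 0, upper = diag(2),
             significant = matrix(FALSE, 2, 2), B = 0L, seed = 0L)
  tr <- simulateTree(8, seed = 71)
  X <- cbind(a = simulateTraits(tr, "BM", list(sigma2 = 1, root = 0),
                                seed = 72),
             b = simulateTraits(tr, "BM", list(sigma2 = 1, root = 0),
                                seed = 73))
  dimnames(res@cov) <- list(colnames(X), colnames(X))
  names(res@rootMean) <- colnames(X)
  pca <- phylomorphospacePCA(res, X, tr)
  expect_equal(pca$varianceFractions, c(0.8, 0.2))
  expect_equal(t(pca$loadings) %*% pca$loadings, diag(2),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(nrow(pca$ancestralScores), tr$Nnode)

  ## star tree: scores equal centered-data PCA scores from a generic oracle
  star <- readNewick("(A:1,B:1,C:1,D:1,E:1,F:1,G:1);")
  set.seed(81)
  Xs <- matrix(rnorm(7 * 3), 7, 3,
               dimnames = list(star$tip.label, c("u", "v", "w")))
  ress <- phyloCovariance(Xs, star, B = 20, seed = 3)
  pcas <- phylomorphospacePCA(ress, Xs, star)
  pr <- prcomp(Xs, center = TRUE, scale. = FALSE)
  for (k in 1:3) {
    expect_equal(abs(cor(pcas$scores[, k], pr$x[, k])), 1,
                 tolerance = 1e-9)
  }
})
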