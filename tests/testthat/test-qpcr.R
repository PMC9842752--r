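mkRecords <- function(cqT, cqC, individual = "ind1", plate = "p1",
                      population = "pop1") {
  data.frame(individual = individual, population = population,
             plate = plate, replicate = seq_along(cqT),
             cq_target = cqT, cq_control = cqC)
}

test_that("triplicate filtering keeps, drops one, or drops all as required", {
  ## within tolerance: all kept
  r <- filterTriplicates(mkRecords(c(20.0, 20.1, 20.15), rep(18, 3)))
  expect_equal(nrow(r$retained), 3L)
  expect_equal(nrow(r$dropLog), 0L)

  ## one outlier: that reaction dropped, pair kept
  r <- filterTriplicates(mkRecords(c(20.0, 20.1, 20.5), rep(18, 3)))
  expect_equal(nrow(r$retained), 2L)
  expect_equal(r$dropLog$replicate, 3L)

  ## no single removal suffices: whole triplicate dropped, individual out
  r <- filterTriplicates(mkRecords(c(20.0, 20.4, 20.8), rep(18, 3)))
  expect_equal(nrow(r$retained), 0L)
  expect_equal(nrow(r$excluded), 1L)

  ## a reaction bad in the control gene is dropped for both genes
  r <- filterTriplicates(mkRecords(rep(20, 3), c(18.0, 18.05, 18.6)))
  expect_equal(nrow(r$retained), 2L)
  expect_equal(r$dropLog$replicate, 3L)

  ## retained groups never violate the tolerance
  set.seed(3)
  for (rep in 1:200) {
    cqT <- 20 + rnorm(3, 0, 0.2)
    cqC <- 18 + rnorm(3, 0, 0.2)
    r <- filterTriplicates(mkRecords(cqT, cqC))
    if (nrow(r$retained) >= 2) {
      expect_lte(max(r$retained$cq_target) - min(r$retained$cq_target), 0.2)
      expect_lte(max(r$retained$cq_control) - min(r$retained$cq_control),
                 0.2)
    }
    ## per-gene agreement with the brute-force single-gene rule when the
    ## other gene is clean
    rT <- filterTriplicates(mkRecords(cqT, rep(18, 3)))
    keepOracle <- bruteForceTriplicateKeep(cqT)
    expect_equal(sort(rT$retained$replicate), sort(keepOracle))
  }
})

test_that("ddCt estimator follows the closed form", {
  ## build records: calibrator dCt 5; test dCt 5, 4, 2
  rec <- rbind(
    mkRecords(rep(25, 3), rep(20, 3), individual = "cal",
              population = "reference"),
    mkRecords(rep(25, 3), rep(20, 3), individual = "same"),
    mkRecords(rep(24, 3), rep(20, 3), individual = "double"),
    mkRecords(rep(22, 3), rep(20, 3), individual = "oct")
  )
  est <- estimateCopyNumber(rec, calibrator = "cal", calibratorCopies = 1)
  cn <- setNames(est$copyNumber, est$individual)
  expect_equal(cn[["same"]], 1)
  expect_equal(cn[["double"]], 2)
  expect_equal(cn[["oct"]], 8)
  ## ddCt ~ -4.585 -> ~24 copies (upper end of the observed range)
  rec2 <- rbind(mkRecords(rep(25, 3), rep(20, 3), individual = "cal"),
                mkRecords(rep(25 - 4.585, 3), rep(20, 3),
                          individual = "high"))
  est2 <- estimateCopyNumber(rec2, "cal")
  expect_equal(est2$copyNumber[est2$individual == "high"], 2^4.585,
               tolerance = 1e-9)
  expect_equal(round(est2$copyNumber[est2$individual == "high"]), 24)

  expect_error(estimateCopyNumber(rec, calibrator = "nope"), "missing")

  ## invariant: copy number = calibratorCopies * 2^(-ddCt) exactly
  expect_equal(est$copyNumber,
               1 * 2^(-est$deltaDeltaCt), tolerance = 1e-12)

  ## monotonicity: raising target Cq never raises the estimate
  base <- rbind(mkRecords(rep(25, 3), rep(20, 3), individual = "cal"),
                mkRecords(rep(24, 3), rep(20, 3), individual = "x"))
  cn1 <- estimateCopyNumber(base, "cal")
  up <- base
  up$cq_target[up$individual == "x"] <- 24.7
  cn2 <- estimateCopyNumber(up, "cal")
  expect_lt(cn2$copyNumber[cn2$individual == "x"],
            cn1$copyNumber[cn1$individual == "x"])
})

test_that("assay efficiency follows the dilution-slope closed form", {
  mass <- rep(c(0.1, 1, 10, 100), each = 3)
  mkCq <- function(slope) 30 + slope * log10(mass)
  f <- fitEfficiency(mass, mkCq(-3.3219), gene = "target")
  expect_equal(f@efficiency, 1, tolerance = 1e-4)
  expect_true(f@accepted)

  f2 <- fitEfficiency(mass, mkCq(-3.6))
  expect_equal(f2@efficiency, 10^(1 / 3.6) - 1, tolerance = 1e-9)
  expect_equal(round(f2@efficiency, 4), 0.8957)
  expect_false(f2@accepted)

  f3 <- fitEfficiency(mass, mkCq(-3.1))
  expect_equal(round(f3@efficiency, 3), 1.102)
  expect_false(f3@accepted)
  f4 <- fitEfficiency(mass, mkCq(-3.104))
  expect_true(f4@accepted)

  expect_error(fitEfficiency(c(1, 1, 10), c(25, 25, 22)), "3 distinct")
})

test_that("population comparison: type II ANOVA, Tukey and letters", {
  set.seed(11)
  est <- data.frame(
    individual = sprintf("i%02d", 1:30),
    population = rep(c("ME", "NH", "NC"), each = 10),
    plate = rep(c("p1", "p2"), 15),
    copyNumber = c(rnorm(10, 11, 1), rnorm(10, 11.2, 1), rnorm(10, 20, 1))
  )
  res <- populationAnova(est)
  expect_true("population" %in% rownames(res$anova))
  expect_lt(res$anova["population", "Pr(>F)"], 1e-6)
  ## NC differs from both; ME and NH share a letter
  expect_equal(res$letters[["ME"]], res$letters[["NH"]])
  expect_false(res$letters[["NC"]] == res$letters[["ME"]])

  ## balanced two-group design: F equals the squared pooled t statistic
  est2 <- data.frame(individual = sprintf("i%02d", 1:20),
                     population = rep(c("A", "B"), each = 10),
                     plate = "p1",
                     copyNumber = c(rnorm(10, 10, 1), rnorm(10, 12, 1)))
  res2 <- populationAnova(est2)
  tt <- t.test(copyNumber ~ population, data = est2, var.equal = TRUE)
  expect_equal(res2$anova["population", "F value"],
               unname(tt$statistic)^2, tolerance = 1e-9)

  ## identical group means: one shared letter
  est3 <- est2
  est3$copyNumber <- rep(c(10, 10.1, 9.9, 10.05), 5)
  res3 <- populationAnova(est3)
  expect_equal(res3$letters[["A"]], res3$letters[["B"]])

  ## type II equals type I on a balanced design (projection oracle)
  est4 <- data.frame(individual = sprintf("i%02d", 1:24),
                     population = rep(c("A", "B"), each = 12),
                     plate = rep(rep(c("p1", "p2"), each = 6), 2),
                     copyNumber = rnorm(24, 10, 2))
  res4 <- populationAnova(est4)
  a1 <- anova(aov(copyNumber ~ population * plate, data = est4))
  for (term in c("population", "plate")) {
    expect_equal(res4$anova[term, "Sum Sq"], a1[term, "Sum Sq"],
                 tolerance = 1e-9)
  }

  ## a population with < 2 individuals is excluded with a warning
  est5 <- rbind(est2, data.frame(individual = "solo", population = "C",
                                 plate = "p1", copyNumber = 15))
  expect_warning(populationAnova(est5), "excluded")
})

test_that("simulated plates round-trip through the estimator", {
  ## noise-free closed loop at the calibrator definition
  plate <- simulateQpcrPlate(c(s1 = 1), calibratorCopies = 1, noiseSd = 0,
                             seed = 5)
  est <- estimateCopyNumber(filterTriplicates(plate)$retained, "calibrator")
  expect_equal(est$copyNumber[est$individual == "s1"], 1)

  ## copies 16 vs calibrator 1: target Cq lower by 4 cycles
  plate16 <- simulateQpcrPlate(c(s1 = 16), noiseSd = 0, seed = 5)
  expect_equal(mean(plate16$cq_target[plate16$individual == "calibrator"]) -
                 mean(plate16$cq_target[plate16$individual == "s1"]), 4)

  ## recovery: true copies 8..24, noise sd 0.05, >= 95% exact after rounding
  trueCopies <- setNames(sample(8:24, 1000, replace = TRUE),
                         sprintf("i%04d", 1:1000))
  plate2 <- simulateQpcrPlate(trueCopies, noiseSd = 0.05, seed = 6)
  keep <- filterTriplicates(plate2)$retained
  est2 <- estimateCopyNumber(keep, "calibrator")
  est2 <- est2[est2$individual != "calibrator", ]
  hit <- round(est2$copyNumber) == trueCopies[est2$individual]
  expect_gte(mean(hit), 0.95)
})
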