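## Synthetic-data generators. Every analysis input the package consumes can
## be produced here, with the statistical structure the analyses assume.
## Trait simulation runs recursively along branches — deliberately a
## different code path from the pruning likelihoods, so recovery tests are
## not circular.

## Number of lineages of a pure-birth process at time t, starting from 1.
.yuleLineagesAt <- function(birthRate, t) {
  k <- 1L; elapsed <- 0
  repeat {
    elapsed <- elapsed + rexp(1L, rate = k * birthRate)
    if (elapsed > t) return(k)
    k <- k + 1L
  }
}

#' Simulate a pure-birth (Yule) tree scaled to height 1
#'
#' Forward construction: waiting time from k to k + 1 lineages is
#' exponential with rate `k * birthRate`, the splitting lineage is chosen
#' uniformly, and the present is set one (memoryless) waiting time after
#' the n-th split. The tree is then rescaled to height 1, so it is
#' ultrametric by construction.
#'
#' @param nTips number of tips, >= 2.
#' @param birthRate speciation rate (1/time), default 1.
#' @param seed RNG seed.
#' @return an ultrametric `ape::phylo` with tips `t1..tn`.
#' @export
simulateTree <- function(nTips, birthRate = 1, seed = 1L) {
  stopifnot(nTips >= 2)
  withSeed(seed, {
    ## active lineages: id, birth time; splits recorded as children
    birth <- c(0)          # birth time per node id
    children <- list(NULL) # children ids per node id
    active <- 1L
    now <- 0
    nextId <- 2L
    while (length(active) < nTips) {
      k <- length(active)
      now <- now + rexp(1L, rate = k * birthRate)
      splitter <- active[sample.int(k, 1L)]
      ids <- c(nextId, nextId + 1L)
      nextId <- nextId + 2L
      birth[ids] <- now
      children[ids] <- list(NULL)
      children[[splitter]] <- ids
      active <- c(setdiff(active, splitter), ids)
    }
    present <- now + rexp(1L, rate = nTips * birthRate)
    tipCounter <- 0L
    newickOf <- function(id) {
      endTime <- if (is.null(children[[id]])) present
                 else birth[children[[id]][1]]
      len <- endTime - birth[id]
      if (is.null(children[[id]])) {
        tipCounter <<- tipCounter + 1L
        sprintf("t%d:%.10f", tipCounter, len)
      } else {
        kids <- children[[id]]
        sprintf("(%s,%s):%.10f", newickOf(kids[1]), newickOf(kids[2]), len)
      }
    }
    kids <- children[[1L]]
    nwk <- sprintf("(%s,%s);", newickOf(kids[1]), newickOf(kids[2]))
    tr <- ape::read.tree(text = nwk)
    tr$edge.length <- tr$edge.length / treeHeight(tr)
    tr
  })
}

#' Simulate a continuous trait along a tree
#'
#' Recursive simulation along branches. BM increments are `N(0, sigma2 t)`;
#' OU uses the exact transition
#' `x' = theta + (x - theta) e^(-alpha t) + N(0, sigma2 / (2 alpha) (1 - e^(-2 alpha t)))`;
#' EB is time-rescaled BM with increment variance
#' `sigma2 (e^(r tau1) - e^(r tau0)) / r` over node depths `tau0 < tau1`;
#' JN adds a Poisson(`lambdaJ t`) number of `N(0, delta2)` jumps to the BM
#' increment.
#'
#' @param tree `ape::phylo`.
#' @param model one of "BM", "OU", "EB", "JN".
#' @param params named list/vector: `sigma2` and `root` always; `alpha`,
#'   `theta` for OU; `r` for EB; `lambdaJ`, `delta2` for JN.
#' @param seed RNG seed.
#' @return named numeric tip vector.
#' @export
simulateTraits <- function(tree, model = c("BM", "OU", "EB", "JN"),
                           params, seed = 1L) {
  model <- match.arg(model)
  p <- as.list(params)
  withSeed(seed, {
    tr <- stats::reorder(tree, "cladewise")
    nTip <- length(tr$tip.label)
    depth <- ape::node.depth.edgelength(tr)
    root <- nTip + 1L
    state <- numeric(nTip + tr$Nnode)
    state[root] <- if (model == "OU") p$theta else p$root
    for (e in seq_len(nrow(tr$edge))) {  # cladewise: parents before children
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      t <- tr$edge.length[e]
      x <- state[par]
      state[ch] <- switch(model,
        BM = x + rnorm(1, 0, sqrt(p$sigma2 * t)),
        OU = p$theta + (x - p$theta) * exp(-p$alpha * t) +
          rnorm(1, 0, sqrt(p$sigma2 / (2 * p$alpha) *
                             (1 - exp(-2 * p$alpha * t)))),
        EB = {
          v <- if (abs(p$r) < 1e-12) p$sigma2 * t
               else p$sigma2 * (exp(p$r * depth[ch]) - exp(p$r * depth[par])) /
                 p$r
          x + rnorm(1, 0, sqrt(v))
        },
        JN = {
          nJumps <- rpois(1, p$lambdaJ * t)
          x + rnorm(1, 0, sqrt(p$sigma2 * t)) +
            (if (nJumps > 0) sum(rnorm(nJumps, 0, sqrt(p$delta2))) else 0)
        })
    }
    setNames(state[seq_len(nTip)], tr$tip.label)
  })
}

#' Simulate correlated traits under multivariate BM
#'
#' Brownian increments along each branch are multivariate normal with
#' covariance `R * t`.
#'
#' @param tree `ape::phylo`.
#' @param R trait covariance matrix (p x p).
#' @param root length-p root mean.
#' @param seed RNG seed.
#' @return tips x traits matrix.
#' @export
simulateMultivariateBM <- function(tree, R, root = rep(0, nrow(R)),
                                   seed = 1L) {
  L <- t(chol(R))
  p <- nrow(R)
  withSeed(seed, {
    tr <- stats::reorder(tree, "cladewise")
    nTip <- length(tr$tip.label)
    state <- matrix(0, nTip + tr$Nnode, p)
    state[nTip + 1L, ] <- root
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      t <- tr$edge.length[e]
      state[ch, ] <- state[par, ] + drop(L %*% rnorm(p)) * sqrt(t)
    }
    out <- state[seq_len(nTip), , drop = FALSE]
    rownames(out) <- tr$tip.label
    colnames(out) <- colnames(R)
    out
  })
}

#' Simulate a diploid population from a haplotype pool
#'
#' Hardy-Weinberg draws of haplotype pairs. With
#' `ensureHomozygotes = TRUE` (requires `nIndividuals >= 3 * pool size`)
#' the population is rejection-resampled until every haplotype has at
#' least one homozygote.
#'
#' @param haplotypes character vector of haplotype identifiers.
#' @param freqs population frequencies (summing to 1).
#' @param nIndividuals population size.
#' @param seed RNG seed.
#' @param ensureHomozygotes guarantee one homozygote per haplotype.
#' @return data.frame with `individual`, `hap1`, `hap2`.
#' @export
simulateLocusPopulation <- function(haplotypes, freqs, nIndividuals,
                                    seed = 1L, ensureHomozygotes = FALSE) {
  stopifnot(abs(sum(freqs) - 1) < 1e-9,
            length(freqs) == length(haplotypes))
  if (ensureHomozygotes && nIndividuals < 3 * length(haplotypes)) {
    stop("ensureHomozygotes needs nIndividuals >= 3 * pool size",
         call. = FALSE)
  }
  withSeed(seed, {
    draw <- function() {
      h1 <- sample(haplotypes, nIndividuals, replace = TRUE, prob = freqs)
      h2 <- sample(haplotypes, nIndividuals, replace = TRUE, prob = freqs)
      data.frame(individual = sprintf("ind%03d", seq_len(nIndividuals)),
                 hap1 = h1, hap2 = h2)
    }
    g <- draw()
    if (ensureHomozygotes) {
      tries <- 0L
      while (!all(haplotypes %in% g$hap1[g$hap1 == g$hap2])) {
        g <- draw()
        tries <- tries + 1L
        if (tries > 10000L) stop("could not satisfy homozygote guarantee")
      }
    }
    g
  })
}

## Apply iid per-base substitution errors to a vector of reads.
.addReadErrors <- function(reads, errorRate) {
  if (errorRate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    ch <- strsplit(r, "")[[1]]
    hit <- runif(length(ch)) < errorRate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(bases, b), 1L)
      }, character(1))
    }
    paste0(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate amplicon reads for one diploid individual
#'
#' Reads are drawn from the union of both haplotypes' variant copies in
#' proportion to copy number; per-base substitution errors at `errorRate`
#' create low-count artifact sequences.
#'
#' @param genotype length-2 character vector of haplotype identifiers.
#' @param haplotypeVariants named list: per haplotype, a character vector of
#'   variant labels with one entry per (amplifiable) gene copy.
#' @param variantSequences named character vector of variant sequences.
#' @param depth number of reads.
#' @param errorRate per-base substitution probability.
#' @param seed RNG seed.
#' @return character vector of reads.
#' @export
simulateAmpliconReads <- function(genotype, haplotypeVariants,
                                  variantSequences, depth,
                                  errorRate = 0, seed = 1L) {
  copies <- c(haplotypeVariants[[genotype[1]]],
              haplotypeVariants[[genotype[2]]])
  if (length(copies) == 0L) return(character(0))
  missing <- setdiff(unique(copies), names(variantSequences))
  if (length(missing)) {
    stop("no sequence for variant(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  withSeed(seed, {
    lab <- sample(copies, depth, replace = TRUE)
    .addReadErrors(unname(variantSequences[lab]), errorRate)
  })
}

#' Simulate a multiplex qPCR plate
#'
#' Control-gene Cq is `c0 + eps`; target Cq is
#' `c0 - log2(copies / calibratorCopies) + baseline + eps`, with one
#' `N(0, noiseSd^2)` draw per reaction, emitted in triplicate. Because the
#' assays are multiplexed in the same well, the reaction-level noise `eps`
#' is shared between the two genes (it cancels in dCt); `geneNoiseSd` adds
#' an optional independent per-gene component on top. The calibrator
#' itself appears as individual `"calibrator"`. Zero-copy individuals get
#' missing target Cq (no amplification).
#'
#' @param trueCopies named numeric vector of diploid copy numbers.
#' @param calibratorCopies calibrator copy number, default 1.
#' @param noiseSd reaction-level (well) Cq noise standard deviation
#'   (cycles), shared by both genes within a reaction.
#' @param geneNoiseSd independent per-gene Cq noise (cycles), default 0.
#' @param seed RNG seed.
#' @param populations optional named vector mapping individuals to
#'   populations (default "pop1").
#' @param plate plate label, default "plate1".
#' @param c0 control-gene baseline Cq, default 20.
#' @param baseline target-vs-control offset for the calibrator, default 5.
#' @return data.frame of reactions: `individual`, `population`, `plate`,
#'   `replicate`, `cq_target`, `cq_control`.
#' @export
simulateQpcrPlate <- function(trueCopies, calibratorCopies = 1,
                              noiseSd = 0.05, seed = 1L,
                              populations = NULL, plate = "plate1",
                              c0 = 20, baseline = 5, geneNoiseSd = 0) {
  inds <- c(names(trueCopies), "calibrator")
  copies <- c(trueCopies, calibrator = calibratorCopies)
  if (is.null(populations)) {
    populations <- setNames(rep("pop1", length(trueCopies)),
                            names(trueCopies))
  }
  pops <- c(populations, calibrator = "reference")
  withSeed(seed, {
    rows <- lapply(inds, function(id) {
      cc <- copies[[id]]
      eps <- rnorm(3, 0, noiseSd)  # shared well-level noise
      cqc <- c0 + eps + rnorm(3, 0, geneNoiseSd)
      cqt <- if (cc > 0) {
        c0 - log2(cc / calibratorCopies) + baseline + eps +
          rnorm(3, 0, geneNoiseSd)
      } else rep(NA_real_, 3)
      data.frame(individual = id, population = pops[[id]], plate = plate,
                 replicate = 1:3, cq_target = cqt, cq_control = cqc)
    })
    do.call(rbind, rows)
  })
}

#' Simulate read pairs from a cluster of near-identical gene copies
#'
#' Pairs are drawn from the variant sequences in proportion to their
#' relative expression; each pair covers a uniformly placed insert of
#' length `insertLen`, with mate 1 from the forward strand 5' end and
#' mate 2 the reverse complement of the insert 3' end.
#'
#' @param variantSeqs named character vector of variant sequences (equal
#'   lengths >= `insertLen`).
#' @param expression relative expression weights (normalized internally).
#' @param nPairs number of pairs.
#' @param readLen mate length.
#' @param insertLen insert length, `readLen <= insertLen <=` variant
#'   length.
#' @param errorRate per-base substitution probability.
#' @param seed RNG seed.
#' @return data.frame with `variant`, `read1`, `read2`.
#' @export
simulateClusterReadPairs <- function(variantSeqs, expression, nPairs,
                                     readLen, insertLen, errorRate = 0,
                                     seed = 1L) {
  stopifnot(length(variantSeqs) == length(expression),
            insertLen >= readLen,
            insertLen <= min(nchar(variantSeqs)))
  w <- expression / sum(expression)
  withSeed(seed, {
    idx <- sample.int(length(variantSeqs), nPairs, replace = TRUE, prob = w)
    rows <- lapply(idx, function(i) {
      s <- variantSeqs[[i]]
      maxStart <- nchar(s) - insertLen
      st <- if (maxStart > 0) sample.int(maxStart + 1L, 1L) else 1L
      insert <- substr(s, st, st + insertLen - 1L)
      r1 <- substr(insert, 1L, readLen)
      r2 <- revComp(substr(insert, insertLen - readLen + 1L, insertLen))
      data.frame(variant = names(variantSeqs)[i], read1 = r1, read2 = r2)
    })
    out <- do.call(rbind, rows)
    out$read1 <- .addReadErrors(out$read1, errorRate)
    out$read2 <- .addReadErrors(out$read2, errorRate)
    out
  })
}

#' Write read pairs as interleaved FASTQ text
#'
#' Plain-text writer with constant quality, byte-identical for identical
#' input.
#'
#' @param pairs data.frame from [simulateClusterReadPairs()].
#' @param file output path.
#' @param qualChar quality character, default "I".
#' @return `file`, invisibly.
#' @export
writePairsFastq <- function(pairs, file, qualChar = "I") {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(pairs))) {
    for (mate in 1:2) {
      r <- pairs[[paste0("read", mate)]][i]
      writeLines(c(sprintf("@pair%d/%d", i, mate), r, "+",
                   strrep(qualChar, nchar(r))), con)
    }
  }
  invisible(file)
}

#' Random DNA sequence helper
#'
#' @param n length in bp.
#' @param seed RNG seed.
#' @return character sequence.
#' @export
randomDna <- function(n, seed = 1L) {
  withSeed(seed, paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""))
}
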