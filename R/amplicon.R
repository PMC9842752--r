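## Amplicon haplotyping: QC filters, primer trimming, seeded subsampling,
## variant calling by the abundance/prevalence rule, Spearman-distance
## sample clustering, and core-haplotype deduction from homozygous
## individuals by exact search.

#' Filter amplicons by length and ambiguity
#'
#' Keeps sequences whose length lies in `[minLen, maxLen]` (inclusive) and
#' that contain only A/C/G/T. Each rejected sequence is tallied under
#' exactly one reason (length checked first, then ambiguity), so the
#' tallies partition the input.
#'
#' @param seqs character vector (or `DNAStringSet`) of joined amplicons.
#' @param minLen,maxLen inclusive bp bounds, defaults 300 and 500.
#' @return list with `retained` (character vector) and `tally` (named
#'   integer: `tooShort`, `tooLong`, `ambiguous`, `retained`).
#' @export
filterAmplicons <- function(seqs, minLen = 300L, maxLen = 500L) {
  seqs <- as.character(seqs)
  len <- nchar(seqs)
  short <- len < minLen
  long <- len > maxLen
  amb <- !short & !long & grepl("[^ACGT]", seqs)
  keep <- !short & !long & !amb
  list(retained = seqs[keep],
       tally = c(tooShort = sum(short), tooLong = sum(long),
                 ambiguous = sum(amb), retained = sum(keep)))
}

## Hamming distance of equal-length strings.
.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Trim amplicon primers
#'
#' The forward primer must match the 5' end and the reverse complement of
#' the reverse primer the 3' end, each with at most `maxMismatch`
#' substitutions; both are removed. Sequences where either primer is not
#' found are rejected with a reason.
#'
#' @param seqs character vector of amplicons.
#' @param fwdPrimer,revPrimer primer sequences (5'->3' on their own
#'   strands), shorter than the amplicons.
#' @param maxMismatch substitutions allowed per primer, default 1.
#' @return list with `trimmed` (character, rejected entries `NA`) and
#'   `reason` (character: `"ok"`, `"fwd_primer_not_found"`,
#'   `"rev_primer_not_found"`).
#' @export
trimPrimers <- function(seqs, fwdPrimer, revPrimer, maxMismatch = 1L) {
  seqs <- as.character(seqs)
  fwd <- toupper(fwdPrimer)
  rcRev <- revComp(toupper(revPrimer))
  nf <- nchar(fwd); nr <- nchar(rcRev)
  trimmed <- rep(NA_character_, length(seqs))
  reason <- character(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    if (nchar(s) <= nf + nr) { reason[i] <- "fwd_primer_not_found"; next }
    if (.hamming(substr(s, 1L, nf), fwd) > maxMismatch) {
      reason[i] <- "fwd_primer_not_found"; next
    }
    if (.hamming(substr(s, nchar(s) - nr + 1L, nchar(s)), rcRev) >
        maxMismatch) {
      reason[i] <- "rev_primer_not_found"; next
    }
    trimmed[i] <- substr(s, nf + 1L, nchar(s) - nr)
    reason[i] <- "ok"
  }
  list(trimmed = trimmed, reason = reason)
}

#' Subsample reads to a fixed depth
#'
#' Uniform sampling without replacement to exactly `depth` reads. Samples
#' with fewer reads than `depth` are excluded (an explicit exclusion
#' record), mirroring removal of under-sequenced samples.
#'
#' @param seqs character vector of reads.
#' @param depth target depth, default 14800.
#' @param seed RNG seed.
#' @return list with `status` (`"ok"` or `"excluded"`), `reads` (character,
#'   empty when excluded) and `available` (input size).
#' @export
subsampleReads <- function(seqs, depth = 14800L, seed = 1L) {
  seqs <- as.character(seqs)
  if (length(seqs) < depth) {
    return(list(status = "excluded", reads = character(0),
                available = length(seqs)))
  }
  reads <- withSeed(seed, seqs[sample.int(length(seqs), depth)])
  list(status = "ok", reads = reads, available = length(seqs))
}

#' Call variants by the abundance/prevalence rule
#'
#' A sequence is a variant iff its post-subsampling count reaches
#' `minAbundance` in at least one individual AND it occurs (count of at
#' least 1) in at least `minIndividuals` individuals. The alternative
#' reading — count reaching `minAbundance` in at least `minIndividuals`
#' individuals — is available via `strict = TRUE`.
#'
#' @param counts integer matrix, individuals x sequences.
#' @param minAbundance default 100.
#' @param minIndividuals default 2.
#' @param strict require the abundance threshold in every counted
#'   individual (default `FALSE`).
#' @return character vector of variant (column) names.
#' @export
callVariants <- function(counts, minAbundance = 100L, minIndividuals = 2L,
                         strict = FALSE) {
  counts <- as.matrix(counts)
  if (strict) {
    ok <- colSums(counts >= minAbundance) >= minIndividuals
  } else {
    ok <- (apply(counts, 2L, max) >= minAbundance) &
      (colSums(counts >= 1L) >= minIndividuals)
  }
  colnames(counts)[ok]
}

#' Genotype profiles from a count matrix
#'
#' Restricts a count matrix to called variants and adds per-individual
#' relative abundances.
#'
#' @param counts integer matrix, individuals x sequences.
#' @param variants variant names from [callVariants()].
#' @return list with `counts` (individuals x variants) and `abundance`
#'   (rows summing to 1 where any variant reads are present).
#' @export
genotypeProfiles <- function(counts, variants) {
  m <- as.matrix(counts)[, variants, drop = FALSE]
  tot <- rowSums(m)
  ab <- m / ifelse(tot > 0, tot, NA_real_)
  list(counts = m, abundance = ab)
}

#' Cluster samples by Spearman distance
#'
#' Pairwise distance `1 - Spearman rho` between relative-abundance vectors,
#' followed by agglomerative clustering with complete linkage. Constant
#' abundance vectors have undefined correlation; their distances are set to
#' 1 with a warning. Samples are pre-sorted by identifier so ties break
#' deterministically.
#'
#' @param abundance numeric matrix, individuals x variants (relative
#'   abundances).
#' @return list with `hclust`, `order` (sample identifiers in dendrogram
#'   order), `dist` (full symmetric matrix) and `newick` (dendrogram as a
#'   Newick string).
#' @export
clusterSamples <- function(abundance) {
  m <- as.matrix(abundance)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 samples and 2 variants", call. = FALSE)
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  constant <- apply(m, 1L, function(r) stats::sd(r) == 0 || all(is.na(r)))
  if (any(constant)) {
    warning("constant abundance vector(s); Spearman undefined, distance ",
            "set to 1: ", paste(rownames(m)[constant], collapse = ", "))
  }
  rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  d <- 1 - rho
  d[is.na(d)] <- 1
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  nw <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, order = rownames(m)[hc$order], dist = d, newick = nw)
}

## Set-key helpers for the haplotype search: sets of variant ids are stored
## as sorted, "|"-joined keys.
.setKey <- function(v) paste(sort(unique(v)), collapse = "|")
.keySet <- function(k) {
  if (nzchar(k)) strsplit(k, "|", fixed = TRUE)[[1]] else character(0)
}

#' Deduce core haplotypes from presence sets
#'
#' A variant is present in an individual when its count reaches
#' `presenceThreshold`. The candidate cores are the distinct observed
#' presence sets; the method finds the minimum-cardinality subset of
#' candidates such that every individual's presence set equals the union of
#' one or two (possibly equal) members. Ties are broken by (i) maximizing
#' the number of individuals whose whole set is itself a core (homozygotes),
#' then (ii) lexicographic order of the sorted set contents. The search is
#' exhaustive over candidate subsets up to `maxCores`; individuals whose
#' set no subset explains are reported unexplained.
#'
#' @param counts integer matrix, individuals x variants (post-subsampling).
#' @param presenceThreshold count defining presence (default 100, the
#'   variant-calling abundance threshold).
#' @param maxCores largest core-set cardinality searched (default 8).
#' @return list with `cores` (named list of variant-id vectors, `H1..`),
#'   `assignments` (data.frame: individual, hap1, hap2, homozygous,
#'   explained) and `unexplained` (individual ids).
#' @export
inferCoreHaplotypes <- function(counts, presenceThreshold = 100L,
                                maxCores = 8L) {
  m <- as.matrix(counts)
  present <- m >= presenceThreshold
  indivSets <- apply(present, 1L, function(r) .setKey(colnames(m)[r]))
  nonEmpty <- nzchar(indivSets)
  freq <- sort(table(indivSets[nonEmpty]), decreasing = TRUE)
  sets <- names(freq)
  if (length(sets) == 0L) {
    return(list(cores = list(), assignments = NULL,
                unexplained = rownames(m)))
  }
  candList <- lapply(sets, .keySet)
  nc <- length(candList)
  ## precompute pairwise union keys (i <= j) and their target indices
  uk <- matrix("", nc, nc)
  for (i in seq_len(nc)) for (j in i:nc) {
    uk[i, j] <- uk[j, i] <- .setKey(c(candList[[i]], candList[[j]]))
  }
  targetKeys <- names(freq)
  targetN <- as.integer(freq)
  ukId <- matrix(match(uk, targetKeys), nc, nc)  # NA: not an observed set
  nT <- length(targetKeys)
  ## candidates contained in each target (the only possible parts of it)
  subsOf <- lapply(seq_len(nT), function(t) {
    tv <- candList[[t]]
    which(vapply(candList, function(cs) all(cs %in% tv), logical(1)))
  })
  explainedTargets <- function(subset) {
    ids <- ukId[subset, subset]
    unique(ids[!is.na(ids)])
  }
  ## iterative-deepening branch-and-bound: at each node branch on the
  ## candidates that can participate in forming the first unexplained
  ## target; collect every cover at the minimal cardinality.
  solutions <- list()
  visited <- NULL
  bb <- function(chosen, remainingDepth) {
    key <- paste0("s", paste(sort(chosen), collapse = ","))
    if (exists(key, envir = visited, inherits = FALSE)) return(invisible(NULL))
    assign(key, TRUE, envir = visited)
    expl <- explainedTargets(chosen)
    open <- setdiff(seq_len(nT), expl)
    if (!length(open)) {
      solutions[[length(solutions) + 1L]] <<- sort(chosen)
      return(invisible(NULL))
    }
    if (remainingDepth == 0L) return(invisible(NULL))
    t <- open[1]
    for (cand in setdiff(subsOf[[t]], chosen)) {
      ## cand must combine with some (possibly equal) part inside t
      parts <- subsOf[[t]]
      forms <- any(!is.na(ukId[cand, parts]) & ukId[cand, parts] == t)
      if (forms) bb(c(chosen, cand), remainingDepth - 1L)
    }
    invisible(NULL)
  }
  solution <- NULL
  for (k in seq_len(min(maxCores, nc))) {
    solutions <- list()
    visited <- new.env(hash = TRUE)
    bb(integer(0), k)
    sols <- unique(solutions)
    sols <- sols[lengths(sols) == k]  # minimal cardinality only
    if (length(sols)) {
      ## tie-break (i): maximize homozygotes
      homoCount <- vapply(sols, function(sub) {
        sum(targetN[targetKeys %in% sets[sub]])
      }, numeric(1))
      sols <- sols[homoCount == max(homoCount)]
      ## tie-break (ii): lexicographic on sorted set contents
      repr <- vapply(sols, function(sub) {
        paste(sort(sets[sub]), collapse = ";")
      }, character(1))
      solution <- sols[[order(repr)[1]]]
      break
    }
  }
  if (is.null(solution)) {
    ## no full cover: greedy max-coverage fallback, stragglers reported
    vdLog("no covering core set up to size ", maxCores,
          "; reporting a best-effort partial cover", level = "warn")
    chosen <- integer(0)
    repeat {
      if (length(chosen) >= maxCores) break
      gains <- vapply(seq_len(nc), function(cand) {
        if (cand %in% chosen) return(-1)
        sum(targetN[explainedTargets(c(chosen, cand))])
      }, numeric(1))
      if (max(gains) <= sum(targetN[explainedTargets(chosen)])) break
      chosen <- c(chosen, which.max(gains))
    }
    solution <- chosen
  }
  coreKeys <- sets[solution]
  ## stable labels H1.. ordered by decreasing size then lexicographic
  o <- order(-lengths(lapply(coreKeys, .keySet)), coreKeys)
  coreKeys <- coreKeys[o]
  cores <- lapply(coreKeys, .keySet)
  names(cores) <- paste0("H", seq_along(cores))
  ## assign each individual a pair of cores (prefer homozygous)
  assign1 <- function(key) {
    if (!nzchar(key)) return(c(NA_character_, NA_character_, NA, FALSE))
    hom <- which(coreKeys == key)
    if (length(hom)) {
      return(c(names(cores)[hom[1]], names(cores)[hom[1]], TRUE, TRUE))
    }
    for (i in seq_along(coreKeys)) for (j in i:length(coreKeys)) {
      if (.setKey(c(cores[[i]], cores[[j]])) == key) {
        return(c(names(cores)[i], names(cores)[j], FALSE, TRUE))
      }
    }
    c(NA_character_, NA_character_, NA, FALSE)
  }
  am <- t(vapply(indivSets, assign1, character(4)))
  assignments <- data.frame(individual = rownames(m),
                            hap1 = am[, 1], hap2 = am[, 2],
                            homozygous = as.logical(am[, 3]),
                            explained = as.logical(am[, 4]),
                            row.names = NULL)
  list(cores = cores, assignments = assignments,
       unexplained = assignments$individual[!assignments$explained])
}
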