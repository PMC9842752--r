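## Locus architecture of a clustered toxin gene family: copy counting with
## pseudogene flags, tandem duplication-unit detection from label order and
## intergenic spacing, minimal block-edit comparison of haplotypes, and
## non-B DNA motif scanning around breakpoints.

#' Construct a HaplotypeArray
#'
#' @param haplotype haplotype identifier.
#' @param loci data.frame with columns `label`, `strand`, `start`, `end`
#'   (0-based half-open bp) and optionally `pseudogene` (default `FALSE`).
#'   Rows are sorted by start.
#' @return A [HaplotypeArray-class].
#' @export
haplotypeArray <- function(haplotype, loci) {
  if (is.null(loci$pseudogene)) loci$pseudogene <- FALSE
  loci <- loci[order(loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  loci$label <- as.character(loci$label)
  loci$start <- as.integer(loci$start)
  loci$end <- as.integer(loci$end)
  new("HaplotypeArray", haplotype = as.character(haplotype), loci = loci)
}

#' Read locus arrays from a BED-like TSV
#'
#' Columns: `haplotype`, `label`, `strand`, `start`, `end`, `pseudogene`
#' (logical). Coordinates are 0-based half-open.
#'
#' @param file path to the TSV.
#' @return named list of [HaplotypeArray-class] objects.
#' @export
readLocusArrays <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("haplotype", "label", "strand", "start", "end")
  if (!all(need %in% names(df))) {
    stop("locus table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$pseudogene)) df$pseudogene <- FALSE
  df$pseudogene <- as.logical(df$pseudogene)
  haps <- split(df[setdiff(names(df), "haplotype")], df$haplotype)
  out <- lapply(names(haps), function(h) haplotypeArray(h, haps[[h]]))
  setNames(out, names(haps))
}

#' Count gene copies in a haplotype array
#'
#' @param h a [HaplotypeArray-class].
#' @param includePseudogenes count pseudogene-flagged loci too (default
#'   `TRUE`).
#' @return integer copy count (0 for the empty haplotype).
#' @export
countCopies <- function(h, includePseudogenes = TRUE) {
  df <- lociTable(h)
  if (includePseudogenes) nrow(df) else sum(!df$pseudogene)
}

#' Flag a coding sequence as a pseudogene
#'
#' A copy is a pseudogene when its translation contains a stop codon before
#' the final codon ("premature stop"), when it has no ATG start ("no ORF"),
#' or when the encoded mature peptide is shorter than
#' `truncationFraction * expectedMatureLength` ("truncated").
#'
#' @param cds nucleotide coding sequence (length divisible by 3 after ORF
#'   trimming).
#' @param expectedMatureLength expected mature-peptide length (residues).
#' @param truncationFraction fraction of the expected length below which
#'   the copy is called truncated (default 0.8).
#' @param matureOffset residues preceding the mature peptide (signal +
#'   propart), default 0.
#' @return list with `pseudogene` (logical) and `reason` (`"none"`,
#'   `"no ORF"`, `"premature stop"`, `"truncated"`).
#' @export
flagPseudogene <- function(cds, expectedMatureLength,
                           truncationFraction = 0.8, matureOffset = 0L) {
  cds <- toupper(cds)
  if (substr(cds, 1, 3) != "ATG") {
    return(list(pseudogene = TRUE, reason = "no ORF"))
  }
  n3 <- (nchar(cds) %/% 3) * 3
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, n3)), if.fuzzy.codon = "X"))
  nAA <- nchar(aa)
  stops <- unlist(gregexpr("*", aa, fixed = TRUE))
  internalStop <- any(stops > 0 & stops < nAA)
  if (internalStop) {
    return(list(pseudogene = TRUE, reason = "premature stop"))
  }
  matureLen <- nAA - matureOffset - (if (substr(aa, nAA, nAA) == "*") 1L else 0L)
  if (matureLen < truncationFraction * expectedMatureLength) {
    return(list(pseudogene = TRUE, reason = "truncated"))
  }
  list(pseudogene = FALSE, reason = "none")
}

## Do two intergenic gaps agree, within max(relative, absolute) tolerance?
.gapsAgree <- function(g1, g2, relTol = 0.2, absTol = 500) {
  tol <- max(relTol * max(g1, g2), absTol)
  abs(g1 - g2) <= tol
}

#' Detect tandem duplication units
#'
#' For each period `u` from 1 to `floor(n/2)` and each start, extends
#' maximal runs where `label[i] == label[i + u]` and corresponding
#' intergenic gaps agree within tolerance (the larger of `gapTolerance`
#' relative and `gapAbsolute` bp). Maximal non-overlapping units are
#' reported, preferring smaller period, then longer span, then smaller
#' start.
#'
#' @param h a [HaplotypeArray-class] with at least 2 loci.
#' @param gapTolerance relative gap tolerance, default 0.2.
#' @param gapAbsolute absolute gap tolerance in bp, default 500.
#' @return data.frame with `unit` (comma-joined label block), `period`,
#'   `count` (repeats, >= 2), `startIndex`, `endIndex` (1-based inclusive
#'   locus indices) and `gapScore` (fraction of compared gap pairs that
#'   agree; 1 when none compared).
#' @export
detectTandemUnits <- function(h, gapTolerance = 0.2, gapAbsolute = 500) {
  df <- lociTable(h)
  n <- nrow(df)
  empty <- data.frame(unit = character(0), period = integer(0),
                      count = integer(0), startIndex = integer(0),
                      endIndex = integer(0), gapScore = numeric(0))
  if (n < 2) return(empty)
  labels <- df$label
  gaps <- intergenicGaps(h)
  ## a unit (s, u, m) spans loci s..e with e = s + u m - 1 and requires
  ## label[j] == label[j + u] for j in s..(e - u) and gap agreement
  ## gap[j] ~ gap[j + u] for j in s..(e - 1 - u) (both gaps inside the span)
  cands <- list()
  runFrom <- function(ok) {
    ## run[i] = number of consecutive TRUE starting at i
    r <- integer(length(ok) + 1L)
    for (i in rev(seq_along(ok))) r[i] <- if (ok[i]) r[i + 1L] + 1L else 0L
    r[seq_along(ok)]
  }
  for (u in seq_len(n %/% 2)) {
    labOK <- labels[seq_len(n - u)] == labels[seq_len(n - u) + u]
    nGap <- n - 1L - u
    gapOK <- if (nGap >= 1) {
      vapply(seq_len(nGap), function(j) {
        .gapsAgree(gaps[j], gaps[j + u], gapTolerance, gapAbsolute)
      }, logical(1))
    } else logical(0)
    labRun <- runFrom(labOK)
    gapRun <- runFrom(gapOK)
    maxM <- function(s) {
      if (s < 1L || s > n - u) return(1L)
      lr <- labRun[s]
      gr <- if (s <= length(gapRun)) gapRun[s] else 0L
      1L + min(lr, gr + 1L) %/% u
    }
    for (s in seq_len(n - 2L * u + 1L)) {
      m <- maxM(s)
      if (m < 2L) next
      if (s - u >= 1L && maxM(s - u) >= m + 1L) next  # not left-maximal
      cands[[length(cands) + 1L]] <- data.frame(
        unit = paste(labels[s:(s + u - 1L)], collapse = ","),
        period = u, count = m, startIndex = s,
        endIndex = s + u * m - 1L, gapScore = 1)
    }
  }
  if (!length(cands)) return(empty)
  cand <- do.call(rbind, cands)
  cand <- cand[order(cand$period, -(cand$endIndex - cand$startIndex),
                     cand$startIndex), , drop = FALSE]
  taken <- rep(FALSE, n)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rng <- cand$startIndex[i]:cand$endIndex[i]
    if (!any(taken[rng])) {
      keep[i] <- TRUE
      taken[rng] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$startIndex), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## One BFS/IDDFS expansion: all sequences reachable by one tandem block
## duplication or one contiguous block deletion, within a length guard.
.editNeighbors <- function(x, maxLen) {
  out <- list()
  n <- length(x)
  for (i in seq_len(n)) for (j in i:n) {
    block <- x[i:j]
    if (n + length(block) <= maxLen) {
      out[[length(out) + 1L]] <- append(x, block, after = j)
    }
    if (n - length(block) >= 0) {
      out[[length(out) + 1L]] <- x[-(i:j)]
    }
  }
  out
}

#' Minimal block-edit distance between haplotype label sequences
#'
#' Breadth-first search for the minimal number of events transforming
#' haplotype `a`'s label sequence into `b`'s, where one event is a tandem
#' block duplication (a contiguous run copied in place) or a contiguous
#' block deletion. The search is capped at `maxEvents`; intermediate
#' sequences are bounded at twice the longer input plus 4 labels.
#'
#' @param a,b [HaplotypeArray-class] objects or character label vectors.
#' @param maxEvents search depth cap, default 6.
#' @return list with `events` (integer, or `NA` when unreachable within the
#'   cap — `capped = TRUE`), `script` (list of `(op, labels)` steps along
#'   one optimal path) and `capped`.
#' @export
compareHaplotypes <- function(a, b, maxEvents = 6L) {
  la <- if (is(a, "HaplotypeArray")) haplotypeLabels(a) else as.character(a)
  lb <- if (is(b, "HaplotypeArray")) haplotypeLabels(b) else as.character(b)
  keyOf <- function(x) paste0("k:", paste(x, collapse = "\r"))
  target <- keyOf(lb)
  if (keyOf(la) == target) {
    return(list(events = 0L, script = list(), capped = FALSE))
  }
  maxLen <- 2L * max(length(la), length(lb)) + 4L
  frontier <- list(la)
  parents <- new.env(hash = TRUE)
  assign(keyOf(la), list(parent = NA, seq = la), envir = parents)
  for (depth in seq_len(maxEvents)) {
    nxt <- list()
    for (x in frontier) {
      for (y in .editNeighbors(x, maxLen)) {
        ky <- keyOf(y)
        if (!exists(ky, envir = parents, inherits = FALSE)) {
          assign(ky, list(parent = keyOf(x), seq = y), envir = parents)
          if (ky == target) {
            ## reconstruct the script
            script <- list()
            cur <- ky
            while (!identical(get(cur, envir = parents)$parent, NA)) {
              nodeRec <- get(cur, envir = parents)
              script <- c(list(nodeRec$seq), script)
              cur <- nodeRec$parent
            }
            steps <- lapply(script, identity)
            return(list(events = depth, script = steps, capped = FALSE))
          }
          nxt[[length(nxt) + 1L]] <- y
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  list(events = NA_integer_, script = list(), capped = TRUE)
}

#' Scan for non-B DNA motifs
#'
#' Finds (i) inverted repeats: arm pairs where the downstream arm is the
#' exact reverse complement of the upstream arm, arm length >= `minArm`,
#' loop (separation) <= `maxLoop`, reported maximal (extendable neither
#' outward nor inward); and (ii) poly(G) and poly(C) homopolymer runs of
#' length >= `minGRun`. Intervals are 0-based half-open.
#'
#' @param seq nucleotide sequence over ACGTN.
#' @param minArm minimum arm length, default 6.
#' @param maxLoop maximum loop length, default 100.
#' @param minGRun minimum homopolymer run, default 8.
#' @return data.frame with `type` (`invertedRepeat`, `polyG`, `polyC`),
#'   `start`, `end` (outer interval), and for inverted repeats `armLength`
#'   and `loop` (`NA` for homopolymers).
#' @export
scanNonBMotifs <- function(seq, minArm = 6L, maxLoop = 100L, minGRun = 8L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch]
  hits <- list()
  ## homopolymer runs
  for (base in c("G", "C")) {
    m <- gregexpr(sprintf("%s{%d,}", base, minGRun), seq)[[1]]
    if (m[1] != -1) {
      for (k in seq_along(m)) {
        hits[[length(hits) + 1L]] <- data.frame(
          type = if (base == "G") "polyG" else "polyC",
          start = m[k] - 1L, end = m[k] - 1L + attr(m, "match.length")[k],
          armLength = NA_integer_, loop = NA_integer_)
      }
    }
  }
  ## inverted repeats: seed with minArm-mers, extend to maximality
  if (n >= 2 * minArm) {
    k <- minArm
    kmers <- substring(seq, 1:(n - k + 1), k:n)
    pos <- split(seq_along(kmers), kmers)
    seen <- character(0)
    for (a in seq_len(n - k + 1)) {
      arm <- substr(seq, a, a + k - 1)
      if (grepl("N", arm, fixed = TRUE)) next
      rc <- revComp(arm)
      bs <- pos[[rc]]
      if (is.null(bs)) next
      for (b1 in bs) {
        ## arm1 = [a, a+k), arm2 = [b1, b1+k) (1-based); require arm2 after
        ## arm1 with loop <= maxLoop
        loop <- b1 - (a + k)
        if (loop < 0 || loop > maxLoop) next
        ## extend to maximal: inward then outward
        s1 <- a; e1 <- a + k - 1; s2 <- b1; e2 <- b1 + k - 1
        while (s2 - 1 > e1 + 1 && ch[e1 + 1] != "N" &&
               comp[e1 + 1] == ch[s2 - 1]) {
          e1 <- e1 + 1; s2 <- s2 - 1
        }
        while (s1 > 1 && e2 < n && ch[s1 - 1] != "N" &&
               ch[e2 + 1] != "N" && comp[s1 - 1] == ch[e2 + 1]) {
          s1 <- s1 - 1; e2 <- e2 + 1
        }
        armLen <- e1 - s1 + 1
        loopLen <- s2 - e1 - 1
        if (loopLen > maxLoop) next
        key <- paste(s1, e1, s2, e2)
        if (key %in% seen) next
        seen <- c(seen, key)
        hits[[length(hits) + 1L]] <- data.frame(
          type = "invertedRepeat", start = s1 - 1L, end = e2,
          armLength = armLen, loop = loopLen)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(type = character(0), start = integer(0),
                      end = integer(0), armLength = integer(0),
                      loop = integer(0)))
  }
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$start, out$end, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif context around breakpoints
#'
#' For each breakpoint, reports motifs overlapping the window
#' `[pos - window, pos + window)` with the signed distance to the nearest
#' motif edge (0 when the breakpoint falls inside the motif, negative when
#' the motif lies left of the breakpoint).
#'
#' @param breakpoints integer positions (0-based).
#' @param motifHits data.frame from [scanNonBMotifs()].
#' @param window half-window in bp, default 500.
#' @param seqLength sequence length for bounds checking (optional).
#' @return data.frame with `breakpoint`, `type`, `start`, `end`,
#'   `distance`.
#' @export
breakpointContext <- function(breakpoints, motifHits, window = 500L,
                              seqLength = NULL) {
  if (!is.null(seqLength) &&
      any(breakpoints < 0 | breakpoints >= seqLength)) {
    stop("breakpoint position out of sequence bounds", call. = FALSE)
  }
  rows <- list()
  for (bp in breakpoints) {
    lo <- bp - window; hi <- bp + window
    for (i in seq_len(nrow(motifHits))) {
      s <- motifHits$start[i]; e <- motifHits$end[i]
      if (e <= lo || s >= hi) next
      d <- if (bp >= s && bp < e) 0L
           else if (e <= bp) e - bp
           else s - bp
      rows[[length(rows) + 1L]] <- data.frame(
        breakpoint = bp, type = motifHits$type[i], start = s, end = e,
        distance = d)
    }
  }
  if (!length(rows)) {
    return(data.frame(breakpoint = integer(0), type = character(0),
                      start = integer(0), end = integer(0),
                      distance = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
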