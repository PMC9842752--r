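## Recovery of sequence variants of a highly duplicated, near-identical
## toxin gene from read pairs mapped against a single collapsed gene model:
## per-pair consensus on model coordinates, exact clustering on a common
## region, the 70%-prefix / 10-copy retention rule, and Nv3 signature
## detection.

NV1_SIGNATURE <- "AAACGCGGCATTCCT"  # encodes KRGIP
NV3_SIGNATURE <- "AAACGCGGCTTTGCT"  # encodes KRGFA

## Align one read to the model in the best orientation with the banded
## fitting aligner (match +1, mismatch -1, gap open -2, gap extend -1,
## band 16); returns NULL when identity < minIdentity. Bases are placed on
## 0-based model coordinates; read insertions are dropped, read deletions
## inside the span become N.
.alignReadToModel <- function(read, model, qual = NULL, minIdentity = 0.9,
                              band = 16L) {
  fwd <- banded_fit_align_cpp(read, model, band)
  rcRead <- revComp(read)
  rev <- banded_fit_align_cpp(rcRead, model, band)
  fs <- if (isTRUE(fwd$ok)) fwd$score else -Inf
  rs <- if (isTRUE(rev$ok)) rev$score else -Inf
  if (!is.finite(fs) && !is.finite(rs)) return(NULL)
  if (fs >= rs) {
    aln <- fwd; q <- qual
  } else {
    aln <- rev; q <- rev(qual)
  }
  if (aln$nmatch / nchar(read) < minIdentity) return(NULL)
  mp <- aln$modelPos  # 1-based, 0 = insertion in read
  hit <- mp > 0L
  if (!any(hit)) return(NULL)
  span <- range(mp[hit])
  bases <- rep("N", span[2] - span[1] + 1L)
  quals <- rep(-Inf, length(bases))
  readCh <- strsplit(read, "", fixed = TRUE)[[1]]
  if (fs < rs) readCh <- strsplit(rcRead, "", fixed = TRUE)[[1]]
  idx <- mp[hit] - span[1] + 1L
  bases[idx] <- readCh[hit]
  quals[idx] <- if (is.null(q)) NA_real_ else q[hit]
  list(pos = (span[1]:span[2]) - 1L, base = bases, qual = quals)
}

#' Consensus of a read pair on gene-model coordinates
#'
#' Each mate is placed against the collapsed gene model by global-in-read /
#' local-in-model alignment (match +1, mismatch -1, gap open -2, gap extend
#' -1), trying both orientations. The consensus covers the union of the two
#' mates' model intervals; interior positions covered by neither mate are
#' `N`. Where the mates overlap and disagree, the base with the higher
#' quality wins when qualities are given, otherwise the position becomes `N`
#' and the conflict count increments.
#'
#' @param read1,read2 mate nucleotide sequences (character).
#' @param model collapsed gene-model sequence (character).
#' @param qual1,qual2 optional numeric per-base qualities.
#' @param minIdentity minimum alignment identity per mate (default 0.9);
#'   below it the pair is rejected (`NULL` returned), mirroring a mapping
#'   failure.
#' @return list with `sequence` (ACGTN), `start`, `end` (0-based half-open
#'   model interval) and `conflicts`, or `NULL` if rejected.
#' @export
alignPairToModel <- function(read1, read2, model, qual1 = NULL, qual2 = NULL,
                             minIdentity = 0.9) {
  a1 <- .alignReadToModel(read1, model, qual1, minIdentity)
  a2 <- .alignReadToModel(read2, model, qual2, minIdentity)
  if (is.null(a1) || is.null(a2)) return(NULL)
  lo <- min(a1$pos, a2$pos)
  hi <- max(a1$pos, a2$pos) + 1L
  len <- hi - lo
  lay <- function(a) {
    b <- rep(NA_character_, len); q <- rep(NA_real_, len)
    b[a$pos - lo + 1L] <- a$base
    q[a$pos - lo + 1L] <- a$qual
    list(b = b, q = q)
  }
  l1 <- lay(a1); l2 <- lay(a2)
  cons <- rep("N", len)
  conflicts <- 0L
  for (i in seq_len(len)) {
    b1 <- l1$b[i]; b2 <- l2$b[i]
    if (is.na(b1) && is.na(b2)) next            # uncovered interior -> N
    if (is.na(b2) || (!is.na(b1) && b2 == "N")) { cons[i] <- b1; next }
    if (is.na(b1) || b1 == "N") { cons[i] <- b2; next }
    if (b1 == b2) { cons[i] <- b1; next }
    q1 <- l1$q[i]; q2 <- l2$q[i]
    if (!is.na(q1) && !is.na(q2) && is.finite(q1) && is.finite(q2) &&
        q1 != q2) {
      cons[i] <- if (q1 > q2) b1 else b2
    } else {
      cons[i] <- "N"
    }
    conflicts <- conflicts + 1L
  }
  list(sequence = paste0(cons, collapse = ""), start = lo, end = hi,
       conflicts = conflicts)
}

#' Cluster identical consensus sequences on a common region
#'
#' Consensi are restricted to a shared model interval ("identical" is only
#' well-defined on a common region): those not fully covering the region
#' are dropped, the rest are trimmed to it, and any trimmed sequence still
#' containing `N` is discarded (counted). Exact-string grouping follows,
#' sorted by count descending with ties broken lexicographically.
#'
#' @param consensi list of consensus records from [alignPairToModel()].
#' @param region length-2 integer `c(start, end)` (0-based half-open);
#'   `NULL` uses the intersection of all consensus intervals.
#' @return data.frame with columns `sequence`, `count`; attributes
#'   `nNotCovering` and `nWithN` tally the discards.
#' @export
clusterIdentical <- function(consensi, region = NULL) {
  consensi <- consensi[!vapply(consensi, is.null, logical(1))]
  if (length(consensi) == 0L) {
    out <- data.frame(sequence = character(0), count = integer(0))
    attr(out, "nNotCovering") <- 0L; attr(out, "nWithN") <- 0L
    return(out)
  }
  starts <- vapply(consensi, `[[`, numeric(1), "start")
  ends <- vapply(consensi, `[[`, numeric(1), "end")
  if (is.null(region)) region <- c(max(starts), min(ends))
  if (region[2] <= region[1]) {
    stop("empty common region across consensi", call. = FALSE)
  }
  covering <- starts <= region[1] & ends >= region[2]
  trimmed <- vapply(which(covering), function(i) {
    s <- consensi[[i]]
    substr(s$sequence, region[1] - s$start + 1L, region[2] - s$start)
  }, character(1))
  hasN <- grepl("N", trimmed, fixed = TRUE)
  tab <- table(trimmed[!hasN])
  out <- data.frame(sequence = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nNotCovering") <- sum(!covering)
  attr(out, "nWithN") <- sum(hasN)
  out
}

#' Apply the variant retention rule
#'
#' Retains the shortest prefix of the count-sorted clusters whose cumulative
#' count reaches `retentionFraction` of the total, plus every cluster with
#' at least `minCopies` identical copies (union of the two rules).
#'
#' @param clusters data.frame with columns `sequence`, `count`, sorted by
#'   count descending (resorted if not).
#' @param retentionFraction default 0.70.
#' @param minCopies default 10.
#' @return the data.frame with a logical `retained` column.
#' @export
retainVariants <- function(clusters, retentionFraction = 0.70,
                           minCopies = 10L) {
  if (nrow(clusters) == 0L) {
    clusters$retained <- logical(0)
    return(clusters)
  }
  o <- order(-clusters$count, clusters$sequence)
  clusters <- clusters[o, , drop = FALSE]
  rownames(clusters) <- NULL
  total <- sum(clusters$count)
  cum <- cumsum(clusters$count)
  prefixEnd <- which(cum >= retentionFraction * total)[1]
  retained <- seq_len(nrow(clusters)) <= prefixEnd |
    clusters$count >= minCopies
  clusters$retained <- retained
  clusters
}

#' Detect the Nv3 / Nv1 signature motif
#'
#' Classifies a nucleotide sequence by the diagnostic 15-mer: Nv3 carries
#' `AAACGCGGCTTTGCT` (KRGFA) where Nv1 carries `AAACGCGGCATTCCT` (KRGIP).
#'
#' @param seq nucleotide sequence of length >= 15.
#' @return `"Nv3"`, `"Nv1"`, or `"neither"`; both motifs present is an
#'   ambiguity error.
#' @export
detectNv3Signature <- function(seq) {
  if (nchar(seq) < 15L) stop("sequence shorter than the signature motif",
                             call. = FALSE)
  has3 <- grepl(NV3_SIGNATURE, seq, fixed = TRUE)
  has1 <- grepl(NV1_SIGNATURE, seq, fixed = TRUE)
  if (has3 && has1) stop("ambiguous: both Nv1 and Nv3 signatures present",
                         call. = FALSE)
  if (has3) "Nv3" else if (has1) "Nv1" else "neither"
}

#' End-to-end transcriptomic variant recovery
#'
#' Runs [alignPairToModel()] on every pair, [clusterIdentical()] on the
#' resulting consensi, and [retainVariants()].
#'
#' @param read1s,read2s character vectors of mate sequences.
#' @param model collapsed gene-model sequence.
#' @param region optional common region (0-based half-open).
#' @param minIdentity mate alignment identity threshold.
#' @param retentionFraction,minCopies retention rule parameters.
#' @return data.frame of clusters with `retained` flags; discard tallies as
#'   attributes, plus `nRejectedPairs`.
#' @export
recoverTranscriptVariants <- function(read1s, read2s, model, region = NULL,
                                      minIdentity = 0.9,
                                      retentionFraction = 0.70,
                                      minCopies = 10L) {
  stopifnot(length(read1s) == length(read2s))
  consensi <- lapply(seq_along(read1s), function(i) {
    alignPairToModel(read1s[i], read2s[i], model, minIdentity = minIdentity)
  })
  nRej <- sum(vapply(consensi, is.null, logical(1)))
  clusters <- clusterIdentical(consensi, region)
  out <- retainVariants(clusters, retentionFraction, minCopies)
  attr(out, "nNotCovering") <- attr(clusters, "nNotCovering")
  attr(out, "nWithN") <- attr(clusters, "nWithN")
  attr(out, "nRejectedPairs") <- nRej
  out
}
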