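## Independent oracle implementations used across the suite. These are kept
## deliberately naive (brute force, enumeration, quadrature) and separate
## from the package's code paths.

## Brute-force BM covariance: pairwise root-to-MRCA path sums over explicit
## node paths.
bruteForceVcv <- function(tree) {
  nTip <- length(tree$tip.label)
  parent <- integer(nTip + tree$Nnode)
  elen <- numeric(nTip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- nTip + 1L
  pathOf <- function(tip) {
    nodes <- integer(0)
    nd <- tip
    while (nd != root) {
      nodes <- c(nodes, nd)
      nd <- parent[nd]
    }
    nodes
  }
  paths <- lapply(seq_len(nTip), pathOf)
  C <- matrix(0, nTip, nTip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nTip)) for (j in seq_len(nTip)) {
    shared <- intersect(paths[[i]], paths[[j]])
    C[i, j] <- sum(elen[shared])
  }
  C
}

## Dense multivariate-normal log-density (eigen-based, distinct from the
## package's Cholesky/pruning routes).
denseMvnLogLik <- function(x, meanVec, V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0) return(-Inf)
  z <- t(e$vectors) %*% (x - meanVec)
  -0.5 * length(x) * log(2 * pi) - 0.5 * sum(log(e$values)) -
    0.5 * sum(z^2 / e$values)
}

## Jump-normal displacement density over a branch: Poisson sum of normals.
jnIncrementDensity <- function(x, t, sigma2, lambdaJ, delta2, Kmax = 80) {
  j <- 0:Kmax
  sum(dpois(j, lambdaJ * t) * dnorm(x, 0, sqrt(sigma2 * t + j * delta2)))
}

## Exact JN likelihood by enumerating per-edge jump counts (small trees).
jnEnumLogLik <- function(x, tree, sigma2, lambdaJ, delta2, a, Kmax = 8) {
  tr <- reorder(tree, "postorder")
  nt <- length(tr$tip.label)
  x <- x[tr$tip.label]
  E <- nrow(tr$edge)
  tipsUnder <- function(nd) {
    if (nd <= nt) return(nd)
    unlist(lapply(tr$edge[tr$edge[, 1] == nd, 2], tipsUnder))
  }
  desc <- lapply(seq_len(E), function(e) tipsUnder(tr$edge[e, 2]))
  grid <- as.matrix(expand.grid(rep(list(0:Kmax), E)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    j <- grid[g, ]
    pw <- prod(dpois(j, lambdaJ * tr$edge.length))
    if (pw < 1e-18) next
    V <- matrix(0, nt, nt)
    for (e in seq_len(E)) {
      idx <- desc[[e]]
      V[idx, idx] <- V[idx, idx] + sigma2 * tr$edge.length[e] + j[e] * delta2
    }
    tot <- tot + pw * exp(denseMvnLogLik(x, rep(a, nt), V))
  }
  log(tot)
}

## GLS ancestral-state oracle: joint ML states for all internal nodes given
## the dense covariance of (tips, nodes) under BM.
denseAsrOracle <- function(x, tree) {
  nTip <- length(tree$tip.label)
  nAll <- nTip + tree$Nnode
  parent <- integer(nAll); elen <- numeric(nAll)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- nTip + 1L
  pathOf <- function(nd) {
    nodes <- integer(0)
    while (nd != root) { nodes <- c(nodes, nd); nd <- parent[nd] }
    nodes
  }
  paths <- lapply(seq_len(nAll), pathOf)
  CC <- matrix(0, nAll, nAll)
  for (i in seq_len(nAll)) for (j in seq_len(nAll)) {
    CC[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
  }
  tipI <- seq_len(nTip)
  nodeI <- setdiff(seq_len(nAll), c(tipI, root))
  Ct <- CC[tipI, tipI]
  one <- rep(1, nTip)
  iC <- solve(Ct)
  a <- drop(t(one) %*% iC %*% x[tree$tip.label]) / drop(t(one) %*% iC %*% one)
  est <- setNames(numeric(tree$Nnode), as.character(root:nAll))
  est[as.character(root)] <- a
  for (nd in nodeI) {
    cv <- CC[nd, tipI]
    est[as.character(nd)] <- a + drop(cv %*% iC %*% (x[tree$tip.label] - a))
  }
  est
}

## Brute-force variant retention: enumerate all prefixes.
bruteForceRetain <- function(counts, frac = 0.70, minCopies = 10) {
  n <- length(counts)
  total <- sum(counts)
  prefix <- rep(FALSE, n)
  for (k in seq_len(n)) {
    if (sum(counts[seq_len(k)]) >= frac * total) {
      prefix[seq_len(k)] <- TRUE
      break
    }
  }
  prefix | (counts >= minCopies)
}

## Brute-force variant calling: explicit double loop.
bruteForceCallVariants <- function(counts, A = 100, minInd = 2) {
  out <- character(0)
  for (v in colnames(counts)) {
    highEnough <- FALSE
    nCarriers <- 0
    for (i in rownames(counts)) {
      if (counts[i, v] >= A) highEnough <- TRUE
      if (counts[i, v] >= 1) nCarriers <- nCarriers + 1
    }
    if (highEnough && nCarriers >= minInd) out <- c(out, v)
  }
  out
}

## Brute-force triplicate filter on a single 3-vector of Cq values:
## returns indices to keep (per gene, ignoring multiplex coupling).
bruteForceTriplicateKeep <- function(cq, tol = 0.2) {
  if (max(dist(cq)) <= tol) return(seq_along(cq))
  best <- NULL
  for (i in seq_along(cq)) {
    rest <- cq[-i]
    if (max(rest) - min(rest) <= tol) {
      score <- abs(cq[i] - mean(rest))
      if (is.null(best) || score > best$score) {
        best <- list(keep = setdiff(seq_along(cq), i), score = score)
      }
    }
  }
  if (is.null(best)) integer(0) else best$keep
}

## Brute-force tandem-unit detection from the span definition: a unit
## (s, u, m) spanning loci s..e (e = s + u m - 1) is valid when
## label[j] == label[j + u] for all j in s..(e - u) and the gaps agree for
## all j in s..(e - 1 - u); candidates are the right-maximal (largest m)
## and left-maximal (not extendable by one more period on the left) valid
## units. Selection mirrors the package rule.
bruteForceTandemUnits <- function(labels, gaps, relTol = 0.2, absTol = 500) {
  n <- length(labels)
  agree <- function(g1, g2) abs(g1 - g2) <= max(relTol * max(g1, g2), absTol)
  valid <- function(s, u, m) {
    e <- s + u * m - 1
    if (s < 1 || e > n || m < 2) return(FALSE)
    for (j in s:(e - u)) if (labels[j] != labels[j + u]) return(FALSE)
    if (e - 1 - u >= s) {
      for (j in s:(e - 1 - u)) if (!agree(gaps[j], gaps[j + u])) {
        return(FALSE)
      }
    }
    TRUE
  }
  cands <- list()
  for (u in seq_len(n %/% 2)) {
    for (s in seq_len(n - 2 * u + 1)) {
      if (!valid(s, u, 2)) next
      m <- 2
      while (valid(s, u, m + 1)) m <- m + 1
      if (valid(s - u, u, m + 1)) next  # left-extendable
      cands[[length(cands) + 1L]] <- data.frame(
        period = u, count = m, startIndex = s, endIndex = s + u * m - 1)
    }
  }
  if (!length(cands)) {
    return(data.frame(period = integer(0), count = integer(0),
                      startIndex = integer(0), endIndex = integer(0)))
  }
  cand <- do.call(rbind, cands)
  cand <- cand[order(cand$period, -(cand$endIndex - cand$startIndex),
                     cand$startIndex), , drop = FALSE]
  taken <- rep(FALSE, n)
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rng <- cand$startIndex[i]:cand$endIndex[i]
    if (!any(taken[rng])) { sel[i] <- TRUE; taken[rng] <- TRUE }
  }
  out <- cand[sel, , drop = FALSE]
  out <- out[order(out$startIndex), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Iterative-deepening DFS block-edit distance (independent of the
## package's breadth-first search).
iddfsBlockEdit <- function(a, b, maxEvents = 4) {
  keyOf <- function(x) paste(x, collapse = "\r")
  target <- keyOf(b)
  maxLen <- 2 * max(length(a), length(b)) + 4
  neighbors <- function(x) {
    out <- list()
    n <- length(x)
    if (n == 0) return(out)
    for (i in seq_len(n)) for (j in i:n) {
      blk <- x[i:j]
      if (n + length(blk) <= maxLen) {
        out[[length(out) + 1L]] <- append(x, blk, after = j)
      }
      out[[length(out) + 1L]] <- x[-(i:j)]
    }
    out
  }
  dfs <- function(x, depth) {
    if (keyOf(x) == target) return(TRUE)
    if (depth == 0) return(FALSE)
    for (y in neighbors(x)) if (dfs(y, depth - 1)) return(TRUE)
    FALSE
  }
  for (d in 0:maxEvents) if (dfs(a, d)) return(d)
  NA_integer_
}

## Brute-force non-B scan: all-pairs arm comparison (arms capped at maxArm
## to bound the enumeration; random sequences never approach the cap).
bruteForceNonB <- function(seq, minArm = 6, maxLoop = 100, minGRun = 8,
                           maxArm = NULL) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch]
  isIR <- function(s1, e1, s2, e2) {
    all(ch[s2:e2] == rev(comp[s1:e1]))
  }
  hits <- list()
  topArm <- if (is.null(maxArm)) n %/% 2 else min(maxArm, n %/% 2)
  for (L in minArm:topArm) {
    for (s1 in 1:(n - 2 * L + 1)) {
      e1 <- s1 + L - 1
      for (s2 in (e1 + 1):min(n - L + 1, e1 + maxLoop + 1)) {
        e2 <- s2 + L - 1
        if (e2 > n) next
        if (any(ch[s1:e1] == "N") || any(ch[s2:e2] == "N")) next
        if (!isIR(s1, e1, s2, e2)) next
        ## maximality
        extendIn <- (s2 - 1 > e1 + 1) && ch[e1 + 1] != "N" &&
          comp[e1 + 1] == ch[s2 - 1]
        extendOut <- (s1 > 1) && (e2 < n) && ch[s1 - 1] != "N" &&
          ch[e2 + 1] != "N" && comp[s1 - 1] == ch[e2 + 1]
        if (extendIn || extendOut) next
        hits[[length(hits) + 1L]] <- data.frame(
          type = "invertedRepeat", start = s1 - 1L, end = e2,
          armLength = L, loop = s2 - e1 - 1L)
      }
    }
  }
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

## Reverse complement via Biostrings (test-side convenience).
rcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
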