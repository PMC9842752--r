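## Maximum-likelihood ancestral state reconstruction under BM by two-pass
## message passing (equivalent to GLS prediction at every node), composition
## reconstruction with clipping/renormalization, and Pagel's lambda.

.combine2 <- function(m1, v1, m2, v2) {
  if (v1 == 0 && v2 == 0) return(c(m1, 0))
  if (v1 == 0) return(c(m1, 0))
  if (v2 == 0) return(c(m2, 0))
  s <- v1 + v2
  c((m1 * v2 + m2 * v1) / s, v1 * v2 / s)
}

#' Ancestral states under Brownian motion
#'
#' Two-pass pruning: a postorder pass folds tip information toward the root,
#' a preorder pass sends parent-side information back down; each internal
#' node's estimate is the precision-weighted combination of all incident
#' messages, which equals the GLS prediction. Variances are conditional
#' variances scaled by `sigma2` (estimated by [fitBM()] when not supplied).
#'
#' @param trait numeric tip values, named by tip label (or in tip order).
#' @param tree rooted `ape::phylo`, at least 2 tips.
#' @param sigma2 optional BM rate for the variance scale.
#' @return data.frame with columns `node` (ape numbering, root first),
#'   `estimate` and `variance`.
#' @examples
#' tr <- readNewick("(A:1,B:3);")
#' asrBM(c(A = 0, B = 4), tr)$estimate  # 1
#' @export
asrBM <- function(trait, tree, sigma2 = NULL) {
  x <- .alignTrait(trait, tree)
  nTip <- length(tree$tip.label)
  if (nTip < 2) stop("at least 2 tips required", call. = FALSE)
  tr <- stats::reorder(tree, "postorder")
  nAll <- nTip + tr$Nnode
  if (any(tr$edge.length == 0 & tr$edge[, 2] > nTip)) {
    warning("zero-length internal branch: ancestral state tied to parent")
  }
  dmean <- numeric(nAll); dvar <- numeric(nAll)
  dmean[seq_len(nTip)] <- x
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  postNodes <- unique(tr$edge[, 1])
  for (node in postNodes) {
    es <- kids[[as.character(node)]]
    ch <- tr$edge[es, 2]
    f <- .foldMessages(dmean[ch], dvar[ch] + tr$edge.length[es])
    dmean[node] <- f$mean; dvar[node] <- f$var
  }
  root <- nTip + 1L
  ## uppass: umean/uvar hold parent-side information at each node
  umean <- numeric(nAll); uvar <- rep(NA_real_, nAll)
  for (node in rev(postNodes)) {  # preorder over internal nodes
    es <- kids[[as.character(node)]]
    ch <- tr$edge[es, 2]
    for (j in seq_along(es)) {
      sibs <- setdiff(seq_along(es), j)
      ms <- dmean[ch[sibs]]; vs <- dvar[ch[sibs]] + tr$edge.length[es[sibs]]
      if (!is.na(uvar[node])) {
        ms <- c(ms, umean[node]); vs <- c(vs, uvar[node])
      }
      m <- ms[1]; v <- vs[1]
      for (k in seq_along(ms)[-1]) {
        cb <- .combine2(m, v, ms[k], vs[k]); m <- cb[1]; v <- cb[2]
      }
      umean[ch[j]] <- m
      uvar[ch[j]] <- v + tr$edge.length[es[j]]
    }
  }
  if (is.null(sigma2)) {
    s2 <- tryCatch(modelParams(fitBM(setNames(x, tree$tip.label),
                                     tree))[["sigma2"]],
                   warning = function(w) 0, error = function(e) 0)
  } else s2 <- sigma2
  nodes <- root:nAll
  est <- numeric(length(nodes)); vr <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[i]
    if (nd == root || is.na(uvar[nd])) {
      est[i] <- dmean[nd]; vr[i] <- s2 * dvar[nd]
    } else {
      cb <- .combine2(dmean[nd], dvar[nd], umean[nd], uvar[nd])
      est[i] <- cb[1]; vr[i] <- s2 * cb[2]
    }
  }
  data.frame(node = nodes, estimate = est, variance = vr)
}

#' Ancestral venom compositions
#'
#' Applies [asrBM()] to each family's fraction independently, then clips
#' node values to \[0, 1\] and renormalizes each node's vector to sum to 1.
#' A node whose clipped vector is all zero gets the uniform composition with
#' a warning.
#'
#' @param comp a [FamilyComposition-class] whose rows are species matching
#'   the tree tips.
#' @param tree rooted `ape::phylo` whose tip set equals the composition
#'   samples.
#' @return matrix of node compositions (rows = internal nodes in ape
#'   numbering, columns = families); rows sum to 1.
#' @export
asrComposition <- function(comp, tree) {
  fr <- compositionFractions(comp)
  if (!setequal(rownames(fr), tree$tip.label)) {
    stop("species set must equal the tree tip set", call. = FALSE)
  }
  if (any(!isDefined(comp))) {
    stop("all species compositions must be defined", call. = FALSE)
  }
  fr <- fr[tree$tip.label, , drop = FALSE]
  nodeStates <- sapply(colnames(fr), function(fam) {
    asrBM(setNames(fr[, fam], rownames(fr)), tree, sigma2 = 1)$estimate
  })
  nodeStates <- matrix(nodeStates, ncol = ncol(fr),
                       dimnames = list(NULL, colnames(fr)))
  nodeStates[nodeStates < 0] <- 0
  nodeStates[nodeStates > 1] <- 1
  tot <- rowSums(nodeStates)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero ancestral composition after clipping; set to uniform")
    nodeStates[zero, ] <- 1 / ncol(nodeStates)
    tot[zero] <- 1
  }
  out <- nodeStates / tot
  rownames(out) <- as.character(length(tree$tip.label) + seq_len(tree$Nnode))
  out
}

#' Pagel's lambda phylogenetic signal
#'
#' ML estimate of `lambda` in `[0, lambdaMax]`, where the covariance
#' `C_lambda` scales off-diagonal entries of the BM covariance by `lambda`
#' (diagonal unchanged) and `lambdaMax` keeps `C_lambda` positive definite.
#' `lambda = 0` is the star tree (no signal); `lambda = 1` is BM.
#'
#' @param trait numeric tip values, named by tip label (or in tip order).
#' @param tree rooted `ape::phylo`, at least 4 tips.
#' @param nGrid grid size for the profile (default 21).
#' @return list with `lambda`, `sigma2`, `root`, `logLik`, `logLik0`
#'   (lambda = 0), `logLik1` (lambda = 1), `lambdaMax`, and the profile grid
#'   as a data.frame.
#' @export
pagelLambda <- function(trait, tree, nGrid = 21L) {
  x <- .alignTrait(trait, tree)
  if (length(x) < 4) stop("at least 4 tips required", call. = FALSE)
  C <- phyloCovarianceMatrix(tree)
  off <- C[row(C) != col(C)]
  lambdaMax <- if (max(off) <= 0) 1 else min(diag(C)) / max(off)
  lambdaMax <- max(lambdaMax, 1)
  llAt <- function(lambda) {
    Cl <- lambda * C
    diag(Cl) <- diag(C)
    .glsProfile(x, Cl)$logLik
  }
  grid <- seq(0, lambdaMax, length.out = nGrid)
  prof <- vapply(grid, llAt, numeric(1))
  best <- .gridRefine(llAt, grid)
  lambda <- min(max(best$par, 0), lambdaMax)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  fit <- .glsProfile(x, Cl)
  list(lambda = lambda, sigma2 = fit$sigma2, root = fit$mean,
       logLik = fit$logLik, logLik0 = llAt(0), logLik1 = llAt(1),
       lambdaMax = lambdaMax,
       profile = data.frame(lambda = grid, logLik = prof))
}
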