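## Multivariate phylogenetic covariance under Brownian motion with
## parametric-bootstrap confidence intervals, and phylomorphospace PCA.

## Symmetric matrix square root with eigenvalues clamped at zero.
.matSqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

.mvBmFit <- function(X, C) {
  n <- nrow(X)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    stop("singular phylogenetic covariance; consider collapsing ",
         "zero-length branches", call. = FALSE)
  }
  one <- rep(1, n)
  W1 <- backsolve(ch, one, transpose = TRUE)
  WX <- backsolve(ch, X, transpose = TRUE)
  a <- drop(crossprod(W1, WX)) / sum(W1^2)
  Rm <- backsolve(ch, X - tcrossprod(one, a), transpose = TRUE)
  R <- crossprod(Rm) / (n - 1)
  list(rootMean = a, R = R)
}

#' Multivariate phylogenetic covariance with bootstrap significance
#'
#' Fits a multivariate Brownian-motion model to a tip-by-trait matrix:
#' root mean `a = (1'C^-1 1)^-1 1'C^-1 X` and evolutionary covariance
#' `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)`. A parametric bootstrap
#' (simulate `B` datasets under the fitted model, refit) gives percentile
#' 95% intervals per entry; an off-diagonal covariance is flagged
#' significant when its interval excludes 0.
#'
#' Expression traits should be variance-stabilized upstream (the package
#' convention is `log(TPM + 1)`, see [logTpm()]).
#'
#' @param traits numeric matrix, tips x traits, rownames matching tip
#'   labels. Needs at least `p + 2` tips for `p` traits.
#' @param tree rooted `ape::phylo`.
#' @param B bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return A [PhyloCovarianceResult-class].
#' @export
phyloCovariance <- function(traits, tree, B = 1000L, seed = 1L) {
  X <- as.matrix(traits)
  if (!is.null(rownames(X))) {
    if (!all(tree$tip.label %in% rownames(X))) {
      stop("trait matrix rownames must cover all tip labels", call. = FALSE)
    }
    X <- X[tree$tip.label, , drop = FALSE]
  } else if (nrow(X) != length(tree$tip.label)) {
    stop("trait matrix must have one row per tip", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2) {
    stop("need at least p + 2 tips for p traits", call. = FALSE)
  }
  if (qr(scale(X, scale = FALSE))$rank < p) {
    warning("rank-deficient trait matrix; covariance is singular and the ",
            "bootstrap uses its positive part")
  }
  C <- phyloCovarianceMatrix(tree)
  fit <- .mvBmFit(X, C)
  CC <- chol(C)
  RR <- .matSqrt(fit$R)
  one <- rep(1, n)
  boot <- withSeed(seed, {
    arr <- array(NA_real_, c(p, p, B))
    for (b in seq_len(B)) {
      Z <- matrix(rnorm(n * p), n, p)
      Xb <- tcrossprod(one, fit$rootMean) + t(CC) %*% Z %*% RR
      arr[, , b] <- .mvBmFit(Xb, C)$R
    }
    arr
  })
  lower <- apply(boot, c(1, 2), quantile, probs = 0.025)
  upper <- apply(boot, c(1, 2), quantile, probs = 0.975)
  sig <- (lower > 0) | (upper < 0)
  diag(sig) <- NA
  dimnames(fit$R) <- list(colnames(X), colnames(X))
  dimnames(lower) <- dimnames(upper) <- dimnames(sig) <- dimnames(fit$R)
  new("PhyloCovarianceResult", cov = fit$R,
      rootMean = setNames(fit$rootMean, colnames(X)),
      lower = lower, upper = upper, significant = sig,
      B = as.integer(B), seed = as.integer(seed))
}

#' Log-transform a TPM matrix
#'
#' The package's variance-stabilizing convention for expression traits:
#' `log(TPM + 1)`.
#'
#' @param tpm nonnegative numeric matrix.
#' @return transformed matrix.
#' @export
logTpm <- function(tpm) {
  if (any(tpm < 0)) stop("TPM must be nonnegative", call. = FALSE)
  log(tpm + 1)
}

#' Phylomorphospace PCA of the evolutionary covariance
#'
#' Eigendecomposition of the evolutionary covariance matrix; tip scores are
#' the root-centered traits projected on the eigenvectors, ancestral node
#' scores are projected from per-trait [asrBM()] states, and variance
#' fractions are eigenvalues over the trace.
#'
#' @param result a [PhyloCovarianceResult-class] from [phyloCovariance()].
#' @param traits the tip-by-trait matrix used to fit it.
#' @param tree the tree used to fit it.
#' @return list with `scores` (tips x PCs), `ancestralScores` (internal
#'   nodes x PCs), `loadings` (orthonormal columns), `eigenvalues` and
#'   `varianceFractions`.
#' @export
phylomorphospacePCA <- function(result, traits, tree) {
  X <- as.matrix(traits)[tree$tip.label, , drop = FALSE]
  R <- covMatrix(result)
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  V <- e$vectors
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  rownames(V) <- colnames(X)
  a <- rootMean(result)
  scores <- sweep(X, 2, a) %*% V
  anc <- sapply(colnames(X), function(tr) {
    asrBM(setNames(X[, tr], rownames(X)), tree, sigma2 = 1)$estimate
  })
  anc <- matrix(anc, ncol = ncol(X), dimnames = list(NULL, colnames(X)))
  ancScores <- sweep(anc, 2, a) %*% V
  rownames(ancScores) <- as.character(length(tree$tip.label) +
                                        seq_len(tree$Nnode))
  vf <- e$values / sum(e$values)
  list(scores = scores, ancestralScores = ancScores, loadings = V,
       eigenvalues = e$values, varianceFractions = vf)
}
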