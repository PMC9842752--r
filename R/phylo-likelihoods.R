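## Likelihoods for continuous-trait models on a phylogeny. The BM likelihood
## uses Felsenstein pruning (contrasts); OU and EB evaluate dense Gaussian
## densities under their model covariances; the jump-normal likelihood is
## mixture pruning compiled in C++.

## Align a named trait vector to tree tip order; unnamed vectors are taken
## to be in tip order already.
.alignTrait <- function(trait, tree) {
  tips <- tree$tip.label
  if (!is.null(names(trait))) {
    if (!all(tips %in% names(trait))) {
      stop("trait vector must be named with all tip labels", call. = FALSE)
    }
    trait <- trait[tips]
  } else if (length(trait) != length(tips)) {
    stop("trait length must equal the number of tips", call. = FALSE)
  }
  as.numeric(trait)
}

## Fold a list of child messages (mean, var-above-node in time units) into
## one, accumulating the log-likelihood of the implied contrasts at unit
## rate. Used by BM pruning and the ASR downpass.
.foldMessages <- function(means, vars) {
  m <- means[1]; v <- vars[1]; ll <- 0
  for (i in seq_along(means)[-1]) {
    s <- v + vars[i]
    ll <- ll + stats::dnorm(m, means[i], sqrt(s), log = TRUE)
    m <- (m * vars[i] + means[i] * v) / s
    v <- v * vars[i] / s
  }
  list(mean = m, var = v, ll = ll)
}

## Postorder traversal core for BM pruning: returns per-node conditional
## (mean, var) plus the accumulated unit-rate contrast log-likelihood.
.bmDownpass <- function(trait, tree) {
  tree <- stats::reorder(tree, "postorder")
  nTip <- length(tree$tip.label)
  nAll <- nTip + tree$Nnode
  mean <- numeric(nAll); vvar <- numeric(nAll)
  mean[seq_len(nTip)] <- trait
  ll <- 0
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  for (node in unique(tree$edge[, 1])) {  # postorder: children first
    es <- kids[[as.character(node)]]
    ch <- tree$edge[es, 2]
    f <- .foldMessages(mean[ch], vvar[ch] + tree$edge.length[es])
    mean[node] <- f$mean; vvar[node] <- f$var
    ll <- ll + f$ll
  }
  root <- nTip + 1L
  list(mean = mean, var = vvar, ll = ll, root = root, tree = tree)
}

#' Brownian-motion log-likelihood
#'
#' Log-density of the tip values under BM with rate `sigma2` and root state
#' `root`: multivariate normal with mean `root * 1` and covariance
#' `sigma2 * C`, evaluated by Felsenstein pruning.
#'
#' @param trait numeric tip values, named by tip label (or in tip order).
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @param sigma2 BM rate (trait^2 per unit time), > 0.
#' @param root root state.
#' @return log-likelihood (scalar). `sigma2 <= 0` returns `-Inf` with a
#'   warning.
#' @export
bmLogLik <- function(trait, tree, sigma2, root) {
  if (sigma2 <= 0) {
    warning("sigma2 must be positive; returning -Inf")
    return(-Inf)
  }
  x <- .alignTrait(trait, tree)
  tr <- stats::reorder(tree, "postorder")
  nTip <- length(tr$tip.label)
  nAll <- nTip + tr$Nnode
  mean <- numeric(nAll); vvar <- numeric(nAll)
  mean[seq_len(nTip)] <- x
  ll <- 0
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  for (node in unique(tr$edge[, 1])) {
    es <- kids[[as.character(node)]]
    ch <- tr$edge[es, 2]
    f <- .foldMessages(mean[ch], vvar[ch] + sigma2 * tr$edge.length[es])
    mean[node] <- f$mean; vvar[node] <- f$var
    ll <- ll + f$ll
  }
  rootNode <- nTip + 1L
  ll + stats::dnorm(mean[rootNode], root, sqrt(vvar[rootNode]), log = TRUE)
}

## Dense Gaussian log-density given covariance V (used by OU/EB/lambda).
.mvnLogLik <- function(x, meanVec, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  z <- backsolve(ch, x - meanVec, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

## GLS mean and ML rate given a unit covariance V0 (V = sigma2 * V0).
## Returns list(mean, sigma2, logLik).
.glsProfile <- function(x, V0) {
  ch <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(ch)) return(list(logLik = -Inf))
  n <- length(x)
  one <- rep(1, n)
  w1 <- backsolve(ch, one, transpose = TRUE)
  wx <- backsolve(ch, x, transpose = TRUE)
  a <- sum(w1 * wx) / sum(w1 * w1)
  q <- sum((wx - a * w1)^2)
  s2 <- q / n
  if (s2 <= 0) return(list(mean = a, sigma2 = 0, logLik = Inf))
  ll <- -0.5 * n * log(2 * pi) - 0.5 * n * log(s2) - sum(log(diag(ch))) -
    0.5 * q / s2
  list(mean = a, sigma2 = s2, logLik = ll)
}

#' Ornstein-Uhlenbeck model covariance (root fixed at the optimum)
#'
#' Unit-rate OU covariance on an ultrametric tree of height `T`:
#' `V_ij = (1 / (2 alpha)) * exp(-2 alpha (T - s_ij)) * (1 - exp(-2 alpha s_ij))`,
#' where `s_ij` is the shared path length. Multiply by `sigma2` for the full
#' covariance.
#'
#' @param tree ultrametric `ape::phylo`.
#' @param alpha pull strength, > 0.
#' @return unit covariance matrix over tips.
#' @export
ouCovariance <- function(tree, alpha) {
  s <- phyloCovarianceMatrix(tree)
  T <- max(diag(s))
  (1 / (2 * alpha)) * exp(-2 * alpha * (T - s)) * (1 - exp(-2 * alpha * s))
}

#' Early-burst model covariance
#'
#' Unit-rate EB covariance: `V_ij = (exp(r s_ij) - 1) / r` with
#' nonpositive `r`; the limit of `r` at 0 is BM (`V_ij = s_ij`), handled
#' analytically.
#'
#' @param tree `ape::phylo`.
#' @param r rate-decay exponent, `<= 0`.
#' @return unit covariance matrix over tips.
#' @export
ebCovariance <- function(tree, r) {
  s <- phyloCovarianceMatrix(tree)
  if (abs(r) < 1e-12) return(s)
  (exp(r * s) - 1) / r
}

#' Ornstein-Uhlenbeck log-likelihood (root at the optimum)
#'
#' Gaussian log-density under the OU covariance of [ouCovariance()] scaled
#' by `sigma2`, with mean `theta`.
#'
#' @inheritParams bmLogLik
#' @param alpha pull strength, > 0.
#' @param theta optimum (= root state).
#' @return log-likelihood (scalar).
#' @export
ouLogLik <- function(trait, tree, sigma2, alpha, theta) {
  x <- .alignTrait(trait, tree)
  .mvnLogLik(x, rep(theta, length(x)), sigma2 * ouCovariance(tree, alpha))
}

#' Early-burst log-likelihood
#'
#' Gaussian log-density under the EB covariance of [ebCovariance()] scaled
#' by `sigma2`, with mean `root`.
#'
#' @inheritParams bmLogLik
#' @param r rate-decay exponent, nonpositive.
#' @return log-likelihood (scalar).
#' @export
ebLogLik <- function(trait, tree, sigma2, r, root) {
  x <- .alignTrait(trait, tree)
  .mvnLogLik(x, rep(root, length(x)), sigma2 * ebCovariance(tree, r))
}

#' Jump-normal (pulsed Levy) log-likelihood
#'
#' Displacement over a branch of length `t` is `N(0, sigma2 t)` convolved
#' with a Poisson(`lambdaJ t`) number of `N(0, delta2)` jumps. Evaluated by
#' pruning with finite normal-mixture messages: the per-branch jump count is
#' truncated at the smallest K with Poisson tail mass below `tailTol`;
#' components with relative weight below `pruneTol` are dropped and mixtures
#' are merged by moment matching down to at most `cap` components.
#'
#' @inheritParams bmLogLik
#' @param lambdaJ jump rate (jumps per unit time), >= 0.
#' @param delta2 jump variance, >= 0.
#' @param tailTol Poisson truncation tail mass, default 1e-8.
#' @param pruneTol relative component-weight floor, default 1e-10.
#' @param cap maximum mixture size, default 256.
#' @return log-likelihood (scalar).
#' @export
jnLogLik <- function(trait, tree, sigma2, lambdaJ, delta2, root,
                     tailTol = 1e-8, pruneTol = 1e-10, cap = 256L) {
  if (sigma2 < 0 || lambdaJ < 0 || delta2 < 0) {
    warning("sigma2, lambdaJ and delta2 must be nonnegative; returning -Inf")
    return(-Inf)
  }
  x <- .alignTrait(trait, tree)
  tr <- stats::reorder(tree, "postorder")
  jn_loglik_cpp(tr$edge, tr$edge.length, x, length(tr$tip.label),
                length(tr$tip.label) + tr$Nnode, sigma2, lambdaJ, delta2,
                root, tailTol, pruneTol, as.integer(cap))
}
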