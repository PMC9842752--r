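## Maximum-likelihood fits of the four trait-evolution models and AIC-weight
## model selection. OU, EB and lambda use profile likelihoods (the GLS mean
## and ML rate are closed-form given the shape parameter), so their searches
## are one-dimensional multi-start grids refined by Brent's method. The
## jump-normal fit is a derivative-free simplex over log-parameters.

.makeFit <- function(model, params, logLik, k, convergence = 0) {
  new("ModelFit", model = model, params = params, logLik = logLik,
      k = as.numeric(k), AIC = 2 * k - 2 * logLik, weight = NA_real_,
      convergence = as.numeric(convergence))
}

## 1-D maximizer: coarse grid then optimize() on the bracketing interval.
.gridRefine <- function(f, grid) {
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo == hi) return(list(par = grid[i], value = vals[i]))
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)
  if (opt$objective >= vals[i]) list(par = opt$maximum, value = opt$objective)
  else list(par = grid[i], value = vals[i])
}

#' Fit Brownian motion by maximum likelihood
#'
#' Closed-form GLS: root estimate `a = (1'C^-1 1)^-1 1'C^-1 x` and ML rate
#' `sigma2 = (x - a 1)' C^-1 (x - a 1) / n` (divisor n). Two free
#' parameters. A constant trait yields `sigma2 = 0` and a degenerate fit
#' (flagged via `convergence = 2` and non-finite log-likelihood).
#'
#' @param trait numeric tip values, named by tip label (or in tip order).
#' @param tree rooted `ape::phylo` with branch lengths; at least 3 tips.
#' @return A [ModelFit-class].
#' @export
fitBM <- function(trait, tree) {
  x <- .alignTrait(trait, tree)
  C <- phyloCovarianceMatrix(tree)
  prof <- .glsProfile(x, C)
  if (!is.finite(prof$logLik) && is.infinite(prof$logLik) && prof$logLik > 0) {
    warning("constant trait: sigma2 = 0, degenerate BM fit")
    return(.makeFit("BM", c(sigma2 = 0, root = prof$mean), NA_real_, 2,
                    convergence = 2))
  }
  if (!is.finite(prof$logLik)) {
    stop("singular phylogenetic covariance; consider collapsing ",
         "zero-length branches", call. = FALSE)
  }
  .makeFit("BM", c(sigma2 = prof$sigma2, root = prof$mean), prof$logLik, 2)
}

#' Fit the Ornstein-Uhlenbeck model (root at the optimum)
#'
#' ML over `(sigma2, alpha, theta)` with the root fixed at the optimum
#' `theta` and covariance
#' `sigma2 / (2 alpha) * exp(-2 alpha (T - s)) * (1 - exp(-2 alpha s))`.
#' `theta` and `sigma2` are profiled in closed form given `alpha`; `alpha`
#' is maximized over a log-spaced multi-start grid spanning at least
#' `[1e-3 / T, 10 / T]`, refined by Brent's method. Three free parameters.
#'
#' @inheritParams fitBM
#' @param nGrid size of the log-spaced alpha grid (default 40).
#' @return A [ModelFit-class] with params `sigma2`, `alpha`, `theta`.
#' @export
fitOU <- function(trait, tree, nGrid = 40L) {
  if (!isUltrametricTree(tree)) {
    stop("OU fit requires an ultrametric tree", call. = FALSE)
  }
  x <- .alignTrait(trait, tree)
  T <- treeHeight(tree)
  s <- phyloCovarianceMatrix(tree)
  profileAt <- function(logAlpha) {
    alpha <- exp(logAlpha)
    V0 <- (1 / (2 * alpha)) * exp(-2 * alpha * (T - s)) *
      (1 - exp(-2 * alpha * s))
    .glsProfile(x, V0)$logLik
  }
  grid <- log(exp(seq(log(1e-4 / T), log(50 / T), length.out = nGrid)))
  best <- .gridRefine(profileAt, grid)
  alpha <- exp(best$par)
  V0 <- (1 / (2 * alpha)) * exp(-2 * alpha * (T - s)) *
    (1 - exp(-2 * alpha * s))
  prof <- .glsProfile(x, V0)
  .makeFit("OU", c(sigma2 = prof$sigma2, alpha = alpha, theta = prof$mean),
           prof$logLik, 3)
}

#' Fit the early-burst model
#'
#' ML over `(sigma2, r, root)` with nonpositive `r` and covariance
#' `sigma2 * (exp(r s) - 1) / r`; the limit of `r` at 0 recovers BM and is
#' handled analytically. `root` and `sigma2` are profiled; `r` is maximized
#' over a grid on `[-20 / T, 0]` refined by Brent's method. Three free
#' parameters.
#'
#' @inheritParams fitOU
#' @return A [ModelFit-class] with params `sigma2`, `r`, `root`.
#' @export
fitEB <- function(trait, tree, nGrid = 40L) {
  if (!isUltrametricTree(tree)) {
    stop("EB fit requires an ultrametric tree", call. = FALSE)
  }
  x <- .alignTrait(trait, tree)
  T <- treeHeight(tree)
  s <- phyloCovarianceMatrix(tree)
  profileAt <- function(r) {
    V0 <- if (abs(r) < 1e-12) s else (exp(r * s) - 1) / r
    .glsProfile(x, V0)$logLik
  }
  grid <- seq(-20 / T, 0, length.out = nGrid)
  best <- .gridRefine(profileAt, grid)
  r <- min(best$par, 0)
  V0 <- if (abs(r) < 1e-12) s else (exp(r * s) - 1) / r
  prof <- .glsProfile(x, V0)
  .makeFit("EB", c(sigma2 = prof$sigma2, r = r, root = prof$mean),
           prof$logLik, 3)
}

#' Fit the jump-normal (pulsed Levy) model
#'
#' ML over `(sigma2, lambdaJ, delta2, root)` of the compound
#' Brownian-plus-Poisson-jumps process, using the mixture-pruning likelihood
#' [jnLogLik()] and Nelder-Mead over log-scale parameters with structured
#' restarts seeded from the BM fit. Four free parameters.
#'
#' @inheritParams fitOU
#' @param nRestarts number of optimizer starts (default 2; the starts split
#'   the BM variance between drift and jumps in different proportions).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param cap mixture-size cap used during optimization (default 32). The
#'   pruning messages are merged down to this many components per node; the
#'   resulting log-likelihood error is orders of magnitude below the AIC
#'   differences that drive model selection, while the fit runs an order of
#'   magnitude faster than at the evaluation default of [jnLogLik()].
#' @return A [ModelFit-class] with params `sigma2`, `lambdaJ`, `delta2`,
#'   `root`.
#' @export
fitJN <- function(trait, tree, nRestarts = 2L, maxit = 300L, cap = 32L) {
  if (!isUltrametricTree(tree)) {
    stop("JN fit requires an ultrametric tree", call. = FALSE)
  }
  x <- .alignTrait(trait, tree)
  T <- treeHeight(tree)
  bm <- fitBM(setNames(x, tree$tip.label), tree)
  s2bm <- max(modelParams(bm)[["sigma2"]], 1e-10)
  tr <- stats::reorder(tree, "postorder")
  nTip <- length(tr$tip.label)
  nAll <- nTip + tr$Nnode
  ## the root state never enters the pruning pass, so it is profiled out:
  ## one pass yields the root mixture, whose mode is the ML root.
  profiled <- function(p) {
    mix <- jn_root_mixture_cpp(tr$edge, tr$edge.length, x, nTip, nAll,
                               exp(p[1]), exp(p[2]), exp(p[3]),
                               1e-8, 1e-10, as.integer(cap))
    if (!isTRUE(mix$ok)) return(list(logLik = -Inf, root = NA_real_))
    sdv <- sqrt(pmax(mix$v, 1e-300))
    dens <- function(a) sum(mix$w * stats::dnorm(a, mix$mu, sdv))
    ## candidates: highest-weight component means
    topI <- utils::head(order(mix$w, decreasing = TRUE), 8L)
    cands <- unique(c(mix$mu[topI], sum(mix$w * mix$mu) / sum(mix$w)))
    vals <- vapply(cands, dens, numeric(1))
    bi <- which.max(vals)
    spread <- sqrt(max(mix$v)) + 1e-8
    opt <- stats::optimize(dens, c(cands[bi] - 2 * spread,
                                   cands[bi] + 2 * spread), maximum = TRUE)
    if (opt$objective >= vals[bi]) {
      a <- opt$maximum; d <- opt$objective
    } else {
      a <- cands[bi]; d <- vals[bi]
    }
    if (d <= 0) return(list(logLik = -Inf, root = NA_real_))
    list(logLik = log(d) + mix$logScale, root = a)
  }
  ## optimization runs over (log sigma2, log vJ, log delta2) where
  ## vJ = lambdaJ * delta2 is the jump contribution to the variance per
  ## unit time: this keeps the BM-like ridge (lambda large, delta2 small)
  ## well conditioned. Box guards keep the simplex out of regions where the
  ## Poisson truncation would explode.
  lamMax <- 60 / T
  negLL <- function(q) {
    if (any(!is.finite(q)) || any(abs(q) > 30)) return(1e10)
    lam <- exp(q[2] - q[3])
    if (lam > lamMax) return(1e10)
    ll <- profiled(c(q[1], log(lam), q[3]))$logLik
    if (!is.finite(ll)) 1e10 else -ll
  }
  ## starts: split the BM tip variance sigma2_bm * T between drift and jumps
  props <- c(0.7, 0.2, 0.5, 0.9, 0.35)[seq_len(max(1L, nRestarts))]
  rates <- c(1, 0.5, 2, 1, 0.5)[seq_len(max(1L, nRestarts))] / T
  best <- NULL
  for (i in seq_along(props)) {
    d2 <- (1 - props[i]) * s2bm / rates[i]
    st <- c(log(props[i] * s2bm),
            log((1 - props[i]) * s2bm),  # vJ = lambda * delta2
            log(d2))
    op <- stats::optim(st, negLL, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-7))
    if (is.null(best) || op$value < best$value) best <- op
  }
  op <- stats::optim(best$par, negLL, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-8))
  if (op$value > best$value) op <- best
  q <- op$par
  p <- c(q[1], q[2] - q[3], q[3])
  pr <- profiled(p)
  .makeFit("JN",
           c(sigma2 = exp(p[1]), lambdaJ = exp(p[2]), delta2 = exp(p[3]),
             root = pr$root),
           pr$logLik, 4, convergence = op$convergence)
}

#' Fit all four models and attach AIC weights
#'
#' Convenience wrapper running [fitBM()], [fitOU()], [fitEB()] and
#' [fitJN()] on the same trait and applying [aicWeights()].
#'
#' @inheritParams fitBM
#' @param models subset of `c("BM", "OU", "EB", "JN")`.
#' @param ... passed to [fitJN()].
#' @return named list of [ModelFit-class] objects with weights set.
#' @export
fitTraitModels <- function(trait, tree, models = c("BM", "OU", "EB", "JN"),
                           ...) {
  fits <- list()
  if ("BM" %in% models) fits$BM <- fitBM(trait, tree)
  if ("OU" %in% models) fits$OU <- fitOU(trait, tree)
  if ("EB" %in% models) fits$EB <- fitEB(trait, tree)
  if ("JN" %in% models) fits$JN <- fitJN(trait, tree, ...)
  aicWeights(fits)
}

#' Akaike weights over a set of model fits
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min AIC`. Weights sum to 1.
#'
#' @param fits list of [ModelFit-class] objects fitted to the same data.
#' @return the list with `weight` slots filled in.
#' @export
aicWeights <- function(fits) {
  aic <- vapply(fits, function(f) f@AIC, numeric(1))
  if (any(!is.finite(aic))) {
    stop("all fits must have finite AIC for weighting", call. = FALSE)
  }
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w <- w / sum(w)
  for (i in seq_along(fits)) fits[[i]]@weight <- w[[i]]
  fits
}

#' Tabulate a list of model fits
#'
#' @param fits named list of [ModelFit-class] objects.
#' @return data.frame with model, parameters, logLik, AIC and weight.
#' @export
modelFitTable <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f@model,
               params = paste(sprintf("%s=%.6g", names(f@params), f@params),
                              collapse = ","),
               logLik = f@logLik, k = f@k, AIC = f@AIC, weight = f@weight,
               row.names = NULL)
  }))
}
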