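## Diploid copy number from multiplex qPCR triplicates by delta-delta-Ct:
## triplicate QC, the estimator, assay-efficiency checking, and the
## population comparison (two-way type II ANOVA + Tukey HSD with letters).

#' Filter qPCR triplicates by Cq tolerance
#'
#' Within each individual x plate group and for each gene separately: if the
#' maximum pairwise Cq difference is within `tol`, all reactions are kept;
#' otherwise the single reaction whose removal brings the remaining pair
#' within `tol` (the most outlying by distance to the pair mean) is
#' dropped; if no single removal suffices the whole triplicate is dropped.
#' Because reactions are multiplex, a reaction dropped for one gene is
#' dropped for both. Groups with fewer than 2 surviving reactions are
#' excluded entirely.
#'
#' @param records data.frame with columns `individual`, `population`,
#'   `plate`, `replicate`, `cq_target`, `cq_control`.
#' @param tol maximum pairwise deviation in cycles, default 0.2.
#' @return list with `retained` (data.frame), `dropLog` (data.frame:
#'   individual, plate, replicate, reason) and `excluded` (data.frame:
#'   individual, plate, reason).
#' @export
filterTriplicates <- function(records, tol = 0.2) {
  need <- c("individual", "plate", "replicate", "cq_target", "cq_control")
  stopifnot(all(need %in% names(records)))
  keyOf <- interaction(records$individual, records$plate, drop = TRUE)
  keep <- logical(nrow(records))
  dropLog <- list(); excluded <- list()
  for (key in levels(keyOf)) {
    idx <- which(keyOf == key)
    grp <- records[idx, ]
    dropRep <- integer(0)
    for (gene in c("cq_target", "cq_control")) {
      cq <- grp[[gene]]
      live <- !is.na(cq)
      if (sum(live) < 2) next
      spread <- max(cq[live]) - min(cq[live])
      if (spread <= tol) next
      ## try removing each single reaction
      feasible <- vapply(which(live), function(i) {
        rest <- cq[live][which(live) != i]
        length(rest) < 2 || (max(rest) - min(rest)) <= tol
      }, logical(1))
      if (any(feasible)) {
        cand <- which(live)[feasible]
        outly <- vapply(cand, function(i) {
          rest <- cq[setdiff(which(live), i)]
          abs(cq[i] - mean(rest))
        }, numeric(1))
        dropRep <- union(dropRep, grp$replicate[cand[which.max(outly)]])
      } else {
        dropRep <- union(dropRep, grp$replicate[live])  # whole triplicate
      }
    }
    if (length(dropRep)) {
      ## re-check both genes after multiplex-coupled removal
      surv <- !(grp$replicate %in% dropRep)
      for (gene in c("cq_target", "cq_control")) {
        cq <- grp[[gene]][surv]
        cq <- cq[!is.na(cq)]
        if (length(cq) >= 2 && (max(cq) - min(cq)) > tol) {
          dropRep <- union(dropRep, grp$replicate)
          surv <- rep(FALSE, nrow(grp))
        }
      }
      dropLog[[key]] <- data.frame(individual = grp$individual[1],
                                   plate = grp$plate[1],
                                   replicate = sort(dropRep),
                                   reason = "cq_deviation")
    } else {
      surv <- rep(TRUE, nrow(grp))
    }
    if (sum(surv) < 2) {
      excluded[[key]] <- data.frame(individual = grp$individual[1],
                                    plate = grp$plate[1],
                                    reason = "fewer than 2 surviving reactions")
      surv <- rep(FALSE, nrow(grp))
    }
    keep[idx] <- surv
  }
  list(retained = records[keep, , drop = FALSE],
       dropLog = if (length(dropLog)) do.call(rbind, c(dropLog,
                                                       make.row.names = FALSE))
                 else data.frame(individual = character(0),
                                 plate = character(0),
                                 replicate = integer(0),
                                 reason = character(0)),
       excluded = if (length(excluded)) do.call(rbind, c(excluded,
                                                         make.row.names = FALSE))
                  else data.frame(individual = character(0),
                                  plate = character(0),
                                  reason = character(0)))
}

#' Estimate diploid copy number by delta-delta-Ct
#'
#' Per reaction, `dCt = Cq_target - Cq_control`; each individual's mean dCt
#' is the mean over its retained reactions; `ddCt` is relative to the
#' calibrator's mean dCt, and the diploid copy number is
#' `calibratorCopies * 2^(-ddCt)`.
#'
#' @param records retained reactions from [filterTriplicates()].
#' @param calibrator identifier of the reference individual of known copy
#'   number.
#' @param calibratorCopies the calibrator's diploid copy number, default 1.
#' @return data.frame with `individual`, `population`, `meanDeltaCt`,
#'   `deltaDeltaCt`, `copyNumber`.
#' @export
estimateCopyNumber <- function(records, calibrator, calibratorCopies = 1) {
  records <- records[!is.na(records$cq_target) & !is.na(records$cq_control), ]
  if (!calibrator %in% records$individual) {
    stop("calibrator '", calibrator, "' missing from retained records",
         call. = FALSE)
  }
  dct <- records$cq_target - records$cq_control
  meanDct <- tapply(dct, records$individual, mean)
  pop <- tapply(as.character(records$population), records$individual,
                `[`, 1L)
  ddct <- meanDct - meanDct[[calibrator]]
  data.frame(individual = names(meanDct),
             population = as.character(pop[names(meanDct)]),
             meanDeltaCt = as.numeric(meanDct),
             deltaDeltaCt = as.numeric(ddct),
             copyNumber = calibratorCopies * 2^(-as.numeric(ddct)),
             row.names = NULL)
}

#' Fit qPCR assay efficiency from a dilution series
#'
#' Ordinary least squares of Cq on log10(input mass); the efficiency is
#' `10^(-1/slope) - 1` and is accepted in the recommended 90-110% range.
#' A perfect doubling assay has slope -3.3219 (efficiency 100%).
#'
#' @param mass input DNA mass per reaction (ng), at least 3 distinct values.
#' @param cq observed Cq values.
#' @param gene assay label.
#' @return An [EfficiencyFit-class].
#' @export
fitEfficiency <- function(mass, cq, gene = "assay") {
  if (length(unique(mass)) < 3) {
    stop("need at least 3 distinct input masses", call. = FALSE)
  }
  fit <- stats::lm(cq ~ log10(mass))
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    warning("non-negative dilution slope; assay is not amplifying as expected")
  } else {
    meanCq <- tapply(cq, mass, mean)
    meanCq <- meanCq[order(as.numeric(names(meanCq)))]
    if (any(diff(meanCq) > 0)) {
      warning("dilution series not monotonic in mean Cq beyond noise")
    }
  }
  E <- 10^(-1 / slope) - 1
  new("EfficiencyFit", gene = gene, slope = slope, efficiency = E,
      accepted = is.finite(E) && E >= 0.90 && E <= 1.10)
}

## Compact letter display by insert-and-absorb from a symmetric logical
## "not significantly different" matrix.
.letterDisplay <- function(nsd) {
  gn <- rownames(nsd)
  letters_ <- list()
  for (g in gn) {
    placed <- FALSE
    for (i in seq_along(letters_)) {
      if (all(nsd[g, letters_[[i]]])) {
        letters_[[i]] <- c(letters_[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) letters_[[length(letters_) + 1L]] <- g
  }
  ## absorb letters contained in others
  keep <- rep(TRUE, length(letters_))
  for (i in seq_along(letters_)) for (j in seq_along(letters_)) {
    if (i != j && keep[i] && keep[j] &&
        all(letters_[[i]] %in% letters_[[j]])) {
      keep[i] <- FALSE
    }
  }
  letters_ <- letters_[keep]
  out <- vapply(gn, function(g) {
    paste0(letters[which(vapply(letters_, function(s) g %in% s,
                                logical(1)))], collapse = "")
  }, character(1))
  out
}

#' Two-way ANOVA and Tukey HSD on copy-number estimates
#'
#' Fits `copyNumber ~ population * plate` with type II sums of squares (to
#' accommodate the unbalanced design) and runs Tukey-Kramer pairwise
#' comparisons on population at `alpha`, with a compact letter display.
#' Populations with fewer than 2 individuals are excluded with a warning.
#'
#' @param estimates data.frame from [estimateCopyNumber()].
#' @param populations,plates vectors aligned with `estimates` rows; when
#'   `NULL`, taken from `estimates$population` / `estimates$plate`.
#' @param alpha familywise error rate for Tukey, default 0.05.
#' @return list with `anova` (type II table), `tukey` (data.frame of
#'   pairwise comparisons) and `letters` (named letter groups).
#' @export
populationAnova <- function(estimates, populations = NULL, plates = NULL,
                            alpha = 0.05) {
  df <- data.frame(
    copyNumber = estimates$copyNumber,
    population = factor(if (is.null(populations)) estimates$population
                        else populations),
    plate = factor(if (is.null(plates)) estimates$plate else plates)
  )
  sizes <- table(df$population)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("population(s) with < 2 individuals excluded: ",
            paste(small, collapse = ", "))
    df <- droplevels(df[!df$population %in% small, ])
  }
  if (nlevels(df$population) < 2) {
    stop("need at least 2 populations with >= 2 individuals", call. = FALSE)
  }
  fullInteraction <- nlevels(df$plate) > 1 &&
    all(table(df$population, df$plate) > 0)
  form <- if (fullInteraction) copyNumber ~ population * plate
          else copyNumber ~ population + plate
  if (nlevels(df$plate) < 2) form <- copyNumber ~ population
  fit <- stats::aov(form, data = df)
  a2 <- car::Anova(fit, type = 2)
  tk <- stats::TukeyHSD(fit, which = "population", conf.level = 1 - alpha)
  tkdf <- as.data.frame(tk$population)
  tkdf$comparison <- rownames(tkdf)
  rownames(tkdf) <- NULL
  names(tkdf) <- c("diff", "lower", "upper", "pAdj", "comparison")
  ## letter display from the "not significantly different" relation
  lev <- levels(df$population)
  nsd <- matrix(TRUE, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_len(nrow(tkdf))) {
    pair <- strsplit(tkdf$comparison[i], "-", fixed = TRUE)[[1]]
    if (tkdf$pAdj[i] < alpha) {
      nsd[pair[1], pair[2]] <- nsd[pair[2], pair[1]] <- FALSE
    }
  }
  means <- tapply(df$copyNumber, df$population, mean)
  ord <- names(sort(means, decreasing = TRUE))
  lett <- .letterDisplay(nsd[ord, ord, drop = FALSE])
  list(anova = a2, tukey = tkdf, letters = lett)
}
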