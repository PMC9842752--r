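## The venom expression phenotype: family-level composition, dominant-family
## classification, species-level pooling, and cysteine frameworks.

#' Aggregate transcript TPM into a family-level venom phenotype
#'
#' Sums TPM over the transcripts annotated to each toxin family and divides
#' by the total annotated TPM to obtain family fractions — the venom
#' expression phenotype. Transcripts present in the expression table but
#' absent from the annotation are ignored; annotated transcripts missing
#' from the expression table are an error. Samples whose total annotated TPM
#' is zero are flagged undefined and carry `NA` fractions.
#'
#' @param expr numeric matrix, samples x transcripts (TPM), e.g. from
#'   [readExpressionTable()].
#' @param annot data.frame with columns `transcript`, `family`, e.g. from
#'   [readToxinAnnotation()].
#' @param families optional character vector declaring the family set (and
#'   column order); families without transcripts get zero TPM.
#' @return A [FamilyComposition-class] object.
#' @examples
#' expr <- matrix(c(100, 50, 150), 1, dimnames = list("s1", c("t1", "t2", "t3")))
#' ann <- data.frame(transcript = c("t1", "t2", "t3"),
#'                   family = c("NaTx", "NaTx", "KTx3"))
#' compositionFractions(aggregateFamilyExpression(expr, ann))
#' @export
aggregateFamilyExpression <- function(expr, annot, families = NULL) {
  missing <- setdiff(annot$transcript, colnames(expr))
  if (length(missing)) {
    stop("annotated transcript(s) absent from expression table: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(families)) families <- sort(unique(annot$family))
  tpm <- matrix(0, nrow(expr), length(families),
                dimnames = list(rownames(expr), families))
  for (fam in intersect(families, unique(annot$family))) {
    tr <- annot$transcript[annot$family == fam]
    tpm[, fam] <- rowSums(expr[, tr, drop = FALSE])
  }
  tot <- rowSums(tpm)
  defined <- tot > 0
  frac <- tpm / ifelse(tot > 0, tot, NA_real_)
  frac[!defined, ] <- NA_real_
  if (any(!defined)) {
    vdLog("sample(s) with zero annotated TPM flagged undefined: ",
          paste(rownames(tpm)[!defined], collapse = ", "), level = "warn")
  }
  new("FamilyComposition", tpm = tpm, fraction = frac, defined = defined)
}

#' Classify the dominant toxin family per sample
#'
#' Returns, per sample, the unique family whose fraction strictly exceeds
#' `threshold`, or `"none"`. At the default threshold of 0.5 at most one
#' family can qualify, so no tie-break is needed.
#'
#' @param comp a [FamilyComposition-class].
#' @param threshold dominance threshold, default 0.5.
#' @return named character vector (family label or `"none"`) per sample.
#' @export
classifyDominant <- function(comp, threshold = 0.5) {
  if (any(!comp@defined)) {
    stop("dominance undefined for sample(s) with zero annotated TPM: ",
         paste(rownames(comp@tpm)[!comp@defined], collapse = ", "),
         call. = FALSE)
  }
  fr <- comp@fraction
  out <- apply(fr, 1L, function(f) {
    hits <- which(f > threshold)
    if (length(hits) == 1L) colnames(fr)[hits] else "none"
  })
  setNames(as.character(out), rownames(fr))
}

#' Pool sample compositions to species level
#'
#' Species composition is the arithmetic mean of its samples' fraction
#' vectors, renormalized to sum to 1. Undefined samples are dropped from the
#' mean.
#'
#' @param comp a [FamilyComposition-class].
#' @param species character vector mapping each sample (row) to a species.
#' @return A [FamilyComposition-class] with one row per species (TPM slot
#'   holds the summed TPM per species).
#' @export
speciesComposition <- function(comp, species) {
  stopifnot(length(species) == nrow(comp@tpm))
  sp <- unique(species)
  tpm <- matrix(0, length(sp), ncol(comp@tpm),
                dimnames = list(sp, colnames(comp@tpm)))
  frac <- tpm
  defined <- logical(length(sp))
  for (i in seq_along(sp)) {
    rows <- which(species == sp[i] & comp@defined)
    tpm[i, ] <- colSums(comp@tpm[species == sp[i], , drop = FALSE])
    if (length(rows)) {
      m <- colMeans(comp@fraction[rows, , drop = FALSE])
      frac[i, ] <- m / sum(m)
      defined[i] <- TRUE
    } else {
      frac[i, ] <- NA_real_
    }
  }
  new("FamilyComposition", tpm = tpm, fraction = frac, defined = defined)
}

#' Write a composition table to TSV
#'
#' Long-format output: sample, family, tpm, fraction, dominant flag.
#'
#' @param comp a [FamilyComposition-class].
#' @param file output path.
#' @param threshold dominance threshold used for the flag.
#' @return the written data.frame, invisibly.
#' @export
writeCompositionTable <- function(comp, file, threshold = 0.5) {
  dom <- tryCatch(classifyDominant(comp, threshold),
                  error = function(e) rep("none", nrow(comp@tpm)))
  df <- do.call(rbind, lapply(seq_len(nrow(comp@tpm)), function(i) {
    data.frame(sample = rownames(comp@tpm)[i],
               family = colnames(comp@tpm),
               tpm = comp@tpm[i, ],
               fraction = comp@fraction[i, ],
               dominant = colnames(comp@tpm) == dom[i],
               row.names = NULL)
  }))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Cysteine framework of a mature peptide
#'
#' Encodes the number and spacing of cysteines as `"C<g1>C<g2>...C"`, where
#' each `g` is the count of residues between consecutive cysteines. Peptides
#' without cysteines yield the empty framework `""`.
#'
#' @param peptide amino-acid sequence (20-letter alphabet plus X).
#' @return framework string.
#' @examples
#' cysteineFramework("ACKCGGCC")  # "C1C2C0C"
#' @export
cysteineFramework <- function(peptide) {
  pos <- which(strsplit(toupper(peptide), "", fixed = TRUE)[[1]] == "C")
  if (length(pos) == 0L) return("")
  if (length(pos) == 1L) return("C")
  paste0(paste0("C", diff(pos) - 1L, collapse = ""), "C")
}

#' Compare two cysteine frameworks
#'
#' Frameworks match when they have the same cysteine count and each
#' inter-cysteine gap differs by at most `gapTolerance` residues. Empty
#' frameworks never match (with a warning).
#'
#' @param a,b framework strings from [cysteineFramework()].
#' @param gapTolerance nonnegative integer, default 0.
#' @return logical.
#' @export
frameworkMatch <- function(a, b, gapTolerance = 0L) {
  if (!nzchar(a) || !nzchar(b)) {
    warning("empty cysteine framework; no match possible")
    return(FALSE)
  }
  ga <- .frameworkGaps(a)
  gb <- .frameworkGaps(b)
  if (length(ga$gaps) != length(gb$gaps) || ga$n != gb$n) return(FALSE)
  all(abs(ga$gaps - gb$gaps) <= gapTolerance)
}

.frameworkGaps <- function(fw) {
  n <- lengths(regmatches(fw, gregexpr("C", fw, fixed = TRUE)))
  gaps <- regmatches(fw, gregexpr("[0-9]+", fw))[[1]]
  list(n = n, gaps = as.integer(gaps))
}
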