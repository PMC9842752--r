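## Shared IO: Newick trees, FASTA, expression/annotation tables, and the
## pipeline configuration. Trees are ape "phylo" objects throughout.

#' Construct a PipelineConfig
#'
#' All defaults are the analysis constants the pipeline applies; see the
#' class documentation for their meaning.
#'
#' @param dominanceThreshold fraction in (0, 1], default 0.5.
#' @param ampliconMinLength,ampliconMaxLength inclusive bp bounds, defaults
#'   300 and 500.
#' @param subsampleDepth default 14800 reads.
#' @param variantMinAbundance default 100 reads.
#' @param variantMinIndividuals default 2.
#' @param retentionFraction default 0.70.
#' @param minIdenticalCopies default 10.
#' @param cqTolerance default 0.2 cycles.
#' @param calibratorCopies default 1 diploid copy.
#' @param bootstrapReplicates default 1000.
#' @param seed default 1.
#' @return A [PipelineConfig-class] object.
#' @examples
#' pipelineConfig()
#' @export
pipelineConfig <- function(dominanceThreshold = 0.5,
                           ampliconMinLength = 300L,
                           ampliconMaxLength = 500L,
                           subsampleDepth = 14800L,
                           variantMinAbundance = 100L,
                           variantMinIndividuals = 2L,
                           retentionFraction = 0.70,
                           minIdenticalCopies = 10L,
                           cqTolerance = 0.2,
                           calibratorCopies = 1,
                           bootstrapReplicates = 1000L,
                           seed = 1L) {
  new("PipelineConfig",
      dominanceThreshold = dominanceThreshold,
      ampliconMinLength = as.integer(ampliconMinLength),
      ampliconMaxLength = as.integer(ampliconMaxLength),
      subsampleDepth = as.integer(subsampleDepth),
      variantMinAbundance = as.integer(variantMinAbundance),
      variantMinIndividuals = as.integer(variantMinIndividuals),
      retentionFraction = retentionFraction,
      minIdenticalCopies = as.integer(minIdenticalCopies),
      cqTolerance = cqTolerance,
      calibratorCopies = calibratorCopies,
      bootstrapReplicates = as.integer(bootstrapReplicates),
      seed = as.integer(seed))
}

#' Read / write a PipelineConfig as JSON
#'
#' @param path file path.
#' @return `readPipelineConfig` returns a [PipelineConfig-class];
#'   `writePipelineConfig` returns `path` invisibly.
#' @export
readPipelineConfig <- function(path) {
  vals <- jsonlite::fromJSON(path)
  do.call(pipelineConfig, as.list(vals))
}

#' @rdname readPipelineConfig
#' @param config a [PipelineConfig-class].
#' @export
writePipelineConfig <- function(config, path) {
  nms <- slotNames("PipelineConfig")
  vals <- lapply(nms, function(nm) slot(config, nm))
  names(vals) <- nms
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rooted tree from Newick text or file
#'
#' Parses Newick with `ape` and validates the result: unique tip labels,
#' branch lengths present and nonnegative on every edge. Tip order is
#' preserved as first encountered in the text.
#'
#' @param text Newick string (used when `file` is `NULL`).
#' @param file optional path to a Newick file.
#' @return An `ape::phylo` tree.
#' @examples
#' tr <- readNewick("((A:1,B:1):1,C:2);")
#' treeHeight(tr)  # 2
#' @export
readNewick <- function(text = NULL, file = NULL) {
  tr <- tryCatch(
    if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(tr) || inherits(tr, "multiPhylo")) {
    stop("Newick parse error: expected exactly one valid tree", call. = FALSE)
  }
  validatePhylo(tr)
  tr
}

#' Validate a phylo object for comparative analysis
#'
#' Checks the invariants every downstream model assumes: a single root,
#' unique tip labels, and finite nonnegative branch lengths on all edges.
#'
#' @param tree an `ape::phylo`.
#' @return `tree`, invisibly, or an error naming the offending element.
#' @export
validatePhylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("missing branch lengths on all edges", call. = FALSE)
  }
  bad <- which(!is.finite(tree$edge.length) | tree$edge.length < 0)
  if (length(bad)) {
    child <- tree$edge[bad[1], 2]
    nm <- if (child <= length(tree$tip.label)) tree$tip.label[child]
          else paste0("internal node ", child)
    stop("missing or negative branch length on edge to ", nm, call. = FALSE)
  }
  invisible(tree)
}

#' Write a tree to Newick
#'
#' @param tree an `ape::phylo`.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
writeNewick <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

#' Tree height (maximum root-to-tip path length)
#'
#' @param tree an `ape::phylo`.
#' @return numeric scalar.
#' @export
treeHeight <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' Check ultrametricity
#'
#' All root-to-tip path lengths must agree within a relative tolerance of
#' the tree height.
#'
#' @param tree an `ape::phylo`.
#' @param rtol relative tolerance, default `1e-6`.
#' @return logical.
#' @export
isUltrametricTree <- function(tree, rtol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  h <- max(d)
  if (h == 0) return(TRUE)
  (max(d) - min(d)) <= rtol * h
}

#' Brownian-motion covariance matrix of a tree
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j;
#' the diagonal holds root-to-tip distances. Symmetric and positive
#' semi-definite by construction.
#'
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @return numeric matrix with tip labels as dimnames.
#' @examples
#' phyloCovarianceMatrix(readNewick("((A:1,B:1):1,C:2);"))
#' @export
phyloCovarianceMatrix <- function(tree) {
  validatePhylo(tree)
  ape::vcv.phylo(tree)
}

#' Mean-path-length ultrametric scaling (convenience only)
#'
#' Dates a non-ultrametric tree by the mean path length method
#' (`ape::chronoMPL`). This is a rough clock-based scaling and is NOT
#' equivalent to penalized-likelihood dating; calibrated chronograms should
#' be produced upstream and read with [readNewick()].
#'
#' @param tree an `ape::phylo`.
#' @return an ultrametric `ape::phylo`.
#' @export
makeUltrametricMPL <- function(tree) {
  vdLog("mean-path-length scaling is a convenience, not a substitute for ",
        "penalized-likelihood dating", level = "warn")
  out <- ape::chronoMPL(tree, se = FALSE, test = FALSE)
  out
}

.IUPAC_DNA <- strsplit("ACGTURYSWKMBDHVN", "")[[1]]
.IUPAC_AA <- strsplit("ACDEFGHIKLMNPQRSTVWYXBZJUO*", "")[[1]]

#' Read FASTA sequences with alphabet validation
#'
#' Parses with Biostrings, uppercases, and validates each record against the
#' IUPAC alphabet; empty records and non-IUPAC characters are format errors
#' naming the record.
#'
#' @param file path to a FASTA file.
#' @param alphabet "DNA" (default) or "AA".
#' @return A `Biostrings::DNAStringSet` or `AAStringSet`, in file order.
#' @export
readFastaFile <- function(file, alphabet = c("DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  raw <- Biostrings::readBStringSet(file)
  seqs <- toupper(as.character(raw))
  ids <- names(raw)
  allowed <- if (alphabet == "DNA") .IUPAC_DNA else .IUPAC_AA
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) {
      stop(sprintf("FASTA format error: empty record '%s'", ids[i]),
           call. = FALSE)
    }
    ch <- unique(strsplit(seqs[i], "", fixed = TRUE)[[1]])
    bad <- setdiff(ch, allowed)
    if (length(bad)) {
      stop(sprintf("FASTA format error: non-IUPAC character '%s' in record '%s'",
                   bad[1], ids[i]), call. = FALSE)
    }
  }
  if (alphabet == "DNA") Biostrings::DNAStringSet(setNames(seqs, ids))
  else Biostrings::AAStringSet(setNames(seqs, ids))
}

#' Read a sample x transcript TPM table
#'
#' Tab-separated with a header row; the first column holds sample
#' identifiers, remaining columns are transcripts. TPM values must be
#' nonnegative.
#'
#' @param file path to the TSV.
#' @return numeric matrix, samples in rows.
#' @export
readExpressionTable <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("expression table contains negative or non-finite TPM", call. = FALSE)
  }
  m
}

#' Read a transcript-to-toxin-family annotation table
#'
#' Tab-separated with header columns `transcript` and `family`. Every
#' transcript must map to exactly one family.
#'
#' @param file path to the TSV.
#' @return data.frame with columns `transcript`, `family`.
#' @export
readToxinAnnotation <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("transcript", "family") %in% names(df))) {
    stop("annotation table needs columns 'transcript' and 'family'",
         call. = FALSE)
  }
  df <- unique(df[, c("transcript", "family")])
  dup <- unique(df$transcript[duplicated(df$transcript)])
  if (length(dup)) {
    stop("transcript(s) annotated to more than one family: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  df
}
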