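## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library code never clobbers user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

#' Log a message to standard error
#'
#' Minimal leveled logger. The threshold is controlled by
#' `options(venomdyn.verbosity = "info")`; levels are "debug" < "info" <
#' "warn" < "quiet".
#'
#' @param ... message parts, pasted together.
#' @param level one of "debug", "info", "warn".
#' @return invisibly `NULL`.
#' @export
vdLog <- function(..., level = c("info", "debug", "warn")) {
  level <- match.arg(level)
  ranks <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  thr <- getOption("venomdyn.verbosity", "info")
  if (ranks[[level]] >= ranks[[thr]]) {
    message(sprintf("[venomdyn %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

## Reverse complement of a character-vector DNA string (ACGTN).
revComp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste0(comp[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Stop unless all conditions are TRUE; `...` are named conditions whose
## names become the error message.
stopifnotNamed <- function(...) {
  conds <- list(...)
  for (nm in names(conds)) {
    if (!isTRUE(all(conds[[nm]]))) stop(nm, call. = FALSE)
  }
  invisible(NULL)
}
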