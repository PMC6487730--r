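#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 0.5 -> 1, 2.675 -> 2.68 at 2 digits), the convention used for all
#' percentage reporting in this package.  Base [round()] uses banker's
#' rounding and would give 2.67.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector of the same length as `x`.
#' @examples
#' roundHalfUp(c(0.5, 1.5, 2.675), c(0, 0, 2))
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  # small cushion absorbs binary representation error in x * p (e.g. 2.675
  # stored as 2.67499...); well below half a unit in the last place kept
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

#' Standard error of the mean
#' @param x numeric vector.
#' @return `sd(x)/sqrt(length(x))`; `NA` for fewer than two values.
#' @keywords internal
sem <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# canonical unordered key for a gene pair, used by homolog and database
# matching ("A|B" with the two names sorted)
unorderedKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# ordered fusion key gene5 >> gene3
fusionKey <- function(gene5, gene3) {
  paste(gene5, gene3, sep = ">>")
}

#' @keywords internal
stopIfNot1Based <- function(pos, what = "position") {
  bad <- which(!is.finite(pos) | pos < 1 | pos != floor(pos))
  if (length(bad)) {
    stop(sprintf("%s must be a 1-based positive integer (offending value %s)",
                 what, pos[bad[1]]), call. = FALSE)
  }
  invisible(pos)
}

# derive independent sub-seeds from one master seed so each generator owns
# its own RNG stream; kept below 2^31 - 1
subSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# run code under a temporary RNG seed, restoring global RNG state after
withSeed <- function(seed, code) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
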