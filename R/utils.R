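# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so generators are pure
#' functions of (parameters, seed) without clobbering the session stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement of a DNA string (A/C/G/T/N)
#' @noRd
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

#' Stop unless a matrix is symmetric within tolerance
#' @noRd
check_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      max(abs(m - t(m))) > tol) {
    stop(what, " must be a symmetric square matrix", call. = FALSE)
  }
  invisible(TRUE)
}
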