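#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix sparseMatrix readMM writeMM
#' @importFrom stats prcomp rnorm runif rpois rnbinom sd var dist pbeta fitted
#' @importFrom utils read.csv write.csv head
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  All seeded operations in the package go through
# this so that user-level RNG state is never clobbered.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(TRUE)
}

as_dense_matrix <- function(x, what = "input") {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("%s must be a numeric matrix (cells in rows)", what),
         call. = FALSE)
  }
  x
}
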