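#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows across all_of n
#' @importFrom tidyr pivot_wider pivot_longer
#' @importFrom purrr map map_dbl map2 imap
#' @importFrom Rcpp evalCpp
#' @useDynLib eegspect, .registration = TRUE
NULL

# Moore-Penrose pseudoinverse via SVD; singular values below
# tol * max(singular value) are treated as zero.
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Average-reference centering operator I - 11'/n (symmetric, idempotent,
# rank n - 1).
centering_operator <- function(n) {
  diag(n) - matrix(1 / n, n, n)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# Derive a vector of child seeds (< 2^31) reproducibly from a master seed.
derive_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Evaluate an expression with a local RNG state seeded at `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
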