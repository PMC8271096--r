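# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a key path
#'
#' All randomness in the package flows from one master seed through named
#' substreams (subject, stage, grid index, ...). Keys are mixed into the
#' master seed with a multiplicative-congruential hash so that distinct key
#' paths give effectively independent seeds while remaining pure functions
#' of `(master, ...)`. The result is a valid 32-bit seed for [set.seed()].
#'
#' @param master Integer master seed.
#' @param ... Further keys (integers or strings) naming the substream.
#' @return An integer in `[0, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(42, "subject", 3, "grid", 17)
derive_seed <- function(master, ...) {
  keys <- list(...)
  m <- 2^31
  x <- as.numeric(master) %% m
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    x <- (x * 69069 + as.numeric(k) + 1) %% m
    x <- (x * 69069 + 12345) %% m
  }
  as.integer(x)
}

# population (divide-by-n) standard deviation
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

# mean over the full N x N zero-diagonal matrix (default convention) or
# over the N*(N-1) off-diagonal cells only
matrix_mean <- function(m, convention = c("full", "offdiag")) {
  convention <- match.arg(convention)
  n <- nrow(m)
  s <- sum(m) - sum(diag(m))
  if (convention == "full") s / (n * n) else s / (n * (n - 1))
}

# strictly upper-triangular entries, column-major order
upper_tri_values <- function(m) m[upper.tri(m)]

stopifnot_square <- function(m, name = deparse(substitute(m))) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  }
  invisible(m)
}

stopifnot_symmetric_zero_diag <- function(m, name = deparse(substitute(m)),
                                          tol = 1e-8) {
  stopifnot_square(m, name)
  if (max(abs(m - t(m))) > tol) {
    stop(sprintf("`%s` must be symmetric", name), call. = FALSE)
  }
  if (any(abs(diag(m)) > tol)) {
    stop(sprintf("`%s` must have a zero diagonal", name), call. = FALSE)
  }
  invisible(m)
}

# symmetrize and zero the diagonal
sym_zero_diag <- function(m) {
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
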