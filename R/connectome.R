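# Synthetic structural connectomes with distance-dependent weights.

new_structural_connectome <- function(counts, lengths) {
  structure(list(counts = counts, lengths = lengths),
    class = "structural_connectome"
  )
}

#' @export
print.structural_connectome <- function(x, ...) {
  n <- nrow(x$counts)
  cat(sprintf(
    "<structural_connectome: %d regions, density %.2f, mean length %.1f mm>\n",
    n, mean(x$counts[upper.tri(x$counts)] > 0),
    mean(x$lengths[upper.tri(x$lengths)])
  ))
  invisible(x)
}

#' Generate a synthetic structural connectome for a parcellation
#'
#' Streamline counts follow a heavy-tailed lognormal law whose log-mean
#' decays linearly with the Euclidean centroid distance:
#' `log k ~ Normal(log(count_scale) - d / decay_length, 0.8)`, rounded to
#' integers with floor 0. Path lengths are the centroid distances under
#' multiplicative lognormal noise. Both matrices are symmetrized with a
#' zero diagonal, and lengths are strictly positive wherever counts are.
#'
#' @param parcellation A `parcellation` object (at least 2 regions).
#' @param decay_length Distance scale of the count decay, mm.
#' @param count_scale Expected count at zero distance.
#' @param length_noise_sd SD of the lognormal length perturbation.
#' @param seed Integer seed.
#' @return A `structural_connectome` with fields `counts` and `lengths`.
#' @export
#' @examples
#' p <- make_parcellation_hierarchy(40, 10, seed = 1)[[1]]
#' sc <- make_structural_connectome(p, decay_length = 60, count_scale = 300, seed = 2)
make_structural_connectome <- function(parcellation, decay_length = 60,
                                       count_scale = 300,
                                       length_noise_sd = 0.1, seed = 1L) {
  n <- parcellation$n_regions
  if (n < 2) stop("need at least 2 regions to build a connectome", call. = FALSE)
  if (decay_length <= 0) stop("`decay_length` must be positive", call. = FALSE)
  if (count_scale <= 0) stop("`count_scale` must be positive", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  d <- as.matrix(stats::dist(parcellation$centroids))
  logmu <- log(count_scale) - d / decay_length
  raw <- matrix(0, n, n)
  iu <- upper.tri(d)
  raw[iu] <- exp(rnorm(sum(iu), mean = logmu[iu], sd = 0.8))
  counts <- raw + t(raw)
  counts <- round(counts)
  counts[counts < 0] <- 0
  diag(counts) <- 0

  lraw <- matrix(0, n, n)
  lraw[iu] <- d[iu] * exp(rnorm(sum(iu), 0, length_noise_sd))
  lengths <- lraw + t(lraw)
  diag(lengths) <- 0
  # lengths must be positive wherever a connection exists
  lengths[counts > 0 & lengths <= 0] <- min(lengths[lengths > 0])

  new_structural_connectome(counts, lengths)
}
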