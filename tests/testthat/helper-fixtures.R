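# Shared fixtures, built in code at test time.

# minimal model network without going through a connectome
toy_network <- function(w, lengths = NULL) {
  n <- nrow(w)
  lengths <- lengths %||% matrix(0, n, n)
  structure(
    list(
      weights = w, lengths = lengths, n_regions = as.integer(n),
      mean_length = parcelfit:::matrix_mean(lengths, "full"),
      convention = "full"
    ),
    class = "model_network"
  )
}

toy_params <- function(f, a = NULL) {
  structure(list(f = f, a = a %||% rep(0.5, length(f))),
    class = "regional_parameters"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small subject bundle with short sessions, fast enough for unit tests
quick_bundle <- function(n_regions = 12, seed = 42,
                         ground_truth = list(
                           model_kind = "limit_cycle", tau = 4, C = 0.3
                         ),
                         n_sessions = 2, n_volumes = 150) {
  p <- make_parcellation_hierarchy(n_regions, n_regions, seed = seed)[[1]]
  make_bold_cohort(
    1, p, ground_truth,
    seed = seed,
    n_sessions = n_sessions, n_volumes = n_volumes
  )[[1]]
}

# hand-built bundle from explicit matrices (no simulation)
manual_bundle <- function(counts, lengths, sessions, tr = 0.72,
                          subject_id = "sub-001") {
  n <- nrow(counts)
  p <- make_parcellation_hierarchy(n, n, seed = 1)[[1]]
  subject_bundle(
    subject_id = subject_id,
    parcellation = p,
    connectome = parcelfit:::new_structural_connectome(counts, lengths),
    bold = bold_dataset(sessions, tr)
  )
}

# random symmetric unit-diagonal matrix, entries in [-1, 1]
random_fc <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n, -0.8, 0.8), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# brute-force Pearson correlation written out from the definition
pearson_brute <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}
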