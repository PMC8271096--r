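# Synthetic subject bundles: structural connectome + model-generated BOLD
# with known ground truth, and coarsening across nested parcellation
# levels.

#' Construct a subject bundle
#'
#' @param subject_id Character identifier.
#' @param parcellation The `parcellation` the data live on.
#' @param connectome A `structural_connectome`.
#' @param bold A `bold_dataset`.
#' @param ground_truth Optional list recording the generating model
#'   (`model_kind`, `tau`, `C`, `seed`).
#' @return A `subject_bundle` whose `efc` field holds one FC matrix per
#'   session plus one for the concatenated signal.
#' @export
subject_bundle <- function(subject_id, parcellation, connectome, bold,
                           ground_truth = NULL) {
  stopifnot(
    inherits(parcellation, "parcellation"),
    inherits(connectome, "structural_connectome"),
    inherits(bold, "bold_dataset")
  )
  if (ncol(bold$concatenated) != parcellation$n_regions) {
    stop("BOLD region count does not match the parcellation", call. = FALSE)
  }
  structure(
    list(
      subject_id = subject_id,
      parcellation = parcellation,
      connectome = connectome,
      bold = bold,
      efc = compute_efc_list(bold),
      ground_truth = ground_truth
    ),
    class = "subject_bundle"
  )
}

#' @export
print.subject_bundle <- function(x, ...) {
  cat(sprintf(
    "<subject_bundle '%s': level %s (%d regions), %d sessions, %d eFC matrices%s>\n",
    x$subject_id, x$parcellation$level_id, x$parcellation$n_regions,
    length(x$bold$sessions), length(x$efc),
    if (!is.null(x$ground_truth)) {
      sprintf(
        ", truth (%s, tau = %g, C = %g)",
        x$ground_truth$model_kind, x$ground_truth$tau, x$ground_truth$C
      )
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Default noise specification for the cohort generator
#'
#' @param bold_noise Measurement-noise SD relative to each region's signal
#'   SD (default 0.5).
#' @param count_jitter SD of the per-subject multiplicative lognormal
#'   jitter on streamline counts (default 0.2).
#' @param freq_jitter SD of the per-subject multiplicative lognormal
#'   jitter on regional natural frequencies (default 0.05).
#' @return A named list.
#' @export
noise_spec <- function(bold_noise = 0.5, count_jitter = 0.2,
                       freq_jitter = 0.05) {
  list(
    bold_noise = bold_noise, count_jitter = count_jitter,
    freq_jitter = freq_jitter
  )
}

#' Generate a synthetic cohort with known ground-truth dynamics
#'
#' Each subject gets (i) a structural connectome derived from a shared
#' group template by per-edge multiplicative lognormal jitter on the
#' counts, (ii) regional natural frequencies jittered around group base
#' frequencies drawn uniformly in 0.02-0.08 Hz, and (iii) BOLD produced
#' by simulating the ground-truth model at `(tau, C)` on the subject's
#' own network, downsampling the observable from the integration step to
#' the repetition time by taking every `round(tr/dt)`-th sample (0.72 s
#' from 0.06 s steps, an exact factor of 12), adding Gaussian measurement
#' noise proportional to each region's signal SD, and splitting into
#' sessions. Functional connectivity is then computed per session and for
#' the concatenation, giving `n_sessions + 1` eFC matrices per subject.
#'
#' @param n_subjects Number of subjects.
#' @param parcellation The `parcellation` to generate at.
#' @param ground_truth List with `model_kind` (`"phase"` or
#'   `"limit_cycle"`), `tau` and `C`; both must lie inside the default
#'   fitting grid ranges (tau in `[0, 94]`, C in `[0, 0.945]`).
#' @param noise A list from [noise_spec()].
#' @param seed Master seed; the cohort is a pure function of the
#'   arguments and this seed.
#' @param n_sessions,n_volumes,tr Session layout (defaults 4 sessions of
#'   1200 volumes at TR = 0.72 s).
#' @param dt,transient,sim_noise Integration step, discarded transient and
#'   dynamical noise amplitude of the generating simulation.
#' @param decay_length,count_scale Template connectome parameters (see
#'   [make_structural_connectome()]).
#' @return List of `subject_bundle` objects.
#' @export
make_bold_cohort <- function(n_subjects, parcellation, ground_truth,
                             noise = noise_spec(), seed = 1L,
                             n_sessions = 4L, n_volumes = 1200L, tr = 0.72,
                             dt = 0.06, transient = 500, sim_noise = 0.3,
                             decay_length = 60, count_scale = 300) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  gt <- ground_truth
  if (is.null(gt$model_kind) || is.null(gt$tau) || is.null(gt$C)) {
    stop("`ground_truth` needs `model_kind`, `tau` and `C`", call. = FALSE)
  }
  grid <- default_grid()
  if (gt$tau < min(grid$tau_values) || gt$tau > max(grid$tau_values) ||
    gt$C < min(grid$C_values) || gt$C > max(grid$C_values)) {
    stop("ground-truth (tau, C) must lie within the default grid ranges",
      call. = FALSE
    )
  }
  every <- round(tr / dt)
  if (abs(every * dt - tr) > 1e-9) {
    stop("`tr` must be an integer multiple of `dt`", call. = FALSE)
  }

  n <- parcellation$n_regions
  template <- make_structural_connectome(
    parcellation,
    decay_length = decay_length, count_scale = count_scale,
    seed = derive_seed(seed, "template")
  )
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "group-frequencies"))
  f_base <- runif(n, 0.02, 0.08)
  a_base <- rnorm(n, 0.5, 0.4)

  n_keep <- n_sessions * n_volumes * every # retained integration steps
  duration <- transient + n_keep * dt

  lapply(seq_len(n_subjects), function(i) {
    set.seed(derive_seed(seed, "subject", i, "effects"))
    # subject-level random effects: symmetric per-edge count jitter and
    # per-region frequency jitter
    jit <- matrix(0, n, n)
    iu <- upper.tri(jit)
    jit[iu] <- exp(rnorm(sum(iu), 0, noise$count_jitter))
    jit <- jit + t(jit)
    counts <- round(template$counts * jit)
    diag(counts) <- 0
    f_subj <- pmin(pmax(f_base * exp(rnorm(n, 0, noise$freq_jitter)), 0.011), 0.099)
    sc <- new_structural_connectome(counts, template$lengths)

    network <- structure(
      list(
        weights = normalize_weights(counts),
        lengths = sc$lengths,
        n_regions = n,
        mean_length = matrix_mean(sc$lengths, "full"),
        convention = "full"
      ),
      class = "model_network"
    )
    params <- structure(list(f = f_subj, a = a_base),
      class = "regional_parameters"
    )
    cfg <- sim_config(
      dt = dt, duration = duration, transient = transient,
      noise_amplitude = sim_noise,
      seed = derive_seed(seed, "subject", i, "dynamics"),
      model_kind = gt$model_kind
    )
    run <- simulate_network(network, params, gt$C, gt$tau, cfg)
    sig <- run$observable[seq(every, n_keep, by = every), , drop = FALSE]

    set.seed(derive_seed(seed, "subject", i, "measurement"))
    sds <- apply(sig, 2, pop_sd)
    sig <- sig + matrix(rnorm(length(sig)), nrow(sig), n) *
      rep(noise$bold_noise * sds, each = nrow(sig))

    sessions <- lapply(seq_len(n_sessions), function(s) {
      sig[((s - 1) * n_volumes + 1):(s * n_volumes), , drop = FALSE]
    })
    subject_bundle(
      subject_id = sprintf("sub-%03d", i),
      parcellation = parcellation,
      connectome = sc,
      bold = bold_dataset(sessions, tr),
      ground_truth = list(
        model_kind = gt$model_kind, tau = gt$tau, C = gt$C, seed = seed,
        f = f_subj, a = a_base
      )
    )
  })
}

#' Model inputs of the generating ground-truth dynamics
#'
#' Rebuilds the network and regional parameters that generated a synthetic
#' bundle's BOLD (weights normalized from the subject's counts; the
#' recorded generating frequencies and amplitudes). Useful for recovery
#' experiments that isolate the grid search from data-driven parameter
#' derivation.
#'
#' @param bundle A `subject_bundle` with a generator-recorded
#'   `ground_truth`.
#' @return A list with `network` and `params`, as from
#'   [derive_model_inputs()].
#' @export
ground_truth_inputs <- function(bundle) {
  gt <- bundle$ground_truth
  if (is.null(gt$f)) {
    stop("bundle has no recorded generating parameters", call. = FALSE)
  }
  d <- derive_model_inputs(bundle)
  d$params$f <- unlist(gt$f)
  d$params$a <- unlist(gt$a)
  d
}

#' Coarsen a subject bundle to a nested coarser parcellation
#'
#' Coarse streamline counts sum the fine counts between units assigned to
#' different coarse regions; coarse path lengths are the count-weighted
#' means of the member lengths (plain means where no streamlines exist);
#' coarse BOLD is the size-weighted mean of member signals; FC matrices
#' are recomputed from the coarse signals. Mapping a bundle onto its own
#' level returns an equivalent bundle.
#'
#' @param bundle A `subject_bundle` at the finer level.
#' @param target A `parcellation` from the same hierarchy at a coarser
#'   (or identical) granularity.
#' @return A `subject_bundle` at the target level.
#' @export
coarsen_subject <- function(bundle, target) {
  stopifnot(inherits(bundle, "subject_bundle"), inherits(target, "parcellation"))
  src <- bundle$parcellation
  member <- region_membership(src, target) # fine region -> coarse region
  m <- target$n_regions

  counts_f <- bundle$connectome$counts
  lengths_f <- bundle$connectome$lengths
  agg <- matrix(0, m, m)
  lw <- matrix(0, m, m) # count-weighted length sums
  ls <- matrix(0, m, m) # plain length sums over contributing fine pairs
  np <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a == b) next
      ia <- which(member == a)
      ib <- which(member == b)
      kab <- counts_f[ia, ib, drop = FALSE]
      lab <- lengths_f[ia, ib, drop = FALSE]
      agg[a, b] <- sum(kab)
      lw[a, b] <- sum(kab * lab)
      ls[a, b] <- sum(lab)
      np[a, b] <- length(lab)
    }
  }
  lengths_c <- ifelse(agg > 0, lw / pmax(agg, 1), ifelse(np > 0, ls / pmax(np, 1), 0))
  lengths_c <- sym_zero_diag(lengths_c)
  agg <- sym_zero_diag(agg)

  # size-weighted mean of member fine-region signals
  sizes <- src$region_sizes
  wmat <- matrix(0, src$n_regions, m)
  for (r in seq_len(src$n_regions)) wmat[r, member[r]] <- sizes[r]
  wmat <- sweep(wmat, 2, colSums(wmat), "/")
  sessions <- lapply(bundle$bold$sessions, function(s) {
    out <- s %*% wmat
    colnames(out) <- NULL
    out
  })

  subject_bundle(
    subject_id = bundle$subject_id,
    parcellation = target,
    connectome = new_structural_connectome(agg, lengths_c),
    bold = bold_dataset(sessions, bundle$bold$tr),
    ground_truth = bundle$ground_truth
  )
}
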