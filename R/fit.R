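# Exhaustive (tau, C) grid search: one simulation per grid point serves
# all six targets (5 eFC matrices + the eSC count matrix); the
# goodness-of-fit is the maximal upper-triangular Pearson correlation
# over the grid.

#' Construct a fitting grid
#'
#' @param tau_values Strictly increasing delay values starting at 0 (s).
#' @param C_values Strictly increasing coupling values starting at 0.
#' @return A `fit_grid`.
#' @export
fit_grid <- function(tau_values, C_values) {
  for (v in list(tau_values, C_values)) {
    if (length(v) < 1 || any(diff(v) <= 0)) {
      stop("grid values must be strictly increasing", call. = FALSE)
    }
    if (v[1] != 0) stop("grid values must start at 0", call. = FALSE)
  }
  structure(list(tau_values = tau_values, C_values = C_values),
    class = "fit_grid"
  )
}

#' The default 48 x 64 fitting grid
#'
#' 48 equally spaced delays spanning `[0, 94]` s (step 2) by 64 equally
#' spaced couplings spanning `[0, 0.945]` (step 0.015).
#'
#' @return A `fit_grid`.
#' @export
#' @examples
#' g <- default_grid()
#' length(g$tau_values) # 48
default_grid <- function() {
  fit_grid(
    tau_values = seq(0, 94, length.out = 48),
    C_values = seq(0, 0.945, length.out = 64)
  )
}

#' A reduced grid for desk-scale experiments
#'
#' The default is a 4-fold coarsening of [default_grid()] along both
#' axes: 12 delays on `[0, 88]` s (step 8) by 16 couplings on `[0, 0.9]`
#' (step 0.06). The delay step matches the intrinsic delay resolution of
#' the fit landscape at desk-scale simulation lengths.
#'
#' @param tau_max,n_tau Delay range `[0, tau_max]` s and point count.
#' @param C_max,n_C Coupling range `[0, C_max]` and point count.
#' @return A `fit_grid`.
#' @export
reduced_grid <- function(tau_max = 88, n_tau = 12, C_max = 0.9, n_C = 16) {
  fit_grid(
    tau_values = seq(0, tau_max, length.out = n_tau),
    C_values = seq(0, C_max, length.out = n_C)
  )
}

#' @export
print.fit_grid <- function(x, ...) {
  cat(sprintf(
    "<fit_grid: %d tau values in [0, %g] s x %d C values in [0, %g]>\n",
    length(x$tau_values), max(x$tau_values),
    length(x$C_values), max(x$C_values)
  ))
  invisible(x)
}

#' Pearson similarity of two matrices over their upper triangles
#'
#' @param A,B Square matrices of equal size, `N >= 3`.
#' @return Pearson correlation of the strictly upper-triangular entries.
#' @export
#' @examples
#' m <- matrix(rnorm(36), 6); m <- m + t(m); diag(m) <- 1
#' upper_tri_similarity(m, m) # 1
upper_tri_similarity <- function(A, B) {
  stopifnot_square(A, "A")
  stopifnot_square(B, "B")
  if (!all(dim(A) == dim(B))) stop("matrices must have equal shape", call. = FALSE)
  if (nrow(A) < 3) stop("need N >= 3", call. = FALSE)
  a <- upper_tri_values(A)
  b <- upper_tri_values(B)
  if (pop_sd(a) == 0 || pop_sd(b) == 0) {
    stop("constant upper triangle: correlation undefined", call. = FALSE)
  }
  cor(a, b)
}

# argmax and top-k of a tau x C plane with deterministic scan-order
# tie-breaking (tau ascending, then C ascending); NA cells are excluded
top_k_points <- function(plane, grid, k = 5L) {
  nt <- length(grid$tau_values)
  nc <- length(grid$C_values)
  ti <- rep(seq_len(nt), times = nc)
  ci <- rep(seq_len(nc), each = nt)
  v <- as.vector(plane)
  keep <- !is.na(v)
  if (!any(keep)) stop("all plane entries missing", call. = FALSE)
  ord <- order(-v[keep], ti[keep], ci[keep])
  take <- head(ord, k)
  tibble::tibble(
    rank = seq_along(take),
    tau = grid$tau_values[ti[keep][take]],
    C = grid$C_values[ci[keep][take]],
    similarity = v[keep][take]
  )
}

#' Fit one subject by exhaustive grid search
#'
#' For every grid point `(tau, C)` the chosen model is simulated once on
#' the subject's personalized network (one stochastic realization, with a
#' seed derived deterministically from the subject, model, and grid
#' indices) and its simulated FC is correlated against all six targets:
#' the subject's eFC matrices (per session and concatenated) and the eSC
#' streamline-count matrix. The goodness-of-fit per target is the plane
#' maximum; ties are broken by scan order (tau ascending, then C
#' ascending). Grid points whose simulation diverges are recorded as
#' missing and excluded from the maximum.
#'
#' @param bundle A `subject_bundle`.
#' @param model_kind `"phase"` or `"limit_cycle"`.
#' @param grid A `fit_grid`.
#' @param config A `sim_config`; its `model_kind` and `seed` are
#'   overridden per grid point.
#' @param top_k Number of best points retained per target (default 5).
#' @param derived Optional precomputed [derive_model_inputs()] output.
#' @return A `fit_result` holding the per-target similarity `planes`, the
#'   grid, and a `summary` tibble (target, fit, tau_opt, C_opt); see
#'   [tidy.fit_result()].
#' @export
fit_subject <- function(bundle, model_kind = c("phase", "limit_cycle"),
                        grid = default_grid(), config = sim_config(),
                        top_k = 5L, derived = NULL) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(bundle, "subject_bundle"), inherits(grid, "fit_grid"))
  if (is.null(derived)) derived <- derive_model_inputs(bundle)
  network <- derived$network
  params <- derived$params

  targets <- c(bundle$efc, list(eSC = bundle$connectome$counts))
  tvecs <- lapply(targets, upper_tri_values)
  for (nm in names(tvecs)) {
    if (pop_sd(tvecs[[nm]]) == 0) {
      stop(sprintf("target '%s' has a constant upper triangle", nm),
        call. = FALSE
      )
    }
  }

  nt <- length(grid$tau_values)
  nc <- length(grid$C_values)
  planes <- lapply(targets, function(...) matrix(NA_real_, nt, nc))
  base_cfg <- config

  for (ci in seq_len(nc)) {
    for (ti in seq_len(nt)) {
      cfg <- base_cfg
      cfg$model_kind <- model_kind
      cfg$seed <- derive_seed(
        config$seed, bundle$subject_id, model_kind, ti, ci
      )
      run <- tryCatch(
        simulate_network(
          network, params,
          C = grid$C_values[ci], tau = grid$tau_values[ti], config = cfg
        ),
        error = function(e) e
      )
      if (inherits(run, "error")) {
        message(sprintf(
          "grid point (tau = %g, C = %g) excluded: %s",
          grid$tau_values[ti], grid$C_values[ci], conditionMessage(run)
        ))
        next
      }
      s <- upper_tri_values(compute_sfc(run))
      for (nm in names(tvecs)) {
        planes[[nm]][ti, ci] <- cor(s, tvecs[[nm]])
      }
    }
  }

  summaries <- purrr::map_dfr(names(planes), function(nm) {
    tk <- top_k_points(planes[[nm]], grid, top_k)
    tibble::tibble(
      target = nm,
      fit = tk$similarity[1],
      tau_opt = tk$tau[1],
      C_opt = tk$C[1]
    )
  })

  structure(
    list(
      subject_id = bundle$subject_id,
      parcellation = bundle$parcellation$level_id,
      model_kind = model_kind,
      grid = grid,
      planes = planes,
      top_k = lapply(names(planes), function(nm) {
        top_k_points(planes[[nm]], grid, top_k)
      }) |> setNames(names(planes)),
      summary = summaries,
      seed = config$seed
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result: subject %s, level %s, %s model, %d x %d grid>\n",
    x$subject_id, x$parcellation, x$model_kind,
    length(x$grid$tau_values), length(x$grid$C_values)
  ))
  print(x$summary)
  invisible(x)
}

#' Tidy a fit result into one row per target
#'
#' @param x A `fit_result`.
#' @param ... Unused.
#' @return A tibble with columns subject, parcellation, model, target,
#'   fit, tau_opt, C_opt, seed.
#' @method tidy fit_result
#' @export
tidy.fit_result <- function(x, ...) {
  dplyr::mutate(
    x$summary,
    subject = x$subject_id,
    parcellation = x$parcellation,
    model = x$model_kind,
    seed = x$seed,
    .before = 1
  )
}

#' Fit every subject of a cohort
#'
#' @param bundles List of `subject_bundle` objects (one parcellation
#'   level).
#' @param model_kind,grid,config,top_k Passed to [fit_subject()].
#' @return Long tibble, one row per (subject, target).
#' @export
fit_cohort <- function(bundles, model_kind = c("phase", "limit_cycle"),
                       grid = default_grid(), config = sim_config(),
                       top_k = 5L) {
  model_kind <- match.arg(model_kind)
  purrr::map_dfr(bundles, function(b) {
    tidy(fit_subject(b, model_kind, grid, config, top_k))
  })
}

#' Count the model runs and optima a study design implies
#'
#' One simulation per grid point serves all targets, so the total run
#' count is `n_subjects * n_parcellations * n_models * |grid|`; each
#' parcellation-model condition yields `5 * n_subjects` functional optima
#' (one per eFC matrix) and `n_subjects` structural optima.
#'
#' @param n_subjects,n_parcellations,n_models Design counts, all `>= 1`.
#' @param grid A `fit_grid`.
#' @return A one-row tibble with `n_runs`, `n_functional_optima` (per
#'   parcellation-model condition) and `n_structural_optima`.
#' @export
#' @examples
#' plan_jobs(272, 11, 2, default_grid())$n_runs # > 18e6
plan_jobs <- function(n_subjects, n_parcellations, n_models,
                      grid = default_grid()) {
  stopifnot(n_subjects >= 1, n_parcellations >= 1, n_models >= 1)
  npts <- length(grid$tau_values) * length(grid$C_values)
  tibble::tibble(
    n_runs = n_subjects * n_parcellations * n_models * npts,
    n_functional_optima = n_subjects * 5,
    n_structural_optima = n_subjects
  )
}
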