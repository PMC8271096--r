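# End-to-end pipeline: generate -> derive -> fit -> variables -> stats.
# Each stage writes text artifacts into the output directory and later
# stages read them back, so stages can run in separate sessions.

#' Pipeline configuration
#'
#' @param n_subjects Cohort size.
#' @param n_fine Number of finest-level units in the synthetic hierarchy.
#' @param granularities Region counts of the analysed levels (finest
#'   first after sorting).
#' @param ground_truth Generating model: list with `model_kind`, `tau`,
#'   `C`.
#' @param noise Cohort noise specification ([noise_spec()]).
#' @param seed Master seed; every stage derives its substreams from it.
#' @param grid `"default"` for the full 48 x 64 grid, `"reduced"` for
#'   [reduced_grid()], or a `fit_grid`.
#' @param model Model to fit: `"phase"` or `"limit_cycle"`.
#' @param sim_duration,sim_transient Fitting-simulation length and
#'   transient, seconds.
#' @param n_sessions,n_volumes,tr Session layout of the generated BOLD.
#' @param stats Stats options: `correction`, `delta`, `floor`, `alpha`,
#'   `mlr_predictors`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 3, n_fine = 60,
                            granularities = c(18, 9),
                            ground_truth = list(
                              model_kind = "phase", tau = 4, C = 0.6
                            ),
                            noise = noise_spec(), seed = 1L,
                            grid = "reduced", model = "phase",
                            sim_duration = 600, sim_transient = 100,
                            n_sessions = 4L, n_volumes = 1200L, tr = 0.72,
                            stats = list()) {
  stats_defaults <- list(
    correction = "bonferroni", delta = 0.1, floor = 0.3, alpha = 0.05,
    mlr_predictors = c(
      "aver[std(BOLD)]", "aver[aver(eFC)]", "corr(eFC,eSC)"
    )
  )
  stats <- utils::modifyList(stats_defaults, stats)
  structure(
    list(
      n_subjects = n_subjects, n_fine = n_fine,
      granularities = sort(granularities, decreasing = TRUE),
      ground_truth = ground_truth, noise = noise, seed = as.integer(seed),
      grid = grid, model = model,
      sim_duration = sim_duration, sim_transient = sim_transient,
      n_sessions = n_sessions, n_volumes = n_volumes, tr = tr,
      stats = stats
    ),
    class = "pipeline_config"
  )
}

config_grid <- function(config) {
  if (inherits(config$grid, "fit_grid")) {
    config$grid
  } else if (identical(config$grid, "default")) {
    default_grid()
  } else if (identical(config$grid, "reduced")) {
    reduced_grid()
  } else if (is.list(config$grid)) {
    fit_grid(unlist(config$grid$tau_values), unlist(config$grid$C_values))
  } else {
    stop("unrecognized grid specification", call. = FALSE)
  }
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop(
      sprintf(
        "missing artifact '%s'; run the `%s` stage first", path, produced_by
      ),
      call. = FALSE
    )
  }
  path
}

read_pipeline_bundles <- function(out) {
  hier_path <- require_artifact(file.path(out, "parcellation.json"), "generate")
  hierarchy <- read_parcellation_hierarchy(hier_path)
  names(hierarchy) <- vapply(hierarchy, function(p) p$level_id, character(1))
  bundles <- lapply(hierarchy, function(p) {
    lvl_dir <- require_artifact(file.path(out, "bundles", p$level_id), "generate")
    dirs <- sort(list.dirs(lvl_dir, recursive = FALSE))
    lapply(dirs, read_bundle, parcellation = p)
  })
  list(hierarchy = hierarchy, bundles = bundles)
}

stage_log <- function(stage, t0, extra = "") {
  message(sprintf(
    "[parcelfit] %s done in %.1f s%s",
    stage, as.numeric(Sys.time()) - t0,
    if (nzchar(extra)) paste0(" (", extra, ")") else ""
  ))
}

#' Run pipeline stages
#'
#' Subcommands: `generate` (synthetic hierarchy and cohort bundles),
#' `derive` (per-bundle model inputs to `derived.json`), `fit` (grid
#' search per subject and level, long `results.tsv`), `variables`
#' (`variables.tsv`), `stats` (`stats_report.json` plus matrices), or
#' `all`. Later stages error with the name of the missing prior stage if
#' its artifacts are absent. Every written JSON artifact embeds the
#' config hash and master seed; re-running with the same config
#' reproduces the outputs exactly.
#'
#' @param subcommand One of `generate`, `derive`, `fit`, `variables`,
#'   `stats`, `all`.
#' @param config A `pipeline_config`.
#' @param out Output directory.
#' @return `out`, invisibly.
#' @export
run_pipeline <- function(subcommand = c(
                           "all", "generate", "derive", "fit",
                           "variables", "stats"
                         ),
                         config = pipeline_config(), out) {
  subcommand <- match.arg(subcommand)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (subcommand == "all") {
    for (s in c("generate", "derive", "fit", "variables", "stats")) {
      run_pipeline(s, config, out)
    }
    return(invisible(out))
  }
  switch(subcommand,
    generate = pipeline_generate(config, out),
    derive = pipeline_derive(config, out),
    fit = pipeline_fit(config, out),
    variables = pipeline_variables(config, out),
    stats = pipeline_stats(config, out)
  )
  invisible(out)
}

pipeline_generate <- function(config, out) {
  t0 <- as.numeric(Sys.time())
  hierarchy <- make_parcellation_hierarchy(
    config$n_fine, config$granularities,
    seed = derive_seed(config$seed, "hierarchy")
  )
  write_parcellation_hierarchy(hierarchy, file.path(out, "parcellation.json"))
  fine <- hierarchy[[1]]
  cohort <- make_bold_cohort(
    config$n_subjects, fine, config$ground_truth,
    noise = config$noise, seed = derive_seed(config$seed, "cohort"),
    n_sessions = config$n_sessions, n_volumes = config$n_volumes,
    tr = config$tr
  )
  for (p in hierarchy) {
    lvl_dir <- file.path(out, "bundles", p$level_id)
    for (b in cohort) {
      bb <- if (identical(p$level_id, fine$level_id)) b else coarsen_subject(b, p)
      write_bundle(bb, file.path(lvl_dir, bb$subject_id))
    }
  }
  jsonlite::write_json(
    list(
      config_hash = config_hash(unclass(config)), seed = config$seed,
      levels = vapply(hierarchy, function(p) p$level_id, character(1)),
      n_subjects = config$n_subjects
    ),
    file.path(out, "generate_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  stage_log("generate", t0, sprintf(
    "%d subjects x %d levels", config$n_subjects, length(hierarchy)
  ))
}

pipeline_derive <- function(config, out) {
  t0 <- as.numeric(Sys.time())
  pb <- read_pipeline_bundles(out)
  for (lvl in names(pb$bundles)) {
    for (b in pb$bundles[[lvl]]) {
      d <- derive_model_inputs(b)
      jsonlite::write_json(
        list(
          subject_id = b$subject_id, level = lvl,
          convention = d$network$convention,
          mean_length = d$network$mean_length,
          f = d$params$f, a = d$params$a,
          config_hash = config_hash(unclass(config)), seed = config$seed
        ),
        file.path(out, "bundles", lvl, b$subject_id, "derived.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
    }
  }
  stage_log("derive", t0)
}

pipeline_fit <- function(config, out) {
  t0 <- as.numeric(Sys.time())
  pb <- read_pipeline_bundles(out)
  require_artifact(
    file.path(
      out, "bundles", names(pb$bundles)[1],
      pb$bundles[[1]][[1]]$subject_id, "derived.json"
    ),
    "derive"
  )
  grid <- config_grid(config)
  cfg <- sim_config(
    duration = config$sim_duration, transient = config$sim_transient,
    seed = config$seed, model_kind = config$model
  )
  results <- purrr::map_dfr(names(pb$bundles), function(lvl) {
    fit_cohort(pb$bundles[[lvl]],
      model_kind = config$model, grid = grid, config = cfg
    )
  })
  utils::write.table(results, file.path(out, "results.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  stage_log("fit", t0, sprintf("%d rows", nrow(results)))
}

pipeline_variables <- function(config, out) {
  t0 <- as.numeric(Sys.time())
  pb <- read_pipeline_bundles(out)
  tab <- cohort_variable_table(pb$bundles)
  utils::write.table(tab, file.path(out, "variables.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  stage_log("variables", t0, sprintf("%d rows", nrow(tab)))
}

pipeline_stats <- function(config, out) {
  t0 <- as.numeric(Sys.time())
  res_path <- require_artifact(file.path(out, "results.tsv"), "fit")
  var_path <- require_artifact(file.path(out, "variables.tsv"), "variables")
  results <- tibble::as_tibble(utils::read.delim(res_path, check.names = FALSE))
  variables <- tibble::as_tibble(utils::read.delim(var_path, check.names = FALSE))

  functional <- dplyr::filter(results, .data$target != "eSC")
  st <- config$stats
  report <- list(
    config_hash = config_hash(unclass(config)), seed = config$seed,
    thresholds = st[c("correction", "delta", "floor", "alpha")]
  )

  fpc <- fit_pattern_correlations(functional, alpha = st$alpha)
  write_matrix(fpc$r, file.path(out, "fit_pattern_r.tsv"), colnames(fpc$r))
  write_matrix(fpc$p, file.path(out, "fit_pattern_p.tsv"), colnames(fpc$p))
  report$fit_pattern <- list(
    r = fpc$r, p = fpc$p, n = fpc$n
  )

  wx <- pairwise_wilcoxon(functional, correction = st$correction)
  pw <- wx$p_adj
  pw[is.na(pw)] <- 1
  write_matrix(pw, file.path(out, "wilcoxon_p.tsv"), colnames(pw))
  report$wilcoxon <- list(
    p_adjusted = wx$p_adj, effect_size = wx$effect,
    correction = wx$correction
  )

  modes <- c(
    "per_parcellation", "joint",
    if (length(unique(variables$parcellation)) >= 3) "group_median"
  )
  vfc <- variable_fit_regression(
    variables, functional,
    modes = modes, delta = st$delta, floor = st$floor, alpha = st$alpha
  )
  report$variable_fit <- vfc$summary

  joined <- dplyr::inner_join(
    variables, dplyr::rename(functional, scope = "target"),
    by = c("subject", "parcellation", "scope")
  )
  preds <- intersect(st$mlr_predictors, names(joined))
  if (nrow(joined) > length(preds) + 2 && length(preds) > 0) {
    ml <- tryCatch(mlr_fit(joined, "fit", preds, alpha = st$alpha),
      error = function(e) NULL
    )
    if (!is.null(ml)) {
      report$mlr <- list(
        coefficients = tidy(ml), r_squared = ml$r_squared, n = ml$n
      )
    }
  }

  conc <- dplyr::filter(results, .data$target == "concatenated")
  dm <- optimal_parameter_distances(conc)
  write_matrix(dm, file.path(out, "optimal_parameter_distance.tsv"), colnames(dm))
  report$optimal_parameter_distance <- dm

  jsonlite::write_json(report, file.path(out, "stats_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  stage_log("stats", t0)
}
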