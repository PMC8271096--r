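# Per-subject scalar data variables computed from BOLD, eFC, eSC, ePL and
# the extracted natural frequencies. Column statistics of connectivity
# matrices always exclude the diagonal (a region's average connectivity is
# to the *rest* of the brain), and eSC/ePL are first normalized by their
# mean, matching how the models consume them.

# per-column mean and population SD excluding the diagonal cell
col_stats_nodiag <- function(m) {
  n <- nrow(m)
  means <- numeric(n)
  sds <- numeric(n)
  for (j in seq_len(n)) {
    v <- m[-j, j]
    means[j] <- mean(v)
    sds[j] <- pop_sd(v)
  }
  list(mean = means, sd = sds)
}

variable_columns <- function() {
  c(
    "aver[std(BOLD)]", "std[std(BOLD)]",
    "aver[aver(eFC)]", "std[aver(eFC)]", "aver[std(eFC)]", "std[std(eFC)]",
    "corr(eFC,eSC)", "corr(eFC,ePL)", "corr(eSC,ePL)",
    "aver[std(eSC)]", "std[aver(eSC)]", "std[std(eSC)]",
    "aver[std(ePL)]", "std[aver(ePL)]", "std[std(ePL)]",
    "aver(fi)", "std(fi)"
  )
}

#' Compute the data variables of one subject bundle
#'
#' Produces one row per session scope: each per-session eFC, plus the
#' concatenated scope. BOLD variables are per-region temporal standard
#' deviations of that scope's signal, summarized by mean and population SD
#' across regions; eFC variables summarize the diagonal-excluded
#' column-wise mean and SD of that scope's FC matrix; cross-matrix
#' correlations use the strictly upper triangles; eSC/ePL variables are
#' computed once (session-independent) from the matrices normalized by
#' their mean; frequency variables summarize the supplied natural
#' frequencies.
#'
#' @param bundle A `subject_bundle`.
#' @param frequencies Natural frequencies (Hz); extracted from the
#'   bundle's BOLD if omitted.
#' @param convention Averaging convention for the eSC/ePL normalization.
#' @return A tibble with columns `subject`, `parcellation`, `scope`, and
#'   the 17 named data variables.
#' @export
compute_data_variables <- function(bundle, frequencies = NULL,
                                   convention = c("full", "offdiag")) {
  convention <- match.arg(convention)
  stopifnot(inherits(bundle, "subject_bundle"))
  if (is.null(frequencies)) {
    frequencies <- extract_natural_frequencies(bundle$bold)
  }

  esc <- bundle$connectome$counts
  epl <- bundle$connectome$lengths
  esc_n <- esc / matrix_mean(esc, convention)
  epl_n <- epl / matrix_mean(epl, convention)
  cs_esc <- col_stats_nodiag(esc_n)
  cs_epl <- col_stats_nodiag(epl_n)
  c_sc_pl <- upper_tri_similarity(esc, epl)

  scopes <- names(bundle$efc)
  signals <- c(bundle$bold$sessions, list(bundle$bold$concatenated))

  purrr::map_dfr(seq_along(scopes), function(i) {
    efc <- bundle$efc[[i]]
    sig <- signals[[i]]
    s_bold <- apply(sig, 2, pop_sd)
    cs_fc <- col_stats_nodiag(efc)
    row <- c(
      mean(s_bold), pop_sd(s_bold),
      mean(cs_fc$mean), pop_sd(cs_fc$mean),
      mean(cs_fc$sd), pop_sd(cs_fc$sd),
      upper_tri_similarity(efc, esc),
      upper_tri_similarity(efc, epl),
      c_sc_pl,
      mean(cs_esc$sd), pop_sd(cs_esc$mean), pop_sd(cs_esc$sd),
      mean(cs_epl$sd), pop_sd(cs_epl$mean), pop_sd(cs_epl$sd),
      mean(frequencies), pop_sd(frequencies)
    )
    names(row) <- variable_columns()
    dplyr::bind_cols(
      tibble::tibble(
        subject = bundle$subject_id,
        parcellation = bundle$parcellation$level_id,
        scope = scopes[i]
      ),
      tibble::as_tibble_row(row)
    )
  })
}

#' Assemble the data-variable table of a cohort
#'
#' @param cohort Either a flat list of `subject_bundle`s or a list of such
#'   lists (one per parcellation level).
#' @param convention Averaging convention for the eSC/ePL normalization.
#' @return A tibble sorted by (parcellation, subject, scope), one row per
#'   (subject, parcellation, scope).
#' @export
cohort_variable_table <- function(cohort, convention = c("full", "offdiag")) {
  convention <- match.arg(convention)
  bundles <- if (length(cohort) > 0 && inherits(cohort[[1]], "subject_bundle")) {
    cohort
  } else {
    purrr::flatten(cohort)
  }
  rows <- purrr::map_dfr(bundles, function(b) {
    tryCatch(
      compute_data_variables(b, convention = convention),
      error = function(e) {
        stop(
          sprintf("subject '%s': %s", b$subject_id, conditionMessage(e)),
          call. = FALSE
        )
      }
    )
  })
  dplyr::arrange(rows, .data$parcellation, .data$subject, .data$scope)
}
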