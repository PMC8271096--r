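# Variability analyses over cohort fit results: Fisher-z handling of
# correlations, cross-parcellation fit-pattern correlation, paired
# one-sided Wilcoxon matrices with correction and rank-biserial effect
# sizes, variable-fit correlation with intra/inter classification,
# multiple linear regression, and optimal-parameter distances.

#' Fisher z-transform of a correlation coefficient
#'
#' Correlations are z-transformed (`z = atanh(r)`) before arithmetic such
#' as averaging and back-transformed afterwards. Inputs within 1e-15 of
#' +/-1 are clipped first so the transform stays finite.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return `atanh` of the clipped input.
#' @export
#' @examples
#' fisher_z(0.5) # 0.549306...
fisher_z <- function(r) {
  lim <- 1 - 1e-15
  atanh(pmin(pmax(r, -lim), lim))
}

#' @rdname fisher_z
#' @param z A Fisher z value.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Fisher-z mean of correlations
#'
#' @param r Vector of correlations; `NA`s are dropped.
#' @return `tanh(mean(atanh(r)))`.
#' @export
fisher_z_mean <- function(r) fisher_z_inv(mean(fisher_z(r), na.rm = TRUE))

# ---------------------------------------------------------------------------

# wide matrix (rows = aligned observations, cols = parcellations) from a
# long fit table
fits_to_wide <- function(fits, value = "fit") {
  keys <- intersect(c("subject", "target"), names(fits))
  wide <- tidyr::pivot_wider(
    fits[c(keys, "parcellation", value)],
    names_from = "parcellation", values_from = dplyr::all_of(value)
  )
  m <- as.matrix(wide[setdiff(names(wide), keys)])
  if (anyNA(m)) {
    stop("fit vectors are not aligned across parcellations", call. = FALSE)
  }
  m
}

#' Cross-parcellation correlation of fit patterns
#'
#' The vectors of Fit values collected over all subjects (and scans) are
#' Pearson-correlated between every two parcellations. Cells failing
#' significance at `alpha` are flagged; with atlas labels, the mean
#' within-atlas and between-atlas correlations are computed via Fisher z
#' (transform, average, back-transform).
#'
#' @param fits Long tibble with columns `subject`, `parcellation`, `fit`
#'   and optionally `target`; rows must align across parcellations.
#' @param atlas Optional named character vector mapping parcellation
#'   level ids to atlas (hierarchy) labels.
#' @param alpha Significance level for the mask (default 0.05).
#' @return A list of class `fit_pattern_cor`: correlation matrix `r`,
#'   p-value matrix `p`, logical `significant` mask, `n` observations,
#'   and (with `atlas`) `intra_mean` / `inter_mean`.
#' @export
fit_pattern_correlations <- function(fits, atlas = NULL, alpha = 0.05) {
  m <- fits_to_wide(fits)
  p_names <- colnames(m)
  k <- ncol(m)
  r <- diag(1, k)
  p <- matrix(0, k, k)
  dimnames(r) <- dimnames(p) <- list(p_names, p_names)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      ct <- cor.test(m[, i], m[, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  out <- list(
    r = r, p = p, significant = p < alpha, n = nrow(m), alpha = alpha
  )
  if (!is.null(atlas)) {
    if (!all(p_names %in% names(atlas))) {
      stop("`atlas` must label every parcellation", call. = FALSE)
    }
    grp <- atlas[p_names]
    iu <- upper.tri(r)
    same <- outer(grp, grp, "==")[iu]
    out$intra_mean <- fisher_z_mean(r[iu][same])
    out$inter_mean <- fisher_z_mean(r[iu][!same])
    out$atlas <- grp
  }
  structure(out, class = "fit_pattern_cor")
}

#' @export
print.fit_pattern_cor <- function(x, ...) {
  cat(sprintf(
    "<fit_pattern_cor: %d parcellations, n = %d>\n", ncol(x$r), x$n
  ))
  print(round(x$r, 3))
  if (!is.null(x$intra_mean)) {
    cat(sprintf(
      "intra-atlas Fisher-z mean: %.3f; inter-atlas: %.3f\n",
      x$intra_mean, x$inter_mean
    ))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------

# One-sided paired Wilcoxon signed-rank test with matched-pairs
# rank-biserial effect size. Zero differences are dropped. The null
# distribution is exact (shift convolution over doubled ranks, which are
# integers even under mid-ranks from ties) for n <= exact_limit, else a
# normal approximation with tie correction and continuity correction.
signed_rank_test <- function(x, y, exact_limit = 25L) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero")
    return(list(p = 1, effect = 0, n = 0, statistic = 0))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  s <- n * (n + 1) / 2
  effect <- 2 * w_pos / s - 1
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r)) # doubled ranks are integers
    dist <- 1
    for (ri in r2) {
      new <- numeric(length(dist) + ri)
      new[seq_along(dist)] <- dist
      new[seq_along(dist) + ri] <- new[seq_along(dist) + ri] + dist
      dist <- new
    }
    dist <- dist / sum(dist)
    w2 <- as.integer(round(2 * w_pos))
    p <- sum(dist[(w2 + 1):length(dist)]) # P(2W >= 2w_obs), support 0..sum(r2)
  } else {
    ties <- table(r)
    mu <- s / 2
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- pnorm((w_pos - 0.5 - mu) / sqrt(sig2), lower.tail = FALSE)
  }
  list(p = min(max(p, 0), 1), effect = effect, n = n, statistic = w_pos)
}

#' Pairwise one-sided Wilcoxon signed-rank matrix over parcellations
#'
#' For every ordered parcellation pair (row, column), tests the
#' alternative that Fit(row) > Fit(column) on paired per-subject values;
#' p-values are corrected across all ordered pairs (Bonferroni by
#' default, Holm optionally). The matched-pairs rank-biserial correlation
#' accompanies each test as effect size.
#'
#' @param fits Long tibble as in [fit_pattern_correlations()]; paired
#'   vectors need at least 5 non-identical pairs.
#' @param correction `"bonferroni"` (default) or `"holm"`.
#' @return A list of class `wilcoxon_matrix` with matrices `p_raw`,
#'   `p_adj`, `effect` (rows = "greater" side).
#' @export
pairwise_wilcoxon <- function(fits, correction = c("bonferroni", "holm")) {
  correction <- match.arg(correction)
  m <- fits_to_wide(fits)
  if (nrow(m) < 5) stop("need at least 5 paired observations", call. = FALSE)
  k <- ncol(m)
  p_raw <- effect <- matrix(NA_real_, k, k,
    dimnames = list(colnames(m), colnames(m))
  )
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      res <- signed_rank_test(m[, i], m[, j])
      p_raw[i, j] <- res$p
      effect[i, j] <- res$effect
    }
  }
  off <- !is.na(p_raw)
  p_adj <- p_raw
  p_adj[off] <- stats::p.adjust(p_raw[off], method = correction)
  structure(
    list(p_raw = p_raw, p_adj = p_adj, effect = effect, correction = correction),
    class = "wilcoxon_matrix"
  )
}

#' @export
print.wilcoxon_matrix <- function(x, ...) {
  cat(sprintf(
    "<wilcoxon_matrix: %d parcellations, %s-corrected one-sided p (row > column)>\n",
    ncol(x$p_adj), x$correction
  ))
  print(signif(x$p_adj, 3))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Correlate data variables with fit values and classify them
#'
#' For every data variable, computes (i) per-parcellation Pearson
#' correlations with the Fit values, (ii) the joint correlation over rows
#' pooled across parcellations, and (iii) the group-median correlation
#' across parcellations (medians of variable and Fit per parcellation,
#' then Pearson over parcellations). Variables are classified by
#' explanatory scope: `intra` when the Fisher-z mean of the
#' per-parcellation |r| exceeds the joint |r| by at least `delta` and the
#' per-parcellation correlations are predominantly significant, `inter`
#' in the mirrored case for the joint correlation, `both` when both
#' magnitudes reach `floor` and differ by less than `delta`, else
#' `neither`. Thresholds are explicit and returned with the table.
#'
#' @param variables Data-variable table from [cohort_variable_table()].
#' @param fits Long fit tibble; rows are joined on subject,
#'   parcellation, and scope/target.
#' @param variable_cols Variables to analyse (default all 17).
#' @param modes Which correlation modes to compute.
#' @param delta Classification margin (default 0.1).
#' @param floor Minimum magnitude for the `both` class (default 0.3).
#' @param alpha Significance level (default 0.05).
#' @return A list of class `variable_fit_cor`: `per_parcellation` (long
#'   tibble), `summary` (one row per variable with mean individual r,
#'   joint r, group-median r, class), and the thresholds used.
#' @export
variable_fit_regression <- function(variables, fits,
                                    variable_cols = variable_columns(),
                                    modes = c(
                                      "per_parcellation", "joint",
                                      "group_median"
                                    ),
                                    delta = 0.1, floor = 0.3, alpha = 0.05) {
  modes <- match.arg(modes, several.ok = TRUE)
  joined <- dplyr::inner_join(
    variables,
    dplyr::rename(fits, scope = "target"),
    by = c("subject", "parcellation", "scope")
  )
  if (nrow(joined) == 0) {
    stop("no matching (subject, parcellation, scope) rows between tables",
      call. = FALSE
    )
  }
  levels_present <- unique(joined$parcellation)
  if ("group_median" %in% modes && length(levels_present) < 3) {
    stop("group-median mode needs at least 3 parcellations", call. = FALSE)
  }

  # a constant variable (or constant fits) has no defined correlation;
  # report NA rather than fail, and classify such variables as `neither`
  safe_cor <- function(x, y) {
    if (pop_sd(x) == 0 || pop_sd(y) == 0) {
      return(list(estimate = NA_real_, p.value = NA_real_))
    }
    cor.test(x, y)
  }

  per <- purrr::map_dfr(variable_cols, function(v) {
    purrr::map_dfr(levels_present, function(lv) {
      d <- joined[joined$parcellation == lv, ]
      ct <- safe_cor(d[[v]], d$fit)
      tibble::tibble(
        variable = v, parcellation = lv,
        r = unname(ct$estimate), p = ct$p.value, n = nrow(d)
      )
    })
  })

  summary <- purrr::map_dfr(variable_cols, function(v) {
    pv <- per[per$variable == v, ]
    mean_indiv <- if (all(is.na(pv$r))) NA_real_ else fisher_z_mean(abs(pv$r))
    indiv_sig <- isTRUE(mean(pv$p < alpha, na.rm = TRUE) >= 0.5)
    joint_r <- joint_p <- NA_real_
    if ("joint" %in% modes) {
      ct <- safe_cor(joined[[v]], joined$fit)
      joint_r <- unname(ct$estimate)
      joint_p <- ct$p.value
    }
    gm_r <- NA_real_
    if ("group_median" %in% modes) {
      med <- dplyr::summarise(
        dplyr::group_by(joined, .data$parcellation),
        mv = median(.data[[v]]), mf = median(.data$fit)
      )
      gm_r <- if (pop_sd(med$mv) > 0 && pop_sd(med$mf) > 0) {
        cor(med$mv, med$mf)
      } else {
        NA_real_
      }
    }
    # a variable constant within every parcellation has no individual
    # correlation at all; it can still be a pure between-parcellation
    # (inter) predictor
    cmp_indiv <- if (is.na(mean_indiv)) 0 else mean_indiv
    cls <- if (isTRUE(mean_indiv >= abs(joint_r) + delta) && indiv_sig) {
      "intra"
    } else if (isTRUE(abs(joint_r) >= cmp_indiv + delta) &&
      isTRUE(joint_p < alpha)) {
      "inter"
    } else if (isTRUE(mean_indiv >= floor) && isTRUE(abs(joint_r) >= floor) &&
      isTRUE(abs(mean_indiv - abs(joint_r)) < delta)) {
      "both"
    } else {
      "neither"
    }
    tibble::tibble(
      variable = v, mean_individual_r = mean_indiv,
      individual_significant = indiv_sig,
      joint_r = joint_r, joint_p = joint_p,
      group_median_r = gm_r, class = cls
    )
  })

  structure(
    list(
      per_parcellation = per, summary = summary,
      delta = delta, floor = floor, alpha = alpha
    ),
    class = "variable_fit_cor"
  )
}

#' @export
print.variable_fit_cor <- function(x, ...) {
  cat(sprintf(
    "<variable_fit_cor: %d variables, delta = %g, floor = %g, alpha = %g>\n",
    nrow(x$summary), x$delta, x$floor, x$alpha
  ))
  print(x$summary)
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Multiple linear regression of fit values on z-scored data variables
#'
#' Ordinary least squares with intercept on predictor columns z-scored
#' (population SD) within the fitted scope, so coefficients are
#' comparable across predictors and the intercept equals the mean
#' response.
#'
#' @param data Data frame holding response and predictors.
#' @param response Response column name (e.g. `"fit"`).
#' @param predictors Character vector of predictor column names.
#' @param alpha Significance level for flagging coefficients.
#' @return An object of class `parcelfit_mlr`; see [tidy.parcelfit_mlr()]
#'   and [glance.parcelfit_mlr()].
#' @export
mlr_fit <- function(data, response = "fit",
                    predictors = variable_columns(), alpha = 0.05) {
  predictors <- intersect(predictors, names(data))
  if (length(predictors) == 0) stop("no predictor columns found", call. = FALSE)
  y <- data[[response]]
  x <- as.matrix(data[predictors])
  if (nrow(x) <= ncol(x) + 1) {
    stop("need more rows than predictors + 1", call. = FALSE)
  }
  sds <- apply(x, 2, pop_sd)
  if (any(sds == 0)) {
    stop(
      sprintf(
        "constant predictor column(s): %s",
        paste(predictors[sds == 0], collapse = ", ")
      ),
      call. = FALSE
    )
  }
  z <- scale(x, center = TRUE, scale = sds)
  qrz <- qr(cbind(1, z))
  if (qrz$rank < ncol(z) + 1) {
    bad <- predictors[setdiff(seq_len(ncol(z)), qrz$pivot[seq_len(qrz$rank)] - 1)]
    stop(
      sprintf(
        "rank-deficient design; linearly dependent column(s): %s",
        paste(bad, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  df <- as.data.frame(z)
  names(df) <- make.names(predictors)
  df$.y <- y
  fit <- lm(.y ~ ., data = df)
  sm <- summary(fit)
  coefs <- tibble::tibble(
    term = c("(Intercept)", predictors),
    estimate = unname(sm$coefficients[, 1]),
    std_error = unname(sm$coefficients[, 2]),
    p_value = unname(sm$coefficients[, 4]),
    significant = unname(sm$coefficients[, 4]) < alpha
  )
  structure(
    list(
      model = fit, coefficients = coefs,
      r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
      n = nrow(df), alpha = alpha, response = response
    ),
    class = "parcelfit_mlr"
  )
}

#' @export
print.parcelfit_mlr <- function(x, ...) {
  cat(sprintf(
    "<parcelfit_mlr: %d observations, %d predictors, R^2 = %.3f>\n",
    x$n, nrow(x$coefficients) - 1, x$r_squared
  ))
  print(x$coefficients)
  invisible(x)
}

#' Tidy method for MLR fits
#'
#' @param x A `parcelfit_mlr`.
#' @param ... Unused.
#' @return Tibble with one row per term.
#' @method tidy parcelfit_mlr
#' @export
tidy.parcelfit_mlr <- function(x, ...) x$coefficients

#' Glance method for MLR fits
#'
#' @param x A `parcelfit_mlr`.
#' @param ... Unused.
#' @return One-row tibble with `r_squared`, `adj_r_squared`, `n`.
#' @method glance parcelfit_mlr
#' @export
glance.parcelfit_mlr <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, adj_r_squared = x$adj_r_squared, n = x$n
  )
}

# ---------------------------------------------------------------------------

#' Mean distances between optimal parameters across parcellations
#'
#' Per subject, the Euclidean distance between grid-normalized optima
#' `(tau / tau_max, C / C_max)` of two parcellations, averaged over
#' subjects. Subjects missing an optimum in either parcellation are
#' excluded with a warning.
#'
#' @param optima Tibble with columns `subject`, `parcellation`,
#'   `tau_opt`, `C_opt` (one row per subject and parcellation; filter to
#'   one target first).
#' @param tau_max,C_max Normalization constants (default grid bounds 94
#'   and 0.945).
#' @return Symmetric matrix of mean normalized distances.
#' @export
optimal_parameter_distances <- function(optima, tau_max = 94, C_max = 0.945) {
  lv <- sort(unique(optima$parcellation))
  k <- length(lv)
  out <- matrix(0, k, k, dimnames = list(lv, lv))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      a <- optima[optima$parcellation == lv[i], ]
      b <- optima[optima$parcellation == lv[j], ]
      common <- intersect(a$subject, b$subject)
      missing <- setdiff(union(a$subject, b$subject), common)
      if (length(missing) > 0) {
        warning(sprintf(
          "excluding subject(s) without optima in both parcellations: %s",
          paste(missing, collapse = ", ")
        ))
      }
      a <- a[match(common, a$subject), ]
      b <- b[match(common, b$subject), ]
      d <- sqrt(((a$tau_opt - b$tau_opt) / tau_max)^2 +
        ((a$C_opt - b$C_opt) / C_max)^2)
      out[i, j] <- out[j, i] <- mean(d)
    }
  }
  out
}
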