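test_that("Fisher z-transform matches closed forms and round-trips", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  for (r in seq(-0.9, 0.9, 0.1)) {
    expect_lt(abs(fisher_z_inv(fisher_z(r)) - r), 1e-12)
  }
  expect_true(is.finite(fisher_z(1)))
  expect_true(is.finite(fisher_z(-1)))
  # mean of {0.8, 0.6} in z-space
  expect_equal(
    fisher_z_mean(c(0.8, 0.6)),
    tanh((atanh(0.8) + atanh(0.6)) / 2)
  )
  expect_equal(fisher_z_mean(c(0.8, 0.6)), 5 / 7) # closed form: tanh(ln(6)/2)
  # identical correlations are returned unchanged
  expect_equal(fisher_z_mean(rep(0.37, 5)), 0.37, tolerance = 1e-12)
})

make_fit_table <- function(m, levels = colnames(m)) {
  purrr::map_dfr(seq_along(levels), function(j) {
    tibble::tibble(
      subject = sprintf("sub-%02d", seq_len(nrow(m))),
      target = "concatenated",
      parcellation = levels[j],
      fit = m[, j]
    )
  })
}

test_that("fit-pattern correlations behave as a correlation matrix", {
  set.seed(81)
  base <- rnorm(30)
  m <- cbind(
    A1 = base + rnorm(30, 0, 0.3),
    A2 = base + rnorm(30, 0, 0.3),
    B1 = rnorm(30)
  )
  fits <- make_fit_table(m)
  fpc <- fit_pattern_correlations(fits, atlas = c(A1 = "A", A2 = "A", B1 = "B"))
  expect_equal(diag(fpc$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(fpc$r, t(fpc$r))
  expect_equal(fpc$r["A1", "A2"], cor(m[, 1], m[, 2]))
  expect_equal(
    fpc$p["A1", "B1"],
    cor.test(m[, 1], m[, 3])$p.value
  )
  # intra pair correlates strongly; the atlas means reflect that
  expect_gt(fpc$intra_mean, fpc$inter_mean)
  # a common permutation of subjects leaves the matrix unchanged
  perm <- sample(30)
  fpc2 <- fit_pattern_correlations(make_fit_table(m[perm, ]))
  expect_equal(fpc2$r, fpc$r)
})

test_that("signed-rank p-values match exhaustive enumeration at n = 6", {
  x <- c(1, 2, 3, 4, 5, 1)
  y <- c(0, 0, 0, 0, 0, 2) # differences +1 +2 +3 +4 +5 -1
  res <- parcelfit:::signed_rank_test(x, y)
  d <- x - y
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  # enumerate all 2^6 sign assignments
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  w_all <- signs %*% r
  expect_equal(res$p, mean(w_all >= w_obs))
  # cross-check against the reference implementation (no ties here)
  skipless <- suppressWarnings(
    stats::wilcox.test(c(3, 9, 14, 22, 5), c(1, 2, 3, 4, 6),
      paired = TRUE, alternative = "greater", exact = TRUE
    )$p.value
  )
  ours <- parcelfit:::signed_rank_test(c(3, 9, 14, 22, 5), c(1, 2, 3, 4, 6))$p
  expect_equal(ours, skipless)
})

test_that("signed-rank edge cases: identical vectors and uniform direction", {
  expect_warning(
    res <- parcelfit:::signed_rank_test(1:6, 1:6),
    "zero"
  )
  expect_equal(res$p, 1)
  expect_equal(res$effect, 0)
  res2 <- parcelfit:::signed_rank_test(2:11, 1:10)
  expect_equal(res2$effect, 1) # all differences positive
})

test_that("one-sided complementarity holds up to ties", {
  set.seed(82)
  for (i in 1:5) {
    x <- rnorm(12)
    y <- rnorm(12)
    p1 <- parcelfit:::signed_rank_test(x, y)$p
    p2 <- parcelfit:::signed_rank_test(y, x)$p
    expect_lte(min(p1, p2), 0.5 + 1e-12)
  }
})

test_that("the Wilcoxon matrix is corrected and directional", {
  set.seed(83)
  m <- cbind(
    high = rnorm(20, 1), mid = rnorm(20, 0.5), low = rnorm(20, 0)
  )
  wx <- pairwise_wilcoxon(make_fit_table(m))
  expect_true(all(is.na(diag(wx$p_adj))))
  expect_true(all(wx$p_adj >= wx$p_raw, na.rm = TRUE))
  expect_lt(wx$p_adj["high", "low"], 0.05)
  expect_gt(wx$p_adj["low", "high"], 0.5)
  expect_gt(wx$effect["high", "low"], 0)
  # identical columns -> corrected p = 1 both ways
  m2 <- cbind(a = m[, 1], b = m[, 1], c = m[, 2])
  wx2 <- suppressWarnings(pairwise_wilcoxon(make_fit_table(m2)))
  expect_equal(wx2$p_adj["a", "b"], 1)
  expect_equal(wx2$p_adj["b", "a"], 1)
})

make_joined_tables <- function(v, fit, levels) {
  n <- length(v) / length(levels)
  vars <- purrr::map_dfr(seq_along(levels), function(j) {
    idx <- ((j - 1) * n + 1):(j * n)
    row <- tibble::tibble(
      subject = sprintf("sub-%02d", seq_len(n)),
      parcellation = levels[j],
      scope = "concatenated"
    )
    for (cc in variable_columns()) row[[cc]] <- 0
    row[["aver[std(BOLD)]"]] <- v[idx]
    row
  })
  fits <- purrr::map_dfr(seq_along(levels), function(j) {
    idx <- ((j - 1) * n + 1):(j * n)
    tibble::tibble(
      subject = sprintf("sub-%02d", seq_len(n)),
      parcellation = levels[j],
      target = "concatenated",
      fit = fit[idx]
    )
  })
  list(vars = vars, fits = fits)
}

test_that("an exactly linear variable-fit relation gives r = 1 in all modes", {
  set.seed(84)
  v <- rnorm(45)
  tabs <- make_joined_tables(v, 2 * v + 1, c("g1", "g2", "g3"))
  out <- variable_fit_regression(
    tabs$vars, tabs$fits,
    variable_cols = "aver[std(BOLD)]"
  )
  expect_true(all(abs(out$per_parcellation$r - 1) < 1e-12))
  expect_equal(out$summary$joint_r, 1, tolerance = 1e-12)
  expect_equal(out$summary$group_median_r, 1, tolerance = 1e-12)
})

test_that("mean shifts between parcellations produce an intra classification", {
  set.seed(85)
  n <- 20
  v <- rnorm(3 * n)
  fit <- 0.8 * v + rnorm(3 * n, 0, 0.3)
  # shift per-parcellation means oppositely so pooling destroys the relation
  shift <- rep(c(-4, 0, 4), each = n)
  tabs <- make_joined_tables(v + shift, fit - 0.8 * shift, c("g1", "g2", "g3"))
  out <- variable_fit_regression(
    tabs$vars, tabs$fits,
    variable_cols = "aver[std(BOLD)]"
  )
  expect_equal(out$summary$class, "intra")
  expect_gt(out$summary$mean_individual_r, abs(out$summary$joint_r) + 0.1)
})

test_that("group-median correlation matches brute force on 3 medians", {
  set.seed(86)
  tabs <- make_joined_tables(rnorm(30), rnorm(30), c("g1", "g2", "g3"))
  out <- variable_fit_regression(
    tabs$vars, tabs$fits,
    variable_cols = "aver[std(BOLD)]"
  )
  joined <- dplyr::inner_join(
    tabs$vars, dplyr::rename(tabs$fits, scope = "target"),
    by = c("subject", "parcellation", "scope")
  )
  med <- dplyr::summarise(
    dplyr::group_by(joined, parcellation),
    mv = median(`aver[std(BOLD)]`), mf = median(fit)
  )
  expect_equal(
    out$summary$group_median_r,
    pearson_brute(med$mv, med$mf)
  )
})

test_that("classification is invariant to flipping a variable's sign", {
  set.seed(87)
  v <- rnorm(60)
  fit <- 0.7 * v + rnorm(60, 0, 0.4)
  tabs <- make_joined_tables(v, fit, c("g1", "g2", "g3"))
  out1 <- variable_fit_regression(tabs$vars, tabs$fits,
    variable_cols = "aver[std(BOLD)]"
  )
  tabs$vars[["aver[std(BOLD)]"]] <- -tabs$vars[["aver[std(BOLD)]"]]
  out2 <- variable_fit_regression(tabs$vars, tabs$fits,
    variable_cols = "aver[std(BOLD)]"
  )
  expect_equal(out1$summary$class, out2$summary$class)
})

test_that("group-median mode requires at least 3 parcellations", {
  set.seed(88)
  tabs <- make_joined_tables(rnorm(20), rnorm(20), c("g1", "g2"))
  expect_error(
    variable_fit_regression(tabs$vars, tabs$fits,
      variable_cols = "aver[std(BOLD)]"
    ),
    "3 parcellations"
  )
  # dropping the mode makes it legal
  out <- variable_fit_regression(tabs$vars, tabs$fits,
    variable_cols = "aver[std(BOLD)]",
    modes = c("per_parcellation", "joint")
  )
  expect_true(is.na(out$summary$group_median_r))
})

test_that("MLR matches the normal-equations oracle", {
  set.seed(89)
  n <- 100
  x <- matrix(rnorm(n * 5), n, 5)
  colnames(x) <- sprintf("v%d", 1:5)
  y <- x %*% c(1, -2, 0.5, 0, 3) + rnorm(n)
  d <- tibble::as_tibble(as.data.frame(x))
  d$fit <- as.vector(y)
  ml <- mlr_fit(d, "fit", sprintf("v%d", 1:5))
  # oracle: solve the normal equations on the same z-scored design
  z <- scale(x, scale = apply(x, 2, function(v) sqrt(mean((v - mean(v))^2))))
  X <- cbind(1, z)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_lt(max(abs(ml$coefficients$estimate - as.vector(beta))), 1e-10)
  # z-scored predictors: intercept equals the response mean
  expect_lt(abs(ml$coefficients$estimate[1] - mean(y)), 1e-10)
  expect_equal(glance(ml)$r_squared, ml$r_squared)
  expect_equal(nrow(tidy(ml)), 6)
})

test_that("an exact linear response gives R^2 = 1 and nesting never hurts", {
  set.seed(90)
  x <- matrix(rnorm(60 * 3), 60, 3)
  colnames(x) <- c("v1", "v2", "v3")
  d <- tibble::as_tibble(as.data.frame(x))
  d$fit <- 2 * d$v1 - d$v2 + 0.3
  ml <- suppressWarnings(mlr_fit(d, "fit", c("v1", "v2"))) # exact fit
  expect_equal(ml$r_squared, 1, tolerance = 1e-12)
  # adding a column cannot decrease R^2
  d$fit <- 2 * d$v1 - d$v2 + rnorm(60)
  r2_small <- mlr_fit(d, "fit", c("v1", "v2"))$r_squared
  r2_big <- mlr_fit(d, "fit", c("v1", "v2", "v3"))$r_squared
  expect_gte(r2_big, r2_small - 1e-12)
})

test_that("MLR rejects degenerate designs", {
  set.seed(91)
  d <- tibble::tibble(v1 = rnorm(30), fit = rnorm(30))
  d$v2 <- 2 * d$v1
  expect_error(mlr_fit(d, "fit", c("v1", "v2")), "depend")
  expect_error(mlr_fit(d[1:3, ], "fit", c("v1", "v2")), "rows")
})

test_that("optimal-parameter distances follow the grid normalization", {
  opt <- tibble::tibble(
    subject = rep(c("s1", "s2"), 2),
    parcellation = rep(c("g1", "g2"), each = 2),
    tau_opt = c(10, 20, 10, 20),
    C_opt = c(0.3, 0.6, 0.3, 0.6)
  )
  d0 <- optimal_parameter_distances(opt)
  expect_true(all(d0 == 0))

  # one tau step (2 s) apart for a single subject: 2/94
  opt2 <- tibble::tibble(
    subject = c("s1", "s1"),
    parcellation = c("g1", "g2"),
    tau_opt = c(10, 12), C_opt = c(0.3, 0.3)
  )
  expect_equal(
    optimal_parameter_distances(opt2)["g1", "g2"], 2 / 94,
    tolerance = 1e-12
  )

  # two subjects: mean of the two Euclidean distances
  opt3 <- tibble::tibble(
    subject = c("s1", "s2", "s1", "s2"),
    parcellation = rep(c("g1", "g2"), each = 2),
    tau_opt = c(0, 0, 4, 0), C_opt = c(0, 0, 0, 0.3)
  )
  expected <- mean(c(4 / 94, 0.3 / 0.945))
  expect_equal(
    optimal_parameter_distances(opt3)["g1", "g2"], expected,
    tolerance = 1e-12
  )

  # missing subject excluded with warning
  opt4 <- opt3[-2, ]
  expect_warning(d4 <- optimal_parameter_distances(opt4), "excluding")
  expect_equal(d4["g1", "g2"], 4 / 94, tolerance = 1e-12)
})
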