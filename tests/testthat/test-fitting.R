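test_that("the default grid matches the stated geometry", {
  g <- default_grid()
  expect_length(g$tau_values, 48)
  expect_length(g$C_values, 64)
  expect_equal(g$tau_values[1], 0)
  expect_equal(g$C_values[1], 0)
  expect_equal(max(g$tau_values), 94)
  expect_equal(max(g$C_values), 0.945)
  expect_equal(unique(round(diff(g$tau_values), 12)), 2)
  expect_equal(unique(round(diff(g$C_values), 12)), 0.015)
})

test_that("grid construction validates its inputs", {
  expect_error(fit_grid(c(0, 2, 2), c(0, 1)), "increasing")
  expect_error(fit_grid(c(1, 2), c(0, 1)), "start at 0")
})

test_that("upper-triangular similarity matches a brute-force oracle", {
  A <- random_fc(6, seed = 31)
  B <- random_fc(6, seed = 32)
  expect_lt(
    abs(upper_tri_similarity(A, B) -
      pearson_brute(A[upper.tri(A)], B[upper.tri(B)])),
    1e-12
  )
  expect_equal(upper_tri_similarity(A, A), 1)
  # exact anti-ordered triangles
  m1 <- matrix(0, 3, 3)
  m1[upper.tri(m1)] <- c(1, 2, 3)
  m2 <- matrix(0, 3, 3)
  m2[upper.tri(m2)] <- c(3, 2, 1)
  expect_equal(upper_tri_similarity(m1 + t(m1), m2 + t(m2)), -1)
  expect_error(upper_tri_similarity(diag(3), diag(3)), "constant")
})

test_that("argmax and top-5 equal a full-sort oracle of the plane", {
  set.seed(41)
  grid <- fit_grid(seq(0, 10, 2), seq(0, 0.5, 0.1))
  plane <- matrix(rnorm(36), 6, 6)
  tk <- parcelfit:::top_k_points(plane, grid, 5)
  ord <- order(-as.vector(plane))
  expect_equal(tk$similarity, as.vector(plane)[ord][1:5])
  expect_equal(tk$similarity, sort(tk$similarity, decreasing = TRUE))
  ij <- arrayInd(ord[1], dim(plane))
  expect_equal(tk$tau[1], grid$tau_values[ij[1]])
  expect_equal(tk$C[1], grid$C_values[ij[2]])
})

test_that("argmax ties break by scan order (tau, then C, ascending)", {
  grid <- fit_grid(c(0, 2, 4), c(0, 0.1))
  plane <- matrix(c(0, 1, 1, 0, 1, 0), 3, 2) # ties at (2,0),(4,0),(2,0.1)
  tk <- parcelfit:::top_k_points(plane, grid, 3)
  expect_equal(tk$tau, c(2, 2, 4))
  expect_equal(tk$C, c(0, 0.1, 0))
})

test_that("a single-point grid returns that point's similarity", {
  b <- quick_bundle(n_regions = 8, seed = 50)
  g1 <- fit_grid(0, 0)
  fr <- fit_subject(b, "phase", g1,
    sim_config(duration = 120, transient = 30, seed = 5)
  )
  expect_equal(nrow(fr$summary), 4) # 2 sessions + concatenated + eSC
  expect_setequal(
    fr$summary$target,
    c("session1", "session2", "concatenated", "eSC")
  )
  for (nm in names(fr$planes)) {
    expect_equal(dim(fr$planes[[nm]]), c(1, 1))
    expect_equal(
      fr$summary$fit[fr$summary$target == nm],
      fr$planes[[nm]][1, 1]
    )
  }
  expect_equal(fr$summary$tau_opt, rep(0, 4))
  expect_equal(fr$summary$C_opt, rep(0, 4))
})

test_that("the structural plane is invariant to mean-normalizing eSC", {
  b <- quick_bundle(n_regions = 8, seed = 51)
  g <- fit_grid(c(0, 4), c(0, 0.3))
  cfg <- sim_config(duration = 120, transient = 30, seed = 6)
  f1 <- fit_subject(b, "phase", g, cfg)
  b2 <- b
  b2$connectome$counts <- b$connectome$counts /
    parcelfit:::matrix_mean(b$connectome$counts, "full")
  f2 <- fit_subject(b2, "phase", g, cfg, derived = derive_model_inputs(b))
  expect_lt(max(abs(f1$planes$eSC - f2$planes$eSC)), 1e-12)
})

test_that("fit values bound every plane entry and top-k is sorted", {
  b <- quick_bundle(n_regions = 8, seed = 52)
  g <- fit_grid(c(0, 4, 8), c(0, 0.2, 0.4))
  fr <- fit_subject(b, "limit_cycle", g,
    sim_config(duration = 120, transient = 30, seed = 7)
  )
  for (nm in names(fr$planes)) {
    fit <- fr$summary$fit[fr$summary$target == nm]
    expect_true(all(fr$planes[[nm]] <= fit + 1e-15))
    tk <- fr$top_k[[nm]]
    expect_true(all(diff(tk$similarity) <= 0))
    expect_equal(tk$similarity[1], fit)
  }
})

test_that("restricting the grid can never increase the fit", {
  b <- quick_bundle(n_regions = 8, seed = 53)
  cfg <- sim_config(duration = 120, transient = 30, seed = 8)
  g_full <- fit_grid(c(0, 4, 8), c(0, 0.2, 0.4))
  g_sub <- fit_grid(c(0, 4), c(0, 0.2))
  f_full <- fit_subject(b, "phase", g_full, cfg)
  f_sub <- fit_subject(b, "phase", g_sub, cfg)
  # the sub-grid planes reuse the same seeds at shared indices
  for (nm in names(f_full$planes)) {
    expect_lte(
      f_sub$summary$fit[f_sub$summary$target == nm],
      f_full$summary$fit[f_full$summary$target == nm] + 1e-12
    )
  }
})

test_that("cohort fitting is order independent up to row permutation", {
  p <- make_parcellation_hierarchy(8, 8, seed = 60)[[1]]
  cohort <- make_bold_cohort(
    2, p, list(model_kind = "phase", tau = 4, C = 0.3),
    seed = 61, n_sessions = 2, n_volumes = 120
  )
  g <- fit_grid(c(0, 4), c(0, 0.3))
  cfg <- sim_config(duration = 120, transient = 30, seed = 9)
  r1 <- fit_cohort(cohort, "phase", g, cfg)
  r2 <- fit_cohort(rev(cohort), "phase", g, cfg)
  expect_equal(
    dplyr::arrange(r1, subject, target),
    dplyr::arrange(r2, subject, target)
  )
})

test_that("job planning reproduces the study bookkeeping", {
  plan <- plan_jobs(272, 11, 2, default_grid())
  expect_gte(plan$n_runs, 18e6)
  expect_equal(plan$n_functional_optima, 272 * 5)
  expect_equal(plan$n_structural_optima, 272)
  expect_equal(plan_jobs(1, 1, 1, fit_grid(0, 0))$n_runs, 1)
})
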