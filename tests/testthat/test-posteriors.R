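fit_m8_small <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      m8 <- site_class_model("M8", kappa = 2, beta_p = 0.5, beta_q = 1.5,
                             p0 = 0.9, omega_s = 4)
      sim <- simulate_alignment(fix_tree8, m8, fix_freqs_uniform, 200,
                                seed = 31)
      f <- fit_model(sim$alignment, fix_tree8, "M8",
                     options = list(n_restarts = 2, seed = 3))
      memo <<- list(fit = f, truth = sim$truth)
    }
    memo
  }
})

test_that("NEB posteriors are proper and degenerate for one-class models", {
  m0 <- site_class_model("M0", kappa = 2, omega = 0.4)
  sim <- simulate_alignment(fix_tree6, m0, fix_freqs_uniform, 50, seed = 30)
  f0 <- fit_model(sim$alignment, fix_tree6, "M0", fix_freqs_uniform)
  p0 <- neb_posteriors(f0)
  expect_true(all(p0$post == 1))
  expect_equal(p0$posterior_mean_omega,
               rep(f0$model$omega, 50), tolerance = 1e-12)

  f8 <- fit_m8_small()$fit
  p8 <- neb_posteriors(f8)
  expect_equal(rowSums(p8$post), rep(1, 200), tolerance = 1e-10)
  expect_true(all(p8$p_positive >= 0 & p8$p_positive <= 1))
})

test_that("NEB ranks truly positive sites above beta sites", {
  st <- fit_m8_small()
  truth_pos <- st$truth$per_site_class == 11
  auc <- simple_auc(truth_pos, neb_posteriors(st$fit)$p_positive)
  expect_gt(auc, 0.8)
})

test_that("BEB equals NEB on a one-point grid and refuses wrong models", {
  f8 <- fit_m8_small()$fit
  neb <- neb_posteriors(f8)
  beb1 <- beb_posteriors(f8, grid_resolution = 1)
  expect_equal(beb1$p_positive, neb$p_positive, tolerance = 1e-14)
  expect_equal(beb1$posterior_mean_omega, neb$posterior_mean_omega,
               tolerance = 1e-12)

  beb <- beb_posteriors(f8)
  expect_true(all(beb$p_positive >= 0 & beb$p_positive <= 1))
  expect_true(all(beb$report$level %in% c("positive", "suggestive")))
  expect_true(all(beb$report$p_positive > 0.8))
  expect_identical(beb$report$level[beb$report$p_positive > 0.9],
                   rep("positive", sum(beb$report$p_positive > 0.9)))

  m7 <- site_class_model("M7")
  sim <- simulate_alignment(fix_tree6, m7, fix_freqs_uniform, 40, seed = 33)
  f7 <- fit_model(sim$alignment, fix_tree6, "M7",
                  options = list(n_restarts = 1, seed = 1))
  expect_error(beb_posteriors(f7), "M8")
})

test_that("site classification produces a proper three-way profile", {
  f8 <- fit_m8_small()$fit
  cl <- classify_sites(neb_posteriors(f8), gene = "g")
  pr <- cl$profile
  expect_equal(pr$p_purifying + pr$p_neutral + pr$p_positive, 1,
               tolerance = 1e-12)
  expect_identical(levels(cl$labels), c("purifying", "neutral", "positive"))

  # all classes omega < 0.5 -> everything purifying
  m7 <- site_class_model("M7", beta_p = 0.5, beta_q = 9)
  sim <- simulate_alignment(fix_tree6, m7, fix_freqs_uniform, 60, seed = 35)
  f7 <- fit_model(sim$alignment, fix_tree6, "M7",
                  options = list(n_restarts = 1, seed = 1))
  cl7 <- classify_sites(neb_posteriors(f7))
  expect_equal(cl7$profile$p_purifying, 1)

  expect_error(classify_sites(neb_posteriors(f8), omega_low = 1.2,
                              omega_high = 1.1), "omega_low")
  expect_error(selection_profile(0.5, 0.4, 0.3), "sum to 1")
})
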