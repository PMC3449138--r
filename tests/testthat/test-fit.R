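test_that("M0 fitting recovers generating parameters on one instance", {
  m <- site_class_model("M0", kappa = 2.5, omega = 0.3)
  sim <- simulate_alignment(fix_tree8, m, fix_freqs_uniform, 300, seed = 5)
  f <- fit_model(sim$alignment, fix_tree8, "M0", fix_freqs_uniform)
  expect_true(f$converged)
  expect_gt(f$model$omega, 0.2)
  expect_lt(f$model$omega, 0.4)
  expect_gt(f$model$kappa, 1.8)
  expect_lt(f$model$kappa, 3.3)
  expect_equal(f$n_free_params, 2L)
})

test_that("warm-started nested fits never lose likelihood and are seeded", {
  m8 <- site_class_model("M8", kappa = 2, beta_p = 0.5, beta_q = 1.5,
                         p0 = 0.92, omega_s = 3)
  sim <- simulate_alignment(fix_tree8, m8, fix_freqs_uniform, 200, seed = 6)
  call <- positive_selection_test(sim$alignment, fix_tree8,
                                  options = list(n_restarts = 2, seed = 9))
  expect_gte(call$fits$M8$lnL, call$fits$M8a$lnL - 1e-6)
  expect_gte(call$fits$M8$lnL, call$fits$M7$lnL - 1e-6)

  # determinism: same data, same seed -> identical lnL to the last bit
  f1 <- fit_model(sim$alignment, fix_tree8, "M8a",
                  options = list(n_restarts = 3, seed = 4))
  f2 <- fit_model(sim$alignment, fix_tree8, "M8a",
                  options = list(n_restarts = 3, seed = 4))
  expect_identical(f1$lnL, f2$lnL)
  expect_identical(f1$model$p0, f2$model$p0)
})

test_that("LRT arithmetic, boundary clamping and nesting rules", {
  m8 <- site_class_model("M8", kappa = 2, beta_p = 0.5, beta_q = 1.5,
                         p0 = 0.92, omega_s = 3)
  sim <- simulate_alignment(fix_tree8, m8, fix_freqs_uniform, 150, seed = 7)
  o <- list(n_restarts = 1, seed = 1)
  f7 <- fit_model(sim$alignment, fix_tree8, "M7", options = o)
  f8a <- fit_model(sim$alignment, fix_tree8, "M8a", options = o)
  f8 <- fit_model(sim$alignment, fix_tree8, "M8", options = o)

  l <- lrt(f7, f8)
  expect_equal(l$df, 2L)
  expect_equal(l$stat, 2 * (f8$lnL - f7$lnL), tolerance = 1e-12)
  expect_equal(l$p_value,
               stats::pchisq(l$stat, 2, lower.tail = FALSE))
  expect_equal(lrt(f8a, f8)$df, 1L)

  # identical lnL -> stat 0, p 1; any genuine negative excess clamps with
  # a warning
  fx <- f8a; fx$lnL <- f8$lnL
  expect_equal(lrt(fx, f8)$stat, 0)
  expect_equal(lrt(fx, f8)$p_value, 1)
  fneg <- f8a; fneg$lnL <- f8$lnL + 1e-6
  expect_warning(lneg <- lrt(fneg, f8), "clamped")
  expect_equal(lneg$stat, 0)
  expect_equal(lneg$p_value, 1)

  expect_error(lrt(f7, f8a), "nested")
  funconv <- f7; funconv$converged <- FALSE
  expect_error(lrt(funconv, f8), "converged")

  # chi-square reference value: stat 5.991 on 2 df sits at p ~ 0.0500
  fa <- f7; fb <- f8
  fb$lnL <- fa$lnL + 5.991 / 2
  expect_equal(lrt(fa, fb)$p_value, 0.05, tolerance = 1e-3)
})

test_that("protocol errors: foreground requirements and withheld verdicts", {
  m0 <- site_class_model("M0", kappa = 2, omega = 0.4)
  sim <- simulate_alignment(fix_tree8, m0, fix_freqs_uniform, 60, seed = 8)
  expect_error(branch_site_test(sim$alignment, fix_tree8),
               "foreground")
  expect_error(fit_model(sim$alignment, fix_tree8, "BSA_alt"),
               "foreground")
  expect_error(positive_selection_test(sim$alignment, fix_tree8, alpha = 0),
               "alpha")
})
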