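test_that("sample_tree produces seeded rooted binary trees", {
  tr <- sample_tree(4, 0.3, seed = 7)
  expect_equal(length(tr$tip.label), 4L)
  expect_equal(nrow(tr$edge), 6L)
  expect_true(ape::is.rooted(tr))
  expect_identical(ape::write.tree(sample_tree(5, 0.2, seed = 3)),
                   ape::write.tree(sample_tree(5, 0.2, seed = 3)))
  expect_error(sample_tree(1), "n_taxa")
  expect_error(sample_tree(4, 0), "mean_branch_length")
})

test_that("alignment simulation is seeded and leaves global RNG alone", {
  m <- site_class_model("M0", kappa = 2, omega = 0.5)
  s1 <- simulate_alignment(fix_tree6, m, fix_freqs_uniform, 40, seed = 5)
  s2 <- simulate_alignment(fix_tree6, m, fix_freqs_uniform, 40, seed = 5)
  expect_identical(s1$alignment$sites, s2$alignment$sites)
  expect_identical(s1$truth$per_site_class, s2$truth$per_site_class)

  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_alignment(fix_tree6, m,
                                              fix_freqs_uniform, 5,
                                              seed = 9))
  expect_identical(runif(1), before)
})

test_that("simulated codon frequencies converge to the stationary law", {
  # two taxa, moderate divergence; 20k codons against pi by chi-square GOF
  tr <- read_newick(text = "(a:0.25,b:0.25);")
  m <- site_class_model("M0", kappa = 2, omega = 0.6)
  s <- simulate_alignment(tr, m, fix_freqs_uniform, 20000, seed = 13)
  # one taxon only: sites are independent draws, tips of one site are not
  counts <- tabulate(s$alignment$sites[1, ], nbins = 61)
  gof <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / 61, 61)))
  expect_gt(gof$p.value, 0.01)
})

test_that("class frequencies follow mixture proportions", {
  m8 <- site_class_model("M8", kappa = 2, beta_p = 1, beta_q = 2,
                         p0 = 0.8, omega_s = 3)
  s <- simulate_alignment(fix_tree6, m8, fix_freqs_uniform, 5000, seed = 17)
  frac_extra <- mean(s$truth$per_site_class == 11)
  expect_equal(frac_extra, 0.2, tolerance = 0.03)
})

test_that("coevolving pairs share profiles at zero jitter and renormalise", {
  p0 <- simulate_coevolving_pair(fix_tree6, c(0.7, 0.2, 0.1), 0, 30,
                                 seed = 19)
  expect_equal(p0$profiles$ligand$p_purifying,
               p0$profiles$receptor$p_purifying)
  expect_false(p0$clipped)
  for (eps in c(0.05, 0.2, 0.5)) {
    p <- simulate_coevolving_pair(fix_tree6, c(0.7, 0.2, 0.1), eps, 10,
                                  seed = 23)
    for (side in p$profiles)
      expect_equal(side$p_purifying + side$p_neutral + side$p_positive, 1,
                   tolerance = 1e-12)
  }
  pc <- simulate_coevolving_pair(fix_tree6, c(0.9, 0.05, 0.05), 0.4, 10,
                                 seed = 29)
  expect_true(pc$clipped)
  expect_error(simulate_coevolving_pair(fix_tree6, c(0.7, 0.2, 0.1), -0.1,
                                        10), "jitter")
})

test_that("Ct simulation inverts exactly at zero noise", {
  expr <- matrix(c(1, 2, 4, 8, 3, 5), 2, 3,
                 dimnames = list(c("g1", "g2"), c("t1", "t2", "t3")))
  tab <- simulate_ct_table(expr, noise_sd = 0, seed = 1)
  rel <- delta_delta_ct(tab, calibrator_rule = "none")
  for (i in seq_len(nrow(rel)))
    expect_equal(rel$fold[i], expr[rel$gene[i], rel$tissue[i]],
                 tolerance = 1e-12)
  # doubling expression lowers mean Ct by one cycle (expr 1 vs 2 at t1)
  ct1 <- tab$ct$Ct[tab$ct$gene == "g1" & tab$ct$tissue == "t1"]
  ct2 <- tab$ct$Ct[tab$ct$gene == "g2" & tab$ct$tissue == "t1"]
  expect_equal(mean(ct1) - mean(ct2), 1)

  t1 <- simulate_ct_table(expr, 0.4, seed = 6)
  t2 <- simulate_ct_table(expr, 0.4, seed = 6)
  expect_identical(t1$ct$Ct, t2$ct$Ct)
  expect_error(simulate_ct_table(expr, -1), "noise_sd")
  expect_error(simulate_ct_table(matrix(c(-1, 2), 1, 2,
    dimnames = list("g", c("a", "b"))), 0), "> 0")
})
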