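test_that("F3x4 frequencies match a hand computation and handle edge cases", {
  # uniform position frequencies -> all sense codons 1/61
  aln_u <- codon_alignment_from_strings(c(
    a = "TTTCCCAAAGGG", b = "CCCAAAGGGTTT", c = "AAAGGGTTTCCC",
    d = "GGGTTTCCCAAA"))
  expect_equal(as.numeric(f3x4_frequencies(aln_u)), rep(1 / 61, 61),
               tolerance = 1e-12)

  # hand computation on a two-sequence fixture
  aln <- codon_alignment_from_strings(c(a = "ATGATG", b = "ATGACG"))
  # position 1: A=1; position 2: T 3/4, C 1/4; position 3: G=1
  p2 <- c(T = 0.75, C = 0.25)
  expected_atg <- 1 * p2[["T"]] * 1
  expected_acg <- 1 * p2[["C"]] * 1
  fr <- f3x4_frequencies(aln)
  expect_equal(unname(fr["ATG"] / fr["ACG"]), expected_atg / expected_acg,
               tolerance = 1e-12)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  # codons using unobserved letters at a position get zero mass
  expect_equal(unname(fr["GGG"]), 0)

  expect_error(f3x4_frequencies(codon_alignment(
    matrix(integer(0), 2, 0), c("a", "b"))), "empty")
})

test_that("GY94 rate matrices satisfy their structural invariants", {
  fr <- f61_frequencies(codon_alignment_from_strings(
    c(a = "ATGAAACCC", b = "ATGAAGCCA")))
  q <- build_rate_matrix(fr, kappa = 2.5, omega = 0.4)
  expect_equal(max(abs(rowSums(q))), 0, tolerance = 1e-10)
  expect_equal(-sum(as.numeric(fr) * diag(q)), 1, tolerance = 1e-12)
  flux <- as.numeric(fr) * q          # pi_i Q_ij
  expect_lt(max(abs(flux - t(flux))), 1e-12)

  # omega = 0: every nonsynonymous entry exactly zero
  q0 <- build_rate_matrix(fr, kappa = 2, omega = 0)
  aa <- fix_code$sense_aa
  nonsyn <- outer(aa, aa, "!=")
  expect_true(all(q0[nonsyn] == 0))

  # uniform freqs, kappa = 1, omega = 1: all single-step rates equal
  qu <- build_rate_matrix(fix_freqs_uniform, 1, 1, normalize = FALSE)
  offd <- qu[qu > 0]
  expect_equal(max(offd), min(offd))

  expect_error(build_rate_matrix(fr, kappa = -1, omega = 1), "kappa")
  expect_error(build_rate_matrix(fr, kappa = 2, omega = -0.1), "omega")
})

test_that("transition matrices are stochastic and Chapman-Kolmogorov holds", {
  q <- build_rate_matrix(fix_freqs_uniform, 2, 0.5)
  expect_equal(transition_matrix(q, fix_freqs_uniform, 0), diag(61),
               tolerance = 1e-10)
  set.seed(5)
  for (t in runif(3, 0.01, 2)) {
    P <- transition_matrix(q, fix_freqs_uniform, t)
    expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-10)
    expect_true(all(P >= 0))
  }
  s <- 0.3; t <- 0.7
  Pst <- transition_matrix(q, fix_freqs_uniform, s + t)
  PsPt <- transition_matrix(q, fix_freqs_uniform, s) %*%
    transition_matrix(q, fix_freqs_uniform, t)
  expect_lt(max(abs(Pst - PsPt)), 1e-8)
  expect_error(transition_matrix(q, fix_freqs_uniform, -0.1), ">= 0")
})

test_that("site-class tables realise each model family correctly", {
  m7 <- build_site_classes(site_class_model("M7", beta_p = 1, beta_q = 3))
  expect_equal(nrow(m7), 10L)
  expect_equal(m7$proportion, rep(0.1, 10))
  expect_true(all(m7$omega_background > 0 & m7$omega_background < 1))
  expect_identical(m7$omega_background, m7$omega_foreground)

  m8a <- build_site_classes(site_class_model("M8a", p0 = 0.85))
  expect_equal(m8a$omega_background[11], 1)
  expect_equal(sum(m8a$proportion), 1, tolerance = 1e-12)

  bsa <- build_site_classes(site_class_model("BSA_alt", bs_p0 = 0.6,
                                             bs_p1 = 0.2, bs_omega0 = 0.1,
                                             bs_omega2 = 2))
  expect_equal(bsa$proportion, c(0.6, 0.2, 0.15, 0.05), tolerance = 1e-12)
  expect_equal(bsa$omega_background, c(0.1, 1, 0.1, 1))
  expect_equal(bsa$omega_foreground, c(0.1, 1, 2, 2))

  expect_error(site_class_model("BSA_alt", bs_p0 = 0, bs_p1 = 0),
               "degenerate")
  m0 <- build_site_classes(site_class_model("M0", omega = 0.3))
  expect_equal(nrow(m0), 1L)
})

test_that("pruning equals the zero-time limit and is invariant to row order", {
  a2 <- codon_alignment_from_strings(c(A = "ATG", B = "ATG"))
  t2 <- read_newick(text = "(A:0,B:0);")
  m0 <- site_class_model("M0", kappa = 2, omega = 0.5)
  ll <- log_likelihood(a2, t2, m0, fix_freqs_uniform)
  expect_equal(ll$lnL, log(1 / 61), tolerance = 1e-12)

  sim <- simulate_alignment(fix_tree6, m0, fix_freqs_uniform, 40, seed = 2)
  l1 <- log_likelihood(sim$alignment, fix_tree6, m0, fix_freqs_uniform)
  perm <- sample(nrow(sim$alignment$sites))
  aln_p <- codon_alignment(sim$alignment$sites[perm, ],
                           sim$alignment$taxon_names[perm])
  l2 <- log_likelihood(aln_p, fix_tree6, m0, fix_freqs_uniform)
  expect_equal(l1$lnL, l2$lnL, tolerance = 1e-10)
})

test_that("pruning lnL is invariant to root placement (pulley principle)", {
  m8 <- site_class_model("M8", kappa = 1.8, beta_p = 0.6, beta_q = 1.4,
                         p0 = 0.9, omega_s = 2.5)
  sim <- simulate_alignment(fix_tree6, m8, fix_freqs_uniform, 30, seed = 3)
  l1 <- log_likelihood(sim$alignment, fix_tree6, m8, fix_freqs_uniform)
  rerooted <- ape::root(ape::unroot(fix_tree6), outgroup = "t3",
                        resolve.root = TRUE)
  rerooted$foreground <- rep(FALSE, nrow(rerooted$edge))
  l2 <- log_likelihood(sim$alignment, rerooted, m8, fix_freqs_uniform)
  expect_equal(l1$lnL, l2$lnL, tolerance = 1e-8)
})

test_that("beta discretisation is stable in the number of categories", {
  m10 <- site_class_model("M7", kappa = 2, beta_p = 0.8, beta_q = 1.6,
                          n_categories = 10)
  m50 <- site_class_model("M7", kappa = 2, beta_p = 0.8, beta_q = 1.6,
                          n_categories = 50)
  sim <- simulate_alignment(fix_tree6, m10, fix_freqs_uniform, 100, seed = 4)
  l10 <- log_likelihood(sim$alignment, fix_tree6, m10, fix_freqs_uniform)$lnL
  l50 <- log_likelihood(sim$alignment, fix_tree6, m50, fix_freqs_uniform)$lnL
  expect_lt(abs(l10 - l50), 0.5)
})

test_that("missing cells marginalise over all states", {
  aln <- codon_alignment_from_strings(c(a = "ATG---", b = "ATGCCC",
                                        c = "ATGCCA"))
  tr <- read_newick(text = "((a:0.1,b:0.1):0.05,c:0.2);")
  m0 <- site_class_model("M0", kappa = 2, omega = 0.5)
  ll <- log_likelihood(aln, tr, m0, fix_freqs_uniform)
  # site 2: explicit marginalisation over taxon a's codon
  tab <- build_site_classes(m0)
  bf <- brute_force_lnl(aln, tr, tab, 2, fix_freqs_uniform)
  expect_equal(ll$lnL, bf, tolerance = 1e-10)
})
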