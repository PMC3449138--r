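test_that("diagonal distance geometry", {
  expect_equal(diagonal_distance(0.3, 0.3), 0)
  expect_equal(diagonal_distance(0, 1), 1 / sqrt(2))
  expect_equal(diagonal_distance(1, 0), 1 / sqrt(2))
  p <- selection_profile(0.8, 0.15, 0.05, "g")
  expect_equal(pair_concordance(p, p), 0)
  expect_error(diagonal_distance(1.2, 0.5), "0,1")
})

test_that("distances are symmetric, nonnegative, zero iff equal", {
  set.seed(12)
  for (i in 1:20) {
    v1 <- as.numeric(stats::rmultinom(1, 100, c(0.6, 0.3, 0.1))) / 100
    v2 <- as.numeric(stats::rmultinom(1, 100, c(0.2, 0.5, 0.3))) / 100
    p1 <- selection_profile(v1[1], v1[2], v1[3])
    p2 <- selection_profile(v2[1], v2[2], v2[3])
    expect_gte(pair_concordance(p1, p2), 0)
    expect_equal(pair_concordance(p1, p2), pair_concordance(p2, p1))
    if (!identical(v1, v2)) expect_gt(pair_concordance(p1, p2), 0)
  }
})

test_that("lineage concordance compares matching classes only", {
  a <- pair_point("rln3", "rxfp3", "purifying", 0.8, 0.82)
  b <- pair_point("rln3", "rxfp3", "purifying", 0.8, 0.82)
  expect_equal(lineage_concordance(a, b), 0)
  d <- lineage_concordance(pair_point("l", "r", "neutral", 0, 0),
                           pair_point("l", "r", "neutral", 1, 1))
  expect_equal(d, sqrt(2))
  expect_error(lineage_concordance(
    a, pair_point("rln3", "rxfp3", "neutral", 0.8, 0.82)), "mismatch")
})

test_that("region selection fractions and the 20% flag", {
  post <- structure(list(p_positive = c(rep(0.95, 3), rep(0.05, 27)),
                         posterior_mean_omega = rep(0.5, 30),
                         method = "NEB"), class = "site_posterior")
  annot <- domain_annotation(data.frame(
    gene = "r1", region = c("LDLa", "LRR"), start = c(1, 11),
    end = c(10, 25)))
  rs <- region_selection_fraction(post, annot)
  expect_equal(rs$fraction[rs$region == "LDLa"], 0.3)
  expect_true(rs$flag_over_20pct[rs$region == "LDLa"])
  expect_equal(rs$fraction[rs$region == "LRR"], 0)
  expect_false(rs$flag_over_20pct[rs$region == "LRR"])
  # codons 26..30 are unannotated and appear in no denominator
  expect_equal(sum(rs$n_codons), 25)

  # row order of the annotation is irrelevant
  rs2 <- region_selection_fraction(post, annot[2:1, ])
  expect_equal(rs[order(rs$region), ], rs2[order(rs2$region), ],
               ignore_attr = TRUE)

  none <- post; none$p_positive <- rep(0, 30)
  rs0 <- region_selection_fraction(none, annot)
  expect_true(all(rs0$fraction == 0) && !any(rs0$flag_over_20pct))

  bad <- domain_annotation(data.frame(gene = "r1", region = "TM1",
                                      start = 28, end = 40))
  expect_error(region_selection_fraction(post, bad), "past alignment")
})

test_that("candidate-receptor ranking scores, ties and weights", {
  lig <- selection_profile(0.7, 0.2, 0.1, "lig")
  recs <- list(match = selection_profile(0.7, 0.2, 0.1),
               off = selection_profile(0.9, 0.08, 0.02))
  rk <- rank_candidate_receptors(lig, recs,
                                 coexpr = c(match = 1, off = 0.2))
  expect_identical(rk$receptor[1], "match")
  expect_equal(rk$concordance_distance[1], 0)

  # w2 = 0: coexpression ignored
  rk0 <- rank_candidate_receptors(lig, recs,
                                  coexpr = c(match = 0, off = 1),
                                  weights = c(1, 0))
  expect_identical(rk0$receptor[1], "match")

  # identical receptors -> reported tie, alphabetical order
  twins <- list(b_rec = selection_profile(0.7, 0.2, 0.1),
                a_rec = selection_profile(0.7, 0.2, 0.1))
  rkt <- rank_candidate_receptors(lig, twins)
  expect_true(all(rkt$tied))
  expect_identical(rkt$receptor, c("a_rec", "b_rec"))
  expect_identical(rkt$rank, c(1L, 1L))

  expect_error(rank_candidate_receptors(lig, recs, weights = c(-1, 1)),
               "nonnegative")
  expect_error(rank_candidate_receptors(lig, list()), "at least one")
})
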