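mk_table <- function(dct_by_gene, tissues = "gonad", sexes = "F",
                     reps = 1, yield = NULL) {
  ref_ct <- 15
  grid <- expand.grid(gene = names(dct_by_gene), tissue = tissues,
                      sex = sexes, replicate = seq_len(reps),
                      stringsAsFactors = FALSE)
  grid$Ct <- ref_ct + dct_by_gene[grid$gene]
  ref <- expand.grid(tissue = tissues, sex = sexes,
                     replicate = seq_len(reps), stringsAsFactors = FALSE)
  ref$Ct_ref <- ref_ct
  y <- yield %||% expand.grid(tissue = tissues, sex = sexes,
                              stringsAsFactors = FALSE)
  if (is.null(yield)) y$yield_ug <- 10
  expression_table(grid, ref, y)
}

test_that("delta-delta-Ct identities and the mean-calibrator worked example", {
  # two genes with dCt 5 and 7 -> calibrator 6 -> folds 2 and 0.5
  tab <- mk_table(c(g1 = 5, g2 = 7))
  rel <- delta_delta_ct(tab)
  expect_equal(rel$fold[rel$gene == "g1"], 2)
  expect_equal(rel$fold[rel$gene == "g2"], 0.5)

  # no calibrator: ddCt = dCt; dCt 0 -> fold 1; dCt -1 -> fold 2
  tab2 <- mk_table(c(a = 0, b = -1))
  rel2 <- delta_delta_ct(tab2, calibrator_rule = "none")
  expect_equal(rel2$fold[rel2$gene == "a"], 1)
  expect_equal(rel2$fold[rel2$gene == "b"], 2)
})

test_that("fold is invariant to a constant added to a (tissue, sex) block", {
  tab <- mk_table(c(g1 = 5, g2 = 7))
  shifted <- tab
  shifted$ct$Ct <- shifted$ct$Ct + 3.7
  shifted$reference$Ct_ref <- shifted$reference$Ct_ref + 3.7
  expect_equal(delta_delta_ct(shifted)$fold, delta_delta_ct(tab)$fold,
               tolerance = 1e-12)
})

test_that("ddCt chain matches a brute-force per-replicate computation", {
  set.seed(40)
  tabn <- simulate_ct_table(matrix(2^runif(6, -2, 3), 2, 3,
                                   dimnames = list(c("g1", "g2"),
                                                   c("t1", "t2", "t3"))),
                            noise_sd = 0.3, seed = 8)
  rel <- delta_delta_ct(tabn)
  # brute force one block
  blk <- tabn$ct[tabn$ct$tissue == "t2" & tabn$ct$sex == "M", ]
  ref <- tabn$reference[tabn$reference$tissue == "t2" &
                          tabn$reference$sex == "M", ]
  folds <- sapply(1:3, function(r) {
    d <- blk[blk$replicate == r, ]
    dct <- d$Ct - ref$Ct_ref[ref$replicate == r]
    2^(-(dct - mean(dct)))
  })
  expect_equal(rel$fold[rel$gene == "g1" & rel$tissue == "t2" &
                          rel$sex == "M"],
               mean(folds[1, ]), tolerance = 1e-12)
})

test_that("yield correction is proportional and validated", {
  tissues <- c("brain", "gonad")
  y <- expand.grid(tissue = tissues, sex = "F", stringsAsFactors = FALSE)
  y$yield_ug <- c(10, 10)
  tab <- mk_table(c(g1 = 2, g2 = 4), tissues = tissues, yield = y)
  rel <- delta_delta_ct(tab)
  yc <- yield_correct(rel, tab)
  expect_equal(yc$yield_corrected, yc$fold) # equal yields: no change

  y2 <- y; y2$yield_ug <- c(20, 10)
  tab2 <- mk_table(c(g1 = 2, g2 = 4), tissues = tissues, yield = y2)
  yc2 <- yield_correct(delta_delta_ct(tab2), tab2)
  brain <- yc2$tissue == "brain"
  expect_equal(yc2$yield_corrected[brain], yc2$fold[brain] * 20 / 15)
  expect_equal(yc2$yield_corrected[!brain], yc2$fold[!brain] * 10 / 15)

  ybad <- y; ybad$yield_ug <- c(-1, 10)
  expect_error(expression_table(tab$ct, tab$reference, ybad), "positive")
})

test_that("coexpression score handles agreement, reversal and degeneracy", {
  mkrel <- function(folds) data.frame(
    gene = "g", tissue = names(folds), sex = "F", fold = unname(folds))
  a <- mkrel(c(brain = 8, gonad = 4, eye = 2, gill = 1))
  expect_equal(coexpression_score(a, a), 1)
  b <- mkrel(c(brain = 1, gonad = 2, eye = 4, gill = 8))
  expect_equal(coexpression_score(a, b), -1)
  flat <- mkrel(c(brain = 2, gonad = 2, eye = 2, gill = 2))
  s <- coexpression_score(a, flat)
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "degenerate"))
  expect_error(coexpression_score(a, mkrel(c(brain = 1, gonad = 2))),
               "3 shared")
})

test_that("expression table validation catches structural holes", {
  tab <- mk_table(c(g1 = 5))
  expect_error(expression_table(tab$ct,
                                tab$reference[0, ], tab$rna_yield),
               "reference")
  expect_error(expression_table(tab$ct, tab$reference,
                                tab$rna_yield[0, ]), "yield")
  bad <- tab$ct; bad$Ct[1] <- -2
  expect_error(expression_table(bad, tab$reference, tab$rna_yield),
               "positive")
})
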