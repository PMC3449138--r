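#' qPCR expression table
#'
#' Bundles the three TSV-shaped inputs of a relative-expression analysis:
#' per-well target Ct values (gene, tissue, sex, replicate, Ct), reference-
#' gene Ct values per (tissue, sex, replicate), and total RNA yield per
#' (tissue, sex). Ct values above \code{ct_ceiling} (undetected wells) are
#' flagged and excluded from averages.
#'
#' @param ct data.frame(gene, tissue, sex, replicate, Ct).
#' @param reference data.frame(tissue, sex, replicate, Ct_ref).
#' @param rna_yield data.frame(tissue, sex, yield_ug), yields > 0.
#' @param ct_ceiling detection ceiling in cycles (default 40).
#' @return An \code{expression_table}.
#' @export
expression_table <- function(ct, reference, rna_yield, ct_ceiling = 40) {
  need <- function(d, cols, what)
    if (!all(cols %in% names(d)))
      stop(what, " needs columns: ", paste(cols, collapse = ", "),
           call. = FALSE)
  need(ct, c("gene", "tissue", "sex", "replicate", "Ct"), "ct")
  need(reference, c("tissue", "sex", "replicate", "Ct_ref"), "reference")
  need(rna_yield, c("tissue", "sex", "yield_ug"), "rna_yield")
  if (any(ct$Ct <= 0) || any(reference$Ct_ref <= 0))
    stop("Ct values must be positive", call. = FALSE)
  if (any(rna_yield$yield_ug <= 0))
    stop("RNA yields must be positive", call. = FALSE)
  blocks <- unique(ct[c("tissue", "sex")])
  key <- function(d) paste(d$tissue, d$sex)
  if (!all(key(blocks) %in% key(reference)))
    stop("missing reference-gene Ct for some (tissue, sex) block",
         call. = FALSE)
  if (!all(key(blocks) %in% key(rna_yield)))
    stop("missing RNA yield for some (tissue, sex) block", call. = FALSE)
  ct$undetected <- ct$Ct > ct_ceiling
  structure(list(ct = ct, reference = reference, rna_yield = rna_yield,
                 ct_ceiling = ct_ceiling),
            class = "expression_table")
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per replicate, \eqn{\Delta Ct = Ct_{gene} - Ct_{ref}} against the
#' reference gene (18S in the motivating study); then
#' \eqn{\Delta\Delta Ct = \Delta Ct - } calibrator, where the default
#' calibrator is the mean \eqn{\Delta Ct} over all genes in the same
#' (tissue, sex) block; fold change is \eqn{2^{-\Delta\Delta Ct}} assuming
#' perfect doubling per cycle. Replicate means and standard errors of the
#' fold are reported over biological replicates (undetected wells excluded).
#'
#' @param table an \code{\link{expression_table}}.
#' @param calibrator_rule "mean_all_genes" (default: the study's calibrator)
#'   or "none" (\eqn{\Delta\Delta Ct = \Delta Ct}).
#' @return data.frame of class \code{relative_expression}: gene, tissue,
#'   sex, fold, fold_se, n_replicates.
#' @export
delta_delta_ct <- function(table, calibrator_rule = c("mean_all_genes",
                                                      "none")) {
  calibrator_rule <- match.arg(calibrator_rule)
  ct <- table$ct[!table$ct$undetected, , drop = FALSE]
  ref <- table$reference
  m <- merge(ct, ref, by = c("tissue", "sex", "replicate"))
  if (nrow(m) < nrow(ct))
    stop("missing reference Ct for some replicate", call. = FALSE)
  m$dct <- m$Ct - m$Ct_ref
  # per-replicate calibrator: mean dCt over genes in the (tissue, sex,
  # replicate) comparison set
  if (calibrator_rule == "mean_all_genes") {
    cal <- stats::aggregate(dct ~ tissue + sex + replicate, m, mean)
    names(cal)[names(cal) == "dct"] <- "calibrator"
    m <- merge(m, cal, by = c("tissue", "sex", "replicate"))
  } else m$calibrator <- 0
  m$fold_rep <- 2^(-(m$dct - m$calibrator))
  ag <- stats::aggregate(fold_rep ~ gene + tissue + sex, m, function(x)
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x)))
  out <- data.frame(gene = ag$gene, tissue = ag$tissue, sex = ag$sex,
                    fold = ag$fold_rep[, "mean"],
                    fold_se = ifelse(is.na(ag$fold_rep[, "se"]), 0,
                                     ag$fold_rep[, "se"]),
                    n_replicates = as.integer(ag$fold_rep[, "n"]))
  out <- out[order(out$gene, out$tissue, out$sex), ]
  rownames(out) <- NULL
  class(out) <- c("relative_expression", "data.frame")
  out
}

#' Correct relative expression for total RNA yield
#'
#' Multiplies each (tissue, sex) block's fold values by
#' \code{yield / mean(yield)}, enabling cross-tissue comparison of relative
#' mRNA amounts per tissue.
#'
#' @param rel a \code{relative_expression} data.frame.
#' @param table the \code{\link{expression_table}} holding the yields.
#' @return \code{rel} with columns \code{yield_corrected} and
#'   \code{yield_corrected_se} added.
#' @export
yield_correct <- function(rel, table) {
  y <- table$rna_yield
  w <- y$yield_ug / mean(y$yield_ug)
  idx <- match(paste(rel$tissue, rel$sex), paste(y$tissue, y$sex))
  if (anyNA(idx))
    stop("missing RNA yield for block ",
         paste(rel$tissue, rel$sex)[which(is.na(idx))[1]], call. = FALSE)
  rel$yield_corrected <- rel$fold * w[idx]
  rel$yield_corrected_se <- rel$fold_se * w[idx]
  rel
}

#' Coexpression score of a ligand-receptor pair across tissues
#'
#' Spearman rank correlation of log fold values across shared tissues,
#' averaging the sexes first. Needs at least 3 shared tissues. A degenerate
#' (zero-variance) profile yields 0 with attribute
#' \code{attr(,"degenerate") = TRUE} so downstream ranking can proceed.
#'
#' @param ligand_expr,receptor_expr \code{relative_expression} rows for one
#'   gene each (columns tissue, sex, fold).
#' @return correlation in [-1, 1].
#' @export
coexpression_score <- function(ligand_expr, receptor_expr) {
  prof <- function(d) {
    a <- stats::aggregate(fold ~ tissue, d, function(x) mean(log2(x)))
    stats::setNames(a$fold, a$tissue)
  }
  pl <- prof(ligand_expr); pr <- prof(receptor_expr)
  shared <- intersect(names(pl), names(pr))
  if (length(shared) < 3L)
    stop("need >= 3 shared tissues, got ", length(shared), call. = FALSE)
  x <- pl[shared]; y <- pr[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(0, degenerate = TRUE))
  stats::cor(x, y, method = "spearman")
}
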