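#' Diagonal distance of a ligand-receptor selection point
#'
#' Coevolving ligand-receptor pairs should have similar proportions of sites
#' under each form of selection, i.e. (ligand, receptor) points lying along
#' the x = y diagonal of the XY-plot. The distance is the perpendicular
#' distance |x - y| / sqrt(2).
#'
#' @param x ligand proportion in [0,1].
#' @param y receptor proportion in [0,1].
#' @return nonnegative real.
#' @export
diagonal_distance <- function(x, y) {
  if (any(x < -1e-12 | x > 1 + 1e-12 | y < -1e-12 | y > 1 + 1e-12))
    stop("proportions must lie in [0,1]", call. = FALSE)
  abs(x - y) / sqrt(2)
}

#' Pair-level concordance of two selection profiles
#'
#' Mean diagonal distance over the three selection classes (purifying,
#' neutral, positive); 0 means identical profiles.
#'
#' @param ligand,receptor \code{\link{selection_profile}}s.
#' @return nonnegative real; 0 iff the profiles are equal.
#' @export
pair_concordance <- function(ligand, receptor) {
  mean(diagonal_distance(
    c(ligand$p_purifying, ligand$p_neutral, ligand$p_positive),
    c(receptor$p_purifying, receptor$p_neutral, receptor$p_positive)))
}

#' Cross-lineage concordance of a ligand-receptor pair
#'
#' Euclidean distance between the (ligand, receptor) proportion points of the
#' same ortholog pair and selection class in two lineages (e.g. mammals vs
#' teleosts); 0 means the pair behaves identically in both lineages.
#'
#' @param point_a,point_b lists with fields \code{selection_class}, \code{x},
#'   \code{y} (see \code{\link{pair_point}}).
#' @return nonnegative real.
#' @export
lineage_concordance <- function(point_a, point_b) {
  if (!identical(point_a$selection_class, point_b$selection_class))
    stop("selection_class mismatch: ", point_a$selection_class, " vs ",
         point_b$selection_class, call. = FALSE)
  sqrt((point_a$x - point_b$x)^2 + (point_a$y - point_b$y)^2)
}

#' XY point of a ligand-receptor pair for one selection class
#'
#' @param ligand,receptor gene names.
#' @param selection_class "purifying", "neutral" or "positive".
#' @param x,y ligand and receptor proportions in [0,1].
#' @return A \code{pair_point} list.
#' @export
pair_point <- function(ligand, receptor, selection_class, x, y) {
  selection_class <- match.arg(selection_class,
                               c("purifying", "neutral", "positive"))
  if (x < 0 || x > 1 || y < 0 || y > 1)
    stop("x and y must be in [0,1]", call. = FALSE)
  structure(list(ligand = ligand, receptor = receptor,
                 selection_class = selection_class, x = x, y = y),
            class = "pair_point")
}

#' Fraction of positively selected codons per receptor region
#'
#' Maps site posteriors onto domain annotations: a codon counts as selected
#' if its p_positive exceeds \code{p_threshold}; fractions are computed over
#' annotated codons only, and regions with more than 20\% selected codons
#' are flagged.
#'
#' @param post a \code{site_posterior}.
#' @param annot a \code{\link{domain_annotation}} (one gene).
#' @param p_threshold posterior threshold (default 0.5).
#' @param flag_fraction region flag threshold (default 0.20).
#' @return data.frame: gene, region, n_codons, n_selected, fraction,
#'   flag_over_20pct.
#' @export
region_selection_fraction <- function(post, annot, p_threshold = 0.5,
                                      flag_fraction = 0.20) {
  n_sites <- length(post$p_positive)
  if (any(annot$end > n_sites))
    stop("annotation extends past alignment length (", n_sites, " codons)",
         call. = FALSE)
  sel <- post$p_positive > p_threshold
  out <- do.call(rbind, lapply(seq_len(nrow(annot)), function(i) {
    idx <- annot$start[i]:annot$end[i]
    data.frame(gene = annot$gene[i], region = annot$region[i],
               n_codons = length(idx), n_selected = sum(sel[idx]),
               fraction = mean(sel[idx]))
  }))
  out$flag_over_20pct <- out$fraction > flag_fraction
  out
}

#' Rank candidate receptors for a ligand
#'
#' Scores each candidate receptor as
#' \code{w1 * (1 - pair_concordance) + w2 * coexpression} (w2 forced to 0
#' when no coexpression scores are supplied) and returns candidates in
#' descending score order; exact ties are broken alphabetically and reported.
#'
#' @param ligand_profile \code{selection_profile} of the ligand.
#' @param receptor_profiles named list of receptor \code{selection_profile}s.
#' @param coexpr optional named numeric vector of ligand-receptor
#'   coexpression scores in [-1,1], names matching receptors.
#' @param weights c(w1, w2), nonnegative.
#' @return data.frame: receptor, concordance_distance, coexpression, score,
#'   rank, tied.
#' @export
rank_candidate_receptors <- function(ligand_profile, receptor_profiles,
                                     coexpr = NULL, weights = c(1, 1)) {
  if (length(receptor_profiles) < 1L)
    stop("need at least one receptor profile", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  nm <- names(receptor_profiles) %||%
    vapply(receptor_profiles, function(p) p$gene, "")
  d <- vapply(receptor_profiles, pair_concordance,
              ligand = ligand_profile, 0)
  cx <- if (is.null(coexpr)) rep(0, length(nm)) else {
    v <- coexpr[nm]
    v[is.na(v)] <- 0
    as.numeric(v)
  }
  w2 <- if (is.null(coexpr)) 0 else weights[2]
  score <- weights[1] * (1 - d) + w2 * cx
  ord <- order(-score, nm)
  out <- data.frame(receptor = nm[ord],
                    concordance_distance = d[ord],
                    coexpression = cx[ord], score = score[ord])
  out$rank <- rank(-out$score, ties.method = "min")
  out$tied <- duplicated(out$score) | duplicated(out$score, fromLast = TRUE)
  rownames(out) <- NULL
  out
}
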