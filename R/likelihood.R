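#' @useDynLib coevsel, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Engine data bundle: site-pattern-compressed tip states, postorder tree
# encoding, frequencies, codon-pair structure, and a cache of per-(kappa,
# omega_bg, omega_fg) site-likelihood columns. The cache is valid for fixed
# branch lengths and frequencies, i.e. one bundle per (gene, tree) pair.
likelihood_data <- function(aln, tree, freqs, use_cache = TRUE) {
  enc <- tree_encoding(tree, aln)
  tipsC <- aln$sites
  tipsC[is.na(tipsC)] <- 0L
  tipsC <- tipsC - 1L # 0-based, -1 missing
  key <- apply(tipsC, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pat_id <- match(key, key[first])
  pat <- tipsC[, first, drop = FALSE]
  w <- tabulate(pat_id, nbins = sum(first))
  p <- aln$code$pairs
  list(tips = pat, weights = as.numeric(w), pattern_of_site = pat_id,
       n_sites = aln$n_codon_sites,
       enc = enc, pi = as.numeric(freqs),
       pair_i = as.integer(p$i - 1L), pair_j = as.integer(p$j - 1L),
       pair_type = as.integer(p$type),
       cache = if (use_cache) new.env(parent = emptyenv()) else NULL)
}

# replace branch lengths (postorder order) -> fresh cache
set_branch_lengths <- function(dat, lengths) {
  dat$enc$length <- as.numeric(lengths)
  if (!is.null(dat$cache)) dat$cache <- new.env(parent = emptyenv())
  dat
}

# per-pattern log-likelihood columns for the classes of `tab`, cached by
# (kappa, omega_background, omega_foreground)
class_cols <- function(dat, kappa, tab) {
  keys <- sprintf("%.15g|%.15g|%.15g", kappa,
                  tab$omega_background, tab$omega_foreground)
  P <- ncol(dat$tips)
  out <- matrix(NA_real_, P, nrow(tab))
  need <- logical(nrow(tab))
  if (is.null(dat$cache)) {
    need[] <- TRUE
  } else {
    for (k in seq_len(nrow(tab))) {
      v <- dat$cache[[keys[k]]]
      if (is.null(v)) need[k] <- TRUE else out[, k] <- v
    }
  }
  if (any(need)) {
    uk <- !duplicated(keys) & need
    om <- cbind(tab$omega_background[uk], tab$omega_foreground[uk])
    cols <- cpp_site_loglik_cols(dat$tips, dat$enc$parent, dat$enc$child,
                                 dat$enc$length, as.integer(dat$enc$foreground),
                                 dat$enc$n_node, dat$enc$root,
                                 dat$pi, kappa, om,
                                 dat$pair_i, dat$pair_j, dat$pair_type)
    ukeys <- keys[uk]
    for (j in seq_along(ukeys)) {
      hit <- need & keys == ukeys[j]
      out[, hit] <- cols[, j]
      if (!is.null(dat$cache)) dat$cache[[ukeys[j]]] <- cols[, j]
    }
  }
  out
}

# mixture log-likelihood over per-pattern class columns
mix_loglik <- function(cols, prop, weights, want_post = FALSE) {
  keep <- prop > 0
  M <- sweep(cols[, keep, drop = FALSE], 2, log(prop[keep]), "+")
  m <- M[, 1]
  if (ncol(M) > 1) for (j in 2:ncol(M)) m <- pmax(m, M[, j])
  bad <- !is.finite(m) # all classes at zero likelihood
  if (any(bad)) m[bad] <- 0
  E <- exp(M - m)
  rs <- rowSums(E)
  site <- m + log(rs)
  if (any(bad)) site[bad] <- -Inf
  res <- list(lnl = sum(weights * site), site = site)
  if (want_post) {
    post <- matrix(0, nrow(cols), length(prop))
    post[, keep] <- E / rs
    res$post <- post
  }
  res
}

#' Site-class mixture log-likelihood of a codon alignment
#'
#' Evaluates the alignment log-likelihood under a \code{\link{site_class_model}}
#' by Felsenstein pruning over the 61 sense-codon states, mixing site classes
#' as \eqn{L_h = \sum_k p_k L_{h|k}}. Foreground branches (from the tree's
#' \code{#1} tags) use each class's foreground omega. Missing cells contribute
#' partial likelihood 1 over all states; per-node rescaling guards against
#' underflow. Likelihood is invariant to taxon row order and root placement
#' (reversible model).
#'
#' @param aln a \code{\link{codon_alignment}}.
#' @param tree an \code{ape::phylo} from \code{\link{read_newick}} with branch
#'   lengths set (expected substitutions per codon at omega = 1).
#' @param model a \code{site_class_model}, or a realised class table
#'   (data.frame with proportion, omega_background, omega_foreground).
#' @param freqs \code{codon_frequencies}.
#' @return list with \code{lnL} (total), \code{per_site_lnL} (length
#'   n_codon_sites), \code{site_class_loglik} (sites x classes matrix of
#'   log conditional likelihoods), and \code{class_table}.
#' @export
log_likelihood <- function(aln, tree, model, freqs) {
  tab <- if (inherits(model, "site_class_model")) build_site_classes(model)
         else model
  kappa <- if (inherits(model, "site_class_model")) model$kappa
           else attr(model, "kappa") %||% 2
  dat <- likelihood_data(aln, tree, freqs, use_cache = FALSE)
  cols <- class_cols(dat, kappa, tab)
  mx <- mix_loglik(cols, tab$proportion, dat$weights)
  idx <- dat$pattern_of_site
  list(lnL = mx$lnl,
       per_site_lnL = mx$site[idx],
       site_class_loglik = cols[idx, , drop = FALSE],
       class_table = tab)
}
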