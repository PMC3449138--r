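# Seeded generators for every input the pipeline consumes: trees, codon
# alignments under any supported omega mixture (with true site labels),
# coevolving ligand-receptor pairs, and qPCR Ct tables. All generators are
# pure functions of (parameters, seed): RNG state is localised, never global.

#' Sample a random rooted tree
#'
#' Random topology by sequential random attachment (via \code{ape::rtree})
#' with exponential branch lengths of the given mean, in expected
#' substitutions per codon at omega = 1.
#'
#' @param n_taxa number of leaves, >= 2.
#' @param mean_branch_length mean of the exponential branch lengths, > 0.
#' @param seed integer seed (NULL = use current RNG state).
#' @return \code{ape::phylo} with \code{foreground} flags all FALSE.
#' @export
sample_tree <- function(n_taxa, mean_branch_length = 0.3, seed = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  if (mean_branch_length <= 0)
    stop("mean_branch_length must be > 0", call. = FALSE)
  tr <- with_seed(seed,
    ape::rtree(n_taxa, rooted = TRUE,
               br = function(n) stats::rexp(n, 1 / mean_branch_length)))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  tr$foreground <- rep(FALSE, nrow(tr$edge))
  tr
}

#' Flag a clade's stem branch as foreground
#'
#' Convenience for branch-site simulations and tests: marks the branch
#' subtending the most recent common ancestor of \code{tips} (or the
#' terminal branch, for a single tip) as foreground.
#'
#' @param tree \code{ape::phylo}.
#' @param tips tip labels of the clade.
#' @return the tree with updated \code{foreground}.
#' @export
flag_foreground_clade <- function(tree, tips) {
  node <- if (length(tips) == 1L) match(tips, tree$tip.label)
          else ape::getMRCA(tree, tips)
  if (is.na(node)) stop("tips not found in tree", call. = FALSE)
  fg <- tree$foreground %||% rep(FALSE, nrow(tree$edge))
  hit <- tree$edge[, 2] == node
  if (!any(hit)) stop("clade has no subtending branch (root?)", call. = FALSE)
  fg[hit] <- TRUE
  tree$foreground <- fg
  tree
}

#' Simulate a codon alignment under a site-class mixture
#'
#' Each site draws a class from the mixture proportions, a root codon from
#' the equilibrium frequencies, and then evolves along the tree with the
#' class's rate matrix; on foreground-flagged branches the class's
#' foreground omega applies (branch-site heterogeneity). Rate matrices use
#' the engine's neutral scale (mean rate 1 at omega = 1), so simulated data
#' and fitted models share branch-length units.
#'
#' @param tree \code{ape::phylo} with branch lengths (and optional
#'   \code{foreground} flags).
#' @param model a \code{\link{site_class_model}}, or a class table
#'   data.frame (proportion, omega_background, omega_foreground) with
#'   \code{attr(, "kappa")}.
#' @param freqs \code{codon_frequencies}.
#' @param n_codons number of codon sites.
#' @param seed integer seed (NULL = current RNG state).
#' @param code a \code{genetic_code}.
#' @return list: \code{alignment} (\code{codon_alignment}) and \code{truth}
#'   (class table, per-site true class index, seed).
#' @export
simulate_alignment <- function(tree, model, freqs, n_codons, seed = NULL,
                               code = standard_genetic_code()) {
  tab <- if (inherits(model, "site_class_model")) build_site_classes(model)
         else as.data.frame(model)
  kappa <- if (inherits(model, "site_class_model")) model$kappa
           else attr(model, "kappa") %||% 2
  if (abs(sum(tab$proportion) - 1) > 1e-9)
    stop("class proportions must sum to 1", call. = FALSE)
  pi <- as.numeric(freqs)
  n_state <- length(pi)
  q1 <- build_rate_matrix(freqs, kappa, 1, code, normalize = FALSE)
  mu1 <- attr(q1, "mean_rate")

  with_seed(seed, {
    cls <- sample.int(nrow(tab), n_codons, replace = TRUE,
                      prob = tab$proportion)
    po <- ape::reorder.phylo(tree, "postorder")
    fg <- tree$foreground %||% rep(FALSE, nrow(tree$edge))
    fg_po <- fg[match(paste(po$edge[, 1], po$edge[, 2]),
                      paste(tree$edge[, 1], tree$edge[, 2]))]
    n_tip <- length(tree$tip.label)
    states <- matrix(NA_integer_, n_tip + tree$Nnode, n_codons)
    root <- n_tip + 1L
    states[root, ] <- sample.int(n_state, n_codons, replace = TRUE, prob = pi)
    qcache <- list()
    q_of <- function(w) {
      k <- sprintf("%.15g", w)
      if (is.null(qcache[[k]]))
        qcache[[k]] <<- unclass(build_rate_matrix(freqs, kappa, w, code,
                                                  normalize = FALSE)) / mu1
      qcache[[k]]
    }
    for (e in rev(seq_len(nrow(po$edge)))) { # parent-before-child order
      pa <- po$edge[e, 1]; ch <- po$edge[e, 2]; t <- po$edge.length[e]
      om <- if (fg_po[e]) tab$omega_foreground[cls] else
                          tab$omega_background[cls]
      for (w in unique(om)) {
        idx <- which(om == w)
        P <- transition_matrix(q_of(w), freqs, t)
        ps <- states[pa, idx]
        for (s in unique(ps)) {
          j <- idx[ps == s]
          states[ch, j] <- sample.int(n_state, length(j), replace = TRUE,
                                      prob = P[s, ])
        }
      }
    }
    aln <- codon_alignment(states[seq_len(n_tip), , drop = FALSE],
                           tree$tip.label, code)
    list(alignment = aln,
         truth = list(class_table = tab, kappa = kappa,
                      per_site_class = cls, seed = seed))
  })
}

#' Simulate a coevolving ligand-receptor gene pair
#'
#' Generates two alignments under three-class omega mixtures (purifying,
#' neutral, positive; default omegas 0.1, 1, 3) whose class proportions are
#' the shared \code{base_profile} perturbed independently by
#' Uniform(-jitter, +jitter) per class and renormalised; proportions pushed
#' below 0 are clipped (flagged). jitter = 0 gives identical true profiles,
#' the fully coevolving case.
#'
#' @param tree \code{ape::phylo}.
#' @param base_profile numeric length-3 (purifying, neutral, positive
#'   proportions, summing to 1) or a \code{\link{selection_profile}}.
#' @param jitter epsilon >= 0.
#' @param n_codons sites per gene.
#' @param seed integer seed.
#' @param kappa transition/transversion ratio (default 2).
#' @param freqs codon frequencies (default uniform).
#' @param class_omegas omegas of the three classes.
#' @return list: \code{ligand}, \code{receptor} (each as from
#'   \code{\link{simulate_alignment}}), \code{profiles} (the realised true
#'   profiles as \code{selection_profile}s), \code{clipped}.
#' @export
simulate_coevolving_pair <- function(tree, base_profile, jitter, n_codons,
                                     seed = NULL, kappa = 2, freqs = NULL,
                                     class_omegas = c(0.1, 1, 3)) {
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  base <- if (inherits(base_profile, "selection_profile"))
    c(base_profile$p_purifying, base_profile$p_neutral,
      base_profile$p_positive) else as.numeric(base_profile)
  if (length(base) != 3L || abs(sum(base) - 1) > 1e-9)
    stop("base_profile must be 3 proportions summing to 1", call. = FALSE)
  freqs <- freqs %||% uniform_frequencies()

  with_seed(seed, {
    clipped <- FALSE
    perturb <- function() {
      p <- base + stats::runif(3, -jitter, jitter)
      if (any(p < 0)) { clipped <<- TRUE; p[p < 0] <- 0 }
      p / sum(p)
    }
    pl <- perturb(); pr <- perturb()
    mk_tab <- function(p) {
      tab <- data.frame(proportion = p, omega_background = class_omegas,
                        omega_foreground = class_omegas)
      attr(tab, "kappa") <- kappa
      tab
    }
    lig <- simulate_alignment(tree, mk_tab(pl), freqs, n_codons)
    rec <- simulate_alignment(tree, mk_tab(pr), freqs, n_codons)
    list(ligand = lig, receptor = rec,
         profiles = list(
           ligand = selection_profile(pl[1], pl[2], pl[3], "ligand"),
           receptor = selection_profile(pr[1], pr[2], pr[3], "receptor")),
         clipped = clipped)
  })
}

#' Simulate a qPCR Ct table from true expression levels
#'
#' \eqn{Ct = Ct_{ref,baseline} - \log_2(expression) + N(0, noise\_sd)} per
#' replicate; the reference gene is constant per (tissue, sex) up to the
#' same noise. With noise 0, \code{\link{delta_delta_ct}} recovers the true
#' fold ratios exactly.
#'
#' @param true_expression matrix gene x tissue of positive expression levels
#'   (used for both sexes), or data.frame(gene, tissue, sex, expression).
#' @param noise_sd Ct noise standard deviation in cycles, >= 0.
#' @param seed integer seed.
#' @param n_replicates biological replicates per block (default 3).
#' @param ref_ct baseline reference-gene Ct in cycles (default 15,
#'   an abundant rRNA-like reference).
#' @param rna_yield optional data.frame(tissue, sex, yield_ug); default 10
#'   micrograms everywhere.
#' @return an \code{\link{expression_table}}.
#' @export
simulate_ct_table <- function(true_expression, noise_sd, seed = NULL,
                              n_replicates = 3L, ref_ct = 15,
                              rna_yield = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.matrix(true_expression)) {
    if (is.null(rownames(true_expression)) ||
        is.null(colnames(true_expression)))
      stop("expression matrix needs gene rownames and tissue colnames",
           call. = FALSE)
    d <- expand.grid(gene = rownames(true_expression),
                     tissue = colnames(true_expression),
                     sex = c("F", "M"), stringsAsFactors = FALSE)
    d$expression <- true_expression[cbind(d$gene, d$tissue)]
  } else d <- as.data.frame(true_expression)
  if (any(d$expression <= 0))
    stop("expression levels must be > 0", call. = FALSE)

  with_seed(seed, {
    blocks <- unique(d[c("tissue", "sex")])
    ct <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(gene = d$gene, tissue = d$tissue, sex = d$sex,
                 replicate = r,
                 Ct = ref_ct - log2(d$expression) +
                   stats::rnorm(nrow(d), 0, noise_sd))
    }))
    ref <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(tissue = blocks$tissue, sex = blocks$sex, replicate = r,
                 Ct_ref = ref_ct + stats::rnorm(nrow(blocks), 0, noise_sd))
    }))
    yield <- rna_yield %||% data.frame(tissue = blocks$tissue,
                                       sex = blocks$sex, yield_ug = 10)
    expression_table(ct, ref, yield)
  })
}
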