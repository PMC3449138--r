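# Shared fixtures, built in code at test time.

fix_code <- standard_genetic_code()
fix_freqs_uniform <- uniform_frequencies()

# balanced 8-taxon tree with one deep foreground stem (branch-site studies)
bs_tree_text <- paste0(
  "(((t1:0.15,t2:0.15):0.1,(t3:0.15,t4:0.15):0.1):0.5,",
  "((t5:0.15,t6:0.15):0.1,(t7:0.15,t8:0.15):0.1)#1:0.5);")
fix_bs_tree <- read_newick(text = bs_tree_text)

fix_tree8 <- sample_tree(8, 0.3, seed = 11)
fix_tree6 <- sample_tree(6, 0.25, seed = 21)

write_tmp_fasta <- function(seqs) {
  f <- tempfile(fileext = ".fa")
  writeLines(c(rbind(paste0(">", names(seqs)), unname(seqs))), f)
  f
}

# independent brute-force mixture likelihood: enumerate all internal-node
# codon assignments (never uses the pruning kernel)
brute_force_lnl <- function(aln, tree, tab, kappa, freqs,
                            code = fix_code) {
  q1 <- build_rate_matrix(freqs, kappa, 1, code, normalize = FALSE)
  mu1 <- attr(q1, "mean_rate")
  q_of <- function(w)
    unclass(build_rate_matrix(freqs, kappa, w, code, normalize = FALSE)) / mu1
  pi <- as.numeric(freqs)
  fg <- tree$foreground %||% rep(FALSE, nrow(tree$edge))
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  tipmap <- match(tree$tip.label, aln$taxon_names)
  grid <- as.matrix(expand.grid(rep(list(seq_along(pi)), n_int)))
  total <- 0
  for (h in seq_len(aln$n_codon_sites)) {
    obs <- aln$sites[tipmap, h]
    Lh <- 0
    for (k in seq_len(nrow(tab))) {
      P <- lapply(seq_len(nrow(tree$edge)), function(e) {
        w <- if (fg[e]) tab$omega_foreground[k] else tab$omega_background[k]
        transition_matrix(q_of(w), freqs, tree$edge.length[e])
      })
      pr <- pi[grid[, 1]] # root is node n_tip + 1 = first internal
      for (e in seq_len(nrow(tree$edge))) {
        a_node <- tree$edge[e, 1]; b_node <- tree$edge[e, 2]
        a <- grid[, a_node - n_tip]
        if (b_node <= n_tip) {
          b <- obs[b_node]
          if (is.na(b)) next # missing tip marginalises to 1
          pr <- pr * P[[e]][cbind(a, b)]
        } else {
          pr <- pr * P[[e]][cbind(a, grid[, b_node - n_tip])]
        }
      }
      Lh <- Lh + tab$proportion[k] * sum(pr)
    }
    total <- total + log(Lh)
  }
  total
}

`%||%` <- coevsel:::`%||%`

# rank-sum AUC of score for binary labels (independent of pROC)
simple_auc <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
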