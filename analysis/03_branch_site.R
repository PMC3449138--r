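#!/usr/bin/env Rscript
# Lineage-specific selection: a branch-site model A test with the foreground
# set to the stem of one clade (the teleost-vs-mammal style contrast), plus
# mapping of positively selected codons onto receptor domains.

suppressPackageStartupMessages(library(coevsel))

out <- "results/branch_site"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# two 4-leaf clades, foreground = one clade stem
tree <- read_newick(text = paste0(
  "(((m1:0.15,m2:0.15):0.1,(m3:0.15,m4:0.15):0.1):0.5,",
  "((f1:0.15,f2:0.15):0.1,(f3:0.15,f4:0.15):0.1)#1:0.5);"))
truth <- site_class_model("BSA_alt", kappa = 2, bs_p0 = 0.7, bs_p1 = 0.05,
                          bs_omega0 = 0.1, bs_omega2 = 3)
sim <- simulate_alignment(tree, truth, uniform_frequencies(), 800, seed = 42)
cat("Simulated an 800-codon receptor with foreground omega2 = 3 on the",
    "flagged clade stem\n")

bt <- branch_site_test(sim$alignment, tree,
                       options = list(n_restarts = 2, seed = 1))
cat(sprintf("Branch-site LRT: 2dlnL = %.3f, df = %d, p = %.4g -> %s\n",
            bt$lrt$stat, bt$lrt$df, bt$lrt$p_value,
            if (bt$significant) "lineage-specific positive selection"
            else "not significant"))

tabs <- list(branch_site_lrt = data.frame(
  stat = bt$lrt$stat, df = bt$lrt$df, p_value = bt$lrt$p_value,
  significant = bt$significant,
  omega2_hat = bt$fits$alt$model$bs_omega2))

if (bt$significant) {
  cat("BEB sites with p > 0.9:", sum(bt$posterior$p_positive > 0.9), "\n")
  tabs$beb_sites <- bt$posterior$report

  # map the lineage-selected codons onto an RXFP1/2-style domain layout
  # (LDLa + LRR ectodomain, then 7TM with intra/extracellular loops)
  bounds <- round(800 * c(0, 0.10, 0.42, 0.46, 0.50, 0.54, 0.58, 0.62,
                          0.66, 0.70, 0.74, 0.78, 0.82, 0.86, 0.90, 0.94))
  dom800 <- data.frame(
    gene = "receptor_sim",
    region = c("LDLa", "LRR", "TM1", "ICL1", "TM2", "ECL1", "TM3", "ICL2",
               "TM4", "ECL2", "TM5", "ICL3", "TM6", "ECL3", "TM7"),
    start = bounds[-length(bounds)] + 1, end = bounds[-1])
  reg_bs <- region_selection_fraction(bt$posterior,
                                      domain_annotation(dom800))
  tabs$region_summary_branch_site <- reg_bs
  cat("Simulated-receptor regions with > 20% selected codons:",
      paste(reg_bs$region[reg_bs$flag_over_20pct], collapse = ", "),
      if (!any(reg_bs$flag_over_20pct)) "(none)", "\n")
}

# receptor-domain mapping of the toy study's rxfp1 site posteriors
sites_f <- "results/selection/sites.tsv"
dom_f <- "results/data/domains.tsv"
if (file.exists(sites_f) && file.exists(dom_f)) {
  sites <- read.delim(sites_f)
  rx <- sites[sites$gene == "rxfp1", ]
  post <- structure(list(p_positive = rx$p_positive,
                         posterior_mean_omega = rx$mean_omega,
                         method = rx$method[1]), class = "site_posterior")
  regions <- region_selection_fraction(post, read_domain_annotation(dom_f))
  tabs$region_summary <- regions
  cat("Regions with > 20% selected codons:",
      paste(regions$region[regions$flag_over_20pct], collapse = ", "),
      if (!any(regions$flag_over_20pct)) "(none)", "\n")
}

write_report(tabs, out)
cat("Branch-site tables written to", out, "\n")
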