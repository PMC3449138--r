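#!/usr/bin/env Rscript
# Pairing synthesis: combine selection-profile concordance with coexpression
# into a scored ligand-receptor pairing report and per-ligand candidate
# rankings.

suppressPackageStartupMessages(library(coevsel))

out <- "results/pairing"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

prof_tab <- read.delim("results/selection/selection_profiles.tsv")
profiles <- lapply(seq_len(nrow(prof_tab)), function(i)
  selection_profile(prof_tab$p_purifying[i], prof_tab$p_neutral[i],
                    prof_tab$p_positive[i], prof_tab$gene[i]))
names(profiles) <- prof_tab$gene

hyp <- read.delim("results/data/pair_hypotheses.tsv")
rel <- read.delim("results/expression/relative_expression.tsv")

coe <- run_coevolution(list(profiles = profiles), hyp, expression = rel,
                       out_dir = out)
cat("Scored pairings (best first):\n")
print(coe$pairs, row.names = FALSE)
if (nrow(coe$unresolved) > 0) {
  cat("Unresolved hypotheses:\n"); print(coe$unresolved, row.names = FALSE)
}
cat("Pairing report written to", out, "\n")
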