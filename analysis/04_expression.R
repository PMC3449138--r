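#!/usr/bin/env Rscript
# qPCR expression: delta-delta-Ct relative expression against the reference
# gene with the mean-of-all-genes calibrator, RNA-yield correction for
# cross-tissue comparison, and ligand-receptor coexpression scores.

suppressPackageStartupMessages(library(coevsel))

data_dir <- "results/data"
out <- "results/expression"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tab <- expression_table(
  read.delim(file.path(data_dir, "ct.tsv")),
  read.delim(file.path(data_dir, "reference_ct.tsv")),
  read.delim(file.path(data_dir, "rna_yield.tsv")))

rel <- delta_delta_ct(tab)
rel <- yield_correct(rel, tab)
cat("Relative expression computed for", length(unique(rel$gene)), "genes x",
    length(unique(rel$tissue)), "tissues x 2 sexes\n")

hyp <- read.delim(file.path(data_dir, "pair_hypotheses.tsv"))
coex <- do.call(rbind, lapply(seq_len(nrow(hyp)), function(i) {
  s <- coexpression_score(rel[rel$gene == hyp$ligand[i], ],
                          rel[rel$gene == hyp$receptor[i], ])
  data.frame(ligand = hyp$ligand[i], receptor = hyp$receptor[i],
             coexpression = as.numeric(s),
             degenerate = isTRUE(attr(s, "degenerate")))
}))
print(coex, row.names = FALSE)

write_report(list(relative_expression = rel, coexpression = coex), out)
cat("Expression tables written to", out, "\n")
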