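#!/usr/bin/env Rscript
# Simulate the toy relaxin-family study: three hypothesised ligand-receptor
# pairs (rln3-rxfp3 truly coevolving; insl5-rxfp4 and rln-rxfp1 discordant)
# on one 6-taxon tree, plus a zebrafish-style qPCR Ct table. Everything is
# written as standard FASTA / Newick / TSV so the downstream steps read it
# back exactly as they would read real data.

suppressPackageStartupMessages(library(coevsel))

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

toy <- simulate_toy_study(seed = seed)
cat("Simulated", length(toy$genes), "genes on a",
    length(toy$tree$tip.label), "taxon tree (seed", seed, ")\n")

for (g in names(toy$genes))
  write_codon_alignment(toy$genes[[g]], file.path(out, paste0(g, ".fa")))
ape::write.tree(toy$tree, file.path(out, "tree.nwk"))

write.table(toy$hypotheses, file.path(out, "pair_hypotheses.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(toy$expression$ct, file.path(out, "ct.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(toy$expression$reference, file.path(out, "reference_ct.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(toy$expression$rna_yield, file.path(out, "rna_yield.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# toy receptor-domain annotation for the region-mapping step: an RXFP1/2-like
# segmentation (LDLa + LRR ectodomain, 7TM with ICL/ECL loops), in alignment
# codon coordinates for the 150-codon toy receptor
ann <- data.frame(
  gene = "rxfp1",
  region = c("LDLa", "LRR", "TM1", "ICL1", "TM2", "ECL1", "TM3", "ICL2",
             "TM4", "ECL2", "TM5", "ICL3", "TM6", "ECL3", "TM7"),
  start = c(1, 16, 61, 68, 74, 80, 86, 92, 98, 104, 110, 116, 122, 128, 134),
  end   = c(15, 60, 67, 73, 79, 85, 91, 97, 103, 109, 115, 121, 127, 133, 140))
write.table(ann, file.path(out, "domains.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- do.call(rbind, lapply(names(toy$true_profiles), function(g) {
  p <- toy$true_profiles[[g]]
  data.frame(gene = g, p_purifying = p$p_purifying,
             p_neutral = p$p_neutral, p_positive = p$p_positive)
}))
write.table(truth, file.path(out, "true_profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote alignments, tree, hypotheses, Ct tables and domain annotation to",
    out, "\n")
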