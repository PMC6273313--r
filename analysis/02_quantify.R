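#!/usr/bin/env Rscript
# Stage 2: peptide evidence -> protein log2 H/L ratios, replicate merge.
#
# Each replicate is quantified separately (median of peptide log2 H/L
# ratios, at least 2 ratios per protein); the merged table keeps the
# replicate intersection with ratios averaged, and the Venn counts report
# how many proteins each replicate contributes.

library(silacemt)

ev1 <- parse_evidence("results/dataset/evidence_rep1.tsv")
ev2 <- parse_evidence("results/dataset/evidence_rep2.tsv")
q1 <- quantify_experiment(ev1, min_ratio_count = 2)
q2 <- quantify_experiment(ev2, min_ratio_count = 2)
merged <- merge_replicates(q1, q2)

write.table(merged$quant, "results/protein_quant.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

v <- merged$venn
cat(sprintf("replicate 1: %d proteins quantified (%.2f%% of %d simulated)\n",
            nrow(q1), quantified_fraction(nrow(q1), 2000), 2000))
cat(sprintf("replicate 2: %d proteins quantified\n", nrow(q2)))
cat(sprintf("Venn: only rep1 %d, only rep2 %d, both %d, union %d\n",
            v$only_a, v$only_b, v$both, v$union))
cat(sprintf("merged table: %d proteins -> results/protein_quant.tsv\n",
            nrow(merged$quant)))
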