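#!/usr/bin/env Rscript
# Stage 5: EMT-vs-cancer-reference concordance.
#
# Screens for proteins significantly regulated in the (synthetic) EMT
# experiment whose regulation direction agrees with the sign of the
# cancer cell-line reference ratio (KK47 vs HCV29 column). The generator
# made 80% of regulated proteins concordant, so recovery should sit near
# that level among truly regulated proteins.

library(silacemt)

dr <- read.delim("results/differential.tsv",
                 colClasses = c(tier = "character"))
bc <- read.delim("results/dataset/bc_reference.tsv")
truth <- read.delim("results/dataset/truth.tsv")

conc <- concordance(dr, dr, bc)
write.table(conc, "results/concordance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

hits <- conc[conc$rule_satisfied, ]
cat(sprintf("%d of %d shared proteins satisfy the concordance rule\n",
            nrow(hits), nrow(conc)))
cat(sprintf("  %d up, %d down\n", sum(hits$direction == "up"),
            sum(hits$direction == "down")))
reg_ids <- truth$protein_id[truth$regulated != "null"]
flagged <- dr$protein_id[dr$tier != "none"]
reg_flagged <- conc[conc$protein_id %in% intersect(reg_ids, flagged), ]
cat(sprintf("among significantly flagged regulated proteins: %.1f%% concordant (generator set 80%%)\n",
            100 * mean(reg_flagged$rule_satisfied)))
cat("wrote results/concordance.tsv\n")
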