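#!/usr/bin/env Rscript
# Stage 4: GO composition and term over-representation.
#
# The up- and downregulated protein lists (95% tier) are tested for GO
# term over-representation against all annotated proteins, using the
# one-sided Fisher exact test, EASE score, and fold enrichment, with the
# filter set: count >= 2, EASE < 0.1, p < 0.05, fold enrichment > 2.5.

library(silacemt)

dr <- read.delim("results/differential.tsv",
                 colClasses = c(tier = "character"))
ann <- read_annotations("results/dataset/annotations.gaf")
aset <- annotation_set(ann)

for (asp in c("F", "P", "C")) {
  comp <- go_composition(dr$protein_id, aset, asp)
  cat(sprintf("aspect %s: %d categories; top: %s (%.2f%%)\n",
              asp, nrow(comp), comp$category[1], comp$percent[1]))
}

sig_up <- dr$protein_id[dr$direction == "up"]
sig_down <- dr$protein_id[dr$direction == "down"]
enr_up <- enrich_terms(sig_up, aset)
enr_down <- enrich_terms(sig_down, aset)

write.table(enr_up, "results/enrichment_up.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(enr_down, "results/enrichment_down.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

report <- function(name, enr) {
  hits <- enr[enr$pass_all, ]
  cat(sprintf("%s (%d proteins): %d terms pass all filters\n",
              name, enr$n[1], nrow(hits)))
  for (i in seq_len(min(3, nrow(hits)))) {
    cat(sprintf("  %s: k=%d/%d, K=%d/%d, EASE %.3g, fold %.2f\n",
                hits$term[i], hits$k[i], hits$n[i], hits$K[i], hits$N[i],
                hits$ease_p[i], hits$fold_enrichment[i]))
  }
}
report("upregulated", enr_up)
report("downregulated", enr_down)
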