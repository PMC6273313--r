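# silacemt

Quantitative SILAC proteomics of TGF-β-induced epithelial-to-mesenchymal
transition (EMT) in bladder epithelial cells, as a tested, reusable R
pipeline.

In a SILAC experiment, "heavy" (TGF-β-treated) and "light" (untreated)
cell populations are mixed and each peptide pair yields a heavy/light
(H/L) intensity ratio. This package takes the peptide-level evidence
exported by a search engine and carries it through the downstream
analysis a proteomics study performs:

1. **Quantitation** (`quantify_experiment`, `merge_replicates`): peptide
   log2(H/L) ratios are rolled up per protein as the median of at least
   2 peptide ratios; two replicate experiments are merged on their
   intersection (ratios averaged) with Venn accounting of the identified
   sets.
2. **Differential regulation** (`differential_table`): each protein's
   log2 H/L ratio is standardized against the population of all
   quantified proteins,

   *z*(b) = (log₂ X(H/L)[b] − mean(log₂ ratios a…n)) / sd(log₂ ratios a…n),

   and classified two-sidedly at the 95 / 99 / 99.9 % confidence tiers
   (|z| ≥ 1.960 / 2.576 / 3.291). Reproducibility statistics
   (`fraction_within_fold`, `threshold_classify`) summarize how much of
   the proteome varied less than 2-fold.
3. **GO over-representation** (`enrich_terms`): for each GO term with
   overlap *k* in a query list of size *n*, against a background of *N*
   proteins of which *K* carry the term, the one-sided Fisher exact
   p-value P(X ≥ k), the EASE score P(X ≥ k−1) (one overlap member
   removed, a conservative variant), and the fold enrichment
   (k/n)/(K/N) are computed from scratch; the filter set is count ≥ 2,
   EASE < 0.1, p < 0.05, fold enrichment > 2.5.
4. **Concordance** (`concordance`): proteins significantly regulated in
   EMT whose direction sign-agrees with independent bladder-cancer
   cell-line comparison ratios (KK47:HCV29, YTS1:HCV29), under a
   configurable rule.

No raw mass-spectrometry data are publicly archived for this study, so
the package ships a first-class synthetic-data generator
(`generate_dataset`, `generate_bc_reference`) that emulates the study
conditions — a Gaussian null log2 H/L population with mean −0.146 and SD
1.298, 1–15 peptides per protein, peptide-level noise, channel dropout,
two replicates, and GO annotations with known enriched terms — together
with ground-truth labels, so every stage is testable with known answers.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on a
simulated dataset of 2000 proteins (5 % regulated at ≥ 1.5 log2 units):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_quantify.R
Rscript analysis/03_differential.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_concordance.R
```

which prints, stage by stage:

```
replicate 1: 1829 proteins quantified (91.45% of 2000 simulated)
replicate 2: 1813 proteins quantified
Venn: only rep1 69, only rep2 53, both 1760, union 1882
population: mean -0.1412, sd 1.4227 (n = 1760)
  95% tier (|z| >= 1.960): 47 up, 40 down
  99% tier (|z| >= 2.576): 3 up, 3 down
  99.9% tier (|z| >= 3.291): 0 up, 1 down
varied < 2-fold: 51.02%
truth check: 28.6% of regulated flagged, 3.76% of nulls falsely flagged
downregulated (40 proteins): 1 terms pass all filters
  GO:0000005: k=7/40, K=138/2000, EASE 0.0531, fold 2.54
51 of 1760 shared proteins satisfy the concordance rule
among significantly flagged regulated proteins: 83.3% concordant (generator set 80%)
```

Reading these numbers: ~91 % of simulated proteins satisfy the
quantitation criteria per replicate and 1760 are quantified in both; the
fitted population SD (1.42) slightly exceeds the null SD because truly
regulated proteins widen the mixture; with effects of only ~1.2 null SDs,
the 95 % tier flags 87 proteins but recovers only 29 % of the truly
regulated ones — modest shifts are genuinely hard to separate from a
null population this wide — while the false-flag rate among nulls stays
near the nominal 5 %; one of the five truly enriched GO terms passes all
four filters in each direction; and concordance recovery among the
significantly flagged regulated proteins (83 %) matches the 80 % the
generator built in.

The same workflow can be configured in one object and run end to end
with `run_pipeline(run_config(...))`, from synthetic settings or from
evidence/annotation/reference files on disk, producing a `report.json`
and all stage tables in one output directory.

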