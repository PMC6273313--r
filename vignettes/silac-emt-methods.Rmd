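---
title: "Methods: SILAC H/L quantitation, z-score tiers, and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SILAC H/L quantitation, z-score tiers, and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacemt)
```

This vignette is the package's own account of the statistical procedure
it implements, the assumptions behind it, and the design choices made
where the underlying analysis convention was genuinely open.

## The model

A SILAC experiment compares two cell states through heavy/light (H/L)
peptide intensity pairs. We model the protein-level log2 H/L ratios of a
cell line as a two-component mixture: a Gaussian **null component**
N(μ₀, σ₀²) describing the great majority of proteins, whose apparent
ratio variation is biological and technical noise around no change, and
a small **regulated component** displaced from μ₀ by at least a minimum
effect. Differential regulation is then judged by the population
z-score

$$z_b = \frac{\log_2(H/L)_b - \bar{x}}{s},$$

where the mean and SD are those of *all* quantified proteins of that
cell line — not a replicate-based per-protein error model. This makes
the procedure applicable with only two replicates, but it also means the
null SD absorbs genuine biology: a wide population (σ₀ ≈ 1.3 log2
units, as in the HCV29 EMT comparison) makes modest regulation
undetectable by construction, which is visible in the analysis scripts'
truth checks.

Classification is two-sided at the 95/99/99.9% tiers with the
conventionally printed cutoffs |z| ≥ 1.960, 2.576, 3.291, using `>=`
comparisons. We deliberately classify with these 3-decimal rounded
constants rather than full-precision quantiles, so that published
z-scores given to printed precision reclassify identically;
`confidence_cutoff(level, rounded = FALSE)` exposes the exact quantile.

## Quantitation choices

The upstream criteria for "a quantified protein" are rarely stated
precisely in publications. The package's convention, configurable in
every function that uses it:

* a peptide contributes a ratio only when **both** channels are
  observed (> 0); log of zero is undefined and imputation is out of
  scope;
* a protein's log2 ratio is the **median** of its peptide log2 ratios,
  requiring at least `min_ratio_count = 2` of them (the median-of-ratios
  convention of common search engines; robust to single aberrant
  peptides);
* replicates are merged on their **intersection** — a protein must
  satisfy the criteria in both experiments — with the two log2 ratios
  combined by arithmetic mean. The mean (not median) of two replicate
  values is the only symmetric choice at n = 2.

The population for z-scoring is the full merged quantified table, not
only candidate proteins; the tier summary counts are therefore
cumulative tail counts and nested by construction.

Statistics around the threshold conventions are strict: "varied less
than 2-fold" means |log2 ratio| < 1 with the boundary excluded, and the
fold-threshold classifier counts strict exceedances. Ties exactly on a
cutoff are classified *into* the tier (`>=`), following the natural
reading of "a z-score ≥ 1.960σ is significant".

## Enrichment statistics

Over-representation of a GO term with background count K (of N) and
overlap k (of a query of n) uses the hypergeometric upper tail
P(X ≥ k), computed from scratch as a log-binomial-coefficient sum — the
one-sided Fisher exact test. The **EASE score** is the same tail with
one member removed from the overlap, P(X ≥ k − 1): a conservative
penalization that hits single-protein overlaps hardest (k = 1 scores
1.0). Numerically, the EASE tail is computed as
`fisher_p + P(X = k − 1)` and the Fisher tail clamped at 1, so the
invariants `fisher_p ≤ ease_p ≤ 1` hold exactly under floating point,
and both agree with brute-force subset enumeration to ~1e-15 (verified
in the tests for all consistent counts with N ≤ 12).

All four published filters are applied independently — count ≥ 2,
EASE < 0.1, Fisher p < 0.05, fold enrichment (k/n)/(K/N) > 2.5 —
because the source convention does not say which single test its
"p-value" refers to; results carry one pass flag per filter plus the
conjunction. Multiple-testing correction is deliberately not applied
(the procedure modeled does not use one); p-values should be read as
ranking scores. GO term ancestry is **not** propagated: terms are
treated flat, as given in the annotation file, since leaf-level term
lists are what the filtered output reports and propagation would
require an ontology graph that is out of scope.

The background defaults to all annotated proteins; a whole-proteome
background can be supplied via `annotation_set(annotations,
background = ...)`.

## Concordance rule

The published comparison of EMT regulation with cancer cell-line
ratios names a 16-protein result but no formal rule. The package makes
the rule an explicit object (`concordance_rule`): a protein must reach
a required tier in at least one EMT cell line, and that line's log2
ratio must sign-agree with every required reference column, with an
optional dead zone ε under which a ratio has no sign (default ε = 0,
a strict sign test). Proteins significant in both EMT lines with
opposite directions — a real phenomenon when two cell lines respond
differently to TGF-β — are flagged (`opposite_emt`) rather than
silently dropped, and never satisfy the rule.

## What the generator emulates — and what it does not

`generate_dataset()` produces data whose *downstream statistical
structure* matches the modeled study: null log2 ratios from N(−0.146,
1.298²) (the published HCV29 population moments), regulated shifts
uniform on ±[effect_min, effect_min + 2] (no published effect-size
model exists; a bounded uniform keeps every regulated protein
detectable at large `effect_min` without unrealistic outliers), 1–15
peptides per protein via 1 + Poisson(mean − 1) capped at 15, peptide
noise N(0, 0.3²), per-protein replicate shifts N(0, 0.1²), and 5%
independent channel dropout. Intensities are synthesized as light ~
LogNormal(log 10⁶, 1) with heavy = light·2^(peptide log2 ratio), so the
quantitation stage consumes realistic positive intensities rather than
ready-made ratios. Peptide-per-protein and missingness statistics were
not published; these defaults are field conventions, exposed in the
configuration and held fixed.

What it does **not** emulate: peptide misidentification and FDR,
protein-group ambiguity (identifiers are opaque and exact-match),
intensity-dependent ratio variance, retention-time structure,
arginine-to-proline conversion, or shared peptides. Passing tests on
synthetic data therefore demonstrate the correctness and calibration of
the *statistical pipeline*, not robustness to every artifact of real
LC-MS/MS data.

The synthetic cancer reference (`generate_bc_reference`) makes a chosen
fraction of regulated proteins sign-concordant (magnitudes uniform on
[1, 4] with the truth's sign) and draws everything else from the null;
it exists to give the concordance stage a known recovery target.

## Calibration and problem sizes

Two properties anchor the test suite, at sizes chosen to keep
Monte-Carlo error well below the tolerances while running in seconds:

* **Null calibration** — with no regulated proteins, the 95%-tier flag
  rate through the full evidence → quantify → merge → z-tier pipeline is
  5% within 3 binomial standard errors, measured over 20 seeds × 1000
  proteins. This holds because the protein-level estimate is standardized
  against the sample moments of the same population; the extra variance
  from peptide noise (≈ 0.02 on a variance of 1.68) inflates both
  numerator and denominator.
* **Parameter recovery** — with 5% regulated at `effect_min` = 4σ₀, at
  least 90% of the truly regulated proteins that satisfy quantitation
  reach the 95% tier (in practice all of them: the smallest such effect
  sits near z ≈ 2.8 even after the regulated tail widens the fitted SD),
  and the null sub-population's recovered moments match the generator
  settings within 4 standard errors. Recovery is measured among
  regulated proteins present in the merged table: a protein observed
  through a single peptide can never satisfy `min_ratio_count = 2`, and
  that structural exclusion is a property of the quantitation criteria,
  not of the classifier under test.

The replication of the published per-protein tier counts requires the
article's supplementary ratio lists, which have no public archive; the
corresponding test documents the expected path
(`inst/extdata/supplementary_data_1.tsv`) and fails informatively when
the file is absent, while the same code path is exercised on synthetic
data and on the published population moments.

## Known limitations

* The population z-score shares its variance estimate across proteins;
  proteins with many peptides are not up-weighted beyond the median's
  stability.
* Hypergeometric p-values are discrete and conservative for small K;
  the permutation test in the suite checks only that they are not
  anti-conservative.
* The concordance rule is an interpretation; published protein lists
  produced by an unstated rule cannot be reproduced exactly and are not
  a target.
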