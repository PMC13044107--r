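---
title: "From diplotypes to population-level drug recommendations"
author: "pgxpop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From diplotypes to population-level drug recommendations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxpop)
```

## The problem

Clinical pharmacogenomic (PGx) resources such as CPIC publish
drug-recommendation frequencies for broad geographic populations
("East Asian", "European", ...). Those aggregates can hide real
differences between the subpopulations they pool: a cohort with a
distinctive demographic history — Japan is the motivating case — may
carry allele frequencies that shift the distribution of actionable
recommendations relative to its containing aggregate. `pgxpop`
implements the secondary-analysis chain needed to test this: it turns
per-individual star-allele diplotype calls into harmonized
recommendation categories, aggregates them into population frequency
tables, and quantifies divergence from a reference population with
standard proportion statistics.

The package deliberately starts *after* variant calling. Callers such
as DRAGEN's CYP2D6 module or PharmCAT produce per-individual diplotypes;
everything downstream of those calls — cohort selection, phenotype
translation, recommendation mapping, aggregation, comparison — is in
scope here.

## The translation model

**Diplotype → phenotype.** Each individual carries two star alleles per
gene, optionally with copy-number multipliers (`*1x2/*5`). For CYP2D6
the phenotype comes from the *activity score*

$$AS = m \cdot v(a_1) + n \cdot v(a_2),$$

the copy-weighted sum of the two alleles' curated activity values
$v$ (normal = 1, decreased in (0,1), no function = 0). The score is
binned: $AS \le 0$ Poor, $0 < AS < 1.25$ Intermediate,
$1.25 \le AS \le 2.25$ Normal, $AS > 2.25$ Ultrarapid. Both the values
and the cutoffs ship as editable configuration
(`default_allele_function_tables()`, `activity_score_cutoffs()`). The
cutoff calibration is the recalibrated CPIC scheme with *10 at 0.25;
pipelines built on the legacy calibration (*10 = 0.5, Normal starting
at 1.0) can reproduce it by editing one TSV and one constructor call.
If either allele has *uncertain*/*unknown* function the score is
undefined — deliberately `NA`, never 0 — and the phenotype is
Indeterminate.

For CYP2C19, CYP2B6 and SLCO1B1 the phenotype is a lookup on the
unordered pair of allele function classes (CPIC diplotype/phenotype
table style); grids are stored with canonically sorted keys so allele
order cannot matter.

**Phenotype → recommendation.** Six drug contexts are covered:
codeine/tramadol (CYP2D6), three statin contexts (SLCO1B1),
citalopram/escitalopram (CYP2C19), and sertraline, which depends on
CYP2B6 *and* CYP2C19 jointly. Every context has a total grid over its
genes' phenotype vocabulary, mapping to a closed six-category
vocabulary: *Use as directed*, *Adjust dosage*, *Avoid and/or use
alternative medication*, *Use with caution*, *Not determined*,
*No call*. Two rules precede any grid lookup: a gene with no diplotype
record at all gives "No call"; an Indeterminate phenotype gives
"Not determined". The distinction matters — the first is an absent
call, the second an unscorable one.

The bundled grids follow the CPIC guideline structure for each drug
class. The sertraline grid was a genuinely open design point (the
guideline's combination table has many clinically equivalent encodings);
we chose the encoding in which CYP2C19 drives the primary action
(ultrarapid/rapid and poor metabolizers → alternative medication,
intermediate → dose adjustment) and reduced-function CYP2B6 adds a dose
adjustment for CYP2C19 normal metabolizers. This reproduces the
characteristic structure of published tables — sertraline shows more
"Adjust dosage" and less "Use as directed" than citalopram in the same
population, with nearly equal "Avoid" mass — and every cell is
overridable in `recommendation_grids.yaml`. A related consequence worth
knowing: the three statin contexts always agree on "Use as directed"
and "Not determined" mass and only redistribute the remainder, which is
why published statin rows repeat the same frequency across drugs.

## Cohort selection by genetic ancestry

The analysis cohort is selected by thresholding per-individual
admixture fractions against a focal reference panel (default: 1000
Genomes JPT). The default threshold, **≥ 87.5%**, is inclusive and
approximates the 1000 Genomes "four grandparents" criterion while
tolerating minor admixture (one great-grandparent elsewhere).
`threshold_sensitivity()` reports how the retained count moves at
threshold ± 2.5%, and `ancestry_histogram()` produces the
retained/excluded histogram used to sanity-check the choice.
Fractions are validated (sum to 1 within 1e-6), never silently
renormalized: a malformed admixture file should fail loudly, not bias
the cohort.

## Population statistics

Per-category frequencies carry **Wilson score intervals** (no
continuity correction), which keep usable coverage near 0 and 1 where
the Wald interval collapses. Cross-population comparison restricts each
context to the two most frequent categories in the reference population
(ties broken deterministically), then per row computes the risk
difference $RD = p_{study} - p_{ref}$ with a Wald 95% CI, a pooled
two-proportion z-test, and Benjamini–Hochberg q-values across all rows
jointly (12 in the standard six-context design; the family size is
recorded on the result). A row is flagged *practically meaningful* when
$|RD| \ge 5$ percentage points and *statistically significant* when
$q < 0.05$.

Reference tables are usually published as rounded percentages plus an
N. Before testing, both sides are converted to integer counts (nearest
integer to $p \cdot n$, half away from zero) and proportions are
recomputed as count/n. This keeps every statistic consistent with
integer data and reproduces published display values that were
themselves computed from counts. The normal quantile is computed
exactly from the confidence level rather than hard-coding 1.96; the
difference is below display rounding.

Degenerate inputs are handled as non-results, not crashes: equal sample
proportions give exactly $z = 0, p = 1$, and a pooled proportion of 0
or 1 (possible in small simulated cohorts) does the same with a
message. Empty store selections raise an error rather than returning
0/0 frequencies.

## The aggregate store

Population analysis should not require individual identifiers. The
store keeps, per individual, exactly `generic_id` (a random hex string
generated at de-identification time; the kit↔generic mapping lives only
in memory), `age`, `sex`, `purchase_location`, and the per-context
recommendations in a second table. User ids, kit ids and timestamps —
the latter a known re-identification proxy — never reach the file. The
schema is fixed and introspectable (`store_schema()`), and the tests
fail on any extra column. The store is a single plain-text file with
two relational tables; age is stored as a raw integer (bucketing, if
wanted, is a query-time concern).

## The synthetic cohort generator

Because individual-level PGx datasets are not freely redistributable,
the generator produces cohorts with the statistical structure the
analysis assumes, so every stage is testable end to end:

* **Diplotypes** are drawn under Hardy–Weinberg equilibrium (two
  independent allele draws per individual) from per-gene allele
  frequency specs. The default CYP2D6 spec
  (*1 = 0.43, *2 = 0.10, *10 = 0.40, *41 = 0.02, *5 = 0.045,
  *14 = 0.005) is a calibration device whose implied recommendation
  distribution resembles a Japanese cohort (~73% CYP2D6 normal
  metabolizers); the CYP2C19, CYP2B6 and SLCO1B1 specs were set once
  from published Japanese allele-frequency ballparks (e.g. CYP2C19
  no-function mass 0.39, CYP2B6 *6 at 0.16, SLCO1B1 decreased mass
  ~0.155). They are not population estimates.
* **Ancestry fractions** come from a two-component mixture: with
  probability 0.9 a Beta(5, 1) draw rescaled onto (0.93, 1) — the
  near-1 pileup of a well-matched cohort — otherwise uniform on
  (0.5, 0.93), the admixed tail.
* **Demographics and identifiers**: uniform ages 20–79, balanced sex,
  a handful of purchase locations — and deliberately also kit ids,
  user ids and timestamps, so de-identification has something to strip.

Genes are drawn independently (the four pharmacogenes are unlinked),
and everything is reproducible under the spec's seed.
`expected_category_probs()` enumerates all diplotype pairs analytically
and is the oracle for the core end-to-end test: at n = 10,000, pipeline
frequencies recover the closed-form category probabilities within
3 standard errors for all six contexts.

What the generator does **not** emulate: genotyping error, structural
variants beyond `xN` copy notation, linkage/phasing, non-HWE structure
(inbreeding, stratification), and the selection biases of a
consumer-testing cohort. Passing tests therefore validate the
*pipeline arithmetic*, not the realism of any particular population's
allele spectrum.

## A worked comparison

The packaged reference tables include a CPIC-style East Asian aggregate
and a published Japanese WGS cohort (n = 632). The "cohort-free" mode
compares them directly:

```{r}
cmp <- compare_reference_populations()
cmp[cmp$meaningful & cmp$significant, c("context", "category", "rd", "q_value")]
```

```{r}
cat(render_report(cmp), sep = "\n")
```

The opioid context shows the study population's "Use as directed" mass
about 18 percentage points above the East Asian aggregate, the statin
contexts about 8 points below, both far under the q < 0.001 line; no
SSRI row is flagged on either criterion.

Two provenance notes travel with the fixtures (see the `note` column of
`reference_frequency_tables()`): the Japanese opioid "Use with caution"
cell is printed inconsistently in its source (0.9% in one table, 25.0%
in the comparison table, with a CI matching 25.0%) and is carried as
25.0%; an EAS statin secondary cell is printed as both 21.9% and 22.0%,
and the comparison value 21.9% is carried. Recomputed non-extreme
q-values (≈ 0.055, 0.38, 0.84, 0.95) agree with published ones
(0.06, 0.39, 0.85, 0.96) only approximately because the exact
underlying counts are not published; the tests report them
informationally rather than asserting them.

## Numerical and design choices

* **Problem sizes in the test suite** were chosen to make the
  statistical checks sharp but cheap: HWE goodness-of-fit at n = 500
  across 100 seeds, Wilson coverage at n = 500 over 1,000 replicates,
  parameter recovery at n = 10,000, BH versus the brute-force step-up
  definition on 1,000 random p-vectors.
* **Suballele normalization** truncates letters (`*1A` → `*1`):
  function is curated at the core-allele level in the shipped tables.
* **Copy-number notation** supports only `xN` on an allele token;
  hybrid/tandem structural notations are rejected with a parse error
  rather than mis-scored.
* **Ancestry threshold** is matched against a single panel component
  (configurable); summing multiple components is possible by editing
  the admixture table upstream.
* **BH family** is all rows of one comparison invocation; composition
  is recorded via the `m` attribute and in the run manifest.

## Limitations

The engine covers four genes and six drug contexts; HLA-based contexts
(where allele function is only positive/negative and "Not determined"
does not exist) are represented in the label harmonization table but
not as contexts. The comparison machinery assumes independent samples
and large-ish n; it offers no exact tests, covariate adjustment, or
meta-analysis across references. Reference tables are only as good as
their transcription; the `note` column carries known inconsistencies.
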