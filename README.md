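# pgxpop

Population-level pharmacogenomics from per-individual star-allele calls.

Clinical PGx resources publish drug-recommendation frequencies for broad
geographic populations. Whether a specific cohort — say, a
genetic-ancestry-filtered Japanese WGS cohort — actually matches its
containing "East Asian" aggregate is an empirical question. `pgxpop`
implements the full secondary-analysis chain needed to answer it:

* **Star-allele engine** — parse diplotypes (`"*1x2/*5"`), translate to
  gene phenotypes: CYP2D6 via the activity score
  `AS = m·v(a₁) + n·v(a₂)` binned at 0 / 1.25 / 2.25
  (Poor / Intermediate / Normal / Ultrarapid), CYP2C19, CYP2B6 and
  SLCO1B1 via CPIC-style function-pair grids. Unscorable alleles
  propagate to "Not determined", absent calls to "No call".
* **Recommendation mapper** — six drug contexts (codeine/tramadol,
  three statin contexts, citalopram/escitalopram, and the two-gene
  CYP2B6×CYP2C19 sertraline rule) mapped onto a closed six-category
  vocabulary; all grids ship as editable YAML/TSV config.
* **Ancestry filter** — inclusive admixture-fraction threshold
  (default JPT ≥ 0.875), threshold-sensitivity and histogram summaries.
* **Population statistics** — Wilson score intervals per category;
  between-population comparison per context restricted to the two most
  frequent reference categories: risk difference `RD = p_study − p_ref`
  with Wald 95% CI, pooled two-proportion z-test, Benjamini–Hochberg
  q-values across all rows, and the decision rule |RD| ≥ 5 pp
  ("meaningful") and q < 0.05 ("significant").
* **Privacy-conscious cohort store** — single-file two-table store
  holding exactly `generic_id / age / sex / purchase_location` plus
  recommendations; no kit ids, user ids or timestamps ever reach disk.
* **Synthetic cohort generator** — Hardy–Weinberg diplotypes, a near-1
  ancestry mode with an admixed tail, demographics and strip-me
  identifiers, plus closed-form expected category probabilities for
  end-to-end validation.

## Worked example

Compare the bundled Japanese cohort frequency table (n = 632) against
the CPIC East Asian aggregate:

```r
library(pgxpop)
cmp <- compare_reference_populations()   # japanese_cohort vs east_asian
cat(render_report(cmp), sep = "\n")
```

```
== Population comparison ==
codeine_tramadol | Use as directed | 71.0% vs 53.2% | RD 18% (14% to 21%) | q <0.001 | MS
codeine_tramadol | Use with caution | 25.0% vs 38.5% | RD -13% (-17% to -10%) | q <0.001 | MS
lova_pita_simva | Use as directed | 67.6% vs 75.7% | RD -8% (-12% to -4%) | q <0.001 | MS
lova_pita_simva | Avoid and/or use alternative medication | 27.5% vs 23.5% | RD 4% (0% to 8%) | q 0.06 | --
pravastatin | Use as directed | 67.6% vs 75.7% | RD -8% (-12% to -4%) | q <0.001 | MS
pravastatin | Use with caution | 25.8% vs 21.9% | RD 4% (0% to 8%) | q 0.06 | --
atorvastatin | Use as directed | 67.6% vs 75.7% | RD -8% (-12% to -4%) | q <0.001 | MS
atorvastatin | Adjust dosage | 25.8% vs 21.9% | RD 4% (0% to 8%) | q 0.06 | --
sertraline | Adjust dosage | 50.8% vs 52.8% | RD -2% (-6% to 2%) | q 0.38 | --
sertraline | Use as directed | 31.6% vs 32.2% | RD -1% (-4% to 3%) | q 0.84 | --
citalopram_escitalopram | Adjust dosage | 46.1% vs 46.0% | RD 0% (-4% to 4%) | q 0.95 | --
citalopram_escitalopram | Use as directed | 36.1% vs 38.1% | RD -2% (-6% to 2%) | q 0.38 | --
```

Each line is one tested (context, category) cell: the two population
frequencies, the risk difference with its Wald interval, the
FDR-adjusted q-value, and the meaningful/significant flags. Reading:
the Japanese cohort diverges from the East Asian aggregate for opioids
(+18 pp "Use as directed") and statins (−8 pp), while no SSRI row
clears either the 5-point or the q < 0.05 bar.

A full cohort run (synthetic here; swap in real TSVs for a real one):

```r
coh <- generate_cohort(cohort_spec(n = 700, seed = 1))
refs <- reference_frequency_tables()
res <- run_pipeline(cohort = coh, out_dir = "run1",
                    reference = subset(refs, population == "east_asian"),
                    seed = 1)
length(res$retained)        # 637 of 700 pass the JPT >= 0.875 filter
res$frequencies             # per-context counts, proportions, Wilson CIs
res$store_path              # de-identified single-file store
```

A thin CLI wrapper for file-based runs lives at
`inst/scripts/pgxpop-pipeline.R`.

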