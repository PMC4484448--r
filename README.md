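# speccount

Differential secretome analysis by label-free spectral counting, for
proteomics practitioners comparing the proteins two cell populations release
into conditioned media — for example an aggressive, N-Myc-amplified tumour
line against a less aggressive one — from search-engine PSM exports rather
than raw spectra.

## What it computes

**Identification.** PSMs are significant when the ion score strictly exceeds
the per-spectrum identity threshold. Proteins require at least two distinct
peptide sequences; confidence is the protein-level target-decoy FDR
(decoys/targets).

**Quantitation.** Relative abundance between samples A (reference) and B
(test) is the ratio of normalized spectral counts with pseudo-count
c = 1.25:

```
RSc = (s_B + c)(T_A − s_A + c) / [(s_A + c)(T_B − s_B + c)]
```

where `s` is a protein's significant spectra and `T` a sample's total. When
RSc < 1 the negative inverse −1/RSc is reported, so +k always reads "k-fold
up in B" and −k "k-fold up in A". Every protein lands in one of five
partitions — unique to A, unique to B, or common and higher / lower /
unchanged in B against an inclusive 2-fold cut-off — with a strict 15-fold
extreme tier.

**Enrichment.** Annotation categories (GMT format) are scored by fold
enrichment (k/n)/(K/N) and one-sided hypergeometric tails with
Benjamini–Hochberg correction, against the detected-secretome background.

**Network modules.** Dense modules of a protein-interaction graph (greedy
modularity with a core trim) are tested for over-representation of the
high-abundance protein set.

A ground-truthed synthetic-data generator (planted fold changes, a
co-enriched protease-like module, decoy spectra, cell-death-derived
intracellular leakage) makes the whole pipeline testable without external
data.

## Worked example

```r
library(speccount)

cfg   <- simulation_config(seed = 1)      # two-condition synthetic secretome
truth <- generate_truth(cfg)
run <- run_pipeline(
  simulate_psm_table(truth, cfg),
  annotations = truth_annotations(truth),
  edges       = simulate_interactions(truth)
)
print(run)
#> <speccount_run>
#>   speccount 0.1.0
#>   samples: A='SH-SY5Y-like' (reference), B='SK-N-BE2-like' (test)
#>   psms: 4400 total, 3765 significant (score > identity threshold)
#>   min_unique_peptides=2, fdr_mode=d_over_t
#>   c=1.25, fold_cutoff=2, high_tier_cutoff=15
#>   alpha=0.05, min_module_size=3, split_threshold=200
#>   identified: 334 target proteins, 2 decoy, fdr=0.00599
#>   partition: 120 unique A | 72 common (12 higher B, 14 lower B) | 102 unique B; total 294
#>   increased in B (unique B + >=2-fold common): 114 proteins
#>   top module: M001 (37 members, density 0.20, p=0.00183)
```

334 proteins pass the two-unique-peptide filter at an estimated FDR of 0.6%
(below the 1% working criterion). The 114 proteins increased in B (unique to
B plus common proteins at least 2-fold up) drive the enrichment stage, which
recovers the planted protease category at the top of the ranking:

```r
head(run$enrichment$increased[, c("category", "k", "n", "fold", "q_value", "direction")], 3)
#>   category                             k     n  fold    q_value direction
#> 1 cysteine-type peptidase activity    19   114 2.45  0.00000136 enriched
#> 2 DNA binding                          3   114 0.387 0.158      depleted
#> 3 RNA binding                          2   114 0.368 0.266      depleted
```

The nucleic-acid-binding categories trend depleted in B because the
generator leaks slightly more intracellular protein into sample A (8.5% vs
7.8% of spectra), mimicking differential cell death. `tidy(run)` returns the
per-protein differential table, `glance(run)` a one-row summary, and
`autoplot(run)`, `plot_differential()`, `plot_enrichment()`,
`plot_modules()` the standard figures. `write_run(run, dir)` writes every
table plus a run log of the thresholds applied.

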