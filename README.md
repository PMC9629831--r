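# moltmap

Phase-resolved mapping of genes that oscillate with the *Caenorhabditis
elegans* molting cycle, and sequence characterisation of the proteins
they encode.

During larval development the worm rebuilds its pharyngeal cuticle every
~8 hours. Thousands of genes oscillate in step with this cycle; the ones
enriched in the pharynx and carrying a signal peptide are candidates for
secretion into the growing cuticle, and many of their products are
low-complexity, intrinsically disordered proteins that fall into a small
number of sequence families. `moltmap` provides the informatic half of
that analysis as a tested, reusable R pipeline for anyone working with
phased expression data and secretome/low-complexity annotation:

* **Temporal map** — harmonic regression fits each gene's log2 expression
  time course at the molting period: `y = mu + a*cos(wt) + b*sin(wt)`,
  phase `phi = atan2(b, a)` mapped to degrees of the cycle, amplitude
  `sqrt(a^2 + b^2)`, and an F-test of the harmonic terms (oscillating at
  p < 0.001 plus an amplitude floor). Phases bin into eight half-open
  45-degree hourly bins; overlaying a molt-upregulated gene set locates
  the peak molting hour (the argmax bin of the overlap counts).
* **Enrichment and secretome** — a gene is tissue-enriched when its TPM
  exceeds 1.5x every other tissue and reaches 25 TPM; it is predicted
  secreted when its signal-peptide score is >= 0.45. Per-bin transcript
  profiles are tested against the global mean with one-sample Student
  t-tests; cell-cluster summaries support average and max-average modes
  and a lagged (bin b vs b-2) one-sided test.
* **Sequence properties** — a native SEG implementation (window 12,
  trigger entropy K2 <= 2.2 bits, extension K2 <= 2.5 bits, and
  minimum-P0 refinement with `P0 = Omega * F / 20^L` computed in log
  space) yields %LCR; disorder tracks yield %IDR under the >= 30
  contiguous disordered residues rule; plus residue composition,
  PLAAC score adjustment (+60), group enrichment statistics and
  transcript-weighted temporal property profiles.
* **Family discovery** — all-against-all global alignment
  (BLOSUM62, affine gaps) gives a percent-identity matrix;
  single-linkage components above an identity threshold become families;
  each family gets a center-star multiple alignment and a position
  frequency matrix (sequence-logo data, residue frequencies plus gap
  fraction summing to one per column).
* **Synthetic data** — `sim_config()` / `gen_timecourse()` /
  `gen_tissue_matrix()` / `gen_proteome()` generate every pipeline input
  with planted ground truth (phases, molt subset, enrichment folds,
  signal peptides, low-complexity families), so the whole pipeline is
  testable end to end without any external download.

## Worked example

```r
library(moltmap)
cfg <- sim_config(n_genes = 1000, frac_oscillating = 0.35,
                  frac_enriched = 0.15, n_families = 3,
                  family_sizes = c(5, 4, 3), seed = 1)
report <- run_pipeline(cfg)
print(report)
#> moltmap pipeline report
#>   oscillating genes on the map : 348
#>   peak molting hour            : 6
#>   pharynx-enriched (oscillating): 52
#>   secreted of those            : 34 (65%)
#>   low-complexity families      : 3
report$strata
#>                stratum   n n_secreted pct_secreted
#> 1 enriched_oscillating  52         34     65.38462
#> 2    other_oscillating 296        123     41.55405
#> 3      non_oscillating 652        137     21.01227
report$bin_profile$mean[6] / report$global_mean_tpm
#> [1] 29.7
```

Reading the output: 348 of 1000 genes were called oscillating (the
generator planted 350); the molt-upregulated overlay peaks in hour 6,
the planted molting hour. Of the 52 pharynx-enriched oscillating genes,
65% carry a signal peptide versus 42% of the remaining oscillators and
21% of non-oscillating genes — the secretome is concentrated on the
map. Transcript abundance of the secreted pharynx set rises ~30-fold
over the map-wide mean in the molting bin, and the 12 planted
low-complexity proteins are recovered as 3 families whose members are
80–90% low-complexity and disordered sequence.

`run_pipeline(cfg, out_dir = "report")` additionally writes every table
(map, strata, bin profiles, property table, family assignment, per-family
position frequency matrices) as TSV with thresholds in header comments,
plus a `provenance.json`. A thin command-line wrapper lives at
`inst/cli/moltmap.R`:

```sh
Rscript inst/cli/moltmap.R simulate --seed 1 --out simdir
Rscript inst/cli/moltmap.R report   --seed 1 --out reportdir
```

Deposited per-gene master tables (phases and annotations already
assigned) can be consumed directly with `report_from_master()`, which
recomputes the map summary statistics from the table.

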