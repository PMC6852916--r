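# eqtlzone

Many true risk variants in a genome-wide association study (GWAS) sit in the
*gray zone*: nominally significant (p < 0.05) but short of genome-wide
significance (p < 5 × 10⁻⁸). `eqtlzone` asks whether a SNP's regulatory
profile predicts its GWAS significance — and therefore whether it can help
prioritize gray-zone SNPs. Working purely from summary statistics, it
relates a SNP's −log₁₀p to:

* its **cis-eQTL status** (a significant expression association, q ≤ 0.05
  after per-tissue Bonferroni adjustment, in ≥ 1 tissue), tested per tissue
  with a two-sided Mann–Whitney U (tie-corrected, signed Z);
* its **tissue breadth** (categories "0", "1", "2", "3", "> 3" tissues);
* the **eQTL density of its ±5 kb neighborhood** (low = 0, intermediate =
  1–7, high = ≥ 8 eQTLs), plus co-localization with TF/miRNA binding sites;
* its **significance zone** — white noise (p ≥ 0.05), light gray
  (5 × 10⁻⁵ ≤ p < 0.05), dark gray (5 × 10⁻⁸ ≤ p < 5 × 10⁻⁵), genome-wide
  (p < 5 × 10⁻⁸) — and 0.5-wide −log₁₀p bins, as eQTL proportions ±
  √(p(1−p)/n), with a Spearman trend over the twelve gray-zone bins;
* a **genome-chopping control**: consecutive non-overlapping 5 kb fragments,
  correlating per-fragment eQTL count with mean −log₁₀p (Spearman), with and
  without fragments holding a genome-wide hit.

Inputs are a delimited GWAS summary table (SNP, chromosome, 1-based
position, p, optional backbone flag), a per-tissue eQTL catalog (pre-filtered
q-values, or raw p-values plus per-tissue test counts for Bonferroni
filtering), and BED intervals for regulatory features. A seeded
synthetic-data generator (`simulate_study()`) emulates all three with known
ground truth, including a null preset for type-I calibration.

## Worked example

```r
library(eqtlzone)

sim <- simulate_study(enriched_config(seed = 20260920))
ann <- annotate_snps(sim$gwas, sim$catalog, sim$features)

mann_whitney_by_tissue(ann, sim$catalog)   # 48 rows, one per tissue
mean_by_tissue_count_category(ann)
eqtl_proportion_by_zone(ann)

frags <- assign_and_aggregate(chop_genome(sim$config$chrom_lengths), ann, sim$catalog)
fragment_correlation(frags)
```

On this seed the run prints (via `analysis/` drivers, which wrap exactly
these calls):

```
48 of 48 tissues show higher -log10 p in eQTL SNPs (positive Z)
mean -log10 p by tissue breadth: 0=0.57, 1=2.41, 2=2.75, 3=3.01, >3=3.89
eQTL proportion by zone (%): white_noise=1.17, light_gray=5.04, dark_gray=45.02, genome_wide=77.62
gray-zone trend: Spearman R = 0.979 over 12 bins (p = 3.1e-08)
TF co-localization: 42.17% in high-density vs 0.12% in low-density regions
12000 fragments (80% without eQTLs); max 17 eQTLs in one fragment
fragment correlation: R = 0.329 (p = 1.7e-300); excluding GW fragments: R = 0.270 (p = 8.4e-196)
```

Read: eQTL SNPs are more significant than non-eQTLs in every tissue;
significance rises with tissue breadth; the eQTL share climbs steeply from
the white-noise zone through the gray zones; the binned proportion rises
near-monotonically across the gray zone; high-eQTL-density SNPs sit in
regulatory elements far more often; and the fragment-level control confirms
the density association without window overlap, surviving removal of
genome-wide peaks.

The numbered scripts under `analysis/` run the same sequence as a workflow —
`01_simulate_inputs.R` … `05_null_calibration.R` — writing compact result
tables under `results/` (bulky intermediates go to `scratch/`). The methods
vignette (`vignettes/methods.Rmd`) documents the model, conventions
(coordinates, zone boundaries, bin grid, window closure), the generator's
parameters, and calibration findings.

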