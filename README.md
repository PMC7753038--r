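# marrowmorph

Quantitative analysis of NESTIN-positive micro-vessels in human bone-marrow
trephine sections, for histomorphometry and niche-biology work: pixel
co-localization of a cytoskeletal marker (NESTIN) with endothelial surface
markers (CD34/CD31), inner-caliber-based vessel classification, and
distribution-based spatial inference on distances to bone and to immature
haematopoietic cells (imHCs). Because archival biopsy images of this kind
are not publicly available, the package ships a seeded synthetic micrograph
generator with full ground truth, so the whole pipeline is testable and
reproducible end to end.

## What it computes

**Co-localization** (`coloc_analysis()`): Costes automatic thresholds —
red is regressed on green, and the green threshold is the highest intensity
level *T* for which pixels with `green < T` and `red < a + bT` are
uncorrelated (Pearson <= 0) — then Pearson's *R* over above-threshold
pixels and the Manders coefficients

    M1 = sum(red[green > Tg]) / sum(red)      # membrane marker inside cytoskeleton+ area
    M2 = sum(green[red > Tr]) / sum(green)

plus the same coefficients (tR, tM1, tM2) after translating the green
channel by 100 px on both axes (thresholds re-estimated on the translated
pair). Group comparisons use Kruskal–Wallis with Dunn's post test
(Bonferroni).

**Morphometry** (`measure_inner_caliber()`, `compute_quartiles()`,
`classify_structure()`): the inner caliber (IC) is the minor axis of the
largest lumen component; quartile cut-offs of the non-zero calibers split
the vessels into bands, and rules assign the classes — non-tubular NC,
no-pericyte NCLT, compressed cEA (IC <= q50), EA (q50 < IC <= q75), artery
A (IC > q75). A 5 x 3 caliber-by-complexity contingency table is tested by
chi-square (`build_contingency()`, `chi_square_table()`).

**Spatial statistics** (`normalize_distance()`, `skewness_z()`,
`normality_diagnostics()`, `clustering_inference()`): distances are
normalized by subtracting IC/2 (floored at 0) and each series is
characterised by Shapiro–Wilk, the adjusted Fisher–Pearson skewness
G1 = m3/m2^{3/2} · sqrt(n(n−1))/(n−2) with its exact standard error
SE = sqrt(6n(n−1)/((n−2)(n+1)(n+3))), z = G1/SE, and de-trended Q-Q
ordinates; verdicts ("right-skewed" / "normal" / "symmetric non-normal")
follow stated (p, z) rules with 40/20/10 um analysis windows.

**Synthetic data** (`fixture_config()`, `generate_dataset()`,
`place_imhcs()`, `simulate_coloc_pair()`): one vessel-centred field of view
per structure, annular cross-sections with graded radial profiles, a
radially offset membrane channel, optional perivascular rings, bone
trabecula polygons, and imHC point patterns that are uniform or
exponentially condensed around a target class.

## Worked example

The published category counts (268 capillary-like tubes, 58 arteries,
97 arterioles including compressed ones, 64 non-tubular cells) give the
headline proportions among the 423 tubular vessels:

```r
pct <- class_percentages(c(A = 58, EA = 58, cEA = 39, NCLT = 268, NC = 64))
pct$percent_1dp
#>           A          EA         cEA EA_plus_cEA        NCLT
#>        13.7        13.7         9.2        22.9        63.4
```

i.e. 13.7% arteries, 22.9% arterioles (EA plus cEA), 63.4% capillary-like
tubes. A published skewness of 1.734 at n = 123 corresponds to

```r
skewness_zscore(1.734, 123)
#> $z
#> [1] 7.945657
#> $z_rounded
#> [1] 8
#> $se_g1
#> [1] 0.2182324
```

The full synthetic study is the `analysis/` workflow:

```
Rscript analysis/01_simulate.R     # 487 ground-truthed fields + measurements
Rscript analysis/02_coloc.R        # co-localization coefficients + controls
Rscript analysis/03_morphometry.R  # cut-offs, classes, contingency test
Rscript analysis/04_spatial.R      # co-occurrence, skewness verdicts, Q-Q
```

which prints, among other things (seed 1):

```
caliber quartile cut-offs (non-zero lumens): 3.4 / 4.4 / 7.5 um
ground-truth recovery: 96.5%
percent of tubular vessels: A 15.1%, EA+cEA 21.5%, NCLT 63.4%
5 x 3 contingency chi-square: X2 = 460.3, df = 8, p = 2.28e-94
  R  = 0.492 +- 0.022   (control tR  = -0.031 +- 0.002)
  M1 = 0.893 +- 0.005   (control tM1 = 0.000 +- 0.000)
bone in FOV: 47.8% of NCLT fields vs 29.7% of other vessels (higher, p = 0.000271)
imHC around NCLT: n = 495, skewness 1.01 (z = 9.2), p_sw = 1.12e-20 -> right-skewed
```

— the qualitative result surface of the study: high Manders co-occurrence
with near-zero translated controls, quartile cut-offs and class proportions
near the reference values, preferential bone co-occurrence of the
capillary-like tubes, and a right-skewed imHC distance distribution
signalling condensation within the perivascular shell. Tables land under
`results/`.

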