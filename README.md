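# chromnano

Quantitative analysis of nuclear chromatin organisation and miRNA-FISH
signal in tissue microscopy, from single-molecule localisation tables
down to per-cell statistics.

Tumour cell heterogeneity shows up in the nucleus: carcinoma cells in
colorectal tissue differ from normal epithelial and stromal cells in
nuclear size, in the fraction of their chromatin that is compacted, and
in the nanoscale texture of chromatin density that single-molecule
localisation microscopy (SMLM) resolves but widefield imaging cannot.
`chromnano` packages the quantitative analyses this kind of study needs,
for image analysts working with localisation tables (ThunderSTORM-style
CSV), confocal nucleus crops, and two-channel FISH tissue fields:

* **Occupancy binning** — localisations inside a nuclear ROI are counted
  on a 50 × 50 nm² grid; the distribution of counts over occupied bins
  (median, quartiles, 1.5·IQR whiskers, outliers) is the per-nucleus
  chromatin-density signature, pooled over replicate nuclei per cell
  type. In the sparse carcinoma regime most occupied bins hold a single
  blinking event, so the pooled median drops.
* **Equal-area radial rings** — the nuclear contour is scaled about its
  centroid by factors √(k/6), cutting the nucleus into six rings of
  exactly equal area from centre to periphery; per-ring localisation
  densities (µm⁻²) quantify the radial chromatin gradient (densest at
  the periphery).
* **Chromatin compaction (confocal)** — Otsu nucleus segmentation, local
  maxima as chromatin domains, seeded region growing with a relative
  half-rise cut; reports nuclear area, number of domains, percent
  compact chromatin and dark area, with cohort summaries as mode ± SD
  from a Freedman–Diaconis histogram.
* **miR-FISH per-cell quantification** — nuclei detection with watershed
  splitting, a cytoplasm band per cell, mean miR-channel intensity on
  the 0–255 scale, miR⁺ classification at the inclusive threshold ≥ 5,
  field-level percentages, and a one-sided unpaired rank-sum
  (Mann–Whitney) test between tissue groups (exact by enumeration for
  small tie-free samples, tie/continuity-corrected normal approximation
  otherwise).
* **Rendering and profiles** — count-conserving histogram rendering of
  localisation tables, widefield emulation (100 nm pixels + Gaussian
  PSF), bilinear line profiles, and a contrast ratio quantifying how
  much stronger the density excursions are in the reconstruction.
* **Synthetic data with planted truth** — clustered SMLM point patterns
  (50–60 nm FWHM clusters, optional radial gradient with a closed-form
  ring law), nucleus images with a plantable compact fraction, and
  tissue fields with a plantable miR⁺ cell fraction, so every stage is
  validated by parameter recovery.

## Worked example

Simulate a carcinoma-like and a normal-like nucleus, bin both, and
profile the normal one radially:

```r
library(chromnano)

carc <- simulate_localisations(smlm_preset("carcinoma-like", seed = 1))
norm <- simulate_localisations(smlm_preset("normal-like",    seed = 2))

bin_count_distribution(bin_localisations(carc$table))
#> Occupied-bin count distribution: n = 461 bins, median 3 [q1 2, q3 4], 14 outlier(s)
bin_count_distribution(bin_localisations(norm$table))
#> Occupied-bin count distribution: n = 213 bins, median 43 [q1 22, q3 69], 0 outlier(s)

rings <- build_rings(smlm_preset("normal-like")$contour, 6)
ring_profile(norm$table, rings)
#> Ring profile (centre -> periphery):
#>   counts:    478 872 1401 1964 2533 2552
#>   per um^2:  6111.9 11149.8 17913.9 25112.7 32388.2 32631.1
```

The carcinoma-like occupancy median (3) is far below the normal-like one
— the sparse, low-density chromatin regime of tumour nuclei — and the
ring densities rise monotonically from nuclear centre to periphery,
reproducing the radial chromatin gradient. A compaction run on a
synthetic nucleus with half its chromatin planted as compact domains:

```r
sim <- simulate_nucleus_image(nucleus_image_spec(40, compact_fraction = 0.5,
                                                 n_domains = 4, noise_sigma = 0,
                                                 seed = 11))
analyze_chromatin_compaction(sim$image)
#> Chromatin segmentation: nucleus 50.36 um^2, 4 domains, 49.7% compact, dark area 25.35 um^2
```

and a two-group miR comparison over simulated tissue fields:

```r
fields <- c(lapply(1:5, function(s) simulate_tissue_field(
              tissue_field_spec(20, 0.5,  seed = s))$field),
            lapply(6:10, function(s) simulate_tissue_field(
              tissue_field_spec(20, 0.05, seed = s))$field))
res <- run_mir(fields, groups = rep(c("tumour", "normal"), each = 5))
res$comparison
#> One-sided rank-sum test (normal_approx, alternative = 'greater'): U = 25, p = 0.001988 (n = 5, m = 5)
```

(Ties among the field percentages push the test onto the corrected
normal approximation; tie-free samples of this size would be enumerated
exactly.)

`pipeline_config()` carries every tunable (bin size 50 nm, 6 rings,
miR threshold 5, alpha 0.05, segmentation parameters) and can be read
from YAML; `run_density()`, `run_rings()`, `run_compaction()` and
`run_mir()` chain the stages over batches of input files and write CSV/
JSON outputs plus a reproducibility manifest.

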