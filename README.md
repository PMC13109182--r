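# chromafoci

Per-cell quantification of **where DNA-damage foci sit relative to
chromatin compaction**, from dual-colour confocal images, using nothing
but a DNA counterstain as the chromatin reference.

Immunofluorescence routinely pairs a damage marker (e.g. γ-H2AX, which
forms foci at double-strand breaks) with a DNA counterstain (e.g. DAPI).
The counterstain intensity itself encodes compaction — heterochromatin
bright, euchromatin dim — so a two-channel image already contains the
answer to "is this damage in dense or open chromatin?". For every
segmented nucleus the package reports:

* **DNA density** — the mean of the per-nucleus max-normalized
  counterstain intensity, `I_norm = I_DNA / I_max`, averaged over the
  damage regions (nucleus mask ∩ damage mask). Values near 1: damage in
  compact chromatin; low values: open chromatin.
* **Colocalization fraction f₁** — from image cross-correlation
  spectroscopy (ICCS). With masked spatial correlation functions
  `G_ab(ξ,η) = ⟨δI_a(x,y) δI_b(x+ξ,y+η)⟩ / (⟨I_a⟩⟨I_b⟩)` fitted by a 2D
  Gaussian `G₀ exp(−(ξ²+η²)/w²) + G∞`, the fractions are the amplitude
  ratios `f₁ = G₀¹²/G₀²²` and `f₂ = G₀¹²/G₀¹¹`, running from 1 (full
  colocalization) through 0 (independence) to −1 (exclusion). No object
  segmentation of either channel is required.

Supporting machinery: isodata nucleus segmentation into count masks,
rolling-ball background subtraction, strict-threshold damage masks with
focus counting, a ground-truthed two-channel nucleus simulator, a batch
pipeline with CSV output and a small CLI, plus a minimal uncompressed
TIFF reader/writer (round-trip verified against `tifffile`).

## Worked example

Simulate the classic validation contrast — a heterochromatin-targeted
marker (`p_het = 1`, every focus on a chromatin blob) versus a
euchromatin-targeted one (`p_het = 0`, foci kept off-blob) — and run the
full pipeline on each nucleus:

```r
library(chromafoci)
cfg <- run_config(foci_threshold = 30)
cells <- do.call(rbind, lapply(1:8, function(s) {
  het <- simulate_nucleus(scene_params(p_het = 1, seed = s))
  eu  <- simulate_nucleus(scene_params(p_het = 0, seed = 100 + s))
  rbind(analyze_field(het$ch1, het$ch2, cfg, image_id = "het_marker")$cells,
        analyze_field(eu$ch1, eu$ch2, cfg, image_id = "eu_marker")$cells)
}))
print(cells[1:4, c("image_id", "cell_id", "n_foci", "roi_area_px",
                   "dna_density", "f1", "valid")], digits = 3)
#>     image_id cell_id n_foci roi_area_px dna_density     f1 valid
#> 1 het_marker       1      5         552       0.456  0.921  TRUE
#> 2  eu_marker       1      5         552       0.195 -0.134  TRUE
#> 3 het_marker       1      5         583       0.436  0.899  TRUE
#> 4  eu_marker       1      5         553       0.205 -0.181  TRUE
print(summarize_cells(cells, "image_id")[, c("image_id", "n_cells",
      "mean_dna_density", "sd_dna_density", "mean_f1", "sd_f1")], digits = 2)
#>     image_id n_cells mean_dna_density sd_dna_density mean_f1 sd_f1
#> 1 het_marker       8             0.45          0.015    0.91 0.018
#> 2  eu_marker       8             0.20          0.011   -0.19 0.040
```

Each row is one nucleus: all 5 planted foci were recovered, the
blob-targeted marker shows high DNA density (0.45) and strong positive
colocalization with the dense-counterstain regions (f₁ ≈ 0.9), the
off-blob marker low density (0.20) and slightly negative f₁ — the
orderings the method is designed to resolve. On real data, replace the
simulation with `run_batch()` over TIFF files:

```r
inputs <- data.frame(image_id = "exp1_fov1",
                     path_ch1 = "fov1.tif",       # 2-page: damage, dna
                     path_ch2 = NA_character_)
run_batch(inputs, cfg, out_dir = "results/")      # results.csv, summary.csv
```

or use the CLI (`inst/cli/chromafoci.R`):
`run`, `simulate`, `summarize` subcommands.

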