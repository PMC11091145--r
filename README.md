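# msitrace

Spatially resolved isotope-tracing analysis for MALDI mass spectrometry
imaging (MSI) of ex vivo machine-perfused kidneys, plus the perfusion
physiology that goes with it.

## The problem

Multi-day machine perfusion keeps donor kidneys metabolically active outside
the body. Whether the tissue is *actually* metabolizing — and which cell
types are — can be read out by perfusing a ¹³C-labeled nutrient
(¹³C₅-glutamine or ¹³C₆-glucose) and imaging the label's fate with
high-resolution MALDI-MSI (5 × 5 µm pixels). Each pixel yields an intensity
vector over m/z features: lipids that fingerprint the cell type occupying
the pixel, and isotopologue channels (M+0 … M+n) of central-carbon
metabolites that record how much label arrived.

`msitrace` implements that analysis chain as composable, deterministic R
functions:

1. **Pixel preprocessing** — total-ion-count (TIC) normalization, the
   ×100-and-floor integer count matrix, lipid feature selection
   (m/z ≥ 400, S/N ≥ 3, MALDI-matrix signals excluded), ±20 ppm feature
   annotation, 99 %-quantile hotspot clipping.
2. **Phenotype segmentation** — log1p variance stabilization → PCA →
   seeded k-means on lipid profiles; marker-based cluster annotation;
   per-cluster differential lipids (rank-sum test, BH adjustment); k-NN
   transfer of metabolite channels from a labeled reference onto a query
   dataset.
3. **Isotope correction** — a forward convolution matrix combining natural
   ¹³C abundance (1.07 %) and tracer purity (99 %), inverted per pixel by
   non-negative least squares; fraction enrichment
   `M+k / Σ M+0..M+n`.
4. **Relative TCA-cycle flux ratios** from ¹³C₅-glutamine enrichments at
   pseudo-steady state:

   ```
   V_GLS/V_OGDH   = glutamate(m+5) / glutamine(m+5)
   V_GLS/V_IDH    = r / (1 − r),   r = glutamate(m+5)/glutamine(m+5)
   V_OGDH/V_SDH(F)= succinate(m+4) / glutamate(m+5)
   V_SDH(F)/V_MDH = malate(m+4) / succinate(m+4)
   ```

5. **Perfusion physiology** — oxygen delivery
   `pO₂ₐ × 0.0031 mL O₂ dL⁻¹ mmHg⁻¹ × flow (dL/min)`, oxygen uptake from
   the arterio-venous ΔpO₂, vascular resistance (MAP/flow), percent weight
   gain, glomerular sieving coefficients from labeled-dextran fluorescence,
   and hemofiltration exchange fractions.
6. **Synthetic data** — a forward flux model that generates MSI-like pixel
   data (blob-shaped phenotype regions, lipid signatures, isotopologue
   channels convolved with the abundance/purity model, log-normal TIC
   variation, truncated Gaussian noise) with full ground truth, so the
   whole chain is testable without any external download.

Who it is for: perfusion scientists and imaging-MS analysts who have a
pixel-by-feature CSV export and want cluster-level enrichments and flux
ratios; methods developers who need a ground-truth-bearing simulator of
spatial isotope-tracing data.

## Worked example

```r
library(msitrace)
report <- run_pipeline(pipeline_config(seed = 2, width = 24, height = 24,
                                       n_types = 2))
print(report)
```

```
# Spatial isotope-tracing pipeline report

Seed: 2

## Cluster composition

- cluster 1 (type2): 245 pixels (42.5%)
- cluster 2 (type1): 331 pixels (57.5%)

## Relative TCA flux ratios

- cluster_1: V_GLS/V_OGDH=0.5343, V_GLS/V_IDH=1.1474, V_OGDH/V_SDH(F)=1.2063, V_SDH(F)/V_MDH=0.9664
- cluster_2: V_GLS/V_OGDH=0.8297, V_GLS/V_IDH=4.8718, V_OGDH/V_SDH(F)=1.3780, V_SDH(F)/V_MDH=0.7840

Weight gain: 14%
```

The simulator drew one flux-ratio set per phenotype; the generator's truth
for these two phenotypes was `V_GLS/V_OGDH` = 0.532 / 0.828,
`V_OGDH/V_SDH(F)` = 1.209 / 1.385 and `V_SDH(F)/V_MDH` = 0.967 / 0.783
(`report$ground_truth$true_flux_ratios`) — the pipeline recovers each from
noisy pixel data to well within 5 % after TIC normalization, segmentation,
and per-pixel isotope correction. The 14 % weight gain is the simulated
4-day perfusion's edema readout (100 × (w₁ − w₀)/w₀, rounded half-up).

Single calculations work standalone, e.g.:

```r
weight_gain_pct(283, 363)$percent_int   # 28
oxygen_delivery(645, 500)               # 9.9975 mL O2/min
v_gls_over_idh(0.4, 0.8)                # 1
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
it simulates a 64 × 64 three-phenotype dataset under the given seed, runs
the full chain (normalize → segment → correct → enrich → flux ratios →
physiology), logs the segmentation agreement and per-cluster ratios, and
writes the target report JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — implementation (one file per stage: `msi_dataset`, `segmentation`,
  `isotope_correction`, `enrichment`, `qflux`, `physiology`,
  `synthetic_data`, `pipeline`).
- `tests/testthat/` — unit, property and acceptance suites.
- `vignettes/spatial-isotope-tracing.Rmd` — the methods vignette: model
  assumptions, parameter choices, what the simulator does and does not
  emulate.
- `inst/scripts/run_pipeline.R` — thin command-line wrapper over
  `run_pipeline()`.
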