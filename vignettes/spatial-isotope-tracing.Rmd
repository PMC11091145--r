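---
title: "Spatial isotope tracing from MSI pixel data: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial isotope tracing from MSI pixel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msitrace)
```

# Scope

`msitrace` turns a pixel-by-feature MSI intensity export into cell-type
resolved ¹³C fraction enrichments and relative TCA-cycle flux ratios, and
provides the standard physiology calculations of ex vivo kidney machine
perfusion. This vignette is the package's account of the underlying models:
what each stage assumes, which tunable parameters matter, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

# The pixel data model

A `spectral_image` is a set of pixels on a regular grid (0-based `(x, y)`
integer coordinates, default 5 µm edge length) with one non-negative
intensity per m/z feature. The reference exchange format is a plain CSV
with header `x,y,<mz>,<mz>,...` — the flat per-pixel table that imaging
software exports after peak picking. No raw-spectrum processing (baseline,
centroiding, recalibration) happens here; the package starts at the
feature-intensity level.

**TIC normalization.** Ionization efficiency varies strongly from pixel to
pixel, so every pixel is divided by its total ion count before any
comparison across pixels. Pixels with a zero TIC carry no information: they
are dropped (and counted) rather than kept as zero vectors, because a
fraction of zero total is undefined and clustering zero vectors is
meaningless. Normalization is idempotent in value: re-dividing by the new
row sums (all 1) changes nothing.

**Count matrix.** For count-based variance stabilization, normalized
fractions are mapped to pseudo-counts as `floor(100 x fraction)`, giving
integers in 0..100. "Taking the integer" is implemented as floor
(truncation toward zero on non-negative values), the behavior of an integer
cast.

**Lipid feature selection.** Segmentation runs on lipid features only:
m/z at or above 400 (default; glycerophospholipid range), signal-to-noise
at or above 3, and not flagged as MALDI-matrix signals. The S/N value and
the matrix flag are *inputs* in the feature table — the upstream peak
picker's estimates — because no S/N estimator or matrix-colocalization
criterion is defined at the feature-table level. m/z annotation matches
observed against reference masses at ≤ 20 ppm relative error, smallest
error wins, exact ties flagged ambiguous and left unmatched.

**Hotspot removal.** Pseudo-images clip values above the empirical 99 %
quantile to that quantile. The quantile uses linear interpolation between
order statistics (R's default type 7); this is stated so results are
bit-reproducible.

# Segmentation

The clustering path is deliberately deterministic and dependency-light:
log1p of the count matrix, per-feature scaling to unit variance, PCA to
`n_components` (default 20), then k-means with a fixed seed and 10 restarts.
Cluster ids are renumbered by first pixel occurrence, so the labeling is
reproducible and pixel-order invariant up to relabeling. A graph-based
clusterer with anchor-based dataset integration would be the
single-cell-style alternative; it was not used because its stochastic
components (UMAP, SNN modularity optimization, anchor sampling) would make
acceptance tests fragile, and the quantity of interest downstream —
phenotype composition and per-cluster means — does not depend on the
specific clusterer once the lipid profiles separate. UMAP remains a
visualization option, never on the computation path.

Cluster annotation replaces immunostain alignment with marker features:
each cluster takes the phenotype whose marker set has the highest mean
intensity in the cluster, with the top-two margin reported; ties at machine
precision leave the cluster unlabeled with a flag.

Differential lipids per cluster use the log2 ratio of means (pseudo-count
1e-9 guards zeros) and a two-sided Wilcoxon rank-sum test per feature, with
Benjamini–Hochberg adjustment across features — the multiple-testing
procedure was an open choice and BH is the field default for marker
screens.

**Metabolite transfer.** To compare labeled datasets against an unlabeled
control, metabolite channels are imputed onto query pixels from their `k`
(default 10) nearest reference pixels in the shared, variance-stabilized
lipid space, weighted by inverse distance (`1/(d + 1e-9)`, normalized).
Because imputed values are convex combinations of reference values, the
transfer never extrapolates outside the reference range; a query identical
to the reference reproduces it to numerical precision.

# Isotope correction

Observed isotopologue intensities mix three signals: tracer-derived label,
natural ¹³C (abundance `p13c`, default 0.0107), and tracer impurity
(per-atom purity, default 0.99). The package models a molecule with `j`
tracer-derived carbons out of `n` as: each labeled carbon is ¹³C with
probability `purity + (1 − purity) x p13c` (an impure position behaves as a
natural-abundance carbon), each unlabeled carbon is ¹³C with probability
`p13c`. Column `j` of the forward matrix is the convolution of the two
binomial distributions; all columns sum to 1. Folding purity into the same
matrix as natural abundance means one inversion performs both corrections;
whether the original workflow applied purity correction before or combined
with abundance correction is not derivable from its description — the
combined matrix is this package's choice, recorded here, and it is
self-consistent end to end.

Only carbon isotopes are corrected: TOF resolution cannot separate
heteroatom isotopologues and the tracers are ¹³C, so H/N/O corrections
would be noise.

The inversion solves `forward x ≈ observed` by Lawson–Hanson non-negative
least squares (implemented in the package; small dense systems of at most
7 unknowns), then renormalizes to a distribution and reports the residual
norm. NNLS guarantees non-negative fractions under noise; a direct
`solve()` path exists for exactness tests on noiseless data. Pixels whose
unconstrained solution is already non-negative take a vectorized direct
inverse — NNLS only runs where the constraint binds. An all-zero
observation is a *masked* value, not an error, and stays NA through every
later aggregation.

Fraction enrichment is `M+k / Σ M+0..M+n` on corrected pools (correct
first, then enrich — enrichment is defined on true isotopologue pools), and
is scale invariant, so it does not matter whether it is computed on raw or
TIC-normalized intensities.

# Flux ratios

At pseudo-steady state with a ¹³C₅-glutamine tracer, enrichment ratios
along glutamine → glutamate/α-KG → succinate → malate report relative
enzyme rates (glutaminase, α-KG dehydrogenase, isocitrate dehydrogenase,
succinate dehydrogenase forward, malate dehydrogenase):

- `V_GLS/V_OGDH = glutamate(m+5)/glutamine(m+5)`
- `V_GLS/V_IDH = r/(1−r)` with `r` the ratio above (the IDH-derived share
  of the α-KG pool is `1−r`)
- `V_OGDH/V_SDH(F) = succinate(m+4)/glutamate(m+5)`
- `V_SDH(F)/V_MDH = malate(m+4)/succinate(m+4)`

The last two use m+4 because succinate and malate have four carbons; an
m+5 species is chemically impossible for them.

Numerical guards: fractions at or below `eps = 1e-6` in a denominator
invalidate the ratio (reason recorded); `r ≥ 1 − eps` invalidates
`V_GLS/V_IDH` (the pool cannot be more than fully glutamine-derived at
steady state, so `r ≥ 1` marks either noise or model violation); zero
*numerators* are also flagged rather than returned as 0, since a zero
forward flux contradicts the steady-state assumption. Ratios are computed
on cluster-mean enrichments by default — matching a workflow that averages
fraction enrichment per cluster before plotting — and nothing prevents
applying them per pixel and averaging afterwards; whether the original
analysis did one or the other is not stated anywhere, so the cluster-mean
default is a package choice.

# Physiology

All formulas are closed-form and unit-explicit:

- Oxygen delivery `= pO₂(art) x 0.0031 mL O₂ dL⁻¹ mmHg⁻¹ x flow (dL/min)`;
  uptake uses the arterio-venous ΔpO₂. The solubility constant is the
  aqueous value appropriate for an acellular (hemoglobin-free) perfusate;
  linearity `uptake = delivery(art) − delivery(ven)` is exact.
- Vascular resistance `= MAP / flow` — the conventional perfusion index; a
  pressure-controlled system holds MAP (set-point 75 mmHg) and resistance
  shows in the flow.
- Weight gain `= 100 x (w₁ − w₀)/w₀`, reported at full precision and
  rounded half-up to the integer percent used in summaries (R's own
  `round()` is half-even, which would turn 28.5 into 28 instead of 29).
- Glomerular sieving coefficient `= (urine − background)/(perfusate −
  background)` on dextran fluorescence; the pre-infusion sample is the
  background because raw fluorescence is measured without a stated blank
  policy. Negative numerators clamp to 0 with a flag; a perfusate signal at
  or below background invalidates the sample.
- Hemofiltration exchange `= 100 x removal rate / reference volume`. The
  reference volume is a *required* argument: a "5 % exchange" at 40 mL/h is
  consistent with an 800 mL reference but not with a ~700 mL circuit volume
  (5.7 %) or the 20 mL/min filter blood flow (3.3 %), so no constant is
  guessed.

# The synthetic-data generator

The generator exists so that every stage — and the full chain — can be
tested against known truth. Its stated world:

- **Tissue**: `n_types` (2–8) contiguous blob-like regions grown by seeded
  multi-source flood fill from random centers on a `width x height` grid
  (≥ 8 px a side). This mimics tubular cross-sections without modeling
  anatomy.
- **Lipid signatures**: per-phenotype log-normal base levels
  (`meanlog 3, sdlog 0.4`) with one 5x-elevated marker lipid per phenotype,
  so marker annotation has a clean surrogate for immunostaining.
- **Metabolite truth**: per-phenotype flux-ratio targets are inverted into
  enrichment vectors (`glutamate(m+5) = ratio x glutamine(m+5)`, etc.),
  residual mass in M+0; the labeled channels are all the flux equations
  pin, so nothing else is modeled. Glucose-tracer channels (lactate, 3PG,
  G3P m+3, etc.) would be generated from user-set fractions without a flux
  model, since no flux ratio is defined on that tracer.
- **Glutamine enrichment**: the true glutamine m+5 fraction — the share of
  the tissue pool replaced by tracer — defaults to 0.25. This keeps the
  whole default ratio box [0.5, 1.5]³ feasible (the implied malate
  enrichment `gln_m5 x r₁ x r₃ x r₄` must stay below 1, which requires
  `gln_m5 < 1/1.5³ ≈ 0.30`) and is a plausible pool replacement after a
  2-hour tracer incubation.
- **Observation model**: observed isotopologue channels are the true
  vectors convolved with the same abundance/purity forward matrix the
  corrector inverts — so synthetic data genuinely require correction —
  scaled by metabolite base abundances (glutamine 80, glutamate 100,
  succinate 60, malate 60 a.u., rough tissue-like pool sizes). Every
  channel is multiplied by a per-pixel log-normal TIC factor (CV 0.2,
  mean 1) and perturbed by additive Gaussian noise with sd proportional to
  the clean intensity (`noise_sd`, default 0.05), truncated at zero as a
  detector would.
- **Perfusion series**: hourly samples; flow rises briefly then plateaus
  near 400 mL/min at a 75 mmHg set-point (placing oxygen delivery in the
  5–15 mL O₂/min band for carbogen-saturated perfusate at pO₂ ≈ 600 mmHg);
  after an optional `failure_day`, flow decays, oxygen uptake falls from
  ~1 mL O₂/min, pH drifts below 7.3 and lactate accumulates. Initial weight
  ~283 g with a weight gain that reaches 28 % at 8 days.

What it does **not** emulate: mass-spectral artifacts (peak shape, matrix
clusters, detector saturation), spatial intensity gradients within a
phenotype, partial-volume mixing at region borders, section-to-section and
subject-to-subject variability, and any real biological heterogeneity of
flux within a phenotype. A green full-chain test therefore establishes that
the *computational* chain is correct and numerically stable under realistic
noise — not that the method would survive every artifact of a real
MALDI-TOF acquisition. No noise characteristics of real instruments were
fitted; the defaults are conventional.

Determinism is a contract: every stochastic step runs under a seed derived
deterministically from the master seed (per-stage children, kept below
2³¹), identical seeds give bit-identical datasets and byte-identical
pipeline report bodies, and generators restore the caller's RNG state.

# Parameters at a glance

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `pixel_size_um` | 5 | µm | high-resolution MALDI-TOF pixel edge |
| `min_mz`, `min_snr` | 400, 3 | m/z, — | lipid selection window |
| `tol_ppm` | 20 | ppm | annotation tolerance |
| `quantile` | 0.99 | — | hotspot clipping |
| `p13c` | 0.0107 | fraction | natural ¹³C abundance |
| `tracer_purity` | 0.99 | fraction | per-atom tracer purity |
| `n_components` | 20 | PCs | segmentation embedding |
| `k` (transfer) | 10 | neighbours | imputation smoothing vs locality |
| `eps` (flux) | 1e-6 | fraction | denominator/boundary guard |
| `gln_m5` | 0.25 | fraction | tracer share of glutamine pool |
| `noise_sd`, `tic_cv` | 0.05, 0.2 | relative | conventional detector noise |

# Known limitations

- Carbon-only correction; overlapping heteroatom isotopologues and adducts
  are out of scope.
- No absolute fluxes: everything is relative to a neighboring enzyme's
  rate, and a reductive (reverse) TCA contribution cannot be separated from
  the forward ratios.
- Cluster standard deviations are across pixels, not across subjects;
  across-sample aggregation is a reporting exercise left to the caller.
- Composition percentages of real kidney sections are not reproduction
  targets: they depend on the section, the cluster count and the
  annotation, none of which are pinned by the package.
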