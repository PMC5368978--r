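# oxiflim

Dual-mode quantification of cellular oxidative stress from fluorescence
intensity + fluorescence lifetime (FLIM) imaging with long-lifetime
turn-on probes.

## The problem

Turn-on metal-complex probes for glutathione (P-GSH), hydrogen peroxide
(P-HP) and hypochlorous acid (P-HA) report their analyte twice: reaction
raises the emission intensity *and* switches the excited-state lifetime
from a few nanoseconds (unreacted: 6, 5.5, 4.3 ns) to 90–225 ns
(reacted: 225, 146, 90.5 ns). Tissue autofluorescence sits at 2–3 ns, so
the slow lifetime is a concentration-independent signature of reacted
probe that rejects intensity-only false positives. This package
implements the analysis chain for such experiments, for microscopists and
image analysts working with TCSPC FLIM of cells:

* **Incomplete-decay model.** At 80 MHz the inter-pulse period is
  T = 12.5 ns, far shorter than the reacted lifetimes; the measured
  histogram is the steady state of all preceding pulse tails. Each pixel
  is modelled as
  `F(t) = A [α₁ e^(−t/τ₁)/(1−e^(−T/τ₁)) + α₂ e^(−t/τ₂)/(1−e^(−T/τ₂))] + C`
  with α₁ + α₂ = 1 — the geometric-series closed form of the periodic
  bi-exponential decay.
* **Poisson maximum-likelihood fitting** of that model per ROI
  (`fit_histogram()`, L-BFGS-B with analytic gradients) and per pixel
  (`fit_stack()`, compiled Levenberg–Marquardt), with lifetime ordering,
  amplitude-constraint, degenerate-component collapse and masking rules.
* **Cell segmentation** (`segment_cells()`): Gaussian smoothing, global
  Otsu threshold, hole filling, connected components, retention of round
  objects 30–70 px in equivalent diameter.
* **Per-cell positivity** (`quantify_cells()`, `percent_positive()`):
  photon-weighted mean slow lifetime > 100 ns.
* **Subpopulation modelling** (`select_components()`): 1- vs 2-component
  Gaussian mixtures of per-cell intensities, AIC selection with
  p = 3k − 1 parameters.
* **Optical oxidative stress index** (`compute_osi()`): mean ROS-probe
  cell intensity over mean GSH-probe cell intensity, plus Student's t
  tests with Bonferroni correction (`compare_groups()`).
* **Synthetic TCSPC scenes** (`make_scene()`, `render_flim()`) emulating
  control / injury / treated liver-imaging conditions with planted ground
  truth, so the whole chain is testable without any acquisition hardware.

## Worked example

Simulate reacted and unreacted P-GSH ROI decays (10⁷ photons, 256 bins
over the 12.5 ns window) and fit them:

```r
library(oxiflim)
acq <- acquisition_spec(80, 256)   # 80 MHz -> 12.5 ns window
gsh <- flim_probes("P-GSH")

roi_sim <- function(tau, seed) {
  p <- decay_params(0, 1, tau, tau)
  mu <- periodic_bin_means(p, acq)
  set.seed(seed)
  rpois(acq$n_bins, mu / sum(mu) * 1e7)
}
opts <- fit_options(fix_offset = 0)
f_r <- fit_histogram(roi_sim(gsh$tau_reacted, 1), acq, opts)
f_u <- fit_histogram(roi_sim(gsh$tau_unreacted, 2), acq, opts)
```

which prints (via `print(f_r)`, `print(f_u)`):

```
<fit_result> tau = (224, 224) ns, alpha2 = 1, C = 0, chisq_r = 0.952 [mono]
<fit_result> tau = (6, 6) ns, alpha2 = 0.534, C = 0, chisq_r = 1.15
```

The reacted decay is recovered at τ₂ = 224.0 ± 4.4 ns — within error of
the 225 ns reacted-state lifetime and far beyond the 100 ns positivity
rule (the `[mono]` tag records that the unidentifiable second component
was collapsed). The unreacted decay fits at 6.00 ns, a 37.3-fold
difference, matching the probe's ~38-fold lifetime switch. The reduced
chi-squares near 1 say both fits are statistically consistent with the
data.

The full chain runs from one call:

```r
m <- run_pipeline(pipeline_config("injury", seed = 1))
m$summary$selected_k          # 2  (injury plants two GSH subpopulations)
round(m$summary$osi, 2)       # 1.37 (elevated ROS / depleted GSH)
```

A treated-condition run at the same seed gives `selected_k = 1` and
OSI ≈ 0.29: treatment collapses the susceptible subpopulation and lowers
the index. `run_pipeline()` writes the stacks (multi-page TIFF + JSON
sidecar), intensity images, per-cell CSV tables, the subpopulation model
and a checksummed manifest to the output directory.

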