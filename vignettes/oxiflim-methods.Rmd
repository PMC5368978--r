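---
title: "Dual-mode FLIM quantification of oxidative stress: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-mode FLIM quantification of oxidative stress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxiflim)
```

## The measurement problem

Turn-on lifetime probes for glutathione (GSH) and reactive oxygen species
(hydrogen peroxide, hypochlorous acid) are transition-metal complexes whose
emission is quenched by photo-induced electron transfer until the analyte
cleaves the responsive group. Reaction switches both the brightness *and*
the excited-state lifetime: from a few nanoseconds in the unreacted state
(P-GSH 6 ns, P-HP 5.5 ns, P-HA 4.3 ns) to 90-225 ns when reacted (P-HA
90.5 ns, P-HP 146 ns, P-GSH 225 ns). Because tissue autofluorescence and
common organic dyes live at 1-5 ns, the slow lifetime is a
concentration-independent signature of the reacted probe: an
intensity-bright cell with a short lifetime is a false positive, and
lifetime imaging rejects it.

`oxiflim` implements the quantification chain for such dual-mode (intensity
plus TCSPC lifetime) experiments: decay modelling and fitting, cell
segmentation, per-cell positivity, subpopulation modelling of per-cell
intensities, and the optical oxidative stress index (OSI), together with a
synthetic scene generator that makes every stage testable against planted
ground truth.

## The incomplete-decay model

Each pixel's TCSPC histogram is modelled as a bi-exponential decay

$$F(t) = A\,(\alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2}) + C, \qquad
\alpha_1 + \alpha_2 = 1,$$

with fast lifetime $\tau_1$ (autofluorescence pooled with unreacted probe),
slow lifetime $\tau_2$ (reacted probe), and a constant baseline $C$.

At an 80 MHz repetition rate the inter-pulse period is $T = 12.5$ ns, far
shorter than the reacted lifetimes. The slow component therefore does not
decay away between pulses; the detector sees the steady-state
superposition of tails from all preceding pulses. Summing the pulse train
as a geometric series gives the closed form used throughout the package:

$$F_T(t) = A\left[\frac{\alpha_1 e^{-t/\tau_1}}{1 - e^{-T/\tau_1}}
 + \frac{\alpha_2 e^{-t/\tau_2}}{1 - e^{-T/\tau_2}}\right] + C,
 \qquad t \in [0, T).$$

This is the unique steady state of periodic excitation; the wrap factor
$1/(1-e^{-T/\tau})$ is negligible for nanosecond lifetimes and large for
the reacted probes (for $\tau = 225$ ns it is $\approx 18.5$, i.e. most of
the detected signal is accumulated tail). The test suite verifies the
closed form against explicit summation of $10^4$ pulses to $10^{-10}$
relative error for all the published lifetimes. Expected counts per TCSPC
bin integrate the model analytically over each bin
(`periodic_bin_means()`); one period integrates to
$A(\alpha_1\tau_1 + \alpha_2\tau_2) + C \cdot n_\mathrm{bins}$, which the
tests assert exactly.

The instrument response is treated as ideal (85 fs excitation pulses are
five orders of magnitude below the bin width); no IRF convolution is
performed.

## Poisson maximum-likelihood fitting

TCSPC bin contents are photon counts, so fits maximise the Poisson
likelihood of the bin-integrated model. Numerically the objective is half
the deviance against the saturated model,
$\sum_j [\mu_j - n_j + n_j \log(n_j/\mu_j)]$ — the same minimiser as the
negative log-likelihood, but $O(1)$ rather than $O(N)$ near the optimum,
which keeps the shallow multi-exponential valley resolvable in double
precision.

Free parameters are $(\log A,\ \mathrm{logit}\,\alpha_2,\ \log\tau_1,\
\log\tau_2)$ and optionally $C \ge 0$, with boxes
$\tau_1 \in [0.1, 12.5]$ ns and $\tau_2 \in [0.1, 2000]$ ns (components are
relabelled after the fit so $\tau_1 \le \tau_2$). Initialisation is a
log-linear fit to the histogram tail (slow component) and to the
tail-subtracted head (fast component); the slow photon fraction is
converted to an amplitude fraction using the identity that a wrapped
component integrates to $A\alpha\tau$ per period. Three deterministic
restarts perturb the initial $\tau_2$ and photon split; with good first
fits (reduced $\chi^2$ below a configurable bar) the extra restarts are
skipped in per-pixel mode.

Two implementations share this model: `fit_histogram()` (R, `optim`
L-BFGS-B with analytic gradients, curvature-based standard errors) for ROI
decays, and a compiled Levenberg-Marquardt kernel (Fisher-scoring steps on
the same deviance) that `fit_stack()` uses for per-pixel maps, where a few
hundred microseconds per pixel matter. An agreement test ties the two
paths together on common data.

Numerical and statistical choices worth knowing:

* **Offset.** $C$ absorbs both background light and, in other software
  conventions, the accumulated slow tail. Because the periodic model
  already represents that tail exactly, simulations are generated with
  $C = 0$ and quantitative recovery studies fix it there. With $C$ free
  and $\tau_2 \gg T$ the two are near-degenerate: the tests assert that
  the reported standard error of $\tau_2$ blows up (an order of magnitude
  and rank-increasing) as $\tau_2$ crosses out of the window, rather than
  pretending precision.
* **Component collapse.** When data are effectively mono-exponential, the
  minor component's lifetime is pure noise. A fitted component is kept
  only if its amplitude fraction exceeds `min_alpha` (1%) *and* its photon
  content $A\alpha\tau$ exceeds $3\sqrt{N}$ (i.e. is statistically
  distinguishable from zero); otherwise the histogram is refit
  mono-exponentially and reported with $\tau_1 = \tau_2$. Without this
  rule, unreacted-probe pixels sporadically report phantom slow lifetimes
  at the parameter bound.
* **Identifiability.** Over a 12.5 ns window, distinct
  $(\alpha_2, \tau_2)$ combinations with $\tau_2 \gg T$ produce nearly
  identical curves; at realistic photon counts the likelihood can
  genuinely prefer a neighbouring ridge point. Classification ("is the
  slow lifetime beyond 100 ns?") is robust to this; per-pixel parameter
  values at low counts are not, and the per-cell statistics are designed
  accordingly (photon-weighted means over many pixels).
* **Masking.** Histograms under `min_photons` (default 100) are masked,
  not fitted. Failed or clearly misfit pixels (deviance per dof $\ge 2$
  without convergence) are masked too and excluded from cell statistics.

## Synthetic scenes and what they do (not) represent

`make_scene()` plants non-overlapping discs of 30-70 px diameter (the
segmenter's published retention range) with per-cell intensities drawn
from condition templates: the injury condition plants two GSH-channel
subpopulations (means 400 and 800 photons/px, SD 60, equal weights), both
dimmer than control (1200); treated plants a single brighter population
(1000); the ROS channel rises with injury (900) and falls with treatment
(300). A planted fraction of cells is probe-negative: they carry unreacted
probe (plus 2.5 ns autofluorescence, the midpoint of the 2-3 ns tissue
range) and FAD-level brightness (280 photons/px). The false-positive
phenomenon is reproducible on demand (`bright_negative_frac`): cells as
bright as positives but with short lifetimes.

`render_flim()` draws independent Poisson counts per bin with means equal
to the planted intensity times the normalised bin-integrated decay of each
cell's true parameters. The tests verify photon conservation against the
intensity image, determinism under fixed seeds, and $\chi^2/\mathrm{dof}
\approx 1$ of simulated histograms against the analytic curve.

Deliberately not modelled: optical point-spread blur, depth-dependent
scattering, respiratory motion, photobleaching (the probes show none over
2 h), and spectral bleed-through beyond a lumped fast background. Passing
tests therefore certify the analysis chain, not robustness to those
acquisition artifacts.

Default problem sizes are desk-scale by design and stated where used: the
end-to-end suite runs 10 injury/treated scene pairs with 24 GSH-channel
cells on 288^2 px and 10 ROS-channel cells on 192^2 px at 64 time bins;
ROI recovery studies use 100 replicates of 10^7 photons at 256 bins. The
generator accepts larger values unchanged.

## Segmentation

`segment_cells()` reproduces the published recipe: Gaussian smoothing
($\sigma = 2$ px), a global Otsu threshold, hole filling, connected
components, then retention of objects with equivalent circular diameter
$2\sqrt{A/\pi}$ in 30-70 px and circularity $4\pi A/P^2 \ge 0.6$.
Definitions the source recipe leaves open, fixed here and logged in the
provenance block: "diameter" means equivalent circular diameter;
"round" means circularity at least 0.6; touching cells are not split (no
watershed); border-touching objects are dropped. Thresholding is applied
to the $\log(1+x)$ image by default — with a dark-background-dominated
histogram a linear Otsu threshold lands above dim probe-negative cells,
which would bias the positive-cell percentage upward by excluding exactly
the negatives. Otsu itself is the textbook 256-bin between-class-variance
maximiser and is tested against exhaustive search.

## Per-cell positivity

Cells are called probe-positive when their photon-weighted mean slow
lifetime exceeds 100 ns, the observed signature of reacted probe within
cells ("characteristic" slow lifetimes beyond 100 ns; reacted states at
90.5-225 ns vs everything else below ~6 ns). The aggregation rule (mean vs
median, the pixel weighting, and the 50% minimum-unmasked-fraction rule
for classifiable cells) is not specified by the source recipe; the
photon-weighted mean is the default, a median alternative is a parameter.
The monotonicity of the positive percentage in the threshold, and exact
agreement with planted labels under noiseless lifetime maps, are tested
properties.

## Subpopulation modelling

Per-cell intensities of positive cells are fit with 1- and 2-component
Gaussian mixtures; the component count with the lower
$\mathrm{AIC}_k = 2(3k-1) - 2\,\widehat{\ell\ell}_k$ wins, ties to the
simpler model. $k=1$ is the closed-form normal MLE; $k=2$ runs EM from a
median-split initialisation plus five seeded random restarts, with an SD
floor of $10^{-3}$ of the data range and rejection of degenerate restarts
(a floored SD or a component carrying under two points). The likelihood is
computed on the raw per-cell values rather than on binned histogram
counts: the histogram is a display device, and maximum likelihood on the
underlying values is the better-defined estimator (the binned
least-squares alternative was evaluated and is markedly less stable for
model selection).

A known limitation, measured rather than hidden: for the *null* case
(truly unimodal data) AIC overselects $k=2$ in roughly 6-12% of samples at
$n = 500{-}1000$ — the $k=1$ vs $k=2$ comparison is boundary-nonregular
and $2\Delta\ell\ell$ has a heavier tail than $\chi^2_3$, so a 2-unit-
per-parameter penalty is not a 5% test. The power side is clean: at
$6\sigma$ separation, $k=2$ is selected essentially always, and planted
injury-template scenes select $k=2$ reliably end to end. Consumers who
need a calibrated null should raise the penalty (BIC-style) or bootstrap;
the AIC rule is retained because it is the method under study.

## OSI and group comparisons

The optical OSI is the ratio of the mean per-cell ROS-probe intensity to
the mean per-cell GSH-probe intensity, computed over lifetime-verified
positive cells (so intensity-only false positives cannot contaminate it).
The two probes cannot be co-injected; ROS and GSH records come from
parallel scenes of the same condition, paired by seed. Group comparisons
use the classic equal-variance two-sample t test (Welch by flag) with
Bonferroni correction, $p_\mathrm{adj} = \min(1, m \cdot p)$, $m$ the
number of pairs tested (configurable, since the number of comparisons per
figure panel is an analysis choice). Type-I calibration of the pipeline's
test at $\alpha = 0.05$ is asserted at 3-7% over 1000 null simulations.

## Dose-response convention

The probes respond linearly up to a stated concentration (10 uM for GSH)
and maximally at a saturating one (20 uM). `reacted_fraction()` uses the
single proportional segment $f(c) = \min(c/c_\mathrm{sat}, 1)$: it
satisfies every stated property (zero at zero, exactly 1 at saturation,
linearity on the linear range, a 5 uM/10 uM response ratio of exactly 1/2)
with one fewer arbitrary constant than a two-slope rule. The saturating
concentrations for P-HP and P-HA are not printed; the package sets them to
twice the linear limit, mirroring the GSH probe's 10-to-20 pattern, and
records that as a convention in `extdata/probes.json`.

## Reproducibility

Every stochastic stage takes an explicit integer seed and is bit-stable
under it; the pipeline derives all stage seeds from the single config
seed, and `run_pipeline()` writes a manifest with MD5 checksums that is
identical across repeated runs of the same config. The scene generator,
renderer, fitters, and mixture models have no hidden global state beyond
R's RNG, which is always set explicitly.
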