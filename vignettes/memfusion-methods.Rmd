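---
title: "Entropic EEG-MEG fusion source imaging: models, priors and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropic EEG-MEG fusion source imaging: models, priors and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(memfusion)
```

## The problem

Interictal epileptic discharges (spikes) recorded simultaneously on EEG
and MEG are generated by spatially extended cortical patches. Localizing
a *single*, non-averaged spike is an ill-posed inverse problem at low
signal-to-noise ratio: the data are a `q x tau` sensor matrix
`M = G J + E`, where `G` is the lead field of `p` dipoles fixed on the
cortical surface with orientations normal to it, and `J` the unknown
current density. This package implements a symmetric fusion of the two
modalities inside the Maximum Entropy on the Mean (MEM) framework,
together with the standard linear references (MNE, dSPM, sLORETA), a
spike/background simulator on synthetic spherical-head geometry, and the
validation metrics used to score localization accuracy.

## The MEM model

The prior ("reference") distribution factorizes over `K << p` connected
cortical parcels. Parcel `k` is active with probability `alpha_k`; when
active its currents are Gaussian `N(mu_k, Sigma_k)`, when inactive they
are exactly zero (a Dirac mass):

```
dnu(j) = prod_k [ (1 - alpha_k) delta(j_k) + alpha_k N(mu_k, Sigma_k) ]
```

The MEM estimate selects, among all distributions reproducing the data
on average (`M = G E[J]`), the one closest to `dnu` in relative entropy,
and reports its mean. By convex duality this reduces to maximizing, per
time sample, the concave dual

```
D(lambda) = lambda' m - 1/2 lambda' Sigma_d lambda
            - sum_k log[(1 - alpha_k) + alpha_k exp(h_k)]
h_k = mu_k' xi_k + 1/2 xi_k' Sigma_k xi_k,   xi_k = G_k' lambda
```

over `lambda` in the q-dimensional sensor space (`Sigma_d` is the
diagonal noise covariance estimated channel by channel from the
baseline; no pre-whitening is applied inside MEM). At the optimum the
primal estimate is `J_k = omega_k (mu_k + Sigma_k xi_k)` with
`omega_k = sigmoid(h_k + logit(alpha_k))`, the posterior probability
that parcel `k` is active: parcels unsupported by the data are shut
down. The solver is a BFGS quasi-Newton iteration from `lambda = 0`
with analytic gradients, log-sum-exp overflow guards, restarts, and a
gradient tolerance of `1e-8 ||m||`; convergence is flagged per sample.
Because `mu_k = 0`, `h_k >= 0` always, so `omega_k >= alpha_k`:
suppression of a parcel can only come from a small `alpha_k`. This
makes the quality of the pre-localization (below) the decisive
ingredient.

In the coherent variant implemented here (cMEM), `Sigma_k` carries a
within-parcel smoothness prior: `Sigma_k = eta (W_k W_k' + 1e-4 I)`
where `W_k` is the square of the lazy random-walk operator
`(I/2 + P/2)` on the parcel subgraph, normalized to unit mean prior
variance. `eta` is a single global scale set from the data at the
highest-power sample of the analysis window so that the prior
predictive source contribution equals a `fraction` (default 0.1) of the
above-noise sensor power. Early experiments allocating the *full*
above-noise power (`fraction = 1`) inflated the prior variance of
parcels far from the generator — part of the above-noise power at a
spike peak is spatially correlated background that a diagonal noise
model cannot absorb — roughly doubling the spatial dispersion of the
estimates while leaving detection (AUC) unchanged; reference MEM
implementations similarly anchor the active variance well below the
data power, at a small fraction of the minimum-norm amplitude scale.
`Sigma_k` is scaled once per analysis window, not per sample.

## Three-level fusion

1. **Normalization and concatenation.** Each modality's data *and* lead
   field are divided by the mean baseline standard deviation over its
   channels (`sigma_bar`), making EEG (volts) and MEG (tesla)
   dimensionless and comparable while preserving `M = G J`; the scaled
   blocks are stacked EEG-above-MEG. A channel-wise variant is
   available (`channelwise = TRUE`).
2. **Fused pre-localization.** MSP scores — the squared projection of
   each unit-norm gain column onto the subspace of the `l` leading left
   singular vectors of the scaled data — are computed per modality and
   combined with a probabilistic OR (`a + b - ab`), so a dipole
   contributing to either modality is retained. The fused map drives a
   data-driven parcellation (DDP): seeds are local maxima of the score
   map within their order-`scale` neighbourhood, parcels grow
   breadth-first to the scale order, and the procedure repeats on the
   unassigned remainder until the surface is tiled (ties always break
   to the lowest vertex index, making the parcellation deterministic).
3. **Activation probabilities.** `alpha_k` is initialized as the median
   fused MSP score within parcel `k`, clipped to `[1e-3, 1 - 1e-3]` so
   no parcel starts exactly shut or exactly Gaussian.

Two numerical choices deserve comment.

*Component rule.* With a short noisy window, an energy criterion
("smallest `l` capturing 95% of the data energy") retains mostly
background components and flattens the MSP contrast to near zero — at
realistic single-spike SNR the leading singular vectors of the data are
not all spike-related. The study pipeline therefore selects the
components whose singular values exceed the largest singular value of
an equal-length baseline segment (at least one component is always
kept); the energy rule remains available through `msp_scores(energy=)`.
MSP also uses a wider window than the solver (default 15 samples on
each side of the peak versus 1) so that the whole main deflection
informs the subspace.

*Parcel tiling.* Growing parcels only from the global local maxima and
attaching the leftover surface to the nearest parcel produces a few
giant parcels (K of order 10 on a 2562-vertex mesh). Iterated
re-seeding on the remainder yields the intended tiling with parcel
areas set by the scale order, and reproduces the expected parcel count
(roughly `p / |order-4 ring|`; about 200 parcels of 2.5 cm^2 on an
8000-vertex 4-mm mesh).

## Linear references

MNE solves the Tikhonov problem on whitened data,
`J = G_w'(G_w G_w' + lambda I)^-1 M_w`; dSPM divides each row of the
MNE operator by its noise standard deviation; sLORETA standardizes by
the estimated source variance `sqrt(diag(W G_w))`, which gives exact
zero localization error for noiseless single dipoles (verified
exhaustively in the tests). The regularization parameter comes from the
L-curve corner — maximum curvature of the log-log (residual, solution
norm) curve over 60 grid points spanning `[1e-6, 1e3]` times the
trace-normalized gain scale, with three-point finite-difference
curvature. On spherical gains the effective rank decays so fast that
the curve can lack a vertical branch, leaving the raw curvature maximum
at the under-regularized end where the solution fits noise; since the
whitened noise floor is known (`E||E_w||^2 = q tau`), corner candidates
whose residual falls below half that floor are excluded. For the fusion
arm the order is: SNR transformation, whitening, concatenation, one
shared lambda.

## The simulation framework

*Anatomy.* The cortex is an icosphere (default 2562 vertices) whose
radius is modulated by a band-limited random field of plane waves
(default: 12 waves, angular frequency 6, amplitude 9 mm on a mean
radius of 80 mm), producing lobe-scale folds with deep troughs inside a
three-shell spherical head (90/95/102 mm, conductivities
0.33:0.0165:0.33 S/m, Rbs = 20). Dipoles sit at the vertices, oriented
along outward vertex normals. The folding seed is fixed by default
(`anatomy_seed`): the anatomy plays the role of the single subject on
which the whole study is run, exactly as a real evaluation uses one
patient's mesh for every simulation, while sources, noise and sampling
derive from the master seed. The default anatomy was chosen, before
freezing the validation thresholds, so that its simulation diagnostics
sit in realistic ranges — achieved SNR roughly 1.5-9, MEG cancellation
indices up to about 0.8, patch eccentricities 73-84 mm — and so that
both radially dominated (EEG-favoured) and tangentially dominated
(MEG-favoured) patches occur.

*Sensors.* 54 EEG electrodes quasi-uniformly cover the scalp cap; 272
point magnetometers with radial orientation sit on a 120-mm helmet
covering the whole head. Reduced 32- and 20-electrode montages are
deterministic farthest-point subsamples. For a montage, the lead field
and data rows are subset and re-referenced (average reference) jointly.

*Spikes.* The source time course is a sum of three Gamma-density
components (sharp ~50 ms spike, undershoot, slow wave) normalized to
unit peak; each dipole of a patch carries `amplitude * w(t)` with the
reference amplitude 9.5 nA.m. Patches grow by neighbourhood order
(`s_e = 3` by default, about 10 cm^2 at the default mesh resolution —
the coarser synthetic mesh makes an order-3 patch larger than on a
4-mm clinical mesh).

*Background.* Two generators are provided. `generate_background()`
produces 1/f-plus-alpha coloured noise, optionally spatially correlated
through a Gaussian kernel over the sensor positions, plus a white
sensor-noise floor. The study default, `brain_noise_generator()`, is
more faithful: diffuse random cortical sources (250 latent patches with
the same coloured spectra) are projected through each modality's own
lead field and topped with 40% white sensor noise; because the latent
sources derive from the seed alone, simultaneously "recorded" EEG and
MEG share the same background brain activity. Noise amplitude is scaled
once per study so that a reference configuration — the most superficial
seed with a ~6 cm^2 patch — reaches the target signal-to-background
ratio (1, i.e. 0 dB, for static studies; 3 for propagation studies),
after which the achieved SNR varies with source location exactly as in
a fixed-scaling protocol. Source seeds are drawn from the part of the
surface above `z = -0.25 r`: the bottom cap of a closed synthetic
surface has no anatomical counterpart and no sensor coverage.

*Model error.* `perturb_rbs()` draws the brain-to-skull conductivity
ratio from a truncated normal (mean 20, sd 3.3, support [15, 25]) and
`run_rbs_experiment()` pairs localizations of data simulated at the
perturbed ratio (but localized at the reference ratio) with matched
simulations.

## Validation metrics

* **AUC** — detection accuracy of the absolute current map at the spike
  peak against the true patch, by tie-corrected pairwise comparison
  (equivalent to trapezoidal ROC integration). The inactive set is
  balanced: negatives are drawn half from the patch surround (within 10
  graph rings) and half from the remaining cortex, averaged over both
  samplings and over 10 seeded draws; for two-source simulations the
  other source's vertices are excluded. The exact negative counts and
  repetition numbers are exposed as arguments rather than fixed.
* **Spatial dispersion (SD)** — energy-weighted RMS of the squared
  minimum Euclidean distance to the patch, in mm.
* **Shape error (SE)** — RMS difference of the peak-normalized
  patch-mean absolute time courses of truth and estimate. Normalization
  uses absolute currents; any global scaling of either argument cancels.

## What the synthetic study does and does not show

`run_study()` reproduces a desk-scale version of the static and
propagating evaluation: by default 30 simulations on the 2562-vertex
anatomy, localized by cMEM/MNE/dSPM/sLORETA on EEG, MEG and fused
MEEG over a 3-sample window at the spike peak (MSP sees 31 samples).
Under these conditions cMEM on fused data attains median AUC well above
the 0.8 good-detection threshold, keeps it with only 20 EEG electrodes
in the fusion, fused arms dominate the monomodal medians for every
method, and cMEM shows the lowest spatial dispersion.

Two caveats matter when carrying these numbers to real data. First, a
spherical surrogate cannot reproduce the lead-field diversity of a
convoluted cortex: on this geometry any unit gain column keeps a
projection of about 0.1 on any plausible topography (against roughly
0.01 on a 4-mm anatomical mesh), so `alpha` never becomes small far
from the source and every method — including cMEM, whose suppression is
bounded by `alpha` — retains a diffuse energy floor. Median spatial
dispersion therefore sits near 60 mm here for all methods, an order of
magnitude above what the same pipeline achieves on anatomical meshes;
the *ordering* of methods is preserved and is what the synthetic study
can meaningfully test. Second, all simulated sources are cortical
patches of uniform amplitude with a single time course; real generators
have graded amplitudes, mixed orientations and propagating fronts, so
absolute AUC levels here are optimistic.

## Reproducibility and problem sizes

Every random element — anatomy (fixed separately), source seeds, noise,
AUC negative sampling, optimizer start — derives from integer seeds, so
a study is bit-reproducible from its configuration. Default problem
sizes (2562 vertices, 326 fused channels, 30-45 simulations, 3-sample
solve windows) were chosen so a full multi-method study completes in a
few minutes on one core; all of them scale up through
`study_config()`.
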