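---
title: "Magnetocardiographic source imaging: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetocardiographic source imaging: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomag)
```

## The problem

Magnetocardiography (MCG) records the heart's magnetic field with a planar
sensor array above the thorax. Imaging the underlying electrical activity —
epicardial potentials $s_q(t)$ at $Q$ nodes of a discretised heart surface —
from $M$ sensor readings $B(t)$ is a linear but severely ill-posed inverse
problem,

$$ B(t) = L\, s(t) + n(t), \qquad M \ll Q, $$

where the lead field $L$ encodes the geometry through the (primary-current)
Biot–Savart kernel

$$ B(r_M) = \frac{\mu_0}{4\pi}\; p \times
   \frac{r_M - r_q}{\lVert r_M - r_q \rVert^{3}} . $$

`cardiomag` builds the whole chain on synthetic geometry: beat simulation
with localised infarct abnormalities, forward modelling with either fixed
radial dipole orientations or time-varying orientations taken from the
vectorcardiogram (VCG), six inverse solvers, and the three evaluation
statistics (epicardial RMSE, orientation angle of deviation, region of
spread).

## The synthetic beat and the three disease cases

`build_epicardial_sources()` emulates the kind of output an epicardial
simulator produces, without claiming physiological fidelity beyond its
printed calibration targets:

* each node carries a piecewise-smooth transmembrane-potential (TMP)
  template (smoothstep upstroke, flat plateau, raised-cosine
  repolarisation), delayed by Euclidean distance from the activation origin
  divided by a conduction speed (default 0.8 mm/ms);
* the epicardial potential of a node is its TMP minus the spatial mean TMP —
  a standard surface-source construction that yields QRS-like deflections
  from depolarisation dispersion and T-like deflections from repolarisation
  dispersion;
* one global scale calibrates the reference node (the vertex nearest the
  detector plane) to a peak-to-peak amplitude of 8 mV.

Template defaults (upstroke 12 ms, plateau 100 ms, repolarisation 70 ms,
beat of 300 samples at 1 ms, 10 ms onset delay) were chosen once so that the
template plus the largest conduction delay of the default geometry fits
inside the beat; the beat length, sampling and conduction speed are the
study conditions.

Fiducial instants are taken from template landmarks, not detected: Q at
activation onset of the reference node, R at its upstroke completion, S at
global depolarisation end, T at mid-repolarisation, and ST midway between S
and T.

The three infarction variants are injected into a region of 2.5 cm
(Euclidean) radius around the reference node and calibrated exactly to their
printed amplitude characteristics at the region centre:

* **D1 (increased R)** — the TMP ascent is slowed (upstroke doubled), the
  node waveforms are recomputed against the *unchanged* spatial mean, and an
  affine map pins the centre-node range to $[-10, 19]$ mV;
* **D2 (ST elevation)** — the TMP magnitude is lowered to 40% with unchanged
  duration at the TMP level; at the epicardial level a raised-cosine bump
  adds exactly +5 mV at the ST fiducial and exactly 0 at the R fiducial;
* **D3 (increased T)** — the TMP active duration is shortened; the
  epicardial waveform gains +6 mV at the T fiducial, zero at ST and earlier.

Because only amplitude and timing characteristics of the abnormal
epicardials are published, the injection is calibrated to those numbers
rather than derived from a propagation model; outside the region the
waveforms are bit-identical to the normal case, which the locality tests
assert.

What the generator does *not* emulate: anisotropic conduction, transmural
gradients, torso inhomogeneity, pathological conduction block. Tests passing
on this generator therefore demonstrate the correctness and the relative
behaviour of the solvers under controlled conditions, not clinical
performance.

## ECG, VCG and orientation priors

The body-surface ECG at eight sites (V1–V6 plus lead I/II derivation
points, placed at fixed fractional coordinates on an elliptic-cylinder
torso) is computed with the analytic infinite-homogeneous-medium
current-dipole potential kernel; the conductor in the forward model is
homogeneous, so no finite-element solve is needed at this level of realism.
The 3-lead VCG is the inverse Dower transform of those eight leads
(`dower_inverse_matrix()`, the published least-squares inverse of the Dower
lead matrix; any 3×8 matrix can be substituted). Per-instant unit VCG
vectors orient the dipoles of the VCG-constrained lead field; instants whose
VCG magnitude falls below 1e-6 mV carry the last valid orientation forward
(+z before any valid instant) and are masked.

One global VCG loop orients all nodes: the VCG is a whole-heart summary
signal, so a per-node orientation is not identifiable from it.

## Forward model

`forward_kernel()` precomputes, for every sensor–source pair, the 3-vector
that maps a dipole moment to the sensed field value; every lead field in the
package is a contraction of this kernel with an orientation. The default
sensing mode is the field component normal to the detector plane (what a
planar MCG array measures); a full-vector mode exists for testing. The
radial orientation $\hat a_q$ is taken from the heart-mesh centroid — under
a translated mesh the global-origin convention would make $\hat a_q$
arbitrary.

One geometric fact shapes several design choices downstream: **the
normal-component planar array is exactly blind to the moment component along
the plane normal** ($\hat n \cdot (p \times u)$ does not depend on
$p \cdot \hat n$). A dipole pointing straight at the array produces no
signal in it.

Units: interface lengths in mm (region radius and spread in cm), internal
computation in SI metres; sources in mV with a unit dipole strength per mV,
so lead-field entries are of order $10^{-5}$ and the synthesized fields are
consistent but not calibrated to physical picotesla.

## The six solvers

With per-instant observation vectors, all solvers operate one time instant
at a time (no spatiotemporal coupling):

1. **Tikhonov (L2)** — $s = (L^TL + \lambda I)^{-1}L^Tb$, dual form for
   $M < Q$.
2. **Deterministic TV (L1)** — IRLS on
   $\tfrac12\lVert b - Ls\rVert^2 + \lambda\sum_e\sqrt{(Ds)_e^2+\varepsilon}$
   with $D$ the edge-difference operator scaled by inverse edge length (cm);
   majorize–minimize guarantees a non-increasing objective.
3. **Gaussian Bayes with evidence approximation** — MAP estimate
   $s_{MP} = (L^TL + (\alpha/\beta)I)^{-1}L^Tb$ with
   $\alpha = \gamma / 2E_s$, $\beta = (M-\gamma)/2E_B$,
   $\gamma = \sum_i \lambda_i/(\lambda_i+\alpha)$ over the eigenvalues of
   $\beta L^TL$ (computed from the $M\times M$ dual Gram matrix — the
   nonzero spectra coincide and zero eigenvalues contribute nothing).
4. **Hierarchical variational-Bayes TV** — auxiliary variables $v_e$ bound
   the TV prior; coordinate ascent on the point-estimate objective
   alternates the posterior mean
   $(\hat\beta L^TL + \hat\alpha D^TW(v)D)^{-1}\hat\beta L^Tb$ with
   $W(v)=\mathrm{diag}(v^{-1/2})$, the auxiliary update $v_e = (Ds)_e^2$
   (floored at 1e-8), and Gamma-hyperprior updates of $\hat\alpha$,
   $\hat\beta$. Each step maximizes one block, so the recorded bound is
   non-decreasing by construction.
5. **VCG-prior Gaussian** and 6. **VCG-prior TV** — per instant, alternate
   (i) building the lead field from the current shared orientation,
   (ii) the inner solver (3 or 4), and (iii) a ridge-regularized
   orientation estimate, renormalised to unit length.

### Design choices that were genuinely open

**Orientation update.** The Gaussian orientation prior is centred on the
unit-VCG vector: the update solves
$\min_e \lVert B - G(\hat s)e\rVert^2 + \alpha_{VCG}\lVert e - e_{VCG}\rVert^2$.
A zero-centred ridge is the more obvious reading of a Gaussian prior on
$e$, but the planar-array blindness above makes the component of $e$ along
the array normal unobservable; a zero-centred ridge simply deletes it and
the orientation error saturates near 70° for typical VCG loops. Centring on
the VCG is what makes the VCG a *prior* in the literal sense: the data
correct the observable components, the prior supplies the unobservable one.
$\alpha_{VCG}$ is expressed relative to the mean diagonal of the (scaled)
normal-equation matrix so its meaning is independent of lead-field units;
default 0.01. The orientation sign is fixed to the hemisphere of the prior
(the sign is absorbed by the source amplitudes).

**VB-TV hyperprior.** The hyperparameter updates are not uniquely
determined by the model statement. With a completely flat hyperprior the
point-estimate coordinate ascent has a degenerate attractor on strongly
underdetermined problems ($M=81$ observations against $E\approx1500$
gradient terms): $TV(s)\to 0$, $\alpha\to\infty$, and the solution collapses
to a spatially constant field. Neither a better starting point nor the
covariance-trace variant of the $v$-update prevents this — the flat
hierarchy genuinely prefers the degenerate point. The default hyperprior is
therefore an empirical-Bayes anchor: $a_{\alpha 0}=E/2$,
$b_{\alpha 0}=(E/2)/\alpha_0$, where $\alpha_0$ matches the TV strength of a
GCV-selected ridge pilot; $\alpha$ can still adapt by roughly a factor of
two in each direction, but cannot run away. The hyperprior on $\beta$ stays
flat. A flat hyperprior on both can be requested explicitly.

**Initialisation.** Both Bayesian solvers seed their hyperparameters from a
generalized-cross-validation ridge pilot (25-point grid on the dual
eigendecomposition). This is scale-free and noise-adaptive; fixed numeric
initial values are meaningless across lead-field magnitudes. Explicitly
supplied `init_alpha`/`init_beta` (including the frozen mode `max_iter = 0`
that reproduces Tikhonov with $\lambda=\alpha/\beta$ exactly) bypass the
pilot.

**Numerical safeguards.** $\beta$ is capped at the precision corresponding
to a $10^{-12}$ relative residual (beyond which the misfit term is rounding
noise); the MAP solve floors its effective $\lambda$ at $10^{-12}$ of the
mean diagonal of $L^TL$; the VB system matrix carries a $10^{-12}$ relative
ridge. The auxiliary floor (`v_floor = 1e-8`), the IRLS smoothing
($\varepsilon=10^{-8}$), and the convergence tolerances ($10^{-6}$ relative
change, 200 inner / 50 outer iterations) are the package defaults. The
$v$-update is per-edge; a covariance-trace term is available behind
`use_cov_trace` but off by default. Degenerate instants (zero observations,
or an orientation the array cannot see) keep the prior orientation and a
zero source estimate, and are flagged.

## Metrics

* `mse_epicardial()` — RMSE over nodes and instants; the root is taken so
  the statistic carries mV units.
* `angle_of_deviation()` — $\arccos$ of the normalised inner product,
  degrees.
* `detect_abnormal_region()` — nodes whose deviation energy from a normal
  reference reconstruction exceeds half the maximum (threshold
  configurable).
* `region_of_spread()` — RMS distance from the abnormality centre to the
  mesh-adjacency border of the detected set, in cm. The mean-of-squares
  variant (cm²) sits behind `squared = TRUE`; the RMS reading is the default
  because the spread is reported in cm and compared against a radius in cm.

## The benchmark protocol

`run_benchmark()` sweeps case × SNR × replicate: generate sources,
synthesize MCG through the VCG-constrained dynamic lead field, add white
Gaussian noise at the configured SNR (defined on total power over all
channels and samples), reconstruct with all six solvers, and score RMSE,
fiducial-instant angles (VCG solvers) and ROS. The abnormal region is
detected against the reconstruction of the normal beat by the same solver
under an independent noise realization — two separate recordings, as a real
comparison would have — and the detected set is restricted to its connected
component around the target node before the spread is computed (the spread
statistic concerns the abnormal points surrounding the targeted node;
disconnected single-node detections are distant outliers of the detector,
not part of the reconstructed region). Deterministic solvers pick $\lambda$
by a discrepancy-principle grid scan (the SNR is part of the protocol, so
the noise power is known); Bayesian solvers set their own hyperparameters.

Problem sizes were chosen for a desktop-class run: reconstruction at the
five fiducial instants of the beat (the instants that enter the reported
statistics), $Q \approx 500$ nodes, a 9×9 detector grid at 30 mm spacing
60 mm above the heart centre, and iteration caps of 50 (evidence), 30
(VB-TV), 15 (IRLS) and 4 orientation updates. Per-cell seeds are derived
from the base seed, the case, the SNR and the replicate index, so any cell
is reproducible in isolation.

## Known limitations

* The volume-current contribution to the magnetic field is omitted — the
  forward kernel is the primary-current Biot–Savart term only, matching the
  model the solvers assume. A hook for a volume-current term would live in
  `forward_kernel()`.
* Euclidean (not geodesic) distances define the infarct region and ROS.
* Per-instant inversion ignores temporal smoothness; no spatiotemporal
  coupling or MCMC-based posterior exploration.
* The static-lead-field solvers operate under deliberate model mismatch
  (radial orientations against VCG-generated data); their absolute RMSE is
  dominated by that mismatch, which is the point of the comparison, but it
  means their reconstructions should be read as deviation maps rather than
  potential maps.
* Amplitude calibration of the simulated ECG and MCG is arbitrary up to the
  per-mV dipole strength; orientation-related results are invariant to it.
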