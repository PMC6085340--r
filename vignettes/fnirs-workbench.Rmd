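---
title: "Methods: photon-transport calibration and event-related analysis for skull-mounted fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photon-transport calibration and event-related analysis for skull-mounted fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nirsim)
```

# The measurement problem

Continuous-wave functional near-infrared spectroscopy (fNIRS) infers
cortical hemodynamics from changes in light attenuation between pairs of
surface optodes at several wavelengths. For a small primate head the
standard human probe geometry fails twice over: the superficial layers are
thin, so the optimal source-detector distance is shorter, and motor
representations (face, hand, arm) sit only millimeters apart, so channel
spacing must be dense. This package implements the computational system
behind such a measurement: a diffusion-approximation photon-transport
simulator that calibrates a dense triangular optode array placed directly
on the skull, the signal chain that turns multi-wavelength absorbance into
oxy-/deoxyhemoglobin concentration changes (dHbO, dHbR), and the
event-related statistics that localize hand and mouth primary motor cortex
(M1), premotor (PMA) and supplementary motor (SMA) areas from
left/right-hand contrasts.

# Forward model

## Diffusion approximation on a voxel grid

Light propagation is modeled by the continuous-wave diffusion equation

$$-\nabla \cdot (D \nabla \Phi) + \mu_a \Phi = S, \qquad
  D = \frac{1}{3(\mu_a + \mu_s')},$$

over the tissue voxels of a labeled head model (air, soft tissue, skull,
CSF, gray matter, white matter). Air voxels are excluded from the domain
entirely: the diffusion approximation is invalid in a non-scattering
medium, so the tissue-air interface is the boundary. There the Robin
(partial-current) condition $\Phi = 2 A D\, \partial\Phi/\partial n$
applies, with the internal-reflection factor $A \approx 3.25$ derived from
the common polynomial fit in the refractive index ($n = 1.40$ for all
tissue layers).

The discretization is a 7-point finite-volume scheme on the voxel grid:
face conductances are series combinations of the half-voxel diffusivities,
the Robin condition enters as an extra face conductance
$h^2 / (h/(2D) + 2A)$, and the sparse symmetric positive-definite system
is factorized once per model and wavelength (supernodal Cholesky) so that
many sources, detectors and channels reuse one factorization. The solve is
direct and deterministic. An unstructured finite-element mesh would add
geometric fidelity the voxelized models do not possess; the acceptance
surface here is agreement with closed-form solutions, not mesh flexibility.

Sources are isotropic points one transport mean free path ($1/\mu_s'$)
below the surface, spread over the neighboring tissue voxels with
trilinear weights. If that nominal depth falls outside tissue, the deepest
tissue position along the surface normal within $2/\mu_s'$ is used.

## Near-field accuracy: the hybrid (singularity-subtracted) solve

A 7-point stencil cannot represent the $1/r$ singularity of a point
source: the raw discrete Green's function is ~25% high one voxel from the
source and still several percent high at ten voxels. `solve_fluence()`
therefore uses a classical hybrid scheme by default: the analytic
extrapolated-boundary point-source solution for the source-layer optical
properties serves as the primary field, and the discrete operator solves
only for the smooth correction that accounts for domain truncation, the
real boundary shape and tissue heterogeneity away from the source (the
discrete residual of the primary field is zeroed inside a 2.5-voxel ball
around the source, where the primary is already the correct physics). On a
homogeneous slab at 1 mm voxels this brings the fluence within a few
percent of the closed form at all depths from 2 to 15 mm. The cost is one
extra matrix-vector product per solve. The plain discrete solve remains
available (`method = "discrete"`).

Two detector models are exposed by `detected_intensity()`. The
`"partial_current"` estimator returns the Robin boundary flux per unit
area under the detector -- the physical reflectance, comparable in
absolute units to closed-form semi-infinite reflectance formulas. The
`"pairing"` estimator evaluates the fluence at the detector optode's own
injection point; since the array is bidirectional (every optode is both
source and detector), detection is then the exact adjoint of injection and
source-detector exchange is reciprocal to machine precision.

## Sensitivity: PMDF, SSP and partial path lengths

The photon measurement density function of a channel is computed from the
reciprocity principle with purely discrete fields:

$$\mathrm{PMDF}(v) = \frac{h^3\, \Phi_s(v)\, \Phi_d(v)}{I},
 \qquad I = \langle s_d, \Phi_s \rangle,$$

where $\Phi_d$ solves the same system with the source placed at the
detector. With this pairing two identities hold *exactly* in the linear
algebra, not just in the continuum limit: the PMDF and $I$ are invariant
under source-detector exchange, and $\sum_v \mathrm{PMDF}(v) =
-\partial \ln I / \partial \mu_a$ (diffusion coefficient held fixed),
which is the mean optical path length $L_{mean}$ by the adjoint identity.
The spatial sensitivity profile (SSP) is this PMDF on the mm scale: its
sum over all voxels is $L_{mean}$, and the sum over a tissue layer is the
partial optical path length in that layer -- in particular $L_{gray}$, the
gray-matter partial path used for channel calibration. (The alternative
convention, rescaling so the total is 1, conflicts with the layer-sum
property; the package fixes total = $L_{mean}$, which reconciles both
statements.) A regional $L_{gray}$ restricted to a 5.4 mm cube at the
hand-knob landmark quantifies sensitivity to the hand-motor cortex
specifically.

The source-detector distance sweep (`sweep_sd_distance()`) places pairs of
5-25 mm separation symmetrically about the scalp projection of the hand
knob, along two orthogonal surface axes. On the packaged flat layered
phantom, "parallel/orthogonal to the central sulcus" has no meaning, so
the two alignments are simply the x and y surface axes; on the flat slab
they agree to rounding. The sweep reproduces the optimization logic for
the 15 mm design choice: detected intensity falls monotonically with
distance, total $L_{gray}$ keeps rising (sensitivity to *all* gray matter,
i.e. degrading spatial specificity), while the regional $L_{gray}$ at the
hand knob saturates above 15 mm -- longer separations buy no further
sensitivity to the target.

## Head models and default optical properties

`build_layered_phantom()` stacks air / soft tissue / skull / CSF / gray /
white top-down on a flat slab (or a spherical cap with the `curvature`
argument); `macaque_phantom()` is the packaged scalp-incised parietal
configuration (skull 2 mm, CSF 1 mm, gray 2 mm, white fill) with the
hand-knob landmark at the gray midplane. The per-tissue absorption and
reduced-scattering coefficients shipped in
`inst/extdata/tissue_optics.csv` are a documented stand-in compiled from
standard 800 nm-region cranial tissue-optics compilations; no
subject-specific values exist to reproduce. Every solver operation reads
properties only from this table, so substituting a user table changes the
whole chain consistently. The same applies to the hemoglobin extinction
table (`extinction_coefficients.csv`): realistic, documented, replaceable.
The low-scattering CSF layer is kept inside the diffusion domain with a
small reduced-scattering value, a known approximation of layered
head models at these thicknesses.

# The triangular bidirectional array

Optodes sit on a regular triangular lattice with 15 mm edges; each optode
is time-multiplexed as source and detector, one channel lives at each
lattice-edge midpoint, and channels sharing an optode are 7.5 mm apart.
One switching cycle (130 ms) has one slot per optode; while an optode
illuminates, all its lattice neighbors detect, so every channel is
measured twice per cycle (once per direction) and the two measurements are
averaged into one 130 ms sample.

The packaged 15-optode array (27 channels) is a two-row staggered lattice
with exactly 27 edges, shipped as CSV + JSON data files. It reproduces the
published array's *topology* -- optode count, channel count, spacing; the
original coordinates are not tabulated anywhere, so absolute positions and
the channel-number-to-position mapping are conventions of this fixture,
and the published region table (PMA channels 8-13, SMA 17/18, hand M1
16/21/22/26 left and 19/23/24/27 right, mouth M1 1/6/20 left and 5/15/25
right) is applied by channel id.

# Signal chain

The canonical order, implemented by `process_absorbance()`:

1. **Duplicate averaging** -- arithmetic mean of the two directed
   measurements per channel per cycle.
2. **Path-length calibration** -- absorbance divided by the simulated
   partial optical path length per channel and wavelength, giving OD/mm so
   channels with different depth sensitivities are comparable. The
   gray-matter partial path is the default denominator because the
   comparison of interest is cortical; total $L_{mean}$ can be supplied
   instead (which of the two the original instrument used is not
   determinable; both are supported).
3. **Cubic detrend** -- least-squares third-degree polynomial subtracted
   per channel/wavelength over the *whole session*; optode-coupling drift
   is a session-scale phenomenon, not a per-trial one.
4. **Butterworth low-pass** -- fourth order at 0.7 Hz, applied zero-phase
   (forward-backward, with odd-reflection edge padding). Zero-phase
   filtering is a deliberate choice not dictated by the hardware: the
   headline statistics are times-to-peak, and a causal filter would bias
   them by its group delay.
5. **MBLL inversion** -- per time point and channel the overdetermined
   system $\Delta A(\lambda) = \varepsilon_{HbO}(\lambda)\Delta HbO +
   \varepsilon_{HbR}(\lambda)\Delta HbR$ is solved by the pseudo-inverse
   of the 3-wavelength-by-2-species extinction matrix. Internally mM,
   reported in micromolar.

Two identifiability notes. First, an absorbance recording measures changes
on top of an unknown baseline, and the detrend removes the session-scale
cubic component of *everything*, signal included; recovery accuracy is
therefore assessed against the ground truth passed through the same
detrend (and filter) -- `pipeline_reference_truth()` -- because the
removed component is unidentifiable by construction, not an implementation
error. Second, the extinction matrix for realistic HbO/HbR spectra at
780/805/830 nm is ill-conditioned (condition number about 30), so OD noise
is amplified roughly twentyfold in concentration space; this is a physical
property of the wavelength set, and it is what sets the instrument noise
floor the generator assumes (below).

# Event-related statistics

Retrieval events come from a laser-sensor trace: onsets at upward
threshold crossings, ends at downward crossings, durations as the
difference; hands alternate (or are supplied explicitly). Epochs are
time-locked to onset with nearest-sample alignment on the native 130 ms
base (no sub-sample interpolation) over a default window of -2 to +15 s,
wide enough to contain the slow mouth-M1 response near 7 s. Block averages
carry mean, SD and trial count per channel, hand and species.

The left/right-hand contrast uses a paired t-test at every time point,
pairing the k-th left with the k-th right trial in temporal order -- the
task alternates hands, which makes temporal-order pairing the natural
choice; an unpaired Welch alternative is available
(`pairing = "welch"`). P-values are two-sided; with 75 trials per hand,
df = 74. Label swapping negates every t-value exactly. No multiple-testing
correction is applied across time points or channels by default,
matching the raw p < 0.05 gating convention of the instrument literature.

Peak metrics are gated: only where a channel's t-curve reaches p < 0.05 at
some time point are the signed extremum of the block-averaged curve
(largest magnitude; ties break to the earliest sample) and its latency
reported. For hemodynamics-behavior correlations the gated metrics are
averaged over each hemisphere's channels (using the hemisphere's
contralateral-hand trials, where the hand-M1 response lives) per session,
and Pearson-correlated against the session's retrieval time normalized to
the initial session. Behavior statistics normalize retrieval durations
with the Box-Cox transform at lambda = -1 ($1 - 1/x$), check
homoscedasticity with Bartlett's test, compare session-by-hand groups with
one-way ANOVA and correct pairwise contrasts with the Tukey-Kramer method
(unequal group sizes supported via `TukeyHSD`).

One deliberate deviation from a naive reading of "significant amplitude in
the t-curves": across ~130 correlated time points, *any* null channel
crosses p < 0.05 somewhere with high probability, so an "any crossing"
rule cannot distinguish lateralized from non-lateralized channels. The
discriminative laterality check in the acceptance analyses therefore
evaluates the t-curve at the sample nearest the hand-M1 response peak
(2.43 s), where the contrast is maximal; `peak_metrics()` keeps the
any-crossing gate for descriptive reporting.

# The synthetic-session generator

No recordings are deposited anywhere, so the generator *is* the study
condition. Defaults: 150 trials per session, 75 per hand, alternating,
about every 20 s (Gaussian jitter, SD 2 s); log-normal retrieval durations
(median 0.9 s, sdlog 0.25) with a hand-specific factor. The hemodynamic
response is a single-gamma kernel (shape 6) normalized to unit peak; the
region model fixes the HbO peak latencies -- 0.71 s in PMA, 2.43 s in hand
M1, 6.63 s in mouth M1 (SMA, for which no latency is reported anywhere, is
set to 1.5 s as a plausible intermediate) -- and the laterality rules:
hand M1 responds only to contralateral-hand trials, PMA and SMA
bilaterally to every retrieval, mouth M1 to every trial since food always
reaches the mouth. dHbR is a scaled negative copy of dHbO (factor 0.4),
reflecting the tight negative linear HbO-HbR coupling of cortical
functional hemodynamics; a zero-response HbR mode exists for null testing.
Restraint conditions are generator modes: `right_restrained` (left-hand
retrieval only) and `mouth_only` (direct feeding; only mouth M1 responds).

Per-trial amplitudes jitter log-normally (CV 0.2), channels carry a small
fixed gain spread (SD 5%), and session-level mean retrieval duration
modulates amplitudes and peak times (couplings 0.8 and 0.5 per unit of
normalized duration), which produces the positive amplitude-vs-retrieval-time
and latency-vs-retrieval-time correlations expected of effortful sessions.

The forward model inverts the signal chain exactly -- $\Delta A(\lambda) =
(\varepsilon_{HbO}\Delta HbO + \varepsilon_{HbR}\Delta HbR) \cdot
L(\lambda)$ -- then adds a random *cubic* baseline drift per
channel/wavelength (coefficient scale 2e-3 OD, shared by both directed
measurements) and independent Gaussian OD noise per directed measurement,
and emits the duplicate-level samples plus the binary sensor trace. Two
generator properties are deliberate idealizations: the drift is exactly
cubic (so the detrend stage can remove it exactly; real drift is only
approximately polynomial), and the HbR coupling is exact up to noise.
Passing tests therefore demonstrate correctness of the chain under the
model's own assumptions, not robustness to motion artifacts, scalp
hemodynamics or model mismatch -- all explicitly out of scope.

No reference noise magnitude exists. The default instrument noise
(5e-6 OD per directed measurement) is pinned by the fidelity condition the
package tests itself against -- per-channel recovery correlation above
0.95 through the full chain -- given the twentyfold noise amplification of
the extinction inversion noted above; drift, not instrument noise,
dominates the raw traces, and trial-to-trial variability comes mostly from
the 20% amplitude jitter. All stochastic calls take explicit seeds and all
outputs are reproducible from (config, seed).

# Numerical choices and problem sizes

* Linear solver: sparse supernodal Cholesky, one factorization per
  (model, wavelength); no iterative tolerance, no randomness.
* Hybrid-solve residual cutoff: 2.5 voxels around the source.
* Finite-difference oracle step for the adjoint identity: 1e-5 /mm.
* Epoch alignment: nearest sample; extremum ties: earliest.
* Degenerate inputs: constant series yield flagged `NA` correlations;
  channels without a region model get zero synthetic response (logged);
  empty event logs yield empty (not failing) results.
* Problem sizes used in the shipped analyses: oracle slab 60 x 60 x 40
  voxels at 1 mm; layered phantom 70 x 70 x 30 at 1 mm (126 voxels wide
  when hosting the full array); sessions of 150 trials (~50 min at 130 ms
  sampling, ~3.7 million duplicate-level samples); 100 seeded sessions for
  the statistical-recovery analyses. These sizes keep every analysis on a
  single CPU core in minutes while leaving the mesh-refinement and
  convergence checks meaningful.

# Known limitations

* The diffusion approximation misrepresents thin clear CSF; the packaged
  phantom uses a weakly scattering CSF layer, standard but approximate.
* The hybrid solve assumes locally homogeneous properties within ~2.5
  voxels of the source; heterogeneity closer than that is absorbed into
  the correction field only approximately.
* The packaged array reproduces topology, not stereotaxic geometry; any
  anatomical interpretation of its coordinates is conventional.
* Motion artifacts, scalp-blood-flow contamination and their removal
  methods are out of scope; the generator does not simulate them.
* Tissue optics and extinction tables are literature-compiled stand-ins,
  clearly labeled, and should be replaced for quantitative use on real
  instruments.
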