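---
title: "Modeling the growth-cone molecular clutch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the growth-cone molecular clutch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcclutch)
```

# The model

Growth cones advance when the rearward-flowing actin network in their
periphery grips the substrate through transmembrane adhesion receptors.
This "molecular clutch" converts actin polymerization at the leading edge
into protrusion: strong coupling slows the retrograde flow and speeds the
growth cone, weak coupling lets the flow slip backward unproductively.
`gcclutch` implements a minimal stochastic version of that picture,
together with the single-molecule analysis chain used to observe it.

## The stochastic clutch simulator

A molecule lives inside a flat conical growth cone (apex at the origin,
leading edge at radius `cone_radius`, half angle `cone_half_angle`) and is
always in one of three states:

* **FREE** — a cytosolic monomer performing 2D Brownian motion with
  diffusivity `D_free`. Each step adds $(2D\Delta t)^{1/2} n_{1,2}$ to the
  coordinates, with $n_i$ standard normal draws.
* **FLOW** — incorporated in a filament carried by the retrograde flow:
  the radial coordinate decreases by $V\,\Delta t$ per step, with slow
  lateral noise of diffusivity `D_flow_lateral` superimposed.
* **BOUND** — a flowing molecule whose filament is attached to a
  substrate-immobilized adhesion; it wobbles with the much smaller
  diffusivity `D_bound` and does not advect.

Transitions are Bernoulli events per time step: FREE molecules within
`edge_band` of the leading edge polymerize into FLOW with probability
$k_{poly}\Delta t$; FLOW molecules bind an adhesion with probability
$k_c\Delta t$ and depolymerize back to FREE with probability
$k_d\Delta t$; BOUND molecules release with probability $k_u\Delta t$;
FLOW molecules reaching the basal region (radius below `base_band`) are
forced to disassemble. FREE molecules never bind adhesions directly, and
BOUND can only be entered from and left to FLOW. The ratio $k_c/k_u$ is
the *coupling strength* of the clutch.

### Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `cone_radius` | 12 | µm | measured growth-cone size |
| `cone_half_angle` | 45 | degrees | flat conical geometry |
| `dt` | 0.05 | s | typical camera frame time |
| `duration` | 160 | s | sptPALM recording length (3200 frames) |
| `D_free` | 3 | µm²/s | fast monomer diffusion |
| `V_flow` | 0.05–0.15 | µm/s | measured retrograde flow speeds |
| `D_flow_lateral` | 0.003 | µm²/s | short-range lateral motion in the flow |
| `D_bound` | 0.001 | µm²/s | residual wobble of trapped molecules |
| `edge_band` | 0.5 | µm | polymerization-competent zone |
| `k_poly` | 0.5 | s⁻¹ | polymerization rate at the edge |
| `k_c` | 0.2 | s⁻¹ | mean pause frequency on N-cadherin substrate |
| `k_u` | 0.001–0.8 | s⁻¹ | extremes of observed adhesive interactions |
| `k_d` | 0.05 | s⁻¹ | speckle-microscopy turnover rate |
| `base_band` | 4 | µm | forced-disassembly region at the base |
| `n_molecules` | 400 | — | trajectories per condition |

### Numerical choices

*Event order.* Within each step the order is fixed: polymerization test,
motion update, coupling/uncoupling test, depolymerization/base test. Any
fixed order is defensible at $k\Delta t \ll 1$; fixing one makes seeded
runs bit-reproducible.

*Boundary handling.* The update rules do not say what happens when a move
leaves the cone. FREE moves are reflected at the leading edge and at the
straight sides (with a clamp if a double bounce would still land outside);
the small FLOW/BOUND wobble is clamped to the cone. Reflection conserves
molecules — the only exits from the flow are depolymerization and the
basal disassembly rule.

*Randomness.* Each step consumes a fixed budget of draws (two normals,
three uniforms) regardless of state, so a molecule's path is a pure
function of its draw set. Molecule $i$ of an ensemble is seeded with
`seed + i`, which makes ensembles reproducible and lets a test replay a
single molecule's integration step by step.

*Validity.* Configurations are rejected unless $\Delta t \cdot
\max(k_{poly}, k_c, k_u, k_d) < 1$, all rates and lengths are
nonnegative, and the edge/base bands fit inside the cone.

## The observation chain

Ground-truth tracks are degraded the way the experiment degrades them:

1. **Photophysics** (`apply_photophysics`): each molecule becomes
   fluorescent at a uniform time in `on_window` (default 0–150 s on a
   160 s record) and bleaches after an exponential on-time. The default
   mean on-time of 7.5 s was chosen so that the camera-frame lifetime is
   approximately exponential with mean 15 frames at the 0.5 s down-sampled
   interval, giving ~63% of trajectories longer than 7 frames and a
   median surviving length near 9–11 frames — the values observed for
   mEos2 fusion proteins.
2. **Camera down-sampling** (`downsample_to_camera`): positions are
   averaged in groups of 5 consecutive 50 ms frames (the trajectory-level
   equivalent of summing camera exposures to 250 ms) and one group of two
   is kept, yielding 2 Hz sampling; a fully detected 3200-frame track
   becomes exactly 320 frames. The retained group indices are
   `keep_every, 2*keep_every, ...`, so the output length is
   `floor(floor(n/5)/2)`.
3. **Detectability**: a molecule is only localizable in a summed frame if
   it stayed within `blur_radius` (default 0.25 µm, the diffraction-limited
   spot scale) of its exposure-mean position. Free monomers (RMS excursion
   ~1.7 µm per 250 ms at `D_free` = 3 µm²/s) therefore never produce
   localizations — this is precisely how the experimental summation
   eliminates the monomer blur — while flowing and bound molecules
   (≤ 0.1 µm) always do. The observed track is the longest contiguous run
   of detected frames. The 0.25 µm default sits an order of magnitude from
   both regimes, so the behavior is insensitive to its exact value.
4. **Length filter** (`filter_tracks`): only trajectories longer than
   seven frames are analyzed.

An alternative to steps 2–3 would be to render the simulated molecules
into images and re-detect and re-link them with a localization/tracking
engine. That path reproduces tracker artifacts too, but requires the
tracker itself; the trajectory-level path keeps ground-truth identities,
preserves the frame arithmetic exactly, and is what the package's tests
build on.

**What the generator does not emulate.** Down-sampled positions carry no
localization error. Real sptPALM localizations are accurate to ~30–50 nm,
which adds a constant $4\sigma^2$ floor to every MSD and, over the short
fit windows of 8–20-frame tracks, swamps the drift signature
($V^2\tau^2 \approx 0.0025\,$µm² at $\tau$ = 0.5 s and $V$ = 0.1 µm/s).
Passing parameter-recovery tests on this generator therefore demonstrates
the correctness of the estimators on idealized tracker output, not their
robustness to localization noise; on real data the directed fraction at a
given flow speed will be lower than the simulated one, and the
confined class inflates correspondingly.

## Trajectory analysis

The time-averaged MSD over all ordered same-lag pairs is fitted in log–log
space with $MSD = 4D\tau^\alpha$. The fit uses the first quarter of
available lags, with a floor of 4 lags so the shortest analyzable tracks
(8 frames) still provide enough points; the window is exposed as
`max_lag_fraction`/`min_lags`. Motion classes follow the
simulation-calibrated thresholds with the printed boundary conventions:
directed is *inclusive* at $\alpha \ge 1.5$, confined is $\alpha < 0.5$,
Brownian is in between.

The mobility split uses the initial-slope estimator: a straight line with
intercept (absorbing any offset) through the first 4 MSD points, $D$ =
slope/4. Trajectories with a non-positive slope get the sentinel
$D = 10^{-5}\,$µm²/s and always classify confined; the threshold itself is
strict ($D <$ 0.015 µm²/s confined, 0.015 exactly is mobile). Two
documented inconsistencies in the source material are surfaced rather than
hidden: the resolution-based derivation $\sigma^2/(4\cdot 4\cdot\Delta t)$
evaluates to ≈0.038 µm²/s with its own stated inputs, not the operational
0.015 — `mobility_threshold()` computes the formula verbatim and the
printed thresholds remain the defaults — and the Vangl2 cut-off appears
both as 0.022 and 0.025 µm²/s in different places; 0.022 is the default.

Directed trajectories additionally get a drift speed from nonnegative
least squares of $MSD = 4D\tau + V^2\tau^2$ on the regressors
$(4\tau, \tau^2)$; a negative unconstrained coefficient is clamped to the
boundary and flagged. On flow-dominated ensembles the mean fitted $V$ of
directed trajectories returns the simulation's input speed to within 15%,
closing the loop between generator and estimator.

## Nanodomain mapping

Localizations are rendered into a 25 nm-pixel intensity histogram
(`render_superres`; the grid total always equals the localization count).
Domains are segmented by a fluorescence threshold. The threshold rule is
not specified in the source protocol, so the default is *relative*: map
mean + 2 SD, computed over the growth-cone mask when one is supplied, and
recorded with each result; domain counts are then invariant under global
intensity rescaling. Each connected component's x and y marginal profiles
are fitted with a product of rising and falling logistic edges,
$A\,\sigma((u-e_1)/w)\,\sigma(-(u-e_2)/w)$, and the domain size per axis
is the distance $e_2 - e_1$ between the half-maximum edge midpoints — the
natural reading of "a 2D sigmoidal fit of the fluorescent area". For an
isotropic Gaussian cluster this size lands near the profile's full width
at half maximum. Components whose fit fails are reported at their
bounding-box size with a `degraded` flag.

Domain density is count per µm² of the cone mask; the periphery ratio
compares density in a peripheral band (default: the outer 20% of the cone
radius, configurable — the protocol does not define "periphery") with the
whole-cone density, so uniform placement gives 1.

### Shape Index

S.I. = $4\pi A/P^2$ with the area from the pixel count and the perimeter
from the 0.5 iso-contour of the mask after two passes of a 3×3 box blur.
Raw marching squares on a binary mask overestimates a disk's perimeter by
~6% (S.I. 0.89); with the smoothing a rasterized disk scores 0.995, a 5:1
ellipse lands within 1% of Ramanujan's perimeter approximation, and a
square comes out ~3.5% above $\pi/4$ because the blur rounds its corners —
a known, documented bias of the estimator for shapes with true corners.

## FRAP

The three-parameter interface (free fraction $\varphi$, diffusion rate
$k_{diff}$, turnover rate $k_{reac}$) is preserved from the experimental
protocol, but the protocol does not print the functional form, which lives
in prior work. The package adopts a two-exponential reaction-dominant
form,
$$F(t) = \varphi\,(1 - e^{-k_{diff} t}) + (1-\varphi)(1 - e^{-k_{reac} t}),$$
with the fast term standing in for diffusive replenishment of the bleached
spot. This is a modeling choice: it has no bleach-spot geometry term, so
$k_{diff}$ is an effective rate, not a diffusion coefficient. Curves are
normalized to pre-bleach 1 and first post-bleach frame 0.

Fitting is bounded Levenberg–Marquardt least squares. Initialization uses
the biphasic structure — the recovery level at the 20 s mark seeds
$\varphi$, the early rise seeds $k_{diff}$, the tail slope seeds
$k_{reac}$. Fits with $k_{diff}/k_{reac} < 5$ are flagged weakly
identified (the two phases are then statistically inseparable), and flat
curves are flagged degenerate instead of being forced through the
optimizer. With the generating parameters $\varphi = 0.5$,
$k_{diff} = 0.15$ s⁻¹, $k_{reac} = 0.005$ s⁻¹ (a ~50% fast phase complete
by ~20 s, as observed for N-cadherin-GFP), noiseless curves are recovered
to 1% and 2%-noise replicates to within 10% in the median.
`turnover_change()` expresses two fitted conditions as the percent change
of $k_{reac}$, the comparison form used to contrast genotypes.

## Optical tweezers

All trap physics is unit-consistent in µm, s, pN and Pa·s: with those
units $F = 6\pi\eta R V$ is already in pN. Stiffness comes from
$\kappa = F/\delta$ for a single measurement or a zero-intercept
regression across laser powers; the minimal escape force is
$\kappa R$ at an escape distance equal to the bead radius. Escape
detection requires the displacement to exceed the escape radius for two
consecutive samples, rejecting single-frame tracking spikes; escape
probability counts escapes within the first 60 s of each recording; and
the post-escape velocity is the OLS slope of displacement versus time
restricted to the 1–4 µm peripheral band. Mean escape times average
*escaped beads only*, as in the source convention — `mean_escape_time()`
makes that explicit rather than censoring. The synthetic generator dwells
with bounded jitter until a constructed escape time and then drifts with
the flow, so the analysis round-trips its construction exactly.

# Problem sizes used by the tests

The test-suite study conditions are the generator defaults: 400 molecules
× 3200 steps per condition for the clutch predictions (three uncoupling
rates at fixed $V$ = 0.10 µm/s, three flow speeds at fixed $k_u$ = 0.05
s⁻¹, seeds fixed a priori), 200-track Brownian ensembles for estimator
recovery, 100 FRAP replicates at 2% noise, and 100-bead batches for the
tweezers round trip. A full 400-molecule condition simulates and analyzes
in roughly 15 s on one core; the complete suite runs in about a minute.

# Known limitations

* No localization noise, no false or missed detections, no track-linking
  errors: the generator models the physics and the sampling, not the
  tracker (see above for what that implies for the tests).
* The clutch model has no force balance — binding does not slow the flow
  globally, it only immobilizes the bound molecule. Flow-speed changes
  between conditions are inputs, not emergent.
* The FRAP model is spatially homogeneous; no radial bleach-profile or
  acquisition-bleaching correction (the normalization hook exists but is
  off by default).
* `detect_domains` assumes domains are resolvable as separate connected
  components at the chosen threshold; overlapping domains merge.
* The Shape Index perimeter estimator slightly overestimates S.I. for
  shapes with true corners, and the mask must be a single connected
  component.
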