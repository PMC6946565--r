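# gcclutch

Tools for studying the **molecular clutch** in neuronal growth cones: the
transient coupling between transmembrane adhesion receptors (here
N-cadherin) and the retrograde flow of filamentous actin that converts
actin treadmilling into forward movement of the axon tip.

The package is aimed at people analyzing single-molecule imaging of growth
cones — sptPALM trajectories, super-resolution localization maps, FRAP
recoveries, optical-tweezers bead recordings — and at people who want to
simulate those experiments to interpret them. Every analysis stage comes
with a synthetic-data generator, so the whole pipeline runs without any
microscopy recordings.

## What it computes

**Clutch simulator.** Actin molecules move inside a 2D conical growth cone
(radius 12 µm, half angle 45°) in one of three states: freely diffusing
(D = 3 µm²/s), bound to the retrograde flow (radial drift −VΔt,
V = 0.05–0.15 µm/s, lateral wobble D′ = 0.003 µm²/s), or attached to a
substrate adhesion (D″ = 0.001 µm²/s). Molecules polymerize within 0.5 µm
of the leading edge at 0.5 s⁻¹, couple to adhesions at k_c = 0.2 s⁻¹,
uncouple at k_u (0.001–0.8 s⁻¹), depolymerize at 0.05 s⁻¹, and are forced
to disassemble in the 4 µm base region. The ratio k_c/k_u is the *coupling
strength*. Simulated tracks then pass through mEos2 photophysics
(uniform activation, exponential bleaching) and camera down-sampling
(sum 5 × 50 ms frames, keep 1 of 2 → a 2 Hz movie in which fast monomers
blur out and are lost).

**Trajectory analysis.** For each track the time-averaged mean squared
displacement is fitted with the anomalous power law

    MSD(τ) = 4 D τ^α

and classified: confined (α < 0.5), Brownian (0.5 ≤ α < 1.5), directed
(α ≥ 1.5). Directed tracks get a drift speed from the quadratic model
MSD = 4Dτ + V²τ², and a confined/mobile split uses the initial-slope
diffusion coefficient against a threshold of 0.015 µm²/s (N-cadherin) or
0.022 µm²/s (Vangl2).

**Nanodomains and morphometry.** Localizations are rendered into a 25 nm
super-resolution map; confinement domains are segmented by intensity
threshold and sized by logistic-edge profile fits; densities (domains/µm²)
and periphery enrichment are reported. Growth-cone masks get a Shape Index
S.I. = 4πA/P² (1 = circle).

**FRAP.** Biphasic recoveries are fitted with a three-parameter
diffusion/reaction model — free fraction φ, diffusive rate k_diff, bond
turnover rate k_reac:
F(t) = φ(1 − e^(−k_diff·t)) + (1 − φ)(1 − e^(−k_reac·t)).

**Optical tweezers.** Stokes drag F = 6πRηV, trap stiffness κ = F/δ,
escape force F_esc = κR, bead escape detection, escape probability, and
post-escape velocity in the 1–4 µm peripheral band.

## Worked example

Simulate 400 molecules under intermediate coupling, run them through the
full observation chain, and classify the surviving trajectories:

```r
library(gcclutch)
cfg <- sim_config(k_u = 0.05, V_flow = 0.10, seed = 42)
run <- run_pipeline(cfg)
run
#> <clutch_run: 400 simulated -> 273 observed -> 170 analyzed tracks>
#>   confined 0.035 | brownian 0.824 | directed 0.141  (k_c/k_u = 4, V = 0.1 um/s)
```

Of the 400 simulated molecules, 273 yield a detectable fluorescent track
after photophysics and camera blur, 170 are longer than seven frames, and
14.1% of those are directed (carried by the flow). Weakening the clutch
(k_u = 0.8, coupling strength 0.25) frees the flow and the directed
fraction triples; the fitted drift speed of those directed tracks returns
the flow speed entered in the simulation:

```r
weak <- run_pipeline(sim_config(k_u = 0.8, V_flow = 0.10, seed = 42))
weak
#> <clutch_run: 400 simulated -> 211 observed -> 124 analyzed tracks>
#>   confined 0.016 | brownian 0.548 | directed 0.435  (k_c/k_u = 0.25, V = 0.1 um/s)
mean(weak$fits$V[weak$fits$class == "directed"], na.rm = TRUE)
#> [1] 0.111
```

A FRAP curve simulated at 2% noise and refitted recovers its generating
parameters:

```r
fit_frap(simulate_frap_curve(0.5, 0.15, 0.005, noise_sd = 0.02, seed = 7))
#> <frap_fit: phi = 0.502, k_diff = 0.1571 /s, k_reac = 0.00503 /s, SSE = 0.0727>
```

And the optical-trap escape force at the calibrated stiffness:

```r
escape_force(kappa = 4.7, R = 0.5)
#> [1] 2.35
```

about 2.3 pN — the force the actin flow must exert through N-cadherin
bonds to pull a bead out of the trap.

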