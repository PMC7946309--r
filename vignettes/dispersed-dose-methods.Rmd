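---
title: "Methods: Monte Carlo dispersed-dose dosimetry in stylized pediatric phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo dispersed-dose dosimetry in stylized pediatric phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When a pediatric patient is irradiated — with a 6 MV photon beam or a
240 MeV proton beam — organs outside the treatment field receive an
unintended *dispersed dose*. Because children are more radiosensitive than
adults and their organs sit closer together, this out-of-field dose is a
first-order concern for secondary-cancer risk. `pedidose` quantifies it
with the dimensionless conversion coefficient

$$F = D_d / D_t,$$

the ratio of the absorbed dose in a non-targeted organ ($D_d$) to the
absorbed dose in the targeted organ ($D_t$), both expressed per primary
particle so that fluence normalization cancels. The package simulates five
ages (newborn, 1, 5, 10, 15 years), two modalities (photon, proton) and
five aim points P1–P5 (testes, colon, liver, left lung, brain), reports
$F$ for six organs (skeleton, skin, brain, spine, left and right lung),
scales a 54 Gy hyper-fractionated left-lung course (CHART: 36 fractions,
3 per day, 12 days) through the coefficients, and compares modalities with
a one-sided paired t-test over the 28 matched $F$ cells per age group.

This is a desk-scale engine. It does **not** model a full accelerator
head, a clinical nozzle, or treatment-room scatter, and it makes no claim
of reproducing production-code absolute dose tables; what it is built to
reproduce are the *structure* of the study (the $F$ matrix, the case
study, the paired test) and its directional physics (protons disperse far
less than photons; smaller bodies disperse more).

## Phantoms

Phantoms are constructive solid geometry over quadric primitives
(ellipsoids, elliptical cylinders, boxes). A point belongs to the
highest-priority region containing it; priorities run organs > spine >
skeleton > residual soft tissue > skin > exterior air, which resolves
overlaps the way cell precedence does in production Monte Carlo codes
without full cell-complement algebra. Coordinates are right-handed: $z$ is
the body axis (feet to head), $y$ posterior to anterior, origin at the
trunk-base midline. Beams travel along $-y$ (anterior entry); this AP
convention is an assumption for P1 as well, where an inferior entry would
also be anatomically defensible.

The published study took its anatomy from the classical stylized
(ORNL/MIRD-type) phantom series without printing dimensions, so the
package ships its own versioned master anatomy at 15-year scale — trunk
and leg elliptical cylinders, head ellipsoid, brain/skull, spine cylinder,
rib shell, pelvis, leg bones, two lungs, liver, colon, testes — and scales
it per age class: axially by $s_z$ (heights 51, 75, 109, 138, 168 cm) and
laterally by $s_{xy}$ chosen so total body masses track the stylized
series (3.6, 9.7, 19.8, 33.2, 56.8 kg). Non-uniform scaling preserves
containment and disjointness exactly, makes every organ mass strictly
monotone in age, and keeps the aim points anatomically ordered along the
body axis (testes < colon < liver < lungs < brain). Absolute fidelity to
any specific reference equation set is *not* claimed; every dimension is
overridable through `build_phantom(..., parameter_overrides = )`, and a
validation pass rejects overrides that make analytic organs overlap
(detected as a disagreement between the closed-form and rejection-sampled
volumes). Arms and posture variation are omitted.

Organ masses use closed forms where they exist (all ellipsoidal organs,
the spine cylinder) and a shared 8×10⁵-point rejection-sampling pass with
a fixed internal seed otherwise (skeleton, soft tissue, skin), so phantom
construction is fully deterministic.

## Physics data

All interaction data are generated at build time from analytic
parameterizations and shipped as checksummed CSV tables
(`generate_physics_tables()` regenerates them):

* **Compton**: Klein–Nishina on an electron-density basis — exact within
  the free-electron approximation (no Doppler broadening, no binding).
* **Photoelectric**: a $Z^{4.5}/E^3$ power law calibrated to water at
  10 keV. Crude, but photoelectric absorption only controls the fate of
  low-energy scattered photons here.
* **Pair production**: a $Z^2 (E - 1.022\,\mathrm{MeV})$ threshold fit
  calibrated to water at 6 MeV; a minor channel below 6 MeV.
* **Coherent (Rayleigh) scattering is omitted** — a documented bias that
  slightly underestimates small-angle dispersal at low energies.
* **Energy transfer**: $\mu_{en}/\rho$ is constructed as an energy
  *transfer* coefficient consistent with the tally (Klein–Nishina mean
  electron-energy fraction for Compton; full transfer for photoelectric;
  $E - 1.022$ MeV for pair), so the track-length estimator and the
  collision-site estimator have identical expectations by construction.
* **Protons**: Bethe stopping power with Bragg-additivity mean excitation
  energies (no shell or density-effect corrections — percent-level above
  1 MeV), CSDA ranges by quadrature from the 1 MeV cutoff, Highland
  multiple-scattering angles from mass-fraction-mixed radiation lengths.
  The water CSDA range at 240 MeV comes out at ≈ 35.1 cm, within ~1% of
  reference tabulations. **Nuclear interactions are ignored**, a ~10–20%
  fluence bias at 240 MeV that flattens the entrance channel but barely
  moves $F$ ratios.

Interpolation is log–log (pair production linear near threshold, clamped
to zero below 1.022 MeV), with no extrapolation: out-of-grid queries are
rejected.

## Beams

**Photon mode.** A point source at 100 cm source-axis distance emits
primaries into the pyramid subtending a rectangular field that
circumscribes the target organ's silhouette plus a configurable margin
(default 0.5 cm; the study never printed its field sizes, so the
circumscribing field is a flagged assumption). Energies come from a
histogram spectrum; the default has a 6 MeV endpoint and its mode near
0.7 MeV (bin weights ∝ ∫ E e^{−E/0.8} dE), the generic shape of a 6 MV
linac spectrum. The accelerator head itself is out of scope; its surrogate
is an *ideal-jaw* model: conceptually the source emits isotropically into
a forward cone (default half-angle 45°) and the jaws absorb everything
outside the field pyramid. Since absorbed primaries deposit nothing, only
in-field photons are transported, and finalized doses are multiplied by
the analytic transmission $\Omega_{field}/\Omega_{cone}$. The half-angle
was fixed by a design-time closed-form estimate,
$D_t \approx \bar{E}\,(\mu_{en}/\rho)\,T / (\Omega_c\,d^2)$
with $\bar E \approx 1.7$ MeV, $\mu_{en}/\rho \approx 0.027$ cm²/g,
transmission $T \approx 0.6$ and $d = 100$ cm, which lands per-primary
target doses at a few $10^{-16}$ Gy — the scale clinical per-primary
normalizations produce. Because the factor cancels in $F$, it affects
only absolute doses. A useful corollary: $D_t$ is nearly independent of
field size, because the in-field solid angle cancels against the fluence
dilution.

**Proton mode.** A 240 MeV source (the energy sufficient to treat
essentially any target depth) is degraded by a PMMA range shifter whose
thickness `select_range_shifter()` picks by bisection so the residual CSDA
range — walked through the actual material sequence along the beam axis —
ends at the target-organ centroid. Primaries are emitted parallel to $-y$,
uniformly over an elliptical aperture with semi-axes equal to the organ's
beam's-eye silhouette plus margin. This replaces the double-scattering
chain (two scatterers, ring collimator, patient collimator): the chain's
purpose is a uniform lateral profile shaped to the target, which the flat
elliptical field realizes directly. A circle (the obvious simplification)
cannot circumscribe an elongated silhouette without either spilling Bragg
peaks past the organ's ends — for the liver that would park peaks directly
in the right lung — or truncating the target, so the ellipse is the
minimal faithful surrogate; a circle is recovered when the two semi-axes
are equal, and the uniform-disc sampling law ($r^2$ uniform) is tested in
that case. The ridge filter (spread-out Bragg peak) is not modelled: the
$F$ study reads on a single course geometry and a pristine peak preserves
every comparison the package makes; adding an SOBP would mainly thicken
the high-dose region inside the target organ. Optional Gaussian exit-energy
straggling is off by default.

## Transport and scoring

**Photons** are transported analytically in the CSG: free paths are drawn
region-by-region against the local total attenuation (boundary-to-boundary
exponential sampling, exact for piecewise-constant $\mu$ and memoryless
across redraws); Compton scattering uses the standard
composition–rejection Klein–Nishina sampler; photoelectric events end the
history; pair production is treated as annihilation-in-place (the
positron's 1.022 MeV reappears as two back-to-back 0.511 MeV photons at
the interaction site — acceptable because at ≤ 6 MeV the positron range is
a couple of centimetres and the channel is small). **Electrons are not
transported**: energy transferred to charged particles is scored locally
along photon segments with the track-length kerma estimator
($w\,L\,E\,\mu_{tr}$ per segment), the classical F6-style tally semantics;
this biases doses near interfaces and within a secondary-electron range of
the field edge. A collision-site analog estimator runs in parallel purely
as a consistency check (the two agree within statistics because
$\mu_{tr}$ was built from the same kinematics the sampler uses).

**Protons** use condensed-history stepping: each step is the minimum of a
maximum step (default 0.1 cm), the distance to the next region boundary
and the step capping the fractional energy loss (default 2%); the step
deposits $S(E)\,\Delta x$ in the current region, deflects the direction by
a Highland-width Gaussian, and a proton whose residual range fits inside
the current step is stopped at its CSDA endpoint, depositing its entire
remaining energy. Below the 1 MeV cutoff (residual range tens of
micrometres) the energy is deposited locally. Bohr energy straggling is
available but off by default so the energy ledger closes exactly and runs
are bit-reproducible.

Randomness is counter-based: every history derives its own splitmix64
substream from (seed, history index), so results are independent of any
batch decomposition and two runs with the same seed are bit-identical.

Numerical conventions: after every surface crossing the particle is nudged
$10^{-6}$ cm along its direction before re-location (deterministic
boundary disambiguation); outside the phantom bounding box the world is
vacuum (the ~100 cm air column would attenuate the beam by well under 1%);
energy bookkeeping per run closes as
primaries = transferred + cutoff + deposited + escaped (annihilation
photons carry the 1.022 MeV deducted at the pair vertex, so creation does
not enter the closure) and is checked to $10^{-6}$ in the tests.

Doses are finalized per primary: per-history batch sums and sums of
squares per organ (correct correlation handling within a history), dose =
mean per-history energy / organ mass × 1.602176634×10⁻¹⁰ Gy·g/MeV, and the
relative error is the standard error of the mean over the mean, reported
as undefined (NA) rather than zero for organs never scored.

## The analysis layer

`build_F_matrix()` assembles the age × modality × position × organ table,
forcing $F = 1$ exactly on the diagonal (targeted organ at its own
position) and propagating first-order uncertainties treating $D_d$ and
$D_t$ as independent — conservative, since they share histories; a
correlation-aware treatment would need per-batch covariances and was not
considered worth the complexity at these precisions. With all five
positions present this leaves 28 non-trivial cells per age and modality.
`chart_doses()` is exact arithmetic — prescription × $F$ cell-wise on the
fixed 36-fraction schedule. `paired_t_test()` performs the one-sided
paired Student t-test (photon − proton > 0) via `stats::t.test()`; the
directional alternative follows the scientific claim being tested, with
the two-sided variant available. The six reported organs are fixed; other
regions are tallied but excluded from the 28-cell structure.

## What the synthetic study does and does not emulate

The phantom generator plus beam surrogates *are* the study conditions:
five ages, two modalities, five aim points, organ-conformal fields,
per-primary normalization. Passing tests therefore demonstrate the
method's internal correctness (estimators, sampling laws, energy
conservation, range placement) and its directional claims under these
conditions. They do **not** demonstrate agreement with measurements on
real patients or with production simulations that include an accelerator
head, room scatter, electron transport and nuclear channels. In practice
the omissions depress the simulated photon out-of-field $F$ values —
head leakage and room scatter are a large fraction of far-organ photon
dose in a real bunker — so the package's photon $F$ magnitudes run
below published full-fidelity values while preserving their ordering
across age, position and modality. That is why the acceptance checks pin
exact worked-example arithmetic to published coefficient values but test
the simulation itself only on oracle properties, scales and directions.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run the full 5 × 2 × 5 grid at
4×10⁴ transported photon histories and 2×10⁴ proton histories per cell
(about 3–4 minutes on one core). Because out-of-field primaries are
removed analytically rather than sampled, 4×10⁴ transported photons carry
the statistics that a naive per-emission source would need millions of
histories to reach; every directional comparison in the acceptance suite
passes at better than 10σ at these sizes. Oracle checks use 10⁵ histories
or samples. The geometry consistency property is exercised on 10⁴ random
rays; volume oracles use 10⁵–4×10⁵ points.

## Configuration

Run configurations (`run_config()`) round-trip through YAML
(`write_run_config()` / `read_run_config()`); YAML was chosen as the
serialization surface because it is the structured-config format the
installed R toolchain reads natively. Every study output embeds an md5
hash of the configuration, and `run_study()` resumes from its manifest,
skipping completed cells when the hash matches. A thin command-line
wrapper over these functions ships in `inst/cli/pedidose.R`
(`build-phantom`, `simulate`, `chart`, `compare`, `validate`, `tracks`).

## Known limitations

* No electron transport (kerma approximation): interface and build-up
  effects are absent.
* No coherent scattering, no Doppler broadening, fitted photoelectric and
  pair terms: percent-to-tens-of-percent local biases in photon
  coefficients away from the calibration points.
* No proton nuclear interactions: entrance-channel fluence ~10–20% high
  at 240 MeV.
* No accelerator head, nozzle hardware or room scatter: absolute photon
  out-of-field doses are underestimated relative to a full treatment-room
  simulation; the head surrogate's cone half-angle only rescales absolute
  per-primary doses, never $F$.
* Stylized anatomy with arms omitted; organ shapes are single quadrics.
* The spread-out Bragg peak is not modelled.
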