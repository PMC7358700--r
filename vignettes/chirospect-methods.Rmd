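---
title: "Simulating chiroptical band shapes of a flexible solvated chromophore"
author: "chirospect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating chiroptical band shapes of a flexible solvated chromophore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirospect)
```

## The problem

Camphor-like ketones show a deceptively simple absorption spectrum — one
band from the formally electric-dipole-forbidden, magnetic-dipole-allowed
n&nbsp;&rarr;&nbsp;&pi;* carbonyl transition — but a *bisignate* circularly
polarized luminescence (CPL) band: the sign of the emitted circular
polarization flips across the band. Reproducing that sign structure
requires treating, at the same time,

1. **specific solvation**: hydrogen bonds between the carbonyl oxygen lone
   pairs and a protic solvent (methanol) shift and reshape the band;
2. **environment fluctuations**: every snapshot of the solvent sees a
   slightly different chromophore;
3. **a large-amplitude motion (LAM)**: in S1 the carbonyl bends out of
   plane into two minima separated by a high barrier, giving two emitting
   conformers with *opposite-sign* rotatory strengths;
4. **vibronic structure** of the remaining small-amplitude modes.

`chirospect` implements the composition machinery for this problem: it
consumes reference electronic-structure data (state energies, transition
dipole matrices, per-state atomic charges) and classical trajectory
snapshots, and produces OPA, ECD, OPE and CPL band shapes. All
electronic-structure and molecular-dynamics computation is out of scope:
those results enter as input files, and a synthetic-fixtures module
generates physically valid stand-ins for every input so the whole pipeline
is testable on its own.

## Virtual sites and the hydrogen-bond score

The two oxygen lone pairs are modeled as massless virtual sites (VS)
placed 0.3067 &Aring; from O with a C&ndash;O&ndash;VS angle of 111.3&deg;,
symmetric about the C=O axis (`place_virtual_sites()`). The plane holding
the two sites depends on the electronic state: in the planar ground state
they lie in the carbonyl fragment plane; in the pyramidalized excited
state they lie in the plane orthogonal to the plane spanned by the
C&ndash;C&ndash;C normal and the oxygen direction. The single VS charge is
fixed by requiring equal charges on both sites, charge conservation
(the oxygen charge is reduced by 2*q*), and a least-squares match of the
point-charge dipole to the QM dipole of the target state
(`fit_vs_charges()`); with one scalar unknown the solution is closed-form.

A hydrogen bond is scored with the smooth geometric function

$$F(r, \theta) \;=\; e^{-\ln 2\,\left(\frac{r - r_0}{w_r}\right)^2}\;
  e^{-\ln 2\,\left(\frac{\theta - \theta_0}{w_\theta}\right)^2},$$

with $r$ the VS&ctdot;H(hydroxyl) distance, $\theta$ the deviation of the
VS&ctdot;H&ndash;O angle from linearity, optima $(r_0, \theta_0) =
(1.8\,\text{&Aring;}, 6^\circ)$ and half-widths $(w_r, w_\theta) =
(0.2\,\text{&Aring;}, 5^\circ)$. The literature this criterion descends
from specifies "exponential decays" parameterized by half-widths at
half-maximum but no closed form; a Gaussian in each deviation is the
natural peaked form for which an HWHM is well defined, and deviations are
penalized on *both* sides of the optimum (no flat top is described
anywhere). A bond is present iff $F \ge 0.7$, applied instantaneously per
frame (no temporal smoothing). Each methanol may bind at most one VS; when
one residue is the best candidate for both sites the conflict is resolved
greedily by descending $F$ with ties to VS1 — the exclusivity is physical,
the resolution rule is ours and is deterministic.

Frames are classified into `noHB`, `HB-VS1`, `HB-VS2` and `twoHB`
(`classify_frame()`, `partition_trajectory()`), and each cluster's average
embedding is represented by a *collective frame*: the union of the
environment sites of $n = 30$ sequential snapshots, cut to a 30 &Aring;
sphere around the solute geometric center, with every charge scaled by
$1/n$ (`build_collective_frame()`). The solute "center" is the geometric
center of its atoms — the source material does not define one, and for a
30 &Aring; cut the difference to any other sensible center is immaterial.

## The perturbed-matrix method

For each cluster a reference configuration carries variationally computed
electronic states. Per frame, the Hamiltonian is written as the diagonal
matrix of reference energies plus a perturbation
$\Delta V$ representing the *difference* of the environment
electrostatics between the frame and the reference:

- **diagonal**, atom-based expansion:
  $[\Delta V]_{ii} = \sum_a q_i(a)\,\Delta\phi(\mathbf r_a)$, with
  $q_i(a)$ the per-state atomic charges and $\Delta\phi$ the potential
  difference at each solute atom;
- **off-diagonal**:
  $[\Delta V]_{ij} = -\Delta\mathbf E \cdot \boldsymbol\mu_{ij}$, the
  reference transition dipoles contracted with the field difference at
  the solute geometric center.

The split reflects what the input data can support: per-state atomic
charges exist (so the diagonal can be atom-resolved), per-*pair*
transition atomic charges usually do not (so couplings use the
dipole-level contraction). If transition charges are available they can be
passed to `build_perturbation()` and the off-diagonal becomes atom-based
too.

`diagonalize_pmm()` diagonalizes $\mathrm{diag}(\varepsilon) + \Delta V$,
fixes every eigenvector sign deterministically (largest-magnitude
component positive) and rotates the electric dipole matrix,
$\mu' = C^\top \mu C$. The radiating transition is tracked across frames
by maximal eigenvector overlap with the reference states, not by energy
order, so near-crossings do not scramble the assignment; exact
degeneracies break ties toward the lower index. The rotatory strength of
a frame is $R' = \boldsymbol\mu' \cdot \mathbf m_\mathrm{ref}$ with the
magnetic moment held at its reference value — environment fluctuations of
magnetic transition dipoles are neglected deliberately (an optional flag
rotates them for sensitivity checks; default off). Rotatory strengths are
reported in atomic units and in the customary $10^{-40}$ cgs units
(1 a.u. = 235.7220 &times; 10&#8315;&#8308;&#8304; cgs).

All 11 (or however many) input states are retained in every frame
diagonalization; nothing in the method suggests truncating them, and the
cost is negligible.

## The large-amplitude motion

The carbonyl out-of-plane bend is solved exactly in 1-D on a supplied
potential scan by sinc-DVR (`solve_dvr()`), using the uniform-grid
Colbert&ndash;Miller kinetic matrix

$$T_{ii} = \frac{\hbar^2}{2 I \Delta x^2}\frac{\pi^2}{3},\qquad
  T_{ij} = \frac{\hbar^2}{2 I \Delta x^2}\,
  \frac{2(-1)^{i-j}}{(i-j)^2},$$

with the potential diagonal. The coordinate is the bend angle in radians
and $I$ is a constant effective inertia supplied with the scan; a
coordinate-dependent inertia is accepted and discretized with a
symmetrized kernel, but the full curvilinear kinetic-energy machinery
that produces such scans is out of scope — the interface accepts its
output. The grid is treated as non-periodic (the scan is a finite arc and
only bound states below the arc edges are of interest). The effective
inertia is *not* published for this coordinate, so it is an input; the
fixture default ($10^6$ a.u.) puts the well frequency near
115 cm&#8315;&sup1;, a typical carbonyl out-of-plane wag, and is
documented as a fixture constant, not a physical claim.

States are assigned to wells by localized probability (&ge; 90% on one
side of the interior barrier maximum; otherwise "delocalized"), thermal
populations are Boltzmann over all computed levels with a 0.5%
retention threshold (reported both unrenormalized and renormalized), and
coordinate-dependent properties — notably $|\mu|$, $|m|$ and their angle,
the quantities that drive the CPL sign — are averaged per vibrational
state by grid quadrature (`lam_average()`, `lam_moment_geometry()`).

The synthetic double well (`gen_double_well()`) is a quartic-plus-linear
polynomial $a(x^2 - x_0^2)^2 + cx$ fitted by nested 1-D root bracketing
so its *stationary values* reproduce the requested barrier and
minima asymmetry to 10&#8315;&#8309; kJ/mol; under the linear tilt the
minima shift slightly off $\pm x_0$, which is the price of an
overdetermined parameterization and is why the fit targets stationary
values, not positions. Defaults are an 18 kJ/mol barrier with minima near
&plusmn;25&deg; on a 4&deg; grid — the S1 topology this package exists
to handle.

## Vertical-gradient vibronic structure

Small-amplitude modes enter through the vertical-gradient (VG) model:
initial-state frequencies plus only the final-state gradient at the
initial geometry. In reduced units the displacement per mode is
$\delta_k = -g_k/\omega_k$, the Huang&ndash;Rhys factor
$S_k = \delta_k^2/2$, and the reorganization energy
$\lambda = \sum_k S_k \omega_k$ (`vg_shifts()`). Because VG reuses the
initial-state modes there is no Duschinsky rotation by construction —
that is a property of the model, not an approximation added here.
Modes parallel to the LAM or to methyl rotations must be removed by the
caller (an explicit index mask; automatic detection is out of scope).

Franck&ndash;Condon factors of equal-frequency displaced oscillators are
analytic (associated Laguerre closed form, `fc_overlap_sq()`); at a cold
initial state they reduce to the Poisson progression
$e^{-S} S^n / n!$. Sticks are enumerated by class — the number of
simultaneously excited final-state modes — with caps $C_{1\max} = 50$
quanta for singles, $C_{2\max} = 30$ for pairs, and a global integral
budget $N_{I\max} = 10^9$ (`enumerate_sticks()`). For classes &ge; 3 the
reference implementation's cap scheme is not published; here mode
combinations are ranked by the product of their single-mode maximum FC
weights and the per-mode quanta cap is halved for each class beyond 2
(never below 1), with `max_class` = 4 by default. Truncation is recorded
by `spectral_progress()`, the recovered fraction of the analytic total
intensity.

VG is evaluated at 0 K for these modes on purpose: temperature enters the
final spectra only through the LAM-state populations and the conformer
Boltzmann weights, mirroring the physical separation of time scales.

Herzberg&ndash;Teller (HT) terms expand the electric transition dipole
linearly in the dimensionless normal coordinates,
$\mu(Q) = \mu_0 + \sum_k (\partial\mu/\partial Q_k) Q_k$, with the
analytic $\langle 0 | Q_k | n_k' \rangle$ matrix elements (in the
$Q = (a + a^\dagger)/\sqrt 2$ convention, so
$|\langle 0|Q|1\rangle|^2 = 1/2$ at zero displacement). HT applies to the
*electric* dipole only; magnetic moments stay at their equilibrium value
throughout. Each stick stores its FC, HT and interference contributions
separately.

## Assembling the spectra

`boltzmann_weights()` converts relative free energies to populations
(R = 8.314462618 J mol&#8315;&sup1; K&#8315;&sup1;). Sticks are broadened
with unit-area Gaussians (`broaden()`); the defaults follow the
three-stage convention of 900 / 550 / 450 cm&#8315;&sup1; HWHM for pure
electronic, vibronic, and combined bands. Band grids default to
10 cm&#8315;&sup1; spacing spanning the sticks &plusmn;5 HWHM.

The combination rules:

- **FC level** (`combine_fc()`): per frame, translate the reference stick
  spectrum so its 0-0 line follows the frame's perturbed transition
  energy, scale all weights by $f = |\mu'|^2/|\mu_\mathrm{ref}|^2$
  (OPA/OPE) or $R'/R_\mathrm{ref}$ (ECD/CPL, *signed* — the only choice
  that lets fluctuations flip the local sign), average over frames,
  broaden at the combined width.
- **HT increment** (`combine_fcht()`): the FC&ndash;FCHT difference is
  computed once, for the reference configuration, and solvent
  fluctuations act on it at *half* the strength fitted for the FC part:
  $S_\mathrm{FCHT} = S_\mathrm{FC,fluct} + \Delta_\mathrm{HT,ref}\,
  \bigl(1 + (\langle f\rangle - 1)/2\bigr)$, with each
  $\Delta_\mathrm{HT}$ copy shifted by the same per-frame energies as the
  FC part (whether the source protocol shifted the HT difference too is
  not stated; shifting both identically is the consistent reading and is
  what is done here).
- **Conformers** (`assemble_emission()`): each S1 well is an independent
  conformer with its own vibronic band and PMM ensemble, combined with
  $\Delta G$-based Boltzmann weights. This matches how the emission
  protocol weights conformers; a per-LAM-state alternative (weighting
  individual vibrational states by their thermal populations from the
  DVR solution) is available through `lam_moment_geometry()` +
  `thermal_populations()` for users who want it.
- **Prefactors** (`prefactor()`): OPA/ECD &prop; $E$, OPE/CPL &prop;
  $E^3$ (spontaneous-emission convention), in arbitrary overall units; a
  unit-prefactor flag supports shape-only comparisons. Cluster
  populations used in assembly are the trajectory fractions from the
  partition (not re-derived from collective frames).
- The global transition-energy correction (e.g. the difference between a
  cheap and a benchmark electronic-structure level for the isolated
  molecule) is a single scalar, `energy_shift`, applied uniformly.

A worked end-to-end identity holds by construction and is enforced in the
tests: with a single frame equal to the reference environment and one
conformer, the full pipeline returns the standalone vibronic band
bit-for-bit.

```{r identity}
sp <- fixture_spec(seed = 606, n_frames = 1, propensities = c(1, 0, 0, 0))
frames <- gen_solvent_frames(sp)$frames
ref <- gen_reference_electronic(6, seed = 607, ref_env = frames[[1]]$env)
ens <- ensemble_sticks(ref, frames)
ms <- gen_mode_set(4, c(0.1, 0.7), seed = 608)
st <- enumerate_sticks(ms, "FC", mu0 = ref$elec_dipole[1, 2, ],
                       m0 = ref$mag_dipole[2, ])
grid <- seq(15000, 45000, 10)
a <- combine_fc(st, ens, ref, "OPE", hwhm = 450, grid = grid)
b <- vibronic_band(st, ens$sticks$E_cm1[1], "OPE", 450, grid)
identical(a$intensity, b$intensity)
```

## What the synthetic generators emulate — and what they do not

`gen_solvent_frames()` produces the rigid carbonyl fragment plus
methanol-like charge triads whose hydrogen-bond labels follow requested
propensities. Bonded triads sample $(r, \theta)$ from Gaussians with the
F-function spreads, rejection-truncated to the $F \ge 0.75$ region, and
unbonded triads stay &ge; 5 &Aring; away ($F$ numerically zero), so the
label a frame was generated with is exactly the label the classifier
recovers; recovery error in population tests is then purely multinomial
counting noise, which is the property those tests are designed to
measure. The triad charges (&minus;0.700, +0.435, +0.265 e) are fixture
constants in the spirit of standard three-site methanol models, not
claims about any force field. The frames contain only electrostatically
relevant solvent — no bulk liquid structure, no diffusion, no
periodic box. Consequently, passing tests demonstrate the correctness of
the scoring/clustering/perturbation machinery, *not* that real methanol
around a real ketone produces any particular cluster population; those
numbers must come from real trajectories.

`gen_reference_electronic()` draws valid reference data with a
camphor-like first gap (~33,000 cm&#8315;&sup1;) and a controllable angle
between the radiating electric and magnetic moments, which is the knob
that sets the rotatory-strength sign in the bisignate-CPL tests.

## Numerical choices and limitations

- Internal units: cm&#8315;&sup1; for energies, atomic units for dipoles,
  &Aring;ngstr&ouml;m for coordinates; Coulomb sums run in atomic units.
- Electrostatic evaluation guards a minimum site&ndash;point distance of
  10&#8315;&sup3; &Aring; and reports the offending frame and site.
- Eigenvector sign and state-tracking conventions (above) make every
  perturbed quantity reproducible run to run.
- Degenerate PMM eigenvalues are resolved by overlap with lower-index
  tie-break; the symmetric double well similarly yields parity pairs
  whose intra-pair mixing is numerically arbitrary — well assignment
  flags such states as delocalized rather than forcing a side.
- The DVR converges exponentially for smooth bound states (harmonic
  ladder to ~10&#8315;&#8310; cm&#8315;&sup1; at 251 points) but only
  algebraically for box-like states with derivative discontinuities at
  the walls.
- Problem sizes used in the test-suite and the reproduction script —
  5,000-frame synthetic trajectories, 100 random 11-state Hamiltonians,
  251-point DVR grids, 2,000-frame fluctuation ensembles — were chosen as
  the smallest sizes at which the statistical assertions (3&sigma;
  binomial recovery, 2% variance addition) are meaningful.
- Out of scope by design: computing reference electronic structure or
  MD trajectories, Duschinsky rotation and adiabatic vibronic models,
  time-dependent (correlation-function) band shapes, absolute intensity
  units, spatial-distribution-function rendering, and multi-dimensional
  treatments of the LAM.
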