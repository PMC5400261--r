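---
title: "Modeling coupled folding and binding with screened electrostatics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling coupled folding and binding with screened electrostatics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpbind)
```

## The model

`idpbind` simulates the binding of an intrinsically disordered peptide (IDP)
to a folded receptor with a coarse-grained, C-alpha structure-based ("Go-like")
model. Each residue is one bead at its C-alpha position. The Hamiltonian is

$$
V = \sum_{\mathrm{bonds}} \epsilon_r (r - r_0)^2
  + \sum_{\mathrm{angles}} \epsilon_\theta (\theta - \theta_0)^2
  + \sum_{\mathrm{dihedrals}} \sum_{n \in \{1,3\}} K_\phi(n)\,[1 - \cos(n(\phi - \phi_0))]
$$
$$
  + \sum_{\mathrm{contacts}} \epsilon_{ij}
      \left[ 5 \left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{12}
           - 6 \left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{10} \right]
  + \sum_{\mathrm{non\text{-}contacts}} \epsilon_{NC}
      \left(\tfrac{\sigma_{NC}}{r_{ij}}\right)^{12}
  + V_{DH},
$$

with $\epsilon_r = 100\,\epsilon/\text{Å}^2$, $\epsilon_\theta =
20\,\epsilon/\text{rad}^2$, $K_\phi(1) = \epsilon$, $K_\phi(3) =
0.5\,\epsilon$. Reference values $r_0, \theta_0, \phi_0, \sigma_{ij}$ come
from the native complex, so the landscape is minimally frustrated: only
native contacts attract. A unit note that matters: the conventional
C-alpha-model bond and angle constants are quoted in Ångström-based units;
internally all lengths are nm, so the bond constant is $10^4\,\epsilon\,
\mathrm{nm}^{-2}$. Quoting them in nm-based units unchanged would give bonds
whose thermal fluctuations (~0.07 nm) rival the bond length itself.

**Flavoring.** Contact strengths are modulated by residue chemistry through
the Miyazawa–Jernigan statistical contact energies:
$\epsilon_{ij} = \gamma\,(e_{ij}/\bar e - 1) + 1$, where $e_{ij}$ is the
magnitude of the tabulated contact energy for the two residue types and
$\bar e$ its mean over the system's native pairs. At $\gamma = 1$ (the
"flavored" default) the mean strength is exactly 1 by construction — an
identity the tests exploit — and at $\gamma = 0$ the model is unflavored.
The ratio form only makes sense on positive numbers, which is why magnitudes
of the (negative) published energies are used. Intermolecular strengths are
scaled by $\beta$ (the binding-affinity calibration knob) and IDP-internal
strengths by $\alpha$ (default 1).

**Electrostatics.** Lys/Arg beads carry $+e$, Asp/Glu $-e$ (termini carry no
charge in the simulation model; they enter only the sequence-level pair
counting, where the printed combinatorics require them). Charged pairs other
than directly bonded ones interact through a Debye–Hückel potential

$$
V_{DH} = \Gamma_{DH} K_{coulomb} B(\kappa) \sum_{i<j}
  \frac{q_i q_j\, e^{-\kappa r_{ij}}}{\epsilon_d\, r_{ij}},
$$

with $K_{coulomb} = 138.94$ kJ mol$^{-1}$ nm e$^{-2}$, dielectric
$\epsilon_d = 80$, and $\kappa = 3.2\sqrt{C_{salt}}$ nm$^{-1}$ — 1.24
nm$^{-1}$ at physiological 0.15 M. The scale factor $\Gamma_{DH}$ is
calibrated so that two unit opposite charges at 0.5 nm contribute exactly
one native-contact energy (1 kJ/mol), which gives $\Gamma_{DH} = 0.535$;
`calibrate_gamma_dh()` solves this closed form. $B(\kappa) = 1$ by default:
back-solving the calibration condition with the printed numbers requires
$B \approx 1$, and a finite-ion-size coefficient can be supplied through
`electrostatic_params()` if wanted. Energy bookkeeping sets $1\,\epsilon
\equiv 1$ kJ/mol so this calibration is satisfied literally.

## Building a topology

`read_calpha_structure()` reads a (multi-model) PDB through `bio3d`, taking
one bead per residue, resolving alternate locations by occupancy, and
failing loudly on residues without a C-alpha. Short missing stretches of a
helical ligand can be rebuilt with `extend_helix()`, which continues the
chain on an ideal alpha-helix (rise 1.5 Å, 100° per residue, radius 2.3 Å)
using internal-coordinate placement — an explicit geometric stand-in for
manual model building, refused beyond 20 residues where extrapolation has no
support.

The native contact map is a documented simplification of shadow-style
algorithms: a cutoff map (default 9 Å between C-alphas, intra-chain pairs
only at sequence separation ≥ 4) with an optional geometric occlusion
filter (`screening = TRUE`) that removes pairs whose connecting segment
passes within 1 Å of a third bead. This is deterministic and testable; the
cost is that contact counts differ somewhat from shadow-map counts of the
same structure, which is why such counts are treated as soft concordance
information rather than assertions.

## Dynamics

`run_langevin()` propagates BAOAB-discretized Langevin dynamics in reduced
units (lengths nm, energies $\epsilon$, masses 1, $k_B = 1$, time $\tau$).
Defaults: timestep $5\times10^{-4}\,\tau$, friction $1\,\tau^{-1}$,
temperature $1\,\epsilon/k_B$. None of these is dictated by the physics of
the model alone; they are standard, stable choices for stiff
structure-based bonds, and with friction 0 the integrator reduces to
velocity Verlet, which the energy-conservation tests use. Because the
thermostat and the $\tau\to$ seconds mapping are model conventions, absolute
rates are reported in $1/\tau$; only dimensionless ratios (fold-changes
between ionic-strength arms) are meaningful, and those are what the kinetic
analyses assert.

Biasing uses a smooth, differentiable fraction of intermolecular native
contacts $Q = N^{-1}\sum_{ij} [1 + e^{k(r_{ij} - \lambda\sigma_{ij})}]^{-1}$
(steepness 50 nm$^{-1}$, $\lambda = 1.5$), either as a harmonic umbrella or
as well-tempered metadynamics (Gaussians of initial height scaled by
$e^{-V_b/(k_B\Delta T)}$, $\Delta T = (\gamma_{bf}-1)T$). The engine keeps
the bias on a fine grid for O(1) per-step evaluation; the exact
deposited-Gaussian ledger is returned with every trajectory and is the
authoritative record used for reweighting. Analysis-side coordinates use the
hard-cutoff Q (formed iff $r < 1.2\,\sigma_{ij}$, the common structure-based
convention).

## Free energies

`wham_1d()` implements standard WHAM self-consistency (tolerance
$10^{-7}\,\epsilon$ on window free energies, $10^5$ iteration cap, an
explicit error naming any pair of adjacent windows without histogram
overlap). `reweight_metadynamics()` weights frames by
$e^{+V_b(\mathrm{cv}_t)/k_BT}$ under the final bias, after discarding an
initial filling fraction (default 10%, more for short runs); any recorded
coordinate can be histogrammed, not just the biased one.
`binding_free_energy()` takes basin windows on $Q_{inter}$ — unbound
$[0, 0.05]$, bound $[0.6, 0.8]$ around the bound-state minimum near 0.72 —
and forms $\Delta G$ by log-sum-exp over bins; no standard-state volume
correction is applied, so the value refers to the simulated effective
concentration set by the confinement sphere. Uncertainty, when block PMFs
are supplied, is the standard deviation of $\Delta G$ across final-segment
blocks.

Both estimators are validated against a particle in an analytic double well
(barrier 5 $\epsilon$, minima at $\pm 1$ nm), where the exact free energy is
the potential itself: WHAM recovers it within 0.3 $\epsilon$ and
metadynamics reweighting within 0.5 $\epsilon$ at the problem sizes the
tests run (15 umbrella windows of $3\times10^6$ steps; one $8\times10^6$-step
well-tempered run).

## Structural observables

Contact-formation analyses follow the two-tier distance rule: intra-IDP
charged contacts count 1.0 at $\le 4.5$ Å and 0.5 in (4.5, 6.0] Å;
intermolecular contacts count 1.0 at $\le 6.0$ Å and 0.5 in (6.0, 10.0] Å,
classified native/non-native (membership in the intermolecular native-pair
set) and opposite/same/non-electrostatic by bead charges. Helix content is
the fraction of C-alpha pseudo-dihedrals inside [30°, 70°] (the ideal helix
sits near +50°); this is a deliberate pseudo-dihedral rule, not DSSP.
Encounter complexes are segments of a trajectory opened when any
intermolecular distance reaches 10 Å while unbound and closed either by
release (all distances beyond 12 Å — the hysteresis prevents boundary
chatter) or by commitment ($Q_{inter} \ge 0.6$). The 10/12 Å values align
with the 10 Å partial-contact ceiling of the contact rule; they are this
package's concrete realization of an encounter-complex definition the
literature leaves informal, so encounter-population statistics should be
read as definition-dependent.

## Kinetics

Each kinetic trajectory starts from `generate_unbound_start()` — receptor
native, ligand re-grown as a self-avoiding coil at least 2 nm from the
receptor inside a 4 nm confinement sphere, briefly relaxed by clamped
steepest descent so that a freshly grown coil never starts on the repulsive
core of an IDP-internal native pair — and runs until the commit threshold or
a step cap. `extract_timeline()` reduces encounter segments to first-passage
quantities: time to bound ($FPT_{on}$), mean capture waiting time
($MPT_{cap}$, including the first capture from $t = 0$), and
capture-to-bound time of the successful segment ($FPT_{evo}$). Rates are
geometric means of reciprocal passage times, $\ln k = n^{-1}\sum \ln(1/\tau_i)$,
with the standard error of $\ln k$; the collision success probability is
bind/capture normalized by the no-charge arm. Trajectories that never bind
within the cap are censored: excluded from the rate estimate and always
reported as counts, a truncation that biases fold-changes toward 1 and is
therefore kept modest by the chosen cap.

## The synthetic mini-complex

Everything above is exercised without any structure download by a generated
fixture: a three-helix receptor bundle (15 beads per helix) with a groove,
and a 12-bead ideal-helix ligand docked in it, emitted as normalized PDB
text plus a machine-readable ground-truth sidecar (bead counts, charges,
native pairs at the builder cutoff, ideal observable values). The charge
pattern emulates the biology the method targets: an *acidic* disordered
ligand (five $-e$ beads, one $+e$) binding a *basic* groove (five $+e$, one
$-e$), with three complementary native pairs and an acidic N-terminal
cluster whose basic receptor counterparts lie just outside the native
contact set. The net-charge complementarity matters: electrostatic steering
of capture is a monopole-dominated effect, and a fixture with balanced
(near-zero net) charges exhibits essentially no ionic-strength dependence
of its binding kinetics — which would defeat the purpose of a fixture built
to exercise exactly that analysis. What the fixture does *not* emulate:
real secondary-structure propensities, sequence-specific flavoring patterns,
receptor flexibility on binding, or the size of a real complex. Passing
tests on the fixture therefore validate the machinery (energies, sampling,
estimators, classifications), not any biological prediction.

Study conditions used by the stochastic acceptance checks (chosen once as
realistic desk-scale conditions and stated here as the package's own
problem sizes): kinetics arms of $n = 50$ trajectories each (no-charge,
zero-charge control, 10 mM, 250 mM) with a $2.5\times10^5$-step cap, record
stride 25, confinement radius 4 nm; thermostat and energy-conservation
checks on the analytic toys at $10^5$ and $10^4$ steps; the double-well
free-energy recoveries at the window/run lengths quoted above.

## Numerical choices and degenerate inputs

Angles are rejected as collinear below $\sin^2\theta = 10^{-12}$; dihedrals
with degenerate cross products name the four beads; contact and
excluded-volume terms guard $r \to 0$; coincident charged beads are an
error rather than an infinity. The integrator aborts with a diagnostic at
$|V| > 10^6\,\epsilon$ rather than overflowing silently. Trajectories are
bit-reproducible for a fixed seed on a single thread, and the unbound-start
generator consumes an isolated RNG stream so it does not perturb the
caller's RNG state.

## Known limitations

* Absolute time and absolute binding free energies are convention-bound:
  no $\tau\to$ ps mapping, no standard-state correction, no $K_d$.
* The contact map is a cutoff map; shadow-map contact counts on real
  structures will differ.
* The Uversky-plane placement depends on the hydropathy scale; the
  Kyte–Doolittle/window-5 choice is documented but other scales shift the
  mean hydrophobicity.
* Electrostatics uses a uniform dielectric and point charges on C-alphas;
  no desolvation, no finite-ion-size default.
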