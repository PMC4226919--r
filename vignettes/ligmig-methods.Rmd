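---
title: "Competitive ligand migration by Metropolis Monte Carlo: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive ligand migration by Metropolis Monte Carlo: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligmig)
```

## The question the package addresses

A histamine-binding lipocalin — an antiparallel beta-barrel with acidic,
Asp-rich loops capping both mouths — competes with histamine's own
G-protein-coupled receptor for free histamine. The experimental readout of
that competition is a *receptor-preference statistic*: the percentage of
clustered ligand-exploration trajectories that end up around one receptor
rather than the other, as a function of the ligand's protonation state
(net charge 0, +1, or +2). `ligmig` implements a desk-scale version of the
whole protocol: a Metropolis Monte Carlo ligand-migration engine with a
simplified nonbonded energy model, the competitive two-receptor assembly,
trajectory filtering, quality-threshold pose clustering, and the
preference statistic — together with a coarse-grained fixture generator
that reproduces the *mechanistic contrast* (acidic barrel vs neutral
barrel vs single-pocket receptor) without requiring any structure
downloads or a production force field.

The package deliberately does **not** attempt to reproduce absolute
binding energies. A full OPLS force field with a generalized Born solvent
is replaced by Lennard-Jones 12-6 plus screened Coulomb terms (next
section); everything tied to absolute energy scales is therefore asserted
as a *property* (signs, orderings, symmetries), never as a number in
kcal/mol.

## Energy model

Every atom (or pseudo-atom bead) carries an element-based Lennard-Jones
class and a point charge. For a pair $i,j$ at distance $r$:

$$E_{ij}(r) \;=\; 4\varepsilon_{ij}\!\left[\left(\tfrac{\sigma_{ij}}{r}\right)^{12}
 - \left(\tfrac{\sigma_{ij}}{r}\right)^{6}\right]
 \;+\; \frac{k\, q_i q_j}{\epsilon(r)\, r},
 \qquad \epsilon(r) = 4r,$$

with Lorentz–Berthelot combining
($\sigma_{ij} = (\sigma_i+\sigma_j)/2$,
$\varepsilon_{ij} = \sqrt{\varepsilon_i \varepsilon_j}$) and
$k = 332.06$ kcal Å mol$^{-1}$ e$^{-2}$. The distance-dependent dielectric
$\epsilon(r) = 4r$ is the classic implicit-solvent proxy: it screens
charge–charge interactions as $1/r^2$, which preserves the *qualitative*
electrostatic asymmetry between an acidic and a neutral surface — the
property the competitive readout rests on — while keeping interaction
ranges short. All pair energies are shifted so they reach exactly zero at
the 12 Å cutoff (energy-shift, not switch, for continuity). Pairs within
one residue are excluded from intra-structure sums, standing in for a
bonded topology.

The receptor–ligand interaction energy is the decomposition
$E = E_{AB} - (E_A + E_B)$; with rigid bodies this equals the sum of all
receptor-atom × ligand-atom pair energies, and the identity holds to
machine precision by construction. The energy evaluators also return
analytic per-atom gradients (one extra vector operation per distance
pass), which the pose minimizer consumes.

Defaults (`ff_params()`): $\varepsilon$ = 0.066/0.17/0.21/0.25/0.03
kcal/mol and $\sigma$ = 3.5/3.25/2.96/3.5/2.5 Å for C/N/O/S/H, a generic
bead class "X" (0.1, 3.5), cutoff 12 Å. All of it is configurable per run.

## The Monte Carlo propagator

Each chain step performs the three-stage move the migration protocol
prescribes:

1. **Perturbation** — a rigid-body move of the ligand: rotation about its
   centroid by an angle uniform in $[0, \texttt{rot\_r}\cdot\pi]$ about a
   uniform random axis, then a translation uniform in the ball of radius
   `tra_r` (12 Å for free migration).
2. **Side-chain sampling** (optional; induced-fit mode) — residues with
   any atom within `sprad` = 6 Å of the ligand receive small random
   rigid displacements, rejected individually if they create an internal
   clash (< 1.5 Å).
3. **Minimization** — deterministic rigid-body relaxation of the 6 pose
   degrees of freedom: Polak–Ribière conjugate gradient on the analytic
   force/torque, with backtracking line search (default 20 iterations,
   tolerance 0.01 kcal/mol). The returned pose never has higher energy
   than its input.

The **Metropolis criterion** then compares the minimized proposal against
the *previous accepted* energy: downhill or equal moves are always
accepted, uphill moves with probability $e^{-\Delta E / k_BT}$. The
protocol description could also be read as comparing against the *initial*
energy; that reading does not yield a proper Markov chain, so the standard
previous-state reference is used. The default temperature is
$k_BT = 0.596$ kcal/mol (300 K) — the protocol never states one — and
setting `temperature_kT = 0` recovers the literal greedy
accept-if-not-worse rule. In competitive mode the Metropolis energy is the
ligand's total interaction energy summed over both receptors (the
protocol does not say whether total or nearest-receptor energy is used;
the total is the only choice that makes the two-receptor system a single
well-defined target distribution).

### Spawning (confined active-site exploration)

When an accepted pose first brings the ligand COM within `spawn_trigger`
of a receptor COM, the chain *spawns*: migration halts and a second,
confined task starts. The ligand is placed just inside the exploration
sphere (radius `spawn_radius` around that receptor's COM), relaxed, and
from then on any proposal leaving the sphere is rejected outright. The
confined task uses its own, much smaller move scale (`spawn_tra_r` =
0.35 Å, `spawn_rot_r` = 0.05): active-site exploration is a local search,
and these two values are the package's calibration point for the standard
~30% Metropolis acceptance rate that the migration protocol was tuned to
(see *Operating point* below). Spawning is permanent for a chain — the
token records which receptor captured it.

Chains are embarrassingly parallel and deterministic: chain $c$ of a run
with seed $s$ uses RNG stream $s + c$, so sequential and parallel
execution are bitwise identical, and every experiment is reproducible
from its seed alone. Only accepted states are appended to a trajectory,
each frame carrying the interaction energy, the per-receptor split, and
the COM distances to both receptors.

## Synthetic fixtures

The generator builds pseudo-atom (bead) receptors at ~40 beads each —
enough geometry to have mouths, cavities and rims, small enough that a
full competitive experiment runs in seconds:

* **acidic_barrel** — five staggered 8-bead rings (radius 4 Å, length
  10 Å) with a 3-bead floor closing the lower mouth; `n_rim_charges` = 6
  beads of charge −1 on the open-mouth rim emulate the Asp-rich loop. With
  `has_second_site = TRUE` an extra −1 bead sits in the closed-mouth
  pocket (the two-site barrel that sequesters two ligands).
* **neutral_barrel** — the *matched control*: bitwise-identical
  coordinates for the same seed, all charges zero. Any preference
  difference between the two is attributable to electrostatics alone —
  the clean synthetic reduction of comparing a structurally similar but
  non-acidic barrel.
* **pocket_receptor** — a hemispherical cavity with one buried −1 site,
  the minimal analog of an aminergic receptor pocket.
* **small_globule** — a compact neutral bead shell (false-positive
  control role).

The ligand is a rigid 4-bead histamine analog: a ring bead pair, a linker,
and an amine-terminus nitrogen. Protonation states map to net charges
0 / +1 / +2; the +2 state is read *cumulatively* (amine +1 **and** ring
+1), since further protonation of the imidazole nitrogen adds to an
already-protonated amine. This cumulative reading is a documented choice —
the alternative (+1 on the imidazole only) is exposed by assigning charges
manually.

### Assembly and orientation

`assemble_system()` reproduces the competitive starting geometry: receptor
COMs 67 Å apart, every free ligand COM on the perpendicular bisector plane
at 42 Å from both COMs, with the placement angle drawn from the seed (the
protocol fixes only distances, never a direction). The desk-scale geometry
(`scaled = TRUE`) is 24 Å / 14 Å — chosen to preserve the full protocol's
receptor-size : separation ratio (~0.6 at both scales) so that, as in the
full-scale runs, only a small minority of chains diffuse away without
reaching either receptor. `make_competition_fixture()` also rotates each
receptor so its binding mouth faces the other receptor (`orient_mouths`),
making both binding sites accessible from the equidistant start point;
without this the capture statistics degenerate into a first-touch lottery
on neutral surface beads.

With the scaled geometry the spawning distances scale coherently too:
`desk_mc_config()` sets trigger 6 Å / radius 5 Å. At bead scale the
receptors are only ~7 Å in radius, so the full-scale 10 Å trigger would
fire on any surface graze; 6 Å fires only on genuine entry into a mouth or
pocket, which is what the full-scale trigger means for a 40 Å protein.

## Filtering, clustering, preference

`filter_frames()` applies the protocol's three cuts, with per-rule
accounting: the first 100 accepted frames of each chain (burn-in toward a
stable energy), frames farther than 100 Å from every receptor COM, and
frames with interaction energy ≥ 0 kcal/mol. Filtering is idempotent.

`cluster_frames()` is greedy quality-threshold clustering on ligand COM
positions of every 10th pooled frame with a 5 Å cutoff, at most 10
clusters: repeatedly take the point with the most neighbors within the
cutoff (ties: lowest frame id), extract it with its neighbors, stop when
only neighborless singletons remain (these stay unassigned). Clusters are
ranked by member count. The cluster metric is COM distance, not per-atom
RMSD — migration frames differ mainly by position. The original analysis
used a visualization tool whose clustering semantics are not fully
documented; the greedy rule above is therefore pinned by an independent
brute-force oracle in the test suite rather than by that tool.

`assign_clusters()` gives each cluster to the receptor whose COM is nearer
its centroid (ties within 1e-6 Å stay unassigned), and `preference()`
reports $100 \cdot c_B / (c_A + c_B)$ over the member counts of assigned
clusters. Percentages are reported at printed precision: rounded to one
decimal, then half-up to an integer. This convention reproduces *all four*
published percentages from their printed per-cluster counts (e.g.
360/567 = 63.49% → 63.5 → 64); plain nearest-integer rounding would give
63 for that case and is therefore demonstrably not the convention the
published arithmetic used.

## Experiment modes

* **individual** — one receptor deleted from the assembly; the ligand
  explores the remaining one (control that the engine samples an active
  site unaided).
* **competitive** — both receptors; the preference statistic is the
  endpoint.
* **induced_fit** — refinement around an already-bound ligand: the bound
  pose is frozen into its receptor (it contributes to that receptor's side
  of the interaction energy), side-chain sampling switches on, `rot_r`
  rises to 0.5, and spawning is restricted to the target receptor.
* **sequential binding** — after each competitive round, the
  "lowest-energy frame farthest from the competitor" is frozen as bound
  and the next ligand explores the updated system. The descriptive rule is
  made deterministic lexicographically: restrict to the quartile of frames
  farthest from the competitor COM, then take the energy minimum.

## Operating point and problem sizes

The migration protocol was explicitly tuned so that roughly 30% of
Metropolis steps are accepted — a standard operating point for this class
of sampler. In this engine the pooled acceptance is controlled by the
confined-task move scale (free migration through empty space accepts
nearly everything, deep-well exploration very little; the mixture is set
by `spawn_tra_r`/`spawn_rot_r`). The defaults are calibrated on the
standard desk-scale fixture — pocket receptor vs acidic barrel,
amine-protonated ligand, 8 chains × 2000 steps — to land the pooled
fraction near that operating point.

The package's standard experiment sizes, used throughout the tests and
the acceptance script, are: 8 chains × 2000 steps per charge state for
the protonation-trend experiment; 8 chains × 800 steps per seed across
12 seeds for the twin-receptor no-bias control. These sizes are the
desk-scale analog of the full protocol's 48 CPUs × 2000 steps and keep a
complete run in the minutes range on a single core.

## What passing tests do and do not show

The synthetic fixtures reproduce the *mechanism* the competitive readout
isolates — an acidic multi-charge mouth versus a neutral matched control
versus a single buried site, a ligand whose net charge rises with
protonation — under the real protocol's sampling machinery. They do not
reproduce: lipocalin topology, side-chain rotamer statistics, absolute
binding energies, solvent structure, or the published per-cluster
trajectory counts (which depend on the production force field). The tests
therefore pin (i) exact arithmetic and geometry, (ii) closed-form
statistical behavior of the sampler, (iii) sign/ordering properties of
the electrostatic mechanism, and (iv) qualitative reproduction of the
published preference *trend* across protonation states — and nothing
about absolute energetics.

## Numerical choices and degenerate inputs

* Center of mass is mass-weighted over heavy atoms by default (hydrogens
  excluded); the original workflow does not state its weighting, so ±0.5 Å
  is the tolerance used wherever a printed COM distance is compared.
* The minimizer stops on `minimize_iters`, a gradient norm below 1e-8, two
  consecutive sub-tolerance improvements, or a failed line search; it
  never returns a pose worse than its input.
* `perturb_ligand` composes rotation before translation; with both radii
  zero the pose is returned bitwise unchanged.
* Equidistant placement requires `ligand_offset >= separation/2`; the
  degenerate equality puts the ligand exactly at the midpoint.
* PDB output is fixed-column v3; HETATM is used for all non-standard
  residues; alternate locations other than blank/'A' are dropped on input;
  charges travel in a sidecar CSV because the PDB format has no charge
  column with usable precision.
* Cluster ranking ties break on the lowest member frame id; preference
  needs at least one assigned cluster and errors otherwise.

## Known limitations

* Receptors are rigid during migration (side-chain sampling is local and
  optional); there are no backbone modes.
* The bead ligand cannot express internal flexibility or tautomers.
* Preference at desk scale is computed from 8 chains, so individual runs
  carry sampling noise of order ±10 percentage points; the test suite
  works with fixed seeds and, for the no-bias control, averages over
  seeds.
* The energy model's absolute scale is arbitrary; only signs, orderings
  and symmetries are meaningful.
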