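# ligmig

Monte Carlo ligand migration between two competing receptors, at desk
scale.

A histamine-binding lipocalin — a β-barrel whose mouths are capped by
acidic, Asp-rich loops — can outcompete histamine's own receptor for free
histamine, and the competition sharpens as the ligand's protonation state
(net charge 0 → +1 → +2) rises. `ligmig` re-implements the simulation
protocol behind that readout for anyone who wants to study
competitive-binding statistics without a production force field or any
structure downloads:

* a **PELE-style Metropolis Monte Carlo propagator**: rigid-body ligand
  perturbation → optional side-chain sampling → analytic-gradient pose
  minimization → Metropolis acceptance against the previous accepted
  energy, with *spawning* (confined active-site exploration once the
  ligand first approaches a receptor's center of mass);
* a **simplified nonbonded energy model**: Lennard-Jones 12-6 with
  Lorentz–Berthelot combining plus screened Coulomb with a
  distance-dependent dielectric ε(r) = 4r, shifted to zero at a 12 Å
  cutoff, with the interaction-energy decomposition
  `E = E_AB − (E_A + E_B)`;
* **synthetic coarse-grained fixtures**: an acidic barrel with a charged
  mouth rim, a coordinate-identical neutral control barrel, a
  single-pocket receptor, and a rigid 4-bead histamine analog whose net
  charge follows its protonation state (0 / +1 / +2);
* the full **analysis protocol**: burn-in/distance/energy trajectory
  filters, stride-and-cutoff quality-threshold pose clustering,
  cluster-to-receptor assignment, and the receptor-preference percentage;
* PDB I/O (multi-model for trajectories), CSV/JSON outputs, and a small
  command-line wrapper (`inst/cli/ligmig.R`) with YAML run configs.

The methods vignette (`vignettes/ligmig-methods.Rmd`) documents the model,
its assumptions, every tunable with units and defaults, and what the
desk-scale experiments do and do not show about the full-scale system.

## Worked example

A competitive experiment on the standard desk-scale fixture — pocket
receptor (A) versus acidic barrel (B), amine-protonated (+1) ligand —
followed by the full analysis:

```r
library(ligmig)

sys <- make_competition_fixture(
  fixture_spec("pocket_receptor", seed = 3),
  fixture_spec("acidic_barrel", seed = 2),
  state = "amine_protonated", seed = 1, scaled = TRUE)
sys
#> <ligmig_system> A: 41 atoms (q=-1.0), B: 43 atoms (q=-6.0), 1 free ligand(s), 0 bound; sep 24.0 A, offset 14.0 A

spec <- run_spec("competitive", sys,
                 desk_mc_config(steps = 2000, n_chains = 8, seed = 1),
                 filters = desk_filter_spec())
ts <- run_experiment(spec)
ts
#> <ligmig_trajset> competitive: 8 chains, 5148 accepted frames, pooled acceptance 32.2%

flt <- filter_frames(ts)
cl  <- assign_clusters(cluster_frames(flt), sys)   # stride 10, 5 A cutoff
preference(cl)
#> <ligmig_preference> A: 189, B: 833 (of 1022) -> 82% preference for B
```

Reading the output: the system holds two ~40-bead receptors 24 Å apart
with the +1 ligand equidistant at 14 Å; 8 independent chains of 2000
steps accept 32% of their proposed moves (the engine's standard operating
point is ~30%, mixing near-free migration with confined active-site
exploration); after filtering, every 10th frame is clustered at a 5 Å
cutoff and each cluster is assigned to the receptor whose COM is nearer.
The preference percentage — occupancy-weighted cluster counts for
receptor B over the total — says how strongly the charged ligand favors
the acidic barrel: 82% at +1 in this run. Rerunning with
`state = "deprotonated"` drops the preference to ~23% (the neutral ligand
favors the geometric pocket), and `"imidazole_protonated"` raises it to
100% — the protonation trend the competitive protocol is designed to
expose.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/ligmig.R simulate --config run.yml --out-dir out/
Rscript inst/cli/ligmig.R analyze --frames out/frames.csv \
        --record out/run_record.json --out-dir out/
```

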