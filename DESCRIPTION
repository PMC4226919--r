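Package: ligmig
Title: Monte Carlo Ligand Migration and Competitive Receptor Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale Metropolis Monte Carlo engine for unconstrained
    ligand migration between two competing receptors, with a simplified
    nonbonded energy model (Lennard-Jones 12-6 plus screened Coulomb with a
    distance-dependent dielectric), rigid-body pose minimization, optional
    side-chain sampling, and spawning (confined active-site exploration).
    Includes a coarse-grained fixture generator emulating an acidic
    two-mouthed lipocalin barrel, a matched neutral-barrel control, and a
    single-pocket receptor; a histamine-like ligand whose net charge tracks
    its protonation state (0/+1/+2); trajectory filtering; quality-threshold
    pose clustering; and receptor-preference statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
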