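test_that("ligand perturbation is rigid, bounded, and identity at zero", {
  x <- coords(make_ligand("deprotonated"))
  set.seed(5)
  expect_identical(perturb_ligand(x, 0, 0), x)
  d0 <- as.matrix(dist(x))
  for (i in 1:20) {
    y <- perturb_ligand(x, tra_r = 3, rot_r = 0.5)
    # rigid: all intra-ligand distances preserved
    expect_equal(as.matrix(dist(y)), d0, tolerance = 1e-9)
    # bounded: centroid displacement never exceeds tra_r
    expect_lte(sqrt(sum((colMeans(y) - colMeans(x))^2)), 3 + 1e-9)
  }
})

test_that("metropolis criterion accepts downhill always, greedy at kT = 0", {
  set.seed(1)
  expect_true(metropolis_accept(-5, -5, 0.596))   # equal -> accept
  expect_true(metropolis_accept(-6, -5, 0.596))   # downhill -> accept
  for (i in 1:100) {
    e <- sort(rnorm(2))
    expect_true(metropolis_accept(e[1], e[2], 0))   # downhill at kT = 0
    expect_false(metropolis_accept(e[2] + 1e-9, e[2], 0))  # uphill rejected
  }
  expect_error(metropolis_accept(NaN, 0, 1), class = "ligmig_domain_error")
})

test_that("uphill acceptance frequency follows the Boltzmann factor", {
  kT <- 0.596
  set.seed(99)
  n <- 20000
  acc <- vapply(seq_len(n), function(i) metropolis_accept(kT, 0, kT),
                logical(1))
  expect_equal(mean(acc), exp(-1), tolerance = 0.015)
})

test_that("rigid-body minimization descends and finds the LJ contact", {
  params <- ff_params()
  # 1-bead ligand against a 1-site receptor: radially symmetric problem
  # with known optimum r* = 2^(1/6) * sigma for neutral beads
  rec <- toy_structure(c(0, 0, 0))
  lig <- toy_structure(c(6, 0, 0), chain = "L")
  ev <- ligmig:::cross_evaluator(rec$atoms, lig$atoms, params)
  out <- minimize_ligand(coords(lig), ev, max_iters = 200, tol = 1e-8)
  sig <- params$lj$sigma[params$lj$class == "C"]
  expect_equal(sqrt(sum(out$xyz^2)), 2^(1 / 6) * sig, tolerance = 1e-2)
  # descent contract on random starts (plain function, numeric gradient)
  f <- function(x) sum((x - 1)^2)
  set.seed(2)
  for (i in 1:5) {
    x0 <- matrix(rnorm(6, sd = 3), 2, 3)
    res <- minimize_ligand(x0, f, max_iters = 10, tol = 1e-6)
    expect_lte(res$energy, f(x0))
  }
  # starting at a flat point the pose is returned unchanged
  flat <- function(x) 0
  x0 <- matrix(rnorm(6), 2, 3)
  expect_equal(minimize_ligand(x0, flat, 10, 1e-6)$xyz, x0)
  expect_error(minimize_ligand(x0, function(x) NaN, 5, 1e-6),
               class = "ligmig_domain_error")
})

test_that("spawn domain tokens follow trigger distances", {
  cfg <- mc_config(seed = 1)
  expect_identical(spawn_check(42, 42, cfg), "unconstrained")
  expect_identical(spawn_check(9, 42, cfg), "a")
  expect_identical(spawn_check(42, 9.5, cfg), "b")
  # an existing capture is permanent
  expect_identical(spawn_check(42, 42, cfg, captured = "a"), "a")
})

test_that("chains are deterministic and respect the spawning constraint", {
  sys <- standard_fixture(seed = 4)
  cfg <- mc_config(steps = 150, seed = 21)
  tr1 <- run_chain(sys, 1, cfg, chain_id = 1)
  tr2 <- run_chain(sys, 1, cfg, chain_id = 1)
  expect_identical(tr1$frames, tr2$frames)
  expect_identical(tr1$coords, tr2$coords)
  # a different chain id gives a different stream
  tr3 <- run_chain(sys, 1, cfg, chain_id = 2)
  expect_false(identical(tr1$frames, tr3$frames))
  # no accepted frame violates an active spawning constraint
  for (tr in list(tr1, tr3)) {
    fr <- tr$frames
    if (any(fr$spawned)) {
      first <- which(fr$spawned)[1]
      post <- fr[first:nrow(fr), ]
      d <- if (tr$captured == "a") post$dist_a else post$dist_b
      expect_true(all(d <= cfg$spawn_radius + 1e-9))
    }
  }
  # step indices strictly increasing
  expect_true(all(diff(tr1$frames$step) > 0))
})

test_that("a single zero-move step leaves the start pose unchanged", {
  sys <- standard_fixture(seed = 4)
  cfg <- mc_config(steps = 1, tra_r = 0, rot_r = 0, minimize_iters = 0,
                   seed = 3)
  tr <- run_chain(sys, 1, cfg, chain_id = 1)
  expect_lte(nrow(tr$frames), 1L)
  if (nrow(tr$frames) == 1L)
    expect_equal(tr$coords[[1]], coords(sys$ligands[[1]]), tolerance = 1e-12)
})

test_that("acceptance rate is monotone non-decreasing in kT", {
  # fixed proposal-energy pairs; empirical acceptance per temperature
  set.seed(17)
  e_ref <- rnorm(200)
  e_new <- e_ref + rexp(200)   # uphill proposals
  accs <- vapply(c(0, 0.3, 0.596, 2, 10), function(kT) {
    set.seed(123)  # common random numbers: acceptance is pointwise monotone
    mean(vapply(seq_along(e_new), function(i)
      metropolis_accept(e_new[i], e_ref[i], kT), logical(1)))
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_identical(accs[1], 0)  # greedy limit rejects all uphill
})

test_that("side-chain sampling is local and clash-free", {
  rec <- make_receptor(fixture_spec("acidic_barrel", seed = 2))
  lig_xyz <- matrix(c(0, 0, 8, 1, 0, 8, 0, 1, 8, 1, 1, 8), 4, 3,
                    byrow = TRUE)
  set.seed(8)
  out <- sample_side_chains(rec, lig_xyz, sprad = 4)
  x0 <- coords(rec); x1 <- coords(out)
  moved <- rowSums((x1 - x0)^2) > 0
  if (any(moved)) {
    # only residues with an atom within sprad of the ligand may move
    res <- paste(rec$atoms$chain, rec$atoms$resno)
    near <- apply(x0, 1, function(p)
      min(sqrt(colSums((t(lig_xyz) - p)^2))) <= 4)
    near_res <- unique(res[near])
    expect_true(all(res[moved] %in% near_res))
    # no internal clash introduced beyond what the input already had
    expect_gte(min(dist(x1)), min(1.5, min(dist(x0))) - 1e-9)
  }
  # ligand far away: receptor untouched
  far <- sample_side_chains(rec, lig_xyz + 100, sprad = 4)
  expect_identical(coords(far), x0)
})

test_that("config validation enforces the documented invariants", {
  expect_error(mc_config(steps = 0), class = "ligmig_config_error")
  expect_error(mc_config(tra_r = -1), class = "ligmig_config_error")
  expect_error(mc_config(spawn_radius = 11, spawn_trigger = 10),
               class = "ligmig_config_error")
  expect_error(mc_config(temperature_kT = -0.1),
               class = "ligmig_config_error")
})
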