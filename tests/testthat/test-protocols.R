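make_toy_trajset <- function(frames_list) {
  trajs <- lapply(seq_along(frames_list), function(i) {
    fr <- frames_list[[i]]
    structure(list(chain_id = i, frames = fr,
                   coords = rep(list(matrix(0, 1, 3)), nrow(fr)),
                   captured = "unconstrained",
                   n_proposed = nrow(fr), n_accepted = nrow(fr),
                   config_fingerprint = ""),
              class = "ligmig_trajectory")
  })
  structure(list(trajectories = trajs, system = NULL, config = NULL,
                 mode = "competitive", filters = filter_spec(),
                 filtered = FALSE),
            class = "ligmig_trajset")
}

toy_frames <- function(dist_a, dist_b, e) {
  n <- length(e)
  data.frame(chain = 1L, step = seq_len(n), e_interaction = e,
             e_a = e / 2, e_b = e / 2, dist_a = dist_a, dist_b = dist_b,
             com_x = 0, com_y = 0, com_z = 0,
             spawned = FALSE, accepted = TRUE, dwell = 1)
}

test_that("filters drop far, unfavorable and burn-in frames with full accounting", {
  fr <- toy_frames(dist_a = c(10, 150, 20, 30, 40),
                   dist_b = c(12, 160, 25, 35, 45),
                   e = c(-5, -1, 3, -2, -4))
  ts <- make_toy_trajset(list(fr))
  out <- filter_frames(ts, filter_spec(burn_in = 0))
  rep <- attr(out, "report")
  expect_equal(rep$kept, 3L)             # one too far, one at +3 kcal/mol
  expect_equal(rep$dropped_distance, 1L)
  expect_equal(rep$dropped_energy, 1L)
  expect_equal(rep$kept + rep$dropped_burn_in + rep$dropped_distance +
                 rep$dropped_energy, rep$total)
  kept <- collect_frames(out)
  expect_equal(kept$step, c(1L, 4L, 5L))
})

test_that("burn-in larger than a chain empties it with a warning", {
  fr <- toy_frames(rep(10, 90), rep(12, 90), rep(-1, 90))
  ts <- make_toy_trajset(list(fr))
  expect_warning(out <- filter_frames(ts, filter_spec(burn_in = 100)),
                 "burn-in")
  expect_equal(nrow(collect_frames(out)), 0L)
})

test_that("filtering is idempotent", {
  fr <- toy_frames(dist_a = runif(200, 5, 120), dist_b = runif(200, 5, 120),
                   e = rnorm(200))
  ts <- make_toy_trajset(list(fr))
  once <- filter_frames(ts, filter_spec(burn_in = 20))
  twice <- filter_frames(once, filter_spec(burn_in = 20))
  expect_identical(collect_frames(once), collect_frames(twice))
})

test_that("run specs validate mode/receptor combinations", {
  sys <- standard_fixture(seed = 2)
  expect_s3_class(run_spec("competitive", sys), "ligmig_runspec")
  expect_error(run_spec("individual", sys), class = "ligmig_config_error")
  expect_error(run_spec("induced_fit", sys), class = "ligmig_config_error")
  rec <- make_receptor(fixture_spec("acidic_barrel", seed = 1))
  isys <- individual_system(rec, make_ligand("amine_protonated"),
                            ligand_offset = 14, seed = 1)
  expect_s3_class(run_spec("individual", isys), "ligmig_runspec")
  expect_error(run_spec("competitive", isys), class = "ligmig_config_error")
})

test_that("competitive experiments are reproducible from their seed", {
  sys <- standard_fixture(seed = 2)
  spec <- run_spec("competitive", sys, mc_config(steps = 60, n_chains = 2,
                                                 seed = 5))
  a <- run_experiment(spec)
  b <- run_experiment(spec)
  expect_identical(collect_frames(a), collect_frames(b))
})

test_that("individual-mode trajectories never reference the absent receptor", {
  rec <- make_receptor(fixture_spec("acidic_barrel", seed = 1))
  isys <- individual_system(rec, make_ligand("amine_protonated"),
                            ligand_offset = 14, seed = 1)
  spec <- run_spec("individual", isys, mc_config(steps = 120, n_chains = 2,
                                                 seed = 5))
  ts <- run_experiment(spec)
  fr <- collect_frames(ts)
  expect_gt(nrow(fr), 0L)
  expect_true(all(is.na(fr$dist_b)))
  expect_true(all(fr$e_b == 0))
})

test_that("an individual run reaches the receptor's spawning zone", {
  rec <- make_receptor(fixture_spec("acidic_barrel", seed = 1))
  isys <- individual_system(rec, make_ligand("amine_protonated"),
                            ligand_offset = 14, seed = 1)
  cfg <- mc_config(steps = 800, n_chains = 4, seed = 7)
  ts <- run_experiment(run_spec("individual", isys, cfg))
  mins <- vapply(ts$trajectories, function(t)
    if (nrow(t$frames)) min(t$frames$dist_a) else Inf, numeric(1))
  expect_true(any(mins <= cfg$spawn_trigger))
})

test_that("the sequential-binding selection rule is lexicographic", {
  # farthest quartile from the competitor first, then minimum energy
  fr <- data.frame(dist_b = c(10, 40, 35, 39),
                   e_interaction = c(-50, -5, -20, -10))
  expect_equal(select_binding_frame(fr, "b"), 2L)  # only 40 in top quartile
  fr2 <- data.frame(dist_b = c(40, 40, 40, 40),
                    e_interaction = c(-5, -30, -10, -30))
  expect_equal(select_binding_frame(fr2, "b"), 2L)  # min energy, first tie
  expect_error(select_binding_frame(fr[0, ], "b"),
               class = "ligmig_protocol_error")
})

test_that("sequential binding freezes a pose and updates the system", {
  sys <- standard_fixture(seed = 6)
  spec <- run_spec("competitive", sys,
                   mc_config(steps = 250, n_chains = 2, seed = 9),
                   filters = filter_spec(burn_in = 10))
  expect_error(run_sequential_binding(spec, 1), class = "ligmig_config_error")
  rounds <- run_sequential_binding(spec, 2, target = "b")
  expect_length(rounds, 2L)
  # the second round's system carries one bound ligand on the target side
  expect_length(rounds[[2]]$system$bound, 1L)
  expect_identical(attr(rounds[[2]]$system$bound[[1]], "receptor"), "b")
})

test_that("induced-fit refinement requires and uses a bound ligand", {
  sys <- standard_fixture(seed = 2)
  bound <- sys$ligands[[1]]
  bound <- ligmig:::translate_structure(
    bound, receptor_coms(sys)$b + c(0, 0, 6) - center_of_mass(bound))
  attr(bound, "receptor") <- "b"
  spec <- run_spec("induced_fit", sys,
                   mc_config(steps = 40, n_chains = 1, seed = 3),
                   bound_ligands = list(bound))
  ts <- run_experiment(spec)
  expect_identical(ts$mode, "induced_fit")
  expect_true(ts$config$side_chain_sampling)
  expect_equal(ts$config$rot_r, 0.5)
  expect_length(ts$system$bound, 1L)
})
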