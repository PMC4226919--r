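# The Monte Carlo propagator: ligand perturbation -> optional side-chain
# sampling -> rigid-body minimization -> Metropolis acceptance, with
# spawning (confined exploration once the ligand first approaches a
# receptor COM).

#' Monte Carlo run configuration
#'
#' Defaults follow the migration protocol: 2000 steps, ligand translation
#' radius \code{tra_r} = 12 A, side-chain perturbation radius \code{sprad} =
#' 6 A, spawning region radius 8 A triggered within 10 A of a receptor COM.
#' \code{rot_r} is a dimensionless magnitude scaling a [0, pi] rotation
#' angle (0.2 for migration; induced-fit refinement uses 0.5).
#' \code{temperature_kT} = 0.596 kcal/mol corresponds to 300 K; at kT = 0
#' the Metropolis rule reduces to greedy accept-if-not-worse.
#'
#' @param steps MC steps per chain (> 0).
#' @param tra_r max translation per move, Angstrom.
#' @param rot_r rotation magnitude (angle ~ U[0, rot_r * pi]).
#' @param sprad side-chain perturbation radius around the ligand, Angstrom.
#' @param spawn_radius confinement radius after spawning, Angstrom.
#' @param spawn_trigger COM distance that triggers spawning, Angstrom.
#' @param spawn_tra_r,spawn_rot_r move magnitudes once a chain is confined
#'   to a spawning region: the confined active-site exploration task uses
#'   much smaller steps than free migration, and their defaults are
#'   calibrated so the engine's pooled Metropolis acceptance sits at the
#'   standard ~30\% operating point.
#' @param n_chains independent chains per experiment.
#' @param temperature_kT kcal/mol.
#' @param side_chain_sampling enable receptor side-chain moves.
#' @param minimize_iters,minimize_tol rigid-body minimizer budget/tolerance.
#' @param seed integer; chain c uses stream seed + c.
#' @return object of class \code{ligmig_mcconfig}.
#' @export
mc_config <- function(steps = 2000, tra_r = 12, rot_r = 0.2, sprad = 6,
                      spawn_radius = 8, spawn_trigger = 10, spawn_tra_r = 0.35,
                      spawn_rot_r = 0.05, n_chains = 8,
                      temperature_kT = 0.596, side_chain_sampling = FALSE,
                      minimize_iters = 20, minimize_tol = 0.01, seed = 1) {
  if (steps <= 0) stop_config("steps must be > 0")
  if (tra_r < 0 || rot_r < 0) stop_config("tra_r and rot_r must be >= 0")
  if (spawn_radius > spawn_trigger)
    stop_config("spawn_radius must be <= spawn_trigger")
  if (temperature_kT < 0) stop_config("temperature_kT must be >= 0")
  if (spawn_tra_r < 0 || spawn_rot_r < 0)
    stop_config("spawn_tra_r and spawn_rot_r must be >= 0")
  cfg <- list(steps = as.integer(steps), tra_r = tra_r, rot_r = rot_r,
              sprad = sprad, spawn_radius = spawn_radius,
              spawn_trigger = spawn_trigger, spawn_tra_r = spawn_tra_r,
              spawn_rot_r = spawn_rot_r, n_chains = as.integer(n_chains),
              temperature_kT = temperature_kT,
              side_chain_sampling = isTRUE(side_chain_sampling),
              minimize_iters = as.integer(minimize_iters),
              minimize_tol = minimize_tol, seed = as.integer(seed))
  class(cfg) <- "ligmig_mcconfig"
  cfg
}

config_fingerprint <- function(config) {
  paste(vapply(config, function(v) paste(format(v), collapse = ","),
               character(1)), collapse = "|")
}

#' Random rigid-body perturbation of a ligand pose
#'
#' Rotation about the pose centroid by an angle uniform in
#' \code{[0, rot_r * pi]} about a uniformly random axis, followed by a
#' translation uniform in the ball of radius \code{tra_r}. Internal geometry
#' is preserved exactly (pure rigid motion).
#'
#' @param xyz n x 3 ligand coordinates.
#' @param tra_r,rot_r move magnitudes (see \code{\link{mc_config}}).
#' @return perturbed n x 3 coordinates.
#' @export
perturb_ligand <- function(xyz, tra_r, rot_r) {
  out <- xyz
  if (rot_r > 0) {
    axis <- stats::rnorm(3)
    angle <- stats::runif(1, 0, rot_r * pi)
    ctr <- colMeans(out)
    R <- rotation_matrix(axis, angle)
    out <- sweep(sweep(out, 2, ctr) %*% R, 2, -ctr, "-")
  }
  if (tra_r > 0) {
    dir <- stats::rnorm(3)
    dir <- dir / vnorm(dir)
    t <- dir * tra_r * stats::runif(1)^(1 / 3)
    out <- sweep(out, 2, -t, "-")
  }
  out
}

#' Metropolis acceptance decision
#'
#' Accept if the proposed energy is equal to or lower than the reference;
#' otherwise accept with probability \code{exp(-(e_new - e_ref) / kT)}. At
#' kT = 0 this is the literal greedy rule (uphill always rejected).
#'
#' @param e_new,e_ref proposed and reference energies, kcal/mol.
#' @param kT temperature in kcal/mol (>= 0).
#' @return logical.
#' @export
metropolis_accept <- function(e_new, e_ref, kT) {
  if (!is.finite(e_new) || !is.finite(e_ref))
    stop_domain("metropolis_accept: non-finite energy")
  if (e_new <= e_ref) return(TRUE)
  if (kT <= 0) return(FALSE)
  stats::runif(1) < exp(-(e_new - e_ref) / kT)
}

#' Rigid-body local minimization of a ligand pose
#'
#' Deterministic steepest descent with backtracking line search over the six
#' pose degrees of freedom (translation + rotation about the centroid). When
#' \code{energy_fn} exposes a \code{grad} argument (as the package's energy
#' evaluators do) the analytic pose gradient (net force and torque about the
#' centroid) is used; otherwise one-sided numerical gradients. The returned
#' pose never has higher energy than the input.
#'
#' @param xyz n x 3 ligand coordinates.
#' @param energy_fn function(n x 3 matrix) -> kcal/mol, optionally accepting
#'   \code{grad = TRUE} and then returning \code{list(energy, grad)}.
#' @param max_iters descent iterations.
#' @param tol stop when an iteration improves by less than this (kcal/mol).
#' @return list with \code{xyz} and \code{energy}.
#' @export
minimize_ligand <- function(xyz, energy_fn, max_iters = 20, tol = 0.01) {
  analytic <- "grad" %in% names(formals(energy_fn))
  e_cur <- energy_fn(xyz)
  if (!is.finite(e_cur))
    stop_domain("minimize_ligand: non-finite start energy")
  cur <- xyz
  h_t <- 0.02   # A, translation probe (numeric fallback)
  h_r <- 0.01   # rad, rotation probe
  apply_move <- function(x, par) {
    ctr <- colMeans(x)
    rv <- par[4:6]
    ang <- vnorm(rv)
    out <- if (ang > 0) {
      sweep(sweep(x, 2, ctr) %*% rotation_matrix(rv, ang), 2, -ctr, "-")
    } else x
    sweep(out, 2, -par[1:3], "-")
  }
  pose_gradient <- function(x, e0) {
    if (analytic) {
      eg <- energy_fn(x, grad = TRUE)
      G <- eg$grad
      ctr <- colMeans(x)
      rel <- sweep(x, 2, ctr)
      # torque about the centroid: sum_j rel_j x grad_j
      c(colSums(G),
        sum(rel[, 2] * G[, 3] - rel[, 3] * G[, 2]),
        sum(rel[, 3] * G[, 1] - rel[, 1] * G[, 3]),
        sum(rel[, 1] * G[, 2] - rel[, 2] * G[, 1]))
    } else {
      g <- numeric(6)
      for (k in 1:3) {
        par <- numeric(6); par[k] <- h_t
        g[k] <- (energy_fn(apply_move(x, par)) - e0) / h_t
      }
      for (k in 4:6) {
        par <- numeric(6); par[k] <- h_r
        g[k] <- (energy_fn(apply_move(x, par)) - e0) / h_r
      }
      g
    }
  }
  # Polak-Ribiere conjugate gradient over incremental 6-DOF moves; the
  # gradient is exact at each iterate (each move is applied from the
  # current pose, where force/torque are the true derivatives).
  step <- 0.5
  g_prev <- NULL; d_prev <- NULL
  stall <- 0L
  for (it in seq_len(max_iters)) {
    g <- pose_gradient(cur, e_cur)
    gn <- vnorm(g)
    if (gn < 1e-8) break
    d <- if (is.null(g_prev)) -g else {
      beta <- max(0, sum(g * (g - g_prev)) / sum(g_prev * g_prev))
      -g + beta * d_prev
    }
    if (sum(d * g) >= 0) d <- -g  # reset on a non-descent direction
    dn <- d / vnorm(d)
    improved <- FALSE
    s <- step
    for (ls in 1:10) {
      cand <- apply_move(cur, dn * s)
      e_cand <- energy_fn(cand)
      if (is.finite(e_cand) && e_cand < e_cur - 1e-12) {
        gain <- e_cur - e_cand
        cur <- cand; e_cur <- e_cand
        improved <- TRUE
        step <- min(s * 2, 2)
        if (gain < tol) stall <- stall + 1L else stall <- 0L
        break
      }
      s <- s / 2
    }
    if (!improved || stall >= 2L) break
    g_prev <- g; d_prev <- d
  }
  list(xyz = cur, energy = e_cur)
}

#' Randomized side-chain sampling near the ligand
#'
#' Residues with any atom within \code{sprad} of any ligand atom receive a
#' random torsion-like displacement (a small rotation of the residue's atoms
#' about a random axis through the residue centroid). A move is rejected --
#' leaving the residue untouched -- if it brings any receptor-internal atom
#' pair closer than 1.5 A. Atoms outside the selection are never modified.
#'
#' @param receptor a \code{ligmig_structure}.
#' @param lig_xyz n x 3 ligand coordinates.
#' @param sprad selection radius, Angstrom.
#' @return the (possibly) modified receptor.
#' @export
sample_side_chains <- function(receptor, lig_xyz, sprad) {
  at <- receptor$atoms
  rx <- coords(receptor)
  near <- rep(FALSE, nrow(rx))
  for (j in seq_len(nrow(lig_xyz))) {
    d2 <- (rx[, 1] - lig_xyz[j, 1])^2 + (rx[, 2] - lig_xyz[j, 2])^2 +
      (rx[, 3] - lig_xyz[j, 3])^2
    near <- near | (d2 <= sprad^2)
  }
  if (!any(near)) return(receptor)
  res <- paste(at$chain, at$resno)
  for (r in unique(res[near])) {
    idx <- which(res == r)
    ctr <- colMeans(rx[idx, , drop = FALSE])
    R <- rotation_matrix(stats::rnorm(3), stats::runif(1, -0.15, 0.15) * pi)
    moved <- sweep(sweep(rx[idx, , drop = FALSE], 2, ctr) %*% R, 2, -ctr, "-")
    other <- rx[-idx, , drop = FALSE]
    clash <- FALSE
    for (i in seq_len(nrow(moved))) {
      d2 <- (other[, 1] - moved[i, 1])^2 + (other[, 2] - moved[i, 2])^2 +
        (other[, 3] - moved[i, 3])^2
      if (any(d2 < 1.5^2)) { clash <- TRUE; break }
    }
    if (!clash) rx[idx, ] <- moved
  }
  set_coords(receptor, rx)
}

#' Spawning state of a ligand pose
#'
#' Reports which exploration domain a pose is in: \code{"unconstrained"}
#' before the ligand has come within \code{spawn_trigger} of either receptor
#' COM, else \code{"a"} or \code{"b"} naming the capturing receptor. Once a
#' chain is captured, proposals leaving the sphere of radius
#' \code{spawn_radius} around that COM are rejected outright.
#'
#' @param dist_a,dist_b ligand-COM distances to the receptor COMs (b may be
#'   NA for individual runs).
#' @param config a \code{ligmig_mcconfig}.
#' @param captured current domain token (\code{"unconstrained"}, \code{"a"},
#'   \code{"b"}).
#' @return updated domain token.
#' @export
spawn_check <- function(dist_a, dist_b, config, captured = "unconstrained") {
  if (captured != "unconstrained") return(captured)
  db <- if (is.na(dist_b)) Inf else dist_b
  if (dist_a <= config$spawn_trigger && dist_a <= db) return("a")
  if (db <= config$spawn_trigger) return("b")
  "unconstrained"
}

#' Run one Monte Carlo chain
#'
#' Per step: rigid perturbation of the ligand, optional side-chain sampling
#' of the nearest receptor, rigid-body minimization, then Metropolis
#' acceptance against the previous accepted energy (the ligand's total
#' interaction energy, summed over both receptors when both are present).
#' Accepted states are appended as frames with COM distances to each
#' receptor. Proposals violating an active spawning constraint are rejected
#' before energy evaluation. Deterministic for a fixed
#' \code{(system, config, chain_id)}.
#'
#' @param system a \code{ligmig_system}.
#' @param ligand_index which free ligand to propagate.
#' @param config a \code{ligmig_mcconfig}.
#' @param chain_id integer chain label; the chain RNG stream is
#'   \code{config$seed + chain_id}.
#' @param params a \code{ligmig_ff}.
#' @param spawn_target restrict spawning to one receptor (\code{"both"},
#'   \code{"a"}, \code{"b"}); induced-fit runs spawn on the target receptor
#'   only.
#' @return object of class \code{ligmig_trajectory}: accepted frames
#'   (data.frame), per-frame ligand coordinates, acceptance counts, and the
#'   capture token.
#' @export
run_chain <- function(system, ligand_index = 1L, config = mc_config(),
                      chain_id = 1L, params = ff_params(),
                      spawn_target = c("both", "a", "b")) {
  spawn_target <- match.arg(spawn_target)
  lig <- system$ligands[[ligand_index]]
  masses <- lig$atoms$mass
  side <- receptor_side_atoms(system)
  coms <- list(a = com_xyz(as.matrix(side$a[, c("x", "y", "z")]),
                           side$a$mass),
               b = if (is.null(side$b)) NULL
                   else com_xyz(as.matrix(side$b[, c("x", "y", "z")]),
                                side$b$mass))
  rec_a <- side$a
  rec_b <- side$b
  sampling <- isTRUE(config$side_chain_sampling)
  ev_a <- cross_evaluator(rec_a, lig$atoms, params)
  ev_b <- if (!is.null(rec_b)) cross_evaluator(rec_b, lig$atoms, params)
  # propagation uses one combined evaluator over both receptor sides
  efun <- cross_evaluator(if (is.null(rec_b)) rec_a else rbind(rec_a, rec_b),
                          lig$atoms, params)

  with_seed(config$seed + chain_id, {
    cur <- coords(lig)
    e_ref <- efun(cur)
    captured <- "unconstrained"
    n_steps <- config$steps
    fr_step <- integer(n_steps); fr_e <- fr_ea <- fr_eb <- numeric(n_steps)
    fr_da <- fr_db <- numeric(n_steps); fr_sp <- logical(n_steps)
    fr_cx <- fr_cy <- fr_cz <- numeric(n_steps)
    fr_coords <- vector("list", n_steps)
    n_acc <- 0L
    for (step in seq_len(n_steps)) {
      confined <- captured %in% c("a", "b")
      prop <- perturb_ligand(cur,
                             if (confined) config$spawn_tra_r else config$tra_r,
                             if (confined) config$spawn_rot_r else config$rot_r)
      samp_side <- NULL
      if (sampling) {
        # perturb side chains of the receptor currently nearest the ligand
        pcom0 <- com_xyz(prop, masses)
        da <- vnorm(pcom0 - coms$a)
        db <- if (is.null(coms$b)) Inf else vnorm(pcom0 - coms$b)
        samp_side <- if (da <= db) "a" else "b"
        if (samp_side == "a") {
          rec_try <- sample_side_chains(
            mol_structure(rec_a, "side_a"), prop, config$sprad)
          efun_try <- cross_evaluator(
            if (is.null(rec_b)) rec_try$atoms else rbind(rec_try$atoms, rec_b),
            lig$atoms, params)
        } else {
          rec_try <- sample_side_chains(
            mol_structure(rec_b, "side_b"), prop, config$sprad)
          efun_try <- cross_evaluator(rbind(rec_a, rec_try$atoms),
                                      lig$atoms, params)
        }
      } else efun_try <- efun
      mn <- minimize_ligand(prop, efun_try, config$minimize_iters,
                            config$minimize_tol)
      pcom <- com_xyz(mn$xyz, masses)
      dist_a <- vnorm(pcom - coms$a)
      dist_b <- if (is.null(coms$b)) NA_real_ else vnorm(pcom - coms$b)
      # active spawning constraint: outright rejection outside the sphere
      if (captured %in% c("a", "b")) {
        d_cap <- if (captured == "a") dist_a else dist_b
        if (d_cap > config$spawn_radius) next
      }
      if (!metropolis_accept(mn$energy, e_ref, config$temperature_kT)) next
      # accept
      cur <- mn$xyz
      e_ref <- mn$energy
      if (!is.null(samp_side)) {
        # commit the sampled receptor
        if (samp_side == "a") {
          rec_a <- rec_try$atoms
          ev_a <- cross_evaluator(rec_a, lig$atoms, params)
        } else {
          rec_b <- rec_try$atoms
          ev_b <- cross_evaluator(rec_b, lig$atoms, params)
        }
        efun <- efun_try
      }
      if (captured == "unconstrained") {
        cand <- spawn_check(dist_a, dist_b, config, captured)
        if (cand != "unconstrained" &&
            (spawn_target == "both" || cand == spawn_target)) {
          captured <- cand
          # spawn: halt migration and restart the confined task from a
          # spawn point inside the exploration sphere, relaxed in place
          com_cap <- coms[[captured]]
          d_cap <- if (captured == "a") dist_a else dist_b
          if (d_cap > config$spawn_radius - 0.5) {
            dir <- (pcom - com_cap) / d_cap
            shift <- com_cap + dir * (config$spawn_radius - 0.5) - pcom
            cur <- sweep(cur, 2, -shift, "-")
          }
          mn2 <- minimize_ligand(cur, efun, config$minimize_iters,
                                 config$minimize_tol)
          pcom2 <- com_xyz(mn2$xyz, masses)
          if (vnorm(pcom2 - com_cap) <= config$spawn_radius) {
            cur <- mn2$xyz  # keep the relaxed spawn pose only if it stays in
            e_ref <- mn2$energy
          } else {
            e_ref <- efun(cur)
          }
          pcom <- com_xyz(cur, masses)
          dist_a <- vnorm(pcom - coms$a)
          dist_b <- if (is.null(coms$b)) NA_real_ else vnorm(pcom - coms$b)
        }
      }
      n_acc <- n_acc + 1L
      fr_step[n_acc] <- step
      fr_ea[n_acc] <- ev_a(cur)
      fr_eb[n_acc] <- if (is.null(ev_b)) 0 else ev_b(cur)
      fr_e[n_acc] <- e_ref
      fr_da[n_acc] <- dist_a; fr_db[n_acc] <- dist_b
      fr_sp[n_acc] <- captured != "unconstrained"
      fr_cx[n_acc] <- pcom[1]; fr_cy[n_acc] <- pcom[2]; fr_cz[n_acc] <- pcom[3]
      fr_coords[[n_acc]] <- cur
    }
    idx <- seq_len(n_acc)
    # dwell: number of engine steps each accepted state persisted (its own
    # step plus subsequent rejections) -- the occupancy weight of the frame
    dwell <- if (n_acc > 0L)
      diff(c(fr_step[idx], n_steps + 1L)) else integer(0)
    frames <- data.frame(
      chain = chain_id, step = fr_step[idx], e_interaction = fr_e[idx],
      e_a = fr_ea[idx], e_b = fr_eb[idx],
      dist_a = fr_da[idx], dist_b = fr_db[idx],
      com_x = fr_cx[idx], com_y = fr_cy[idx], com_z = fr_cz[idx],
      spawned = fr_sp[idx], accepted = TRUE, dwell = dwell)
    structure(list(chain_id = chain_id, frames = frames,
                   coords = fr_coords[idx], captured = captured,
                   n_proposed = n_steps, n_accepted = n_acc,
                   config_fingerprint = config_fingerprint(config)),
              class = "ligmig_trajectory")
  })
}

#' @export
print.ligmig_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ligmig_trajectory> chain %d: %d/%d accepted (%.1f%%), capture: %s\n",
    x$chain_id, x$n_accepted, x$n_proposed,
    100 * x$n_accepted / x$n_proposed, x$captured))
  invisible(x)
}
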