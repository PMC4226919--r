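# Experiment protocols: individual binding, competitive binding, induced-fit
# refinement, sequential multi-ligand binding, and trajectory filtering.

#' Trajectory filter specification
#'
#' Defaults mirror the migration protocol's analysis cutoffs: frames beyond
#' 100 A of both receptor COMs or with non-negative interaction energy are
#' discarded, and the first 100 accepted frames of each chain are treated as
#' burn-in (chains are still relaxing toward a stable energy).
#'
#' @param max_com_distance Angstrom (default 100).
#' @param max_energy kcal/mol; frames with energy >= this are dropped
#'   (default 0).
#' @param burn_in accepted frames discarded from the start of each chain
#'   (default 100).
#' @return object of class \code{ligmig_filterspec}.
#' @export
filter_spec <- function(max_com_distance = 100, max_energy = 0,
                        burn_in = 100) {
  if (burn_in < 0) stop_config("burn_in must be >= 0")
  structure(list(max_com_distance = max_com_distance,
                 max_energy = max_energy, burn_in = as.integer(burn_in)),
            class = "ligmig_filterspec")
}

#' Experiment specification
#'
#' @param mode \code{"individual"} (one receptor), \code{"competitive"}
#'   (both receptors, energies evaluated against both simultaneously), or
#'   \code{"induced_fit"} (refinement around an already-bound pose:
#'   side-chain sampling on, rot_r = 0.5, spawning on the target receptor
#'   only).
#' @param system a \code{ligmig_system}; receptor B must be absent in
#'   individual mode and present in competitive mode.
#' @param mc a \code{\link{mc_config}}.
#' @param bound_ligands list of ligand structures frozen onto a receptor
#'   (each may carry a \code{"receptor"} attribute, default \code{"a"});
#'   required non-empty for induced-fit runs.
#' @param filters a \code{\link{filter_spec}}.
#' @return object of class \code{ligmig_runspec}.
#' @export
run_spec <- function(mode = c("competitive", "individual", "induced_fit"),
                     system, mc = mc_config(), bound_ligands = list(),
                     filters = filter_spec()) {
  mode <- match.arg(mode)
  if (mode == "individual" && !is.null(system$receptor_b))
    stop_config("individual mode requires a system without receptor B")
  if (mode == "competitive" &&
      (is.null(system$receptor_a) || is.null(system$receptor_b)))
    stop_config("competitive mode requires both receptors")
  if (mode == "induced_fit" && length(bound_ligands) == 0 &&
      length(system$bound) == 0)
    stop_config("induced-fit mode requires at least one bound ligand")
  structure(list(mode = mode, system = system, mc = mc,
                 bound_ligands = bound_ligands, filters = filters),
            class = "ligmig_runspec")
}

#' Desk-scale Monte Carlo configuration
#'
#' \code{\link{mc_config}} with the spawning distances rescaled coherently
#' with the desk-scale fixture geometry (24 A separation instead of 67 A):
#' trigger 6 A and confinement radius 5 A. At bead scale the receptors are
#' only ~7 A in radius, so the full-scale trigger of 10 A would fire on any
#' surface contact and turn capture into a first-touch lottery; 6 A fires
#' only on genuine entry into a binding mouth or pocket, matching the
#' full-scale semantics ("active site" distances, not surface distances).
#'
#' @param ... overrides passed on to \code{\link{mc_config}}.
#' @return a \code{ligmig_mcconfig}.
#' @export
desk_mc_config <- function(...) {
  args <- list(...)
  defaults <- list(spawn_trigger = 6, spawn_radius = 5)
  do.call(mc_config, utils::modifyList(defaults, args))
}

#' Desk-scale trajectory filters
#'
#' \code{\link{filter_spec}} with the burn-in rescaled to desk-scale chain
#' lengths: 25 accepted frames per chain instead of 100. Desk-scale chains
#' produce a few hundred accepted frames, so the full-scale burn-in would
#' swallow a disproportionate share of them (and all of a low-acceptance
#' chain); 25 frames covers the migration transient at this scale.
#'
#' @param ... overrides passed on to \code{\link{filter_spec}}.
#' @return a \code{ligmig_filterspec}.
#' @export
desk_filter_spec <- function(...) {
  do.call(filter_spec, utils::modifyList(list(burn_in = 25), list(...)))
}

#' Build a single-receptor system for individual-binding runs
#'
#' @param receptor a \code{ligmig_structure}.
#' @param ligand a ligand structure.
#' @param ligand_offset starting ligand COM distance from the receptor COM.
#' @param seed placement-angle seed.
#' @return a \code{ligmig_system} with \code{receptor_b = NULL}.
#' @export
individual_system <- function(receptor, ligand, ligand_offset = 42,
                              seed = 1) {
  receptor <- translate_structure(receptor, -center_of_mass(receptor))
  dir <- with_seed(seed, { v <- stats::rnorm(3); v / vnorm(v) })
  ligand <- translate_structure(
    ligand, dir * ligand_offset - center_of_mass(ligand))
  structure(list(receptor_a = receptor, receptor_b = NULL,
                 ligands = list(ligand), bound = list(),
                 geometry = list(separation = NA_real_,
                                 ligand_offset = ligand_offset, seed = seed)),
            class = "ligmig_system")
}

#' Run an experiment (a set of independent Monte Carlo chains)
#'
#' Chains are independent and deterministic given \code{(spec, seed)}:
#' chain c uses RNG stream \code{mc$seed + c}, so sequential and parallel
#' execution give identical results. In competitive mode the Metropolis
#' energy is the ligand's total interaction energy over both receptors; in
#' individual mode, over the single receptor. Induced-fit mode freezes the
#' bound ligand(s) into their receptor, enables side-chain sampling, sets
#' rot_r = 0.5 and spawns on the target receptor only.
#'
#' @param spec a \code{\link{run_spec}}.
#' @param params a \code{ligmig_ff}.
#' @return object of class \code{ligmig_trajset}: list of trajectories plus
#'   the system, config and mode.
#' @export
run_experiment <- function(spec, params = ff_params()) {
  if (!inherits(spec, "ligmig_runspec")) stop_config("not a run spec")
  system <- spec$system
  mc <- spec$mc
  spawn_target <- "both"
  if (length(spec$bound_ligands)) {
    for (bl in spec$bound_ligands) {
      if (is.null(attr(bl, "receptor"))) attr(bl, "receptor") <- "a"
      system$bound <- c(system$bound, list(bl))
    }
  }
  if (spec$mode == "induced_fit") {
    mc$rot_r <- 0.5
    mc$side_chain_sampling <- TRUE
    spawn_target <- attr(spec$bound_ligands[[1]], "receptor") %||% "a"
  }
  trajs <- lapply(seq_len(mc$n_chains), function(ch)
    run_chain(system, ligand_index = 1L, config = mc, chain_id = ch,
              params = params, spawn_target = spawn_target))
  structure(list(trajectories = trajs, system = system, config = mc,
                 mode = spec$mode, filters = spec$filters,
                 filtered = FALSE),
            class = "ligmig_trajset")
}

#' @export
print.ligmig_trajset <- function(x, ...) {
  acc <- acceptance_fraction(x)
  cat(sprintf(
    "<ligmig_trajset> %s: %d chains, %d accepted frames, pooled acceptance %.1f%%%s\n",
    x$mode, length(x$trajectories),
    sum(vapply(x$trajectories, function(t) nrow(t$frames), integer(1))),
    100 * acc, if (isTRUE(x$filtered)) " (filtered)" else ""))
  invisible(x)
}

#' Pooled Metropolis acceptance fraction of a trajectory set
#' @param trajs a \code{ligmig_trajset}
#' @return fraction in [0, 1]
#' @export
acceptance_fraction <- function(trajs) {
  sum(vapply(trajs$trajectories, function(t) t$n_accepted, integer(1))) /
    sum(vapply(trajs$trajectories, function(t) t$n_proposed, integer(1)))
}

#' Apply the trajectory filters
#'
#' Drops the first \code{burn_in} accepted frames of each chain, then frames
#' farther than \code{max_com_distance} from every receptor COM, then frames
#' with interaction energy at or above \code{max_energy}. Idempotent: a
#' filtered set passes through unchanged (burn-in is not re-applied). The
#' kept/dropped counts per rule are attached as attribute \code{"report"}.
#'
#' @param trajs a \code{ligmig_trajset}.
#' @param filters a \code{\link{filter_spec}}; defaults to the set's own.
#' @return the filtered \code{ligmig_trajset}.
#' @export
filter_frames <- function(trajs, filters = NULL) {
  filters <- filters %||% trajs$filters %||% filter_spec()
  total <- 0L; d_burn <- 0L; d_dist <- 0L; d_energy <- 0L
  trajs$trajectories <- lapply(trajs$trajectories, function(tr) {
    fr <- tr$frames
    n <- nrow(fr)
    total <<- total + n
    keep <- rep(TRUE, n)
    if (!isTRUE(trajs$filtered) && filters$burn_in > 0L) {
      nb <- min(filters$burn_in, n)
      keep[seq_len(nb)] <- FALSE
      d_burn <<- d_burn + nb
      if (nb == n && n > 0L)
        warning(sprintf("chain %d: all %d frames fall inside burn-in",
                        tr$chain_id, n), call. = FALSE)
    }
    mind <- pmin(fr$dist_a, ifelse(is.na(fr$dist_b), Inf, fr$dist_b))
    far <- keep & mind > filters$max_com_distance
    d_dist <<- d_dist + sum(far)
    keep <- keep & !far
    hot <- keep & fr$e_interaction >= filters$max_energy
    d_energy <<- d_energy + sum(hot)
    keep <- keep & !hot
    tr$frames <- fr[keep, , drop = FALSE]
    tr$coords <- tr$coords[keep]
    tr
  })
  trajs$filtered <- TRUE
  attr(trajs, "report") <- list(
    total = total, kept = total - d_burn - d_dist - d_energy,
    dropped_burn_in = d_burn, dropped_distance = d_dist,
    dropped_energy = d_energy)
  trajs
}

#' Select the binding frame for the next sequential round
#'
#' The descriptive rule "the lowest-energy trajectory that is farthest from
#' the competitor's COM" is made deterministic lexicographically: restrict
#' to the quartile of frames farthest from the competitor COM, then take
#' the minimum interaction energy (ties: first frame).
#'
#' @param frames data.frame with columns \code{e_interaction} and the
#'   competitor distance column named by \code{competitor}
#'   (\code{"dist_a"} or \code{"dist_b"}).
#' @param competitor which receptor is the competitor (default \code{"b"}).
#' @return the selected row index.
#' @export
select_binding_frame <- function(frames, competitor = c("b", "a")) {
  competitor <- match.arg(competitor)
  if (nrow(frames) == 0L) stop_protocol("no frames to select from")
  d <- frames[[paste0("dist_", competitor)]]
  thr <- stats::quantile(d, 0.75, names = FALSE, type = 7)
  cand <- which(d >= thr)
  cand[which.min(frames$e_interaction[cand])]
}

#' Sequential multi-ligand binding rounds
#'
#' After each round the selected frame's ligand pose (see
#' \code{\link{select_binding_frame}}) is frozen as bound to the target
#' receptor, and the next ligand explores the updated system (bound ligands
#' contribute to their receptor's side of the interaction energy).
#'
#' @param spec a competitive \code{\link{run_spec}}.
#' @param n_ligands total ligands to bind sequentially (>= 2).
#' @param target receptor the ligands bind to (\code{"a"} or \code{"b"});
#'   the other receptor is the competitor in the selection rule.
#' @param params a \code{ligmig_ff}.
#' @return list of \code{ligmig_trajset}, one per round.
#' @export
run_sequential_binding <- function(spec, n_ligands, target = "a",
                                   params = ff_params()) {
  if (n_ligands < 2) stop_config("sequential binding needs n_ligands >= 2")
  competitor <- if (target == "a") "b" else "a"
  rounds <- vector("list", n_ligands)
  for (round in seq_len(n_ligands)) {
    ts <- run_experiment(spec, params = params)
    rounds[[round]] <- ts
    if (round == n_ligands) break
    flt <- filter_frames(ts, spec$filters)
    fr <- collect_frames(flt)
    if (nrow(fr) == 0L)
      stop_protocol(
        "round %d: no frame survives the filters (%d frames before filtering); cannot select a bound pose",
        round, sum(vapply(ts$trajectories, function(t) nrow(t$frames),
                          integer(1))))
    sel <- select_binding_frame(fr, competitor)
    tr <- flt$trajectories[[match(fr$chain[sel],
      vapply(flt$trajectories, function(t) t$chain_id, integer(1)))]]
    in_chain <- which(tr$frames$step == fr$step[sel])[1]
    bound <- set_coords(spec$system$ligands[[1]], tr$coords[[in_chain]])
    attr(bound, "receptor") <- target
    spec$bound_ligands <- c(spec$bound_ligands, list(bound))
    spec$mc$seed <- spec$mc$seed + 1000L  # fresh streams per round
  }
  rounds
}
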