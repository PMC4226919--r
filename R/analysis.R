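# Trajectory analysis: frame pooling, stride-and-cutoff quality-threshold
# clustering of ligand COM positions, cluster-to-receptor assignment,
# preference percentages, COM-distance traces, RMSD, scatter export.

#' Pool accepted frames of a trajectory set into one table
#'
#' Frames are concatenated chain-major (chain 1's frames first, in step
#' order) and given a global \code{frame} id used by the clustering
#' tie-break rules.
#'
#' @param trajs a \code{ligmig_trajset}.
#' @return data.frame with chain, step, energies, COM distances and COM
#'   coordinates.
#' @export
collect_frames <- function(trajs) {
  out <- do.call(rbind, lapply(trajs$trajectories, function(t) t$frames))
  if (is.null(out))
    out <- data.frame(chain = integer(0), step = integer(0),
                      e_interaction = numeric(0), e_a = numeric(0),
                      e_b = numeric(0), dist_a = numeric(0),
                      dist_b = numeric(0), com_x = numeric(0),
                      com_y = numeric(0), com_z = numeric(0),
                      spawned = logical(0), accepted = logical(0),
                      dwell = numeric(0))
  out$frame <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Quality-threshold clustering of ligand poses
#'
#' Takes every \code{stride}-th pooled frame and greedily clusters their
#' ligand COM positions: repeatedly pick the point with the most neighbors
#' within \code{cutoff} (ties: lowest frame id), form a cluster of it plus
#' those neighbors, remove them, until \code{max_clusters} clusters exist or
#' only neighborless points remain. Leftover singletons stay unassigned.
#' Defaults mirror the analysis protocol: every 10th frame, 5 A cutoff, at
#' most 10 clusters ranked by member count.
#'
#' @param frames pooled frame table (\code{\link{collect_frames}}) or a
#'   \code{ligmig_trajset}.
#' @param stride keep every stride-th frame (starting at the first).
#' @param cutoff neighbor distance cutoff, Angstrom.
#' @param max_clusters maximum clusters extracted.
#' @return object of class \code{ligmig_clusters}: ranked clusters (member
#'   frame ids, centroid, size, receptor assignment), the strided frame
#'   table, and unassigned frame ids.
#' @export
cluster_frames <- function(frames, stride = 10, cutoff = 5,
                           max_clusters = 10) {
  if (inherits(frames, "ligmig_trajset")) frames <- collect_frames(frames)
  n <- nrow(frames)
  if (n == 0L) stop_domain("cluster_frames: no frames")
  sel <- seq(1L, n, by = max(1L, as.integer(stride)))
  fr <- frames[sel, , drop = FALSE]
  pts <- as.matrix(fr[, c("com_x", "com_y", "com_z")])
  m <- nrow(pts)
  active <- rep(TRUE, m)
  within <- as.matrix(stats::dist(pts)) <= cutoff  # includes self
  clusters <- list()
  while (length(clusters) < max_clusters && any(active)) {
    counts <- colSums(within[active, active, drop = FALSE]) - 1L
    if (max(counts) == 0L) break  # only neighborless singletons remain
    act_idx <- which(active)
    pick <- act_idx[which.max(counts)]  # which.max: first max = lowest id
    members <- act_idx[within[pick, active]]
    clusters[[length(clusters) + 1L]] <- list(
      members = fr$frame[members],
      centroid = colMeans(pts[members, , drop = FALSE]),
      size = length(members),
      receptor_assignment = "unassigned")
    active[members] <- FALSE
  }
  ord <- order(-vapply(clusters, function(cl) cl$size, numeric(1)),
               vapply(clusters, function(cl) min(cl$members), numeric(1)))
  structure(list(clusters = clusters[ord], stride = stride, cutoff = cutoff,
                 max_clusters = max_clusters, frames = fr,
                 unassigned = fr$frame[active]),
            class = "ligmig_clusters")
}

#' @export
print.ligmig_clusters <- function(x, ...) {
  cat(sprintf("<ligmig_clusters> %d cluster(s) from %d strided frames (stride %d, cutoff %.1f A)\n",
              length(x$clusters), nrow(x$frames), x$stride, x$cutoff))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  #%d: %d frames, centroid (%.1f, %.1f, %.1f), %s\n", i,
                cl$size, cl$centroid[1], cl$centroid[2], cl$centroid[3],
                cl$receptor_assignment))
  }
  invisible(x)
}

#' Assign clusters to the nearer receptor
#'
#' Each cluster is assigned to the receptor whose COM is nearer its
#' centroid; centroids equidistant within 1e-6 A stay unassigned. With a
#' single receptor every cluster is assigned to it.
#'
#' @param clusters a \code{ligmig_clusters}.
#' @param system the \code{ligmig_system} the frames came from.
#' @return the cluster set with assignments filled in.
#' @export
assign_clusters <- function(clusters, system) {
  coms <- receptor_coms(system)
  clusters$clusters <- lapply(clusters$clusters, function(cl) {
    da <- vnorm(cl$centroid - coms$a)
    if (is.null(coms$b)) { cl$receptor_assignment <- "a"; return(cl) }
    db <- vnorm(cl$centroid - coms$b)
    cl$receptor_assignment <-
      if (abs(da - db) <= 1e-6) "unassigned" else if (da < db) "a" else "b"
    cl
  })
  clusters
}

round_pref_percent <- function(p) {
  # printed-precision convention: percent to one decimal, then half-up
  floor(round(p, 1) + 0.5)
}

#' Receptor-preference statistic
#'
#' The headline readout: the percentage of clustered trajectories assigned
#' to receptor B out of all clustered trajectories, i.e.
#' 100 * counts_b / (counts_a + counts_b). Counts sum the member frames of
#' each assigned cluster. The percentage is reported at printed precision:
#' rounded to one decimal and then half-up to an integer (so 360/567 ->
#' 63.5% -> 64%).
#'
#' Called either on a \code{ligmig_clusters} (after
#' \code{\link{assign_clusters}}) or directly on two vectors of per-cluster
#' counts.
#'
#' @param x a \code{ligmig_clusters}, or a numeric vector of per-cluster
#'   counts for receptor A.
#' @param ... for the default method, \code{counts_b}: per-cluster counts
#'   for receptor B.
#' @return object of class \code{ligmig_preference}: \code{counts_a},
#'   \code{counts_b}, \code{total}, \code{preference_b_percent}.
#' @export
preference <- function(x, ...) UseMethod("preference")

#' @rdname preference
#' @param weight \code{"dwell"} (default) weights each member frame by the
#'   number of engine steps its state persisted — the occupancy estimator
#'   of a Metropolis chain, which keeps chains of different acceptance
#'   rates comparable; \code{"frames"} counts member frames directly.
#' @export
preference.ligmig_clusters <- function(x, weight = c("dwell", "frames"),
                                       ...) {
  weight <- match.arg(weight)
  counts <- vapply(x$clusters, function(cl) {
    if (weight == "dwell" && !is.null(x$frames$dwell))
      sum(x$frames$dwell[match(cl$members, x$frames$frame)])
    else cl$size
  }, numeric(1))
  assign <- vapply(x$clusters, function(cl) cl$receptor_assignment,
                   character(1))
  if (!any(assign %in% c("a", "b")))
    stop_domain("preference: no assigned clusters")
  preference(counts[assign == "a"], counts[assign == "b"])
}

#' @rdname preference
#' @param counts_b per-cluster counts for receptor B (default method).
#' @export
preference.default <- function(x, counts_b, ...) {
  counts_a <- sum(x); counts_b <- sum(counts_b)
  total <- counts_a + counts_b
  if (total <= 0) stop_domain("preference: no counted trajectories")
  structure(list(counts_a = counts_a, counts_b = counts_b, total = total,
                 preference_b_percent =
                   round_pref_percent(100 * counts_b / total)),
            class = "ligmig_preference")
}

#' @export
print.ligmig_preference <- function(x, ...) {
  cat(sprintf(
    "<ligmig_preference> A: %d, B: %d (of %d) -> %d%% preference for B\n",
    x$counts_a, x$counts_b, x$total, x$preference_b_percent))
  invisible(x)
}

#' COM-distance trace of one trajectory
#'
#' @param traj a \code{ligmig_trajectory}.
#' @param receptor \code{"a"} or \code{"b"}.
#' @return numeric series of ligand-COM to receptor-COM distances, in frame
#'   order.
#' @export
com_distance_trace <- function(traj, receptor = c("a", "b")) {
  if (nrow(traj$frames) == 0L) stop_domain("empty trajectory")
  receptor <- tryCatch(match.arg(receptor),
                       error = function(e)
                         stop_domain("unknown receptor token"))
  traj$frames[[paste0("dist_", receptor)]]
}

#' RMSD to a reference pose
#'
#' Root-mean-square deviation over paired coordinates, optionally after a
#' least-squares rigid superposition. When \code{fit_indices} is given the
#' superposition is computed on that subset (e.g. a backbone frame of
#' reference) and the RMSD reported over all points.
#'
#' @param xyz,ref paired n x 3 coordinate matrices (heavy atoms).
#' @param superpose_first fit before measuring.
#' @param fit_indices optional row subset used for the fit.
#' @return RMSD in Angstrom.
#' @export
rmsd_to_reference <- function(xyz, ref, superpose_first = FALSE,
                              fit_indices = NULL) {
  xyz <- as.matrix(xyz); ref <- as.matrix(ref)
  if (!all(dim(xyz) == dim(ref)))
    stop_domain("rmsd_to_reference: coordinate sets differ in size")
  if (superpose_first) {
    idx <- fit_indices %||% seq_len(nrow(xyz))
    fit <- superpose(xyz[idx, , drop = FALSE], ref[idx, , drop = FALSE])
    xyz <- sweep(xyz %*% fit$rotation, 2, -fit$translation, "-")
  }
  sqrt(mean(rowSums((xyz - ref)^2)))
}

#' Export a distance-vs-energy scatter table
#'
#' One row per frame passing the scatter cutoffs (distance to the named
#' receptor <= \code{max_distance}, energy < \code{max_energy}), with the
#' fixed header \code{chain, step, distance_A, energy_kcal_mol}.
#'
#' @param frames pooled frame table or \code{ligmig_trajset}.
#' @param receptor \code{"a"} or \code{"b"}.
#' @param path output CSV path.
#' @param max_distance,max_energy scatter cutoffs (100 A, 0 kcal/mol).
#' @return the exported data.frame, invisibly.
#' @export
export_scatter <- function(frames, receptor = c("a", "b"), path,
                           max_distance = 100, max_energy = 0) {
  receptor <- match.arg(receptor)
  if (inherits(frames, "ligmig_trajset")) frames <- collect_frames(frames)
  if (nrow(frames) == 0L) stop_domain("export_scatter: no frames")
  d <- frames[[paste0("dist_", receptor)]]
  keep <- !is.na(d) & d <= max_distance & frames$e_interaction < max_energy
  out <- data.frame(chain = frames$chain[keep], step = frames$step[keep],
                    distance_A = d[keep],
                    energy_kcal_mol = frames$e_interaction[keep])
  ok <- tryCatch({ utils::write.csv(out, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_input("cannot write scatter CSV to %s", path)
  invisible(out)
}

#' Write cluster centroid poses as a multi-model PDB
#'
#' One MODEL block per cluster, each holding a single pseudo-atom at the
#' cluster centroid (rank order preserved).
#'
#' @param clusters a \code{ligmig_clusters}.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_cluster_pdb <- function(clusters, path) {
  at <- data.frame(serial = 1L, name = "CEN", element = "C",
                   resname = "CLU", resno = 1L, chain = "X",
                   x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  s <- mol_structure(at, "cluster-centroids")
  models <- lapply(clusters$clusters, function(cl)
    matrix(cl$centroid, ncol = 3))
  if (length(models) == 0L) stop_domain("no clusters to write")
  write_pdb(s, path, models = models)
}
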