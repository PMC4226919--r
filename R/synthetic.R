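# Coarse-grained synthetic fixtures: an acidic beta-barrel with charged
# mouth loops (the lipocalin stand-in), a geometry-identical neutral barrel
# (the matched control: coordinates are bitwise equal for the same seed, so
# any preference difference is attributable to electrostatics alone), a
# single-pocket receptor, and a compact neutral globule.

#' Specification of a synthetic receptor fixture
#'
#' @param archetype one of \code{"acidic_barrel"}, \code{"neutral_barrel"},
#'   \code{"pocket_receptor"}, \code{"small_globule"}.
#' @param n_rim_charges beads carrying \code{rim_charge} on the open-mouth
#'   rim of the acidic barrel (default 6, emulating an Asp-rich mouth loop).
#' @param rim_charge per-bead charge in elementary units (default -1).
#' @param barrel_radius,barrel_length barrel dimensions in Angstrom.
#' @param has_second_site add a charged pocket at the closed mouth (the
#'   second, buried binding site of the two-site barrel).
#' @param seed integer; geometry jitter is drawn from it, so equal seeds
#'   give bitwise-identical coordinates across archetypes sharing a
#'   geometry (acidic vs neutral barrel).
#' @return object of class \code{ligmig_fixture_spec}.
#' @export
fixture_spec <- function(archetype = c("acidic_barrel", "neutral_barrel",
                                       "pocket_receptor", "small_globule"),
                         n_rim_charges = 6, rim_charge = -1,
                         barrel_radius = 4, barrel_length = 10,
                         has_second_site = FALSE, seed = 1) {
  if (length(archetype) == 1 &&
      !archetype %in% c("acidic_barrel", "neutral_barrel",
                        "pocket_receptor", "small_globule"))
    stop_config("unknown fixture archetype: '%s'", archetype)
  archetype <- match.arg(archetype)
  if (barrel_radius <= 0 || barrel_length <= 0)
    stop_config("barrel radius and length must be > 0")
  if (!is.finite(rim_charge)) stop_config("rim_charge must be finite")
  structure(list(archetype = archetype, n_rim_charges = n_rim_charges,
                 rim_charge = rim_charge, barrel_radius = barrel_radius,
                 barrel_length = barrel_length,
                 has_second_site = has_second_site, seed = seed),
            class = "ligmig_fixture_spec")
}

bead_df <- function(xyz, charge, resno, prefix = "BD") {
  n <- nrow(xyz)
  data.frame(serial = seq_len(n),
             name = sprintf("%s%d", prefix, seq_len(n)),
             element = "C", resname = "BRL", resno = resno,
             chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             mass = element_mass(rep("C", n)), charge = charge,
             stringsAsFactors = FALSE)
}

barrel_geometry <- function(spec) {
  n_rings <- 5L
  per_ring <- 8L
  zs <- seq(-spec$barrel_length / 2, spec$barrel_length / 2,
            length.out = n_rings)
  xyz <- NULL; resno <- integer(0)
  for (k in seq_len(n_rings)) {
    ang <- 2 * pi * (seq_len(per_ring) - 1) / per_ring +
      (k - 1) * pi / per_ring  # stagger successive rings
    ring <- cbind(spec$barrel_radius * cos(ang),
                  spec$barrel_radius * sin(ang),
                  rep(zs[k], per_ring))
    xyz <- rbind(xyz, ring)
    resno <- c(resno, rep(k, per_ring))
  }
  # closed-mouth floor: three beads capping the bottom end
  cap_ang <- 2 * pi * (0:2) / 3
  cap <- cbind(1.5 * cos(cap_ang), 1.5 * sin(cap_ang), rep(zs[1] - 0.8, 3))
  xyz <- rbind(xyz, cap)
  resno <- c(resno, rep(n_rings + 1L, 3))
  jitter <- matrix(stats::runif(length(xyz), -0.15, 0.15), ncol = 3)
  list(xyz = xyz + jitter, resno = resno,
       top_ring = which(resno == n_rings), n_res = n_rings + 1L)
}

#' Generate a synthetic receptor
#'
#' Pseudo-atom (bead) receptors, deterministic per seed:
#' \describe{
#'   \item{acidic_barrel}{an open cylinder of bead rings with a capped
#'     (closed) lower mouth; \code{n_rim_charges} rim beads at the open
#'     mouth carry \code{rim_charge}, and with \code{has_second_site} an
#'     extra charged bead sits in the closed-mouth pocket.}
#'   \item{neutral_barrel}{the identical geometry (same seed, bitwise equal
#'     coordinates) with all charges zero.}
#'   \item{pocket_receptor}{a hemispherical cavity of beads with one buried
#'     -1 site at its base, the analog of an aminergic receptor pocket.}
#'   \item{small_globule}{a compact neutral bead shell.}
#' }
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return a \code{ligmig_structure}.
#' @export
make_receptor <- function(spec) {
  if (!inherits(spec, "ligmig_fixture_spec")) stop_config("not a fixture spec")
  with_seed(spec$seed, {
    if (spec$archetype %in% c("acidic_barrel", "neutral_barrel")) {
      g <- barrel_geometry(spec)
      charge <- rep(0, nrow(g$xyz))
      resno <- g$resno
      xyz <- g$xyz
      if (spec$archetype == "acidic_barrel") {
        nq <- min(spec$n_rim_charges, length(g$top_ring))
        charge[g$top_ring[seq_len(nq)]] <- spec$rim_charge
        if (spec$has_second_site) {
          xyz <- rbind(xyz, c(0, 0, -spec$barrel_length / 2 + 1))
          charge <- c(charge, spec$rim_charge)
          resno <- c(resno, g$n_res + 1L)
        }
      } else if (spec$has_second_site) {
        # matched control keeps the extra bead, uncharged
        xyz <- rbind(xyz, c(0, 0, -spec$barrel_length / 2 + 1))
        charge <- c(charge, 0)
        resno <- c(resno, g$n_res + 1L)
      }
      at <- bead_df(xyz, charge, resno)
    } else if (spec$archetype == "pocket_receptor") {
      # hemisphere (cavity opening up) built from rings at fixed polar angles
      r <- spec$barrel_radius + 1
      xyz <- NULL; resno <- integer(0); res <- 0L
      for (phi in c(0.45, 0.85, 1.25) * pi / 2) {
        m <- c(6L, 10L, 14L)[res + 1L]
        ang <- 2 * pi * (seq_len(m) - 1) / m
        res <- res + 1L
        ring <- cbind(r * sin(phi) * cos(ang), r * sin(phi) * sin(ang),
                      rep(-r * cos(phi), m))
        xyz <- rbind(xyz, ring)
        resno <- c(resno, rep(res, m))
      }
      # rim ring at the opening and the buried site at the base
      ang <- 2 * pi * (0:9) / 10
      xyz <- rbind(xyz, cbind(r * cos(ang), r * sin(ang), rep(0.8, 10)))
      resno <- c(resno, rep(res + 1L, 10))
      xyz <- rbind(xyz, c(0, 0, -r + 1.2))
      resno <- c(resno, res + 2L)
      charge <- c(rep(0, nrow(xyz) - 1L), -1)
      xyz <- xyz + matrix(stats::runif(length(xyz), -0.15, 0.15), ncol = 3)
      at <- bead_df(xyz, charge, resno)
    } else {  # small_globule
      n <- 30L
      i <- seq_len(n)
      phi <- acos(1 - 2 * (i - 0.5) / n)
      theta <- pi * (1 + sqrt(5)) * i
      r <- spec$barrel_radius
      xyz <- cbind(r * sin(phi) * cos(theta), r * sin(phi) * sin(theta),
                   r * cos(phi))
      xyz <- xyz + matrix(stats::runif(length(xyz), -0.15, 0.15), ncol = 3)
      at <- bead_df(xyz, rep(0, n), rep(seq_len(n %/% 5 + 1), each = 5)[1:n])
    }
    mol_structure(at, label = spec$archetype)
  })
}

#' Generate the histamine-like ligand
#'
#' A rigid 4-bead analog: an aromatic ring bead pair (the imidazole
#' surrogate), a linker bead, and an amine-terminus nitrogen bead. Charges
#' follow the protonation state: 0; +1 on the amine bead; or +1 amine and
#' +1 ring bead (net +2).
#'
#' @param state a protonation token or \code{\link{protonation_state}} list.
#' @param seed unused placeholder for interface symmetry (geometry is fixed).
#' @return a \code{ligmig_structure}.
#' @export
make_ligand <- function(state = "deprotonated", seed = 1) {
  at <- data.frame(
    serial = 1:4,
    name = c("RG1", "RG2", "LNK", "AMN"),
    element = c("C", "C", "C", "N"),
    resname = "HSM", resno = 1L, chain = "L",
    x = c(0.0, 1.40, 2.40, 3.40),
    y = c(0.0, 0.00, 1.00, 1.80),
    z = c(0.0, 0.00, 0.00, 0.30),
    stringsAsFactors = FALSE)
  lig <- mol_structure(at, label = "histamine-analog")
  assign_protonation(lig, state)
}

#' Build a complete competitive fixture
#'
#' Assembles two synthetic receptors and one ligand into a competitive
#' system. The full-scale geometry mirrors the competitive protocol (67 A
#' separation, 42 A ligand offset); \code{scaled = TRUE} selects the
#' desk-scale geometry (24 A / 14 A) used for fast experiments, recorded in
#' the system's metadata. The desk-scale values preserve the full protocol's
#' receptor-size to separation ratio at bead resolution, so that most chains
#' reach a receptor rather than diffusing away.
#'
#' @param spec_a,spec_b \code{\link{fixture_spec}}s for receptors A and B.
#' @param state ligand protonation token.
#' @param seed integer seed (geometry jitter + ligand placement angle).
#' @param scaled use the desk-scale geometry.
#' @param separation,ligand_offset explicit overrides (Angstrom).
#' @param orient_mouths rotate each receptor so its binding mouth faces the
#'   other receptor (default TRUE).
#' @return a \code{ligmig_system}; \code{$geometry$scaled} records whether a
#'   non-default geometry was used.
#' @export
make_competition_fixture <- function(spec_a, spec_b,
                                     state = "deprotonated", seed = 1,
                                     scaled = FALSE,
                                     separation = NULL, ligand_offset = NULL,
                                     orient_mouths = TRUE) {
  separation <- separation %||% (if (scaled) 24 else 67)
  ligand_offset <- ligand_offset %||% (if (scaled) 14 else 42)
  rec_a <- make_receptor(spec_a)
  rec_b <- make_receptor(spec_b)
  if (orient_mouths) {
    # binding mouths (built facing +z) turned toward the competition arena,
    # i.e. toward the other receptor, so both sites are accessible from the
    # equidistant ligand start point
    rec_a <- rotate_about_com(rec_a, rotation_matrix(c(0, 1, 0), pi / 2))
    rec_b <- rotate_about_com(rec_b, rotation_matrix(c(0, 1, 0), -pi / 2))
  }
  lig <- make_ligand(state, seed)
  sys <- assemble_system(rec_a, rec_b, lig, separation = separation,
                         ligand_offset = ligand_offset, seed = seed)
  sys$geometry$scaled <- !identical(c(separation, ligand_offset), c(67, 42))
  sys$protonation <- if (is.character(state)) state else state$token
  sys
}

#' Write a fixture to disk (PDB + charge sidecar)
#'
#' PDB files have no charge column with usable precision, so per-atom
#' charges go to a sidecar CSV keyed by atom serial.
#'
#' @param structure a \code{ligmig_structure}.
#' @param path output PDB path; the sidecar is written next to it as
#'   \code{<path minus .pdb>_charges.csv}.
#' @return character vector of the two paths written, invisibly.
#' @export
write_fixture <- function(structure, path) {
  write_pdb(structure, path)
  sidecar <- paste0(sub("\\.pdb$", "", path), "_charges.csv")
  utils::write.csv(structure$atoms[, c("serial", "charge")], sidecar,
                   row.names = FALSE)
  invisible(c(path, sidecar))
}

#' Read a fixture written by \code{\link{write_fixture}}
#' @param path PDB path (sidecar located automatically).
#' @return a \code{ligmig_structure} with charges applied.
#' @export
read_fixture <- function(path) {
  s <- read_pdb(path)
  sidecar <- paste0(sub("\\.pdb$", "", path), "_charges.csv")
  if (file.exists(sidecar)) {
    ch <- utils::read.csv(sidecar)
    if (!all(c("serial", "charge") %in% names(ch)))
      stop_format("charge sidecar %s lacks serial/charge columns", sidecar)
    i <- match(s$atoms$serial, ch$serial)
    s$atoms$charge[!is.na(i)] <- ch$charge[i[!is.na(i)]]
  }
  s
}
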