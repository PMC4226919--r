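# Simplified nonbonded energy model: Lennard-Jones 12-6 (Lorentz-Berthelot
# combining) plus screened Coulomb with a distance-dependent dielectric
# eps(r) = 4r, shifted to zero at the cutoff. This is a deliberately small
# stand-in for a full force field + implicit solvent: it preserves the
# electrostatic asymmetry between an acidic and a neutral receptor surface,
# which is the property the competitive-binding readout rests on.

#' Force-field parameters for the simplified nonbonded model
#'
#' @param lj data.frame with columns \code{class}, \code{epsilon} (kcal/mol)
#'   and \code{sigma} (Angstrom); one row per atom class (element). Unknown
#'   elements fall back to the pseudo-bead class \code{"X"}.
#' @param dielectric_model \code{"distance_dependent"} (eps(r) =
#'   \code{dielectric_scale * r}, the implicit-solvent proxy) or
#'   \code{"constant"} (eps = \code{dielectric_scale}).
#' @param dielectric_scale dimensionless scale, default 4.
#' @param nonbonded_cutoff cutoff distance in Angstrom (default 12); pair
#'   energies are shifted so they reach exactly 0 at the cutoff.
#' @param coulomb_constant 332.06 kcal A / (mol e^2).
#' @return object of class \code{ligmig_ff}.
#' @export
ff_params <- function(lj = NULL,
                      dielectric_model = c("distance_dependent", "constant"),
                      dielectric_scale = 4,
                      nonbonded_cutoff = 12,
                      coulomb_constant = 332.06) {
  dielectric_model <- match.arg(dielectric_model)
  if (is.null(lj)) {
    lj <- data.frame(
      class   = c("C", "N", "O", "S", "H", "X"),
      epsilon = c(0.066, 0.170, 0.210, 0.250, 0.030, 0.100),
      sigma   = c(3.50, 3.25, 2.96, 3.50, 2.50, 3.50),
      stringsAsFactors = FALSE)
  }
  if (any(lj$epsilon < 0)) stop_domain("lj epsilon must be >= 0")
  if (any(lj$sigma <= 0)) stop_domain("lj sigma must be > 0")
  if (nonbonded_cutoff <= max(lj$sigma))
    stop_domain("cutoff must exceed the largest sigma")
  structure(list(lj = lj, dielectric_model = dielectric_model,
                 dielectric_scale = dielectric_scale,
                 nonbonded_cutoff = nonbonded_cutoff,
                 coulomb_constant = coulomb_constant),
            class = "ligmig_ff")
}

lj_lookup <- function(params, element) {
  i <- match(toupper(element), toupper(params$lj$class))
  i[is.na(i)] <- match("X", toupper(params$lj$class))
  list(epsilon = params$lj$epsilon[i], sigma = params$lj$sigma[i])
}

# Raw (unshifted) pair energy at squared distance r2, given combined
# eps_ij, sig2_ij = sigma_ij^2 and qq = k * q_i * q_j. Vectorized.
.raw_pair <- function(r2, eps, sig2, qq, params) {
  s6 <- (sig2 / r2)^3
  e <- 4 * eps * (s6 * s6 - s6)
  if (params$dielectric_model == "distance_dependent") {
    e + qq / (params$dielectric_scale * r2)
  } else {
    e + qq / (params$dielectric_scale * sqrt(r2))
  }
}

#' Nonbonded energy of a single atom pair
#'
#' Lennard-Jones 12-6 with Lorentz-Berthelot combining plus screened
#' Coulomb, shifted so the energy is continuous (zero) at the cutoff.
#'
#' @param atom_i,atom_j one-row data.frames or lists with fields
#'   \code{element}, \code{charge}, \code{x}, \code{y}, \code{z}.
#' @param params a \code{ligmig_ff}.
#' @return energy in kcal/mol (0 at or beyond the cutoff).
#' @export
pair_energy <- function(atom_i, atom_j, params = ff_params()) {
  d <- c(atom_i$x - atom_j$x, atom_i$y - atom_j$y, atom_i$z - atom_j$z)
  r2 <- sum(d * d)
  if (r2 == 0) stop_domain("pair_energy: atoms coincide (r = 0)")
  rc2 <- params$nonbonded_cutoff^2
  if (r2 >= rc2) return(0)
  li <- lj_lookup(params, atom_i$element)
  lj <- lj_lookup(params, atom_j$element)
  eps <- sqrt(li$epsilon * lj$epsilon)
  sig <- (li$sigma + lj$sigma) / 2
  qq <- params$coulomb_constant * atom_i$charge * atom_j$charge
  .raw_pair(r2, eps, sig^2, qq, params) - .raw_pair(rc2, eps, sig^2, qq, params)
}

# Per-atom combined parameter vectors for fast vectorized evaluation.
.atom_params <- function(atoms, params) {
  l <- lj_lookup(params, atoms$element)
  list(eps = l$epsilon, sig = l$sigma, q = atoms$charge)
}

# Fast evaluator of the total cross (receptor x ligand) energy as a function
# of the ligand coordinate matrix. All pair constants are precomputed; the
# per-call work is one distance pass per ligand atom. With grad = TRUE the
# closure also returns the analytic per-ligand-atom gradient (the same pass
# computes dE/dr^2, so forces cost about one extra vector op per term).
cross_evaluator <- function(rec_atoms, lig_atoms, params) {
  rp <- .atom_params(rec_atoms, params)
  lp <- .atom_params(lig_atoms, params)
  rx <- rec_atoms$x; ry <- rec_atoms$y; rz <- rec_atoms$z
  nl <- nrow(lig_atoms)
  rc2 <- params$nonbonded_cutoff^2
  k <- params$coulomb_constant
  dd <- params$dielectric_model == "distance_dependent"
  ds <- params$dielectric_scale
  # per (receptor-atom, ligand-atom) combined constants, ligand-major
  eps <- lapply(seq_len(nl), function(j) sqrt(rp$eps * lp$eps[j]))
  sig2 <- lapply(seq_len(nl), function(j) ((rp$sig + lp$sig[j]) / 2)^2)
  qq <- lapply(seq_len(nl), function(j) k * rp$q * lp$q[j])
  shift <- lapply(seq_len(nl), function(j) {
    s6 <- (sig2[[j]] / rc2)^3
    e <- 4 * eps[[j]] * (s6 * s6 - s6)
    if (dd) e + qq[[j]] / (ds * rc2) else e + qq[[j]] / (ds * sqrt(rc2))
  })
  function(lig_xyz, grad = FALSE) {
    e_tot <- 0
    G <- if (grad) matrix(0, nl, 3)
    for (j in seq_len(nl)) {
      dx <- lig_xyz[j, 1] - rx; dy <- lig_xyz[j, 2] - ry; dz <- lig_xyz[j, 3] - rz
      r2 <- dx * dx + dy * dy + dz * dz
      sel <- r2 < rc2
      if (!any(sel)) next
      r2s <- r2[sel]
      if (any(r2s == 0)) stop_domain("overlapping atoms (r = 0)")
      s6 <- (sig2[[j]][sel] / r2s)^3
      ee <- eps[[j]][sel]
      qs <- qq[[j]][sel]
      e <- 4 * ee * (s6 * s6 - s6)
      e <- e + if (dd) qs / (ds * r2s) else qs / (ds * sqrt(r2s))
      e_tot <- e_tot + sum(e - shift[[j]][sel])
      if (grad) {
        # dE/dr2 summed over interacting receptor atoms
        de <- -12 * ee * s6 * (2 * s6 - 1) / r2s
        de <- de + if (dd) -qs / (ds * r2s * r2s)
                   else -qs / (2 * ds * r2s^1.5)
        f <- 2 * de
        G[j, ] <- c(sum(f * dx[sel]), sum(f * dy[sel]), sum(f * dz[sel]))
      }
    }
    if (grad) list(energy = e_tot, grad = G) else e_tot
  }
}

#' Internal nonbonded energy of one structure
#'
#' Sum of pair energies over all intra-structure pairs, excluding pairs
#' within the same residue (the stand-in for bonded exclusions).
#'
#' @param structure a \code{ligmig_structure}.
#' @param params a \code{ligmig_ff}.
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(structure, params = ff_params()) {
  at <- structure$atoms
  n <- nrow(at)
  if (n < 2L) return(0)
  res <- paste(at$chain, at$resno)
  ap <- .atom_params(at, params)
  rc2 <- params$nonbonded_cutoff^2
  e_tot <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    keep <- res[j] != res[i]
    if (!any(keep)) next
    j <- j[keep]
    dx <- at$x[j] - at$x[i]; dy <- at$y[j] - at$y[i]; dz <- at$z[j] - at$z[i]
    r2 <- dx * dx + dy * dy + dz * dz
    sel <- r2 < rc2
    if (!any(sel)) next
    j <- j[sel]; r2 <- r2[sel]
    if (any(r2 == 0)) stop_domain("overlapping atoms (r = 0)")
    eps <- sqrt(ap$eps[i] * ap$eps[j])
    sig2 <- ((ap$sig[i] + ap$sig[j]) / 2)^2
    qq <- params$coulomb_constant * ap$q[i] * ap$q[j]
    e_tot <- e_tot + sum(.raw_pair(r2, eps, sig2, qq, params) -
                         .raw_pair(rc2, eps, sig2, qq, params))
  }
  e_tot
}

#' Receptor-ligand interaction energy decomposition
#'
#' The interaction energy is the energy of the complex minus the sum of its
#' parts: E = E_AB - (E_A + E_B). With rigid bodies this equals the sum of
#' all cross (receptor-atom x ligand-atom) pair energies, and the identity
#' \code{e_interaction == e_complex - (e_receptor + e_ligand)} holds exactly.
#'
#' @param receptor,ligand \code{ligmig_structure}s.
#' @param params a \code{ligmig_ff}.
#' @return list of class \code{ligmig_energy} with fields \code{e_complex},
#'   \code{e_receptor}, \code{e_ligand}, \code{e_interaction} (kcal/mol).
#' @export
interaction_energy <- function(receptor, ligand, params = ff_params()) {
  e_a <- structure_energy(receptor, params)
  e_b <- structure_energy(ligand, params)
  ev <- cross_evaluator(receptor$atoms, ligand$atoms, params)
  cross <- ev(coords(ligand))
  e_complex <- e_a + e_b + cross
  # e_interaction is defined through the decomposition, so the identity
  # holds exactly in floating point; it agrees with the cross-pair sum to
  # rounding
  structure(list(e_complex = e_complex,
                 e_receptor = e_a, e_ligand = e_b,
                 e_interaction = e_complex - (e_a + e_b)),
            class = "ligmig_energy")
}

#' Ligand interaction energies against both receptors of a system
#'
#' Bound ligands (frozen poses from earlier binding rounds) count as part of
#' the receptor they are attached to.
#'
#' @param system a \code{ligmig_system}.
#' @param ligand_index index into \code{system$ligands}.
#' @param params a \code{ligmig_ff}.
#' @return list with \code{e_a}, \code{e_b} and their sum \code{total}
#'   (kcal/mol); \code{e_b} is 0 when receptor B is absent.
#' @export
system_energy <- function(system, ligand_index = 1L, params = ff_params()) {
  if (ligand_index < 1L || ligand_index > length(system$ligands))
    stop_domain("invalid ligand index %d", ligand_index)
  lig <- system$ligands[[ligand_index]]
  side_atoms <- receptor_side_atoms(system)
  e_a <- cross_evaluator(side_atoms$a, lig$atoms, params)(coords(lig))
  e_b <- if (is.null(side_atoms$b)) 0
         else cross_evaluator(side_atoms$b, lig$atoms, params)(coords(lig))
  list(e_a = e_a, e_b = e_b, total = e_a + e_b)
}

# Atom tables for each receptor side, with bound ligands merged into the
# receptor they are attached to.
receptor_side_atoms <- function(system) {
  a <- system$receptor_a$atoms
  b <- if (is.null(system$receptor_b)) NULL else system$receptor_b$atoms
  for (bl in system$bound) {
    side <- attr(bl, "receptor") %||% "a"
    if (side == "a") a <- rbind(a, bl$atoms)
    else if (!is.null(b)) b <- rbind(b, bl$atoms)
  }
  list(a = a, b = b)
}
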