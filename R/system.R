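# Assembly of the two-receptor competitive system.

#' Assemble a two-receptor competitive system
#'
#' Receptor A is centered at the origin (by COM) and receptor B rigidly
#' translated onto the x-axis so that the inter-COM distance equals
#' \code{separation}. Each unbound ligand COM is placed on the perpendicular
#' bisector plane of the COM--COM segment, at \code{ligand_offset} from both
#' receptor COMs; the placement angle on that circle is drawn from
#' \code{seed} (the geometry fixes only the two distances, not a direction).
#'
#' Defaults follow the competitive-binding protocol: receptors 67 Angstrom
#' apart, ligands equidistant at 42 Angstrom.
#'
#' @param receptor_a,receptor_b \code{ligmig_structure} receptors.
#' @param ligands a single ligand structure or a list of them.
#' @param separation inter-receptor COM distance (Angstrom, default 67).
#' @param ligand_offset ligand COM to each receptor COM (Angstrom, default 42).
#' @param seed integer controlling the placement angle(s).
#' @return object of class \code{ligmig_system} with fields
#'   \code{receptor_a}, \code{receptor_b}, \code{ligands} (list),
#'   \code{bound} (list of ligand structures frozen onto a receptor, with a
#'   \code{"receptor"} attribute), and \code{geometry}.
#' @export
assemble_system <- function(receptor_a, receptor_b, ligands,
                            separation = 67, ligand_offset = 42, seed = 1) {
  if (inherits(ligands, "ligmig_structure")) ligands <- list(ligands)
  if (!is.numeric(separation) || separation <= 0)
    stop_geometry("separation must be > 0")
  if (ligand_offset < separation / 2)
    stop_geometry(
      "ligand_offset (%.3g) < separation/2 (%.3g): equidistant placement impossible",
      ligand_offset, separation / 2)
  receptor_a <- translate_structure(receptor_a, -center_of_mass(receptor_a))
  receptor_b <- translate_structure(receptor_b, -center_of_mass(receptor_b))
  receptor_b <- translate_structure(receptor_b, c(separation, 0, 0))
  mid <- c(separation / 2, 0, 0)
  rho <- sqrt(max(ligand_offset^2 - (separation / 2)^2, 0))
  thetas <- with_seed(seed, stats::runif(length(ligands), 0, 2 * pi))
  ligands <- lapply(seq_along(ligands), function(i) {
    lg <- ligands[[i]]
    target <- mid + rho * c(0, cos(thetas[i]), sin(thetas[i]))
    translate_structure(lg, target - center_of_mass(lg))
  })
  sys <- structure(list(
    receptor_a = receptor_a, receptor_b = receptor_b,
    ligands = ligands, bound = list(),
    geometry = list(separation = separation, ligand_offset = ligand_offset,
                    seed = seed)),
    class = "ligmig_system")
  validate_system(sys)
  sys
}

validate_system <- function(sys, tol = 1e-6) {
  ca <- center_of_mass(sys$receptor_a)
  if (!is.null(sys$receptor_b)) {
    cb <- center_of_mass(sys$receptor_b)
    if (abs(vnorm(ca - cb) - sys$geometry$separation) > tol)
      stop_geometry("inter-receptor COM distance violates the separation")
    for (lg in sys$ligands) {
      cl <- center_of_mass(lg)
      if (abs(vnorm(cl - ca) - sys$geometry$ligand_offset) > tol ||
          abs(vnorm(cl - cb) - sys$geometry$ligand_offset) > tol)
        stop_geometry("ligand COM is not equidistant at the stated offset")
    }
  }
  invisible(sys)
}

#' Receptor COMs of a system
#' @param system a \code{ligmig_system}
#' @return list with elements \code{a} and \code{b} (NULL if absent)
#' @export
receptor_coms <- function(system) {
  list(a = center_of_mass(system$receptor_a),
       b = if (is.null(system$receptor_b)) NULL
           else center_of_mass(system$receptor_b))
}

#' @export
print.ligmig_system <- function(x, ...) {
  cat(sprintf(
    "<ligmig_system> A: %d atoms (q=%+.1f), B: %s, %d free ligand(s), %d bound; sep %.1f A, offset %.1f A\n",
    nrow(x$receptor_a$atoms), net_charge(x$receptor_a),
    if (is.null(x$receptor_b)) "absent"
    else sprintf("%d atoms (q=%+.1f)", nrow(x$receptor_b$atoms),
                 net_charge(x$receptor_b)),
    length(x$ligands), length(x$bound),
    x$geometry$separation, x$geometry$ligand_offset))
  invisible(x)
}
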