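# Atomic structures: PDB I/O, center of mass, protonation, superposition.

# Standard atomic masses (amu) for the elements this package meets; pseudo
# beads ("X") are carbon-mass.
.element_masses <- c(
  "H" = 1.008, "C" = 12.011, "N" = 14.007, "O" = 15.999, "P" = 30.974,
  "S" = 32.06, "F" = 18.998, "CL" = 35.45, "BR" = 79.904, "I" = 126.904,
  "FE" = 55.845, "ZN" = 65.38, "MG" = 24.305, "NA" = 22.990, "K" = 39.098,
  "CA" = 40.078, "X" = 12.011
)

element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  m[is.na(m)] <- .element_masses[["X"]]
  unname(m)
}

# Infer the element from a PDB atom-name token (columns 13-16) when the
# element column is blank: strip digits/primes, take the leading alpha token;
# two-letter elements only when they match a known symbol.
infer_element <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9' ]", "", nm)
    if (!nzchar(nm)) return("X")
    two <- toupper(substr(nm, 1, 2))
    if (nchar(nm) >= 2 && two %in% names(.element_masses) &&
        !two %in% c("CA", "NA")) return(two)  # CA/NA in proteins are C/N atoms
    toupper(substr(nm, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' Construct an atomic structure
#'
#' The package's basic container: an ordered table of atom records plus a
#' label. Masses default from the element; partial charges default to zero
#' (PDB files carry no usable charge column; synthetic fixtures ship charges
#' in a sidecar CSV).
#'
#' @param atoms data.frame with columns \code{serial, name, element, resname,
#'   resno, chain, x, y, z} and optionally \code{mass, charge}.
#' @param label free-text label.
#' @return object of class \code{ligmig_structure}.
#' @export
mol_structure <- function(atoms, label = "") {
  need <- c("serial", "name", "element", "resname", "resno", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop_domain("atom table is missing column(s): %s",
                paste(miss, collapse = ", "))
  if (nrow(atoms) < 1L) stop_domain("a structure needs at least one atom")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop_domain("non-finite atom coordinates")
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop_domain("atom masses must be positive and finite")
  if (any(!nzchar(atoms$element))) stop_domain("empty element symbol")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label), class = "ligmig_structure")
}

#' @export
print.ligmig_structure <- function(x, ...) {
  cat(sprintf("<ligmig_structure> %s: %d atoms, net charge %+.3f e\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$atoms), net_charge(x)))
  invisible(x)
}

#' Net charge of a structure (sum of per-atom partial charges)
#' @param structure a \code{ligmig_structure}
#' @return net charge in elementary-charge units
#' @export
net_charge <- function(structure) sum(structure$atoms$charge)

#' Coordinates of a structure as an n x 3 matrix
#' @param structure a \code{ligmig_structure}
#' @return numeric matrix with columns x, y, z
#' @export
coords <- function(structure)
  unname(as.matrix(structure$atoms[, c("x", "y", "z")]))

set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure$atoms))
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

translate_structure <- function(structure, t) {
  set_coords(structure, sweep(coords(structure), 2, -t, "-"))
}

# rigid rotation about the structure's own (heavy-atom) center of mass;
# R acts on column vectors, coordinates are rows
rotate_about_com <- function(structure, R) {
  ctr <- center_of_mass(structure)
  xyz <- sweep(coords(structure), 2, ctr)
  set_coords(structure, sweep(xyz %*% t(R), 2, -ctr, "-"))
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (first MODEL of a multi-model file) via
#' \pkg{bio3d}; masses are assigned from the element, which is inferred from
#' the atom name when the element column is blank. Charges are initialized
#' to zero. Alternate locations other than ' ' or 'A' are dropped.
#'
#' @param path path to a PDB file.
#' @param label optional label; defaults to the file name.
#' @return a \code{ligmig_structure}.
#' @export
read_pdb <- function(path, label = NULL) {
  if (!file.exists(path)) stop_input("PDB file not found: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop_format("cannot parse PDB %s: %s", path,
                                    conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop_format("no ATOM/HETATM records in %s", path)
  keep <- is.na(at$alt) | at$alt %in% c("", " ", "A")
  at <- at[keep, , drop = FALSE]
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad))
    stop_format("malformed coordinate field in %s (atom serial %s)",
                path, at$eleno[bad[1]])
  elem <- at$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- infer_element(at$elety[blank])
  elem <- toupper(trimws(elem))
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = elem,
    resname = at$resid, resno = at$resno, chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    mass = element_mass(elem), charge = 0,
    stringsAsFactors = FALSE)
  mol_structure(atoms, label = label %||% basename(path))
}

#' Read all models of a multi-model PDB file
#' @param path path to a PDB file with MODEL/ENDMDL blocks.
#' @return list with the first-model \code{structure} and a list of
#'   per-model coordinate matrices \code{models}.
#' @export
read_pdb_models <- function(path) {
  s <- read_pdb(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  models <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  list(structure = s, models = models)
}

fmt_pdb_line <- function(rec, serial, name, resname, chain, resno, x, y, z,
                         element) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial %% 100000L, nm, substr(resname, 1, 3),
          substr(chain, 1, 1), resno %% 10000L, x, y, z, 1.0, 0.0,
          substr(element, 1, 2))
}

#' Write a structure to a PDB file
#'
#' Fixed-column PDB v3 ATOM/HETATM records. Protein-standard residue names
#' are written as ATOM, everything else as HETATM. If \code{models} is
#' supplied (a list of n x 3 coordinate matrices) a multi-model file with
#' MODEL/ENDMDL blocks is written, one block per matrix.
#'
#' @param structure a \code{ligmig_structure}.
#' @param path output path.
#' @param models optional list of coordinate matrices for multi-model output.
#' @return path, invisibly.
#' @export
write_pdb <- function(structure, path, models = NULL) {
  if (!inherits(structure, "ligmig_structure") || nrow(structure$atoms) == 0L)
    stop_domain("refusing to write an empty structure")
  at <- structure$atoms
  aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
           "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
  rec <- ifelse(toupper(at$resname) %in% aa3, "ATOM", "HETATM")
  body <- function(xyz) {
    vapply(seq_len(nrow(at)), function(i)
      fmt_pdb_line(rec[i], at$serial[i], at$name[i], at$resname[i],
                   at$chain[i], at$resno[i], xyz[i, 1], xyz[i, 2], xyz[i, 3],
                   at$element[i]),
      character(1))
  }
  con <- tryCatch(file(path, "wt"),
                  error = function(e) stop_input("cannot write %s", path))
  on.exit(close(con))
  if (is.null(models)) {
    writeLines(c(body(coords(structure)), "END"), con)
  } else {
    for (m in seq_along(models)) {
      writeLines(sprintf("MODEL     %4d", m), con)
      writeLines(body(models[[m]]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Center of mass
#'
#' Mass-weighted mean position. By default hydrogens are excluded, matching
#' the common heavy-atom convention for ligand/receptor COM distances.
#'
#' @param structure a \code{ligmig_structure}.
#' @param heavy_only exclude hydrogens (default TRUE).
#' @return length-3 numeric vector (x, y, z) in Angstroms.
#' @export
center_of_mass <- function(structure, heavy_only = TRUE) {
  at <- structure$atoms
  if (heavy_only) at <- at[toupper(at$element) != "H", , drop = FALSE]
  if (nrow(at) == 0L) stop_domain("no atoms left after heavy-atom filter")
  w <- at$mass / sum(at$mass)
  c(sum(w * at$x), sum(w * at$y), sum(w * at$z))
}

com_xyz <- function(xyz, mass) {
  w <- mass / sum(mass)
  c(sum(w * xyz[, 1]), sum(w * xyz[, 2]), sum(w * xyz[, 3]))
}

#' Protonation states of the histamine-like ligand
#'
#' Fixed mapping from protonation token to ligand net charge:
#' \code{deprotonated} = 0, \code{amine_protonated} = +1,
#' \code{imidazole_protonated} = +2. The imidazole state is cumulative:
#' protonating the imidazole nitrogen is read as *further* protonation on
#' top of the charged amine terminus, so the ligand carries +2 (one unit on
#' the amine site, one on the imidazole/ring site).
#'
#' @param token one of \code{"deprotonated"}, \code{"amine_protonated"},
#'   \code{"imidazole_protonated"}.
#' @return list with \code{token} and \code{net_ligand_charge}.
#' @export
protonation_state <- function(token = c("deprotonated", "amine_protonated",
                                        "imidazole_protonated")) {
  token <- match.arg(token)
  charge <- c(deprotonated = 0, amine_protonated = 1,
              imidazole_protonated = 2)[[token]]
  list(token = token, net_ligand_charge = charge)
}

# Designated protonation sites, located by atom name.
.amine_names <- c("AMN", "NZ", "NT")
.imidazole_names <- c("RG1", "ND1", "NE2")

#' Assign a protonation state to a ligand
#'
#' Sets the ligand's partial charges so that its net charge equals the
#' state's mapped value: all charges are cleared, then +1 is placed on the
#' designated amine-terminus site (states +1 and +2) and a further +1 on the
#' designated imidazole/ring site (state +2). Geometry is untouched.
#'
#' @param ligand a \code{ligmig_structure} with designated amine and
#'   imidazole sites (atom names AMN/NZ/NT and RG1/ND1/NE2).
#' @param state a token accepted by \code{\link{protonation_state}}, or the
#'   list it returns.
#' @return the ligand with updated charges.
#' @export
assign_protonation <- function(ligand, state) {
  if (is.character(state)) state <- protonation_state(state)
  at <- ligand$atoms
  amine <- which(toupper(at$name) %in% .amine_names)[1]
  imid <- which(toupper(at$name) %in% .imidazole_names)[1]
  if (is.na(amine)) stop_domain("ligand has no designated amine-terminus site")
  if (is.na(imid)) stop_domain("ligand has no designated imidazole site")
  at$charge <- 0
  if (state$net_ligand_charge >= 1) at$charge[amine] <- at$charge[amine] + 1
  if (state$net_ligand_charge >= 2) at$charge[imid] <- at$charge[imid] + 1
  ligand$atoms <- at
  ligand$protonation <- state$token
  ligand
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired point sets (no reflection allowed).
#'
#' @param mobile n x 3 matrix to be fitted.
#' @param reference n x 3 matrix, paired by row.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3;
#'   the fit is \code{mobile \%*\% rotation + translation}), and \code{rmsd}
#'   after the fit.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop_domain("superpose: point counts differ (%d vs %d)",
                nrow(mobile), nrow(reference))
  if (nrow(mobile) < 3L) stop_domain("superpose needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  R <- t(R)  # so that fitted = mobile %*% R + t
  tvec <- cr - cm %*% R
  fitted <- sweep(mobile %*% R, 2, -as.numeric(tvec), "-")
  list(rotation = R, translation = as.numeric(tvec),
       rmsd = sqrt(mean(rowSums((fitted - reference)^2))))
}
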