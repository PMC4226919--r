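# Shared toy builders and independent oracles for the test suite.

toy_atoms <- function(xyz, element = "C", charge = 0, resno = NULL,
                      chain = "A") {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  n <- nrow(xyz)
  data.frame(serial = seq_len(n), name = paste0("X", seq_len(n)),
             element = rep_len(element, n), resname = "TOY",
             resno = resno %||% seq_len(n), chain = rep_len(chain, n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             charge = rep_len(charge, n), stringsAsFactors = FALSE)
}

toy_structure <- function(xyz, element = "C", charge = 0, resno = NULL,
                          chain = "A", label = "toy") {
  mol_structure(toy_atoms(xyz, element, charge, resno, chain), label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force pair-energy oracle: literal formula, scalar loop,
# no shared code with the package's vectorized evaluators.
oracle_pair <- function(ai, aj, params) {
  r <- sqrt((ai$x - aj$x)^2 + (ai$y - aj$y)^2 + (ai$z - aj$z)^2)
  rc <- params$nonbonded_cutoff
  if (r >= rc) return(0)
  lj_of <- function(el) {
    i <- match(toupper(el), toupper(params$lj$class))
    if (is.na(i)) i <- match("X", toupper(params$lj$class))
    params$lj[i, ]
  }
  li <- lj_of(ai$element); lj <- lj_of(aj$element)
  eps <- sqrt(li$epsilon * lj$epsilon)
  sig <- (li$sigma + lj$sigma) / 2
  e_at <- function(rr) {
    lj_term <- 4 * eps * ((sig / rr)^12 - (sig / rr)^6)
    coul <- if (params$dielectric_model == "distance_dependent") {
      params$coulomb_constant * ai$charge * aj$charge /
        (params$dielectric_scale * rr * rr)
    } else {
      params$coulomb_constant * ai$charge * aj$charge /
        (params$dielectric_scale * rr)
    }
    lj_term + coul
  }
  e_at(r) - e_at(rc)
}

oracle_cross_energy <- function(rec, lig, params) {
  e <- 0
  for (i in seq_len(nrow(rec$atoms)))
    for (j in seq_len(nrow(lig$atoms)))
      e <- e + oracle_pair(rec$atoms[i, ], lig$atoms[j, ], params)
  e
}

# Independent greedy quality-threshold clustering: plain loops over a
# point matrix, returning a membership integer vector (0 = unassigned).
oracle_qt_cluster <- function(pts, cutoff, max_clusters) {
  n <- nrow(pts)
  member <- integer(n)
  active <- rep(TRUE, n)
  cl <- 0L
  while (cl < max_clusters && any(active)) {
    best <- 0L; best_n <- -1L
    for (i in which(active)) {
      cnt <- 0L
      for (j in which(active)) {
        if (i != j &&
            sqrt(sum((pts[i, ] - pts[j, ])^2)) <= cutoff) cnt <- cnt + 1L
      }
      if (cnt > best_n) { best_n <- cnt; best <- i }
    }
    if (best_n == 0L) break
    cl <- cl + 1L
    for (j in which(active)) {
      if (j == best || sqrt(sum((pts[best, ] - pts[j, ])^2)) <= cutoff) {
        member[j] <- cl
        active[j] <- FALSE
      }
    }
  }
  member
}

# pooled frame table with planted COM positions; accepts an n x 3 matrix
# or a flat vector read row-wise
planted_frames <- function(coms, chain = 1L, e = -1) {
  if (!is.matrix(coms)) coms <- matrix(coms, ncol = 3, byrow = TRUE)
  n <- nrow(coms)
  data.frame(chain = rep_len(chain, n), step = seq_len(n),
             e_interaction = rep_len(e, n), e_a = 0, e_b = 0,
             dist_a = 1, dist_b = 1,
             com_x = coms[, 1], com_y = coms[, 2], com_z = coms[, 3],
             spawned = FALSE, accepted = TRUE, dwell = 1, frame = seq_len(n))
}

standard_fixture <- function(state = "amine_protonated", seed = 1) {
  make_competition_fixture(fixture_spec("pocket_receptor", seed = 3),
                           fixture_spec("acidic_barrel", seed = 2),
                           state, seed = seed, scaled = TRUE)
}
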