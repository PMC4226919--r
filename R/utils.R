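`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

#' Rotation matrix from axis and angle (Rodrigues formula)
#' @param axis numeric length-3, need not be normalized
#' @param angle rotation angle in radians
#' @return 3x3 rotation matrix
#' @keywords internal
rotation_matrix <- function(axis, angle) {
  n <- vnorm(axis)
  if (n < .Machine$double.eps) return(diag(3))
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Run expr under a fixed seed, restoring the caller's RNG state afterwards,
# so seeded operations never perturb the global random stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Classed conditions so callers (and the CLI) can map errors to exit codes.
stop_ligmig <- function(class, msg, ...) {
  stop(structure(class = c(class, "ligmig_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
stop_input    <- function(msg, ...) stop_ligmig("ligmig_input_error", msg, ...)
stop_format   <- function(msg, ...) stop_ligmig("ligmig_format_error", msg, ...)
stop_domain   <- function(msg, ...) stop_ligmig("ligmig_domain_error", msg, ...)
stop_geometry <- function(msg, ...) stop_ligmig("ligmig_geometry_error", msg, ...)
stop_config   <- function(msg, ...) stop_ligmig("ligmig_config_error", msg, ...)
stop_protocol <- function(msg, ...) stop_ligmig("ligmig_protocol_error", msg, ...)
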