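# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards.  All stochastic generators in
#' the package route their randomness through this helper so that everything
#' outside the synthetic-data module stays deterministic.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Residue key: chain id, author residue number, insertion code verbatim.
residue_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", resno, icode)
}

# van der Waals radii (Angstrom) by element, Bondi-style values used for the
# sphere-point solvent-accessible surface.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                H = 1.20, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                SE = 1.90)

vdw_radius <- function(element) {
  el <- toupper(trimws(element))
  r <- .vdw_radii[el]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Deterministic near-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Rotation matrices about the z / x axes, angle in radians (row-vector
# convention: use as xyz %*% rot).
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

rot_x <- function(theta) {
  matrix(c(1, 0, 0,
           0, cos(theta), sin(theta),
           0, -sin(theta), cos(theta)), 3, 3)
}

# Random proper rotation matrix (QR of a Gaussian matrix, det forced to +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
}
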