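# Force-constant rigidity profiling, B-factors, and residue-depth
# solvent-protection profiles.
#
# The rigidity profile follows the distance-fluctuation convention: for each
# residue i the mean distance d_i(t) to all non-neighbor residues is tracked
# over the ensemble, and the effective force constant is the inverse of its
# variance scaled by thermal energy,
#
#     k_i = factor * k_B * T / < (d_i - <d_i>)^2 >     [kcal/mol/A^2]
#
# with factor = 3 by default (the fluctuation-method convention; the profile
# is used comparatively, so the scale is a configurable convention, not a
# fitted quantity).

#' Configuration for stability profiling
#'
#' @param k_b Boltzmann constant, kcal mol^-1 K^-1.
#' @param temperature temperature in Kelvin (default 300).
#' @param exclusion neighbor-exclusion width in residues: atoms of residues
#'   i-w .. i+w (same chain) are excluded from residue i's distance average,
#'   since those distances are nearly constant (default 1).
#' @param mode residue representation, `"calpha"` or `"allatom"` (see
#'   [select_residue_atoms()]).
#' @param factor proportionality constant multiplying k_B T (default 3).
#' @param rigid_tol variance (Angstrom^2) below which a residue is flagged
#'   rigid instead of being assigned a force constant.
#' @return list of class `stability_config`.
#' @export
stability_config <- function(k_b = 1.987e-3, temperature = 300, exclusion = 1,
                             mode = "calpha", factor = 3, rigid_tol = 1e-12) {
  if (temperature <= 0) stop("'temperature' must be positive")
  if (exclusion < 0) stop("'exclusion' must be >= 0")
  obj <- list(k_b = k_b, temperature = temperature,
              exclusion = as.integer(exclusion), mode = mode,
              factor = factor, rigid_tol = rigid_tol)
  class(obj) <- "stability_config"
  obj
}

#' Per-atom mean-distance series over an ensemble
#'
#' For every selection atom a (belonging to residue i), computes the mean
#' distance from a to all selection atoms of admissible residues in each
#' frame.  Admissible partners exclude residue i itself and its sequence
#' neighbors within the configured exclusion width (same chain only;
#' inter-chain pairs are always admissible).
#'
#' @param ensemble a [conf_ensemble()] with >= 2 frames.
#' @param selection a [select_residue_atoms()] selection; defaults to the
#'   config's mode.
#' @param config a [stability_config()].
#' @return object of class `distance_series`: matrix `d` (frames x selection
#'   atoms), the atom-to-residue map, and the residue table.
#' @export
mean_distance_series <- function(ensemble, selection = NULL,
                                 config = stability_config()) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  nf <- n_frames(ensemble)
  if (nf < 2L) stop("ensemble has a single frame: no fluctuations to analyze")
  if (is.null(selection)) selection <- select_residue_atoms(ensemble, config$mode)
  rt <- selection$residues
  atom_idx <- unlist(selection$atom_idx)
  atom_res <- rep(seq_len(nrow(rt)), lengths(selection$atom_idx))
  a <- length(atom_idx)
  excl <- config$exclusion

  # admissible residue pairs: different residue, and (different chain OR
  # |chain position difference| > exclusion width)
  same_chain <- outer(rt$chain, rt$chain, "==")
  pos_diff <- abs(outer(rt$chain_pos, rt$chain_pos, "-"))
  res_ok <- !(same_chain & pos_diff <= excl)

  n_admissible <- rowSums(res_ok)
  if (any(n_admissible == 0L))
    stop("no admissible partner residues under exclusion width ", excl,
         " for residue(s): ",
         paste(rt$key[n_admissible == 0L], collapse = ", "))

  x <- ensemble$coords[atom_idx, , , drop = FALSE]  # [a, 3, frames]
  d <- matrix(0, nf, a)
  for (ai in seq_len(a)) {
    diff2 <- sweep(x, c(2, 3), x[ai, , ], `-`)^2
    dm <- sqrt(colSums(matrix(aperm(diff2, c(2, 1, 3)), nrow = 3)))
    dm <- matrix(dm, a, nf)  # distances from atom ai to every atom, per frame
    ok <- res_ok[atom_res[ai], atom_res]
    d[, ai] <- colMeans(dm[ok, , drop = FALSE])
  }
  obj <- list(d = d, atom_res = atom_res, residues = rt,
              mode = selection$mode, exclusion = excl)
  class(obj) <- "distance_series"
  obj
}

#' Force-constant profile from a distance series
#'
#' Computes k = factor * k_B * T / Var(d) per selection atom (population
#' variance over frames), then averages atom force constants within each
#' residue; with an alpha-carbon selection this reduces to one value per
#' residue.  Residues whose every atom has (numerically) zero variance are
#' flagged rigid and carry no numeric force constant.
#'
#' @param series a [mean_distance_series()] result.
#' @param config a [stability_config()].
#' @return a [residue_profile()] of class `fc_profile` with columns `value`
#'   (k_i, kcal mol^-1 A^-2; `NA` for rigid residues), `d_mean`, `d_var`,
#'   `rigid`.
#' @export
force_constants <- function(series, config = stability_config()) {
  stopifnot(inherits(series, "distance_series"))
  f <- nrow(series$d)
  mu <- colMeans(series$d)
  v <- colMeans(series$d^2) - mu^2
  v[v < 0] <- 0  # numerical guard
  kt <- config$factor * config$k_b * config$temperature
  k_atom <- ifelse(v > config$rigid_tol, kt / v, NA_real_)
  nres <- nrow(series$residues)
  k <- d_mean <- d_var <- numeric(nres)
  rigid <- logical(nres)
  for (r in seq_len(nres)) {
    sel <- series$atom_res == r
    d_mean[r] <- mean(mu[sel])
    d_var[r] <- mean(v[sel])
    ka <- k_atom[sel]
    if (all(is.na(ka))) {
      rigid[r] <- TRUE
      k[r] <- NA_real_
    } else k[r] <- mean(ka, na.rm = TRUE)
  }
  p <- residue_profile(series$residues, k, "force_constant")
  p$d_mean <- d_mean
  p$d_var <- d_var
  p$rigid <- rigid
  class(p) <- c("fc_profile", class(p))
  attr(p, "config") <- config
  p
}

#' Force-constant profile straight from an ensemble
#'
#' Convenience wrapper chaining [select_residue_atoms()],
#' [mean_distance_series()] and [force_constants()].
#'
#' @inheritParams mean_distance_series
#' @return an `fc_profile`.
#' @export
force_constant_profile <- function(ensemble, config = stability_config()) {
  sel <- select_residue_atoms(ensemble, config$mode)
  force_constants(mean_distance_series(ensemble, sel, config), config)
}

#' @export
print.fc_profile <- function(x, ...) {
  cat(sprintf("fc_profile: %d residues, %d rigid; k range [%.3g, %.3g] kcal/mol/A^2\n",
              nrow(x), sum(x$rigid),
              suppressWarnings(min(x$value, na.rm = TRUE)),
              suppressWarnings(max(x$value, na.rm = TRUE))))
  invisible(as.data.frame(x))
}

#' @export
plot.fc_profile <- function(x, ...) {
  v <- x$value
  cap <- suppressWarnings(max(v, na.rm = TRUE))
  v[x$rigid] <- cap  # rigid residues capped at the profile maximum
  graphics::plot(seq_along(v), v, type = "l", xlab = "residue index",
                 ylab = "force constant (kcal/mol/A^2)", ...)
  if (any(x$rigid)) graphics::points(which(x$rigid), v[x$rigid], pch = 17)
  invisible(x)
}

#' Computed B-factors from an ensemble
#'
#' B_i = (8 pi^2 / 3) <|dr_i|^2>, the mean squared displacement of the
#' residue's representative atoms about their ensemble mean (frames are
#' assumed already superposed; see [superpose()]).
#'
#' @param ensemble a [conf_ensemble()].
#' @param selection a [select_residue_atoms()] selection (default alpha
#'   carbons).
#' @return a [residue_profile()] of B-factors in Angstrom^2.
#' @export
bfactors <- function(ensemble, selection = NULL) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (is.null(selection)) selection <- select_residue_atoms(ensemble, "calpha")
  nf <- n_frames(ensemble)
  if (nf < 2L) {
    warning("single-frame ensemble: B-factors are identically zero")
    return(residue_profile(selection$residues,
                           rep(0, nrow(selection$residues)), "bfactor"))
  }
  b <- vapply(selection$atom_idx, function(idx) {
    x <- ensemble$coords[idx, , , drop = FALSE]           # [na, 3, nf]
    m <- apply(x, c(1, 2), mean)
    dev2 <- sweep(x, c(1, 2), m, `-`)^2
    msd_per_atom <- colMeans(t(apply(dev2, c(1, 3), sum))) # mean over frames
    mean(msd_per_atom)
  }, numeric(1))
  residue_profile(selection$residues, (8 * pi^2 / 3) * b, "bfactor")
}

#' Residue-depth profile below the solvent-accessible surface
#'
#' Per frame, the solvent-accessible surface is approximated by a
#' deterministic golden-spiral point cloud on each atom's expanded sphere
#' (van der Waals radius + probe), keeping points not buried inside any other
#' atom's expanded sphere.  An atom's depth is the minimum distance from its
#' center to any surface point; a residue's depth is the mean over its heavy
#' atoms, and the profile is the mean over frames.  An isolated atom's depth
#' is exactly its expanded radius.
#'
#' @param ensemble a [conf_ensemble()] (heavy atoms).
#' @param probe_radius solvent probe radius, Angstrom (default 1.4).
#' @param n_sphere_points surface points per atom (default 96).
#' @return a [residue_profile()] of depths in Angstrom.
#' @export
residue_depth_profile <- function(ensemble, probe_radius = 1.4,
                                  n_sphere_points = 96) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  at <- ensemble$topology$atoms
  n <- nrow(at)
  if (n < 2L) stop("residue depth requires a structure with >= 2 atoms")
  radii <- vdw_radius(at$element) + probe_radius
  unit <- sphere_points(n_sphere_points)
  nf <- n_frames(ensemble)
  depth <- matrix(NA_real_, n, nf)
  for (f in seq_len(nf)) {
    xyz <- ensemble$coords[, , f, drop = TRUE]
    surf <- vector("list", n)
    for (i in seq_len(n)) {
      pts <- sweep(unit * radii[i], 2, xyz[i, ], `+`)
      keep <- rep(TRUE, nrow(pts))
      for (j in seq_len(n)[-i]) {
        if (!any(keep)) break
        dj2 <- colSums((t(pts[keep, , drop = FALSE]) - xyz[j, ])^2)
        keep[keep] <- dj2 > (radii[j] - 1e-9)^2
      }
      surf[[i]] <- pts[keep, , drop = FALSE]
    }
    allsurf <- do.call(rbind, surf)
    if (!nrow(allsurf)) stop("no solvent-accessible surface points generated")
    for (i in seq_len(n)) {
      d2 <- colSums((t(allsurf) - xyz[i, ])^2)
      depth[i, f] <- sqrt(min(d2))
    }
  }
  atom_depth <- rowMeans(depth)
  rt <- residue_table(ensemble)
  res_of <- match(at$key, rt$key)
  val <- vapply(seq_len(nrow(rt)), function(r) mean(atom_depth[res_of == r]),
                numeric(1))
  residue_profile(rt, val, "depth")
}

#' Differential residue-depth profile between two states
#'
#' Positive values mean increased burial/solvent protection in state `a`.
#' Profiles are matched on residue keys; residues present in only one state
#' are dropped with a warning.
#'
#' @param state_a,state_b [residue_profile()]s of depths.
#' @return a [residue_profile()] of depth differences (a minus b).
#' @export
differential_depth <- function(state_a, state_b) {
  common <- intersect(state_a$key, state_b$key)
  if (!length(common)) stop("profiles share no residues")
  drop_n <- (nrow(state_a) - length(common)) + (nrow(state_b) - length(common))
  if (drop_n > 0)
    warning(drop_n, " residue(s) present in only one state were dropped")
  ia <- match(common, state_a$key)
  ib <- match(common, state_b$key)
  residue_profile(state_a[ia, c("chain", "resno", "icode", "resname")],
                  state_a$value[ia] - state_b$value[ib], "delta_depth")
}
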