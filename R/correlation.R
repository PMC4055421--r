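# Frame superposition, coordinate covariance, residue cross-correlation
# matrices, principal modes, and mode-averaged mobility profiles.

# Kabsch optimal rotation: rotates `mobile` (already centered) onto `ref`
# (already centered).  Returns the 3x3 proper rotation matrix.
kabsch_rotation <- function(mobile, ref) {
  s <- svd(crossprod(mobile, ref))  # M = U D V'
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superpose ensemble frames onto their iteratively refined mean
#'
#' Each frame is least-squares fitted (optimal rotation + translation, equal
#' weights) onto the running mean structure of the selection atoms; the mean
#' is recomputed and the fit repeated until it moves by less than `tol`
#' (RMSD, Angstrom).  The transform computed on the selection is applied to
#' all atoms.
#'
#' @param ensemble a [conf_ensemble()] with >= 2 frames.
#' @param selection fitting selection (default alpha carbons).
#' @param tol convergence tolerance on the mean-structure RMSD change.
#' @param max_iter iteration cap.
#' @return the superposed [conf_ensemble()].
#' @export
superpose <- function(ensemble, selection = NULL, tol = 1e-6, max_iter = 50) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (n_frames(ensemble) < 2L) stop("superposition requires >= 2 frames")
  if (is.null(selection)) selection <- select_residue_atoms(ensemble, "calpha")
  sel <- unlist(selection$atom_idx)
  if (length(sel) < 3L) stop("superposition requires >= 3 selection atoms")
  coords <- ensemble$coords
  nf <- dim(coords)[3]

  ref <- coords[sel, , 1, drop = TRUE]
  refc <- sweep(ref, 2, colMeans(ref))
  sv <- svd(refc)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate (collinear) selection: superposition is underdetermined")

  mean_sel <- refc
  for (it in seq_len(max_iter)) {
    for (f in seq_len(nf)) {
      fr <- coords[, , f, drop = TRUE]
      mob <- fr[sel, , drop = FALSE]
      mc <- colMeans(mob)
      r <- kabsch_rotation(sweep(mob, 2, mc), mean_sel)
      coords[, , f] <- sweep(fr, 2, mc) %*% r
    }
    new_mean <- apply(coords[sel, , , drop = FALSE], c(1, 2), mean)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    shift <- sqrt(mean(rowSums((new_mean - mean_sel)^2)))
    mean_sel <- new_mean
    if (shift < tol) break
  }
  out <- ensemble
  out$coords <- coords
  out
}

# One representative point per residue: centroid of the residue's selection
# atoms per frame.  Returns [n_res, 3, nf].
residue_points <- function(ensemble, selection) {
  nf <- n_frames(ensemble)
  nres <- nrow(selection$residues)
  arr <- array(NA_real_, c(nres, 3L, nf))
  for (r in seq_len(nres)) {
    idx <- selection$atom_idx[[r]]
    if (length(idx) == 1L) arr[r, , ] <- ensemble$coords[idx, , ]
    else arr[r, , ] <- apply(ensemble$coords[idx, , , drop = FALSE], c(2, 3), mean)
  }
  arr
}

#' Residue dynamic cross-correlation matrix
#'
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>) over frames, with one
#' representative point per residue (the alpha carbon under the default
#' selection).  The ensemble should already be superposed.  C_ij = 1 marks
#' fully in-phase motion, C_ij = -1 anti-phase motion.  Residues with zero
#' fluctuation get correlation 0 to every partner (flagged), and a unit
#' diagonal is enforced.
#'
#' @param ensemble a superposed [conf_ensemble()] with >= 3 frames.
#' @param selection residue selection (default alpha carbons).
#' @return an N x N matrix of class `corr_matrix` with residue keys as
#'   dimnames; attribute `"zero_fluctuation"` flags degenerate residues.
#' @export
cross_correlation <- function(ensemble, selection = NULL) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (n_frames(ensemble) < 3L) stop("cross-correlation requires >= 3 frames")
  if (is.null(selection)) selection <- select_residue_atoms(ensemble, "calpha")
  pts <- residue_points(ensemble, selection)
  nres <- dim(pts)[1]
  nf <- dim(pts)[3]
  m <- apply(pts, c(1, 2), mean)
  dev <- sweep(pts, c(1, 2), m, `-`)
  # inner products: sum over axes of dev_i(t) dev_j(t), averaged over frames
  inner <- matrix(0, nres, nres)
  for (ax in 1:3) {
    da <- dev[, ax, , drop = TRUE]
    if (is.null(dim(da))) da <- matrix(da, nrow = nres)
    inner <- inner + tcrossprod(da)
  }
  inner <- inner / nf
  msd <- diag(inner)
  zero <- msd <= 0 | msd < 1e-300
  denom <- sqrt(outer(msd, msd))
  c_mat <- matrix(0, nres, nres)
  ok <- denom > 0
  c_mat[ok] <- inner[ok] / denom[ok]
  c_mat[zero, ] <- 0
  c_mat[, zero] <- 0
  c_mat <- (c_mat + t(c_mat)) / 2
  c_mat[c_mat > 1] <- 1
  c_mat[c_mat < -1] <- -1
  diag(c_mat) <- 1
  dimnames(c_mat) <- list(selection$residues$key, selection$residues$key)
  attr(c_mat, "zero_fluctuation") <- selection$residues$key[zero]
  attr(c_mat, "residues") <- selection$residues
  class(c_mat) <- c("corr_matrix", "matrix")
  c_mat
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("corr_matrix: %d x %d residue cross-correlations in [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  nz <- attr(x, "zero_fluctuation")
  if (length(nz)) cat("  zero-fluctuation residues:", paste(nz, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.corr_matrix <- function(x, ...) {
  m <- unclass(x)[, rev(seq_len(ncol(x)))]
  graphics::image(seq_len(nrow(x)), seq_len(ncol(x)), m, zlim = c(-1, 1),
                  col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  xlab = "residue", ylab = "residue", ...)
  invisible(x)
}

#' Write a correlation matrix as TSV
#'
#' Two files: the square headered matrix, and (optionally) a flat
#' `(key_i, key_j, C_ij)` edge list for graph consumption.
#'
#' @param c_mat a [cross_correlation()] matrix.
#' @param path output TSV path for the square matrix.
#' @param edge_list_path optional path for the flat upper-triangle list.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(c_mat, path, edge_list_path = NULL) {
  m <- as.data.frame(unclass(c_mat))
  utils::write.table(cbind(key = rownames(c_mat), signif(m, 12)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(edge_list_path)) {
    ut <- which(upper.tri(c_mat), arr.ind = TRUE)
    el <- data.frame(key_i = rownames(c_mat)[ut[, 1]],
                     key_j = colnames(c_mat)[ut[, 2]],
                     c_ij = sprintf("%.12e", c_mat[ut]))
    utils::write.table(el, edge_list_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Principal modes of a conformational ensemble
#'
#' Eigendecomposition of the 3N coordinate covariance (population form, one
#' representative point per residue), modes sorted by decreasing eigenvalue.
#' By the quasi-harmonic correspondence the largest-variance principal
#' components play the role of the lowest-frequency modes.
#'
#' @param ensemble a superposed [conf_ensemble()].
#' @param selection residue selection (default alpha carbons).
#' @param n_modes number of modes to retain (clamped to 3N with a warning).
#' @return object of class `mode_set`: `values` (eigenvalues, Angstrom^2),
#'   `vectors` (3N x n_modes, orthonormal), `residues`, `total_variance`.
#' @export
pca_modes <- function(ensemble, selection = NULL, n_modes = 20) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (n_frames(ensemble) < 2L) stop("PCA requires >= 2 frames")
  if (is.null(selection)) selection <- select_residue_atoms(ensemble, "calpha")
  pts <- residue_points(ensemble, selection)
  nres <- dim(pts)[1]
  nf <- dim(pts)[3]
  # 3N x F matrix of centered coordinates (residue-major: x1 y1 z1 x2 ...)
  flat <- matrix(aperm(pts, c(2, 1, 3)), nrow = 3 * nres)
  flat <- flat - rowMeans(flat)
  cov3n <- tcrossprod(flat) / nf
  if (n_modes > 3 * nres) {
    warning("n_modes clamped to 3N = ", 3 * nres)
    n_modes <- 3 * nres
  }
  e <- eigen(cov3n, symmetric = TRUE)
  obj <- list(values = pmax(e$values, 0), vectors = e$vectors[, seq_len(n_modes), drop = FALSE],
              n_modes = as.integer(n_modes), residues = selection$residues,
              total_variance = sum(diag(cov3n)), all_values = pmax(e$values, 0))
  class(obj) <- "mode_set"
  obj
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set: %d retained modes over %d residues; top eigenvalues: %s\n",
              x$n_modes, nrow(x$residues),
              paste(signif(utils::head(x$values, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Mode-averaged mobility profile
#'
#' Per-residue displacement amplitude sqrt(sum_m lambda_m |v_m,i|^2) over the
#' `n_use` largest-variance ("lowest-frequency") modes.
#'
#' @param modes a [pca_modes()] result.
#' @param n_use number of modes to average (default 3).
#' @return a [residue_profile()] of mobilities in Angstrom.
#' @export
mobility_profile <- function(modes, n_use = 3) {
  stopifnot(inherits(modes, "mode_set"))
  if (n_use < 1) stop("'n_use' must be >= 1")
  if (n_use > modes$n_modes)
    stop("'n_use' exceeds the ", modes$n_modes, " retained modes")
  nres <- nrow(modes$residues)
  amp2 <- numeric(nres)
  for (m in seq_len(n_use)) {
    v <- matrix(modes$vectors[, m], nrow = 3)  # residue-major 3 x N
    amp2 <- amp2 + modes$values[m] * colSums(v^2)
  }
  residue_profile(modes$residues, sqrt(amp2), "mobility")
}
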