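# Synthetic ensembles, structures, and graphs with known statistical
# structure.  Every downstream stage of the package has an analytic or
# brute-force oracle rooted in one of these generators.  Random number
# generation is confined to this module; everything else is deterministic
# given its inputs.

# Compact lattice blob: n points on a cubic lattice, chosen nearest-first from
# the lattice origin, then centered on `center`.  Deterministic.
blob_lattice <- function(n, spacing = 3.8, center = c(0, 0, 0)) {
  m <- ceiling(n^(1 / 3)) + 2L
  g <- seq(-m, m) * spacing
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[order(rowSums(pts^2), pts[, 1], pts[, 2], pts[, 3]), , drop = FALSE]
  sweep(pts[seq_len(n), , drop = FALSE], 2, center, `+`)
}

toy_atoms <- function(n, chain = "A", resname = "GLY") {
  data.frame(serial = seq_len(n), name = "CA", resname = resname,
             chain = chain, resno = seq_len(n), icode = "",
             element = "C", stringsAsFactors = FALSE)
}

#' Build a deterministic toy chain structure
#'
#' One alpha-carbon pseudo-atom per residue (glycine, chain A, residues
#' numbered from 1).  Three geometries are available: an `"extended"` chain
#' (3.8 Angstrom spacing with a small seeded jitter), a `"helix"` (ideal
#' alpha-helical parameters: 2.3 Angstrom radius, 1.5 Angstrom rise, 100
#' degrees per residue), and a two-domain `"dumbbell"` (two compact lattice
#' clusters joined by a short extended linker).
#'
#' @param n_res number of residues (>= 3).
#' @param geometry `"extended"`, `"helix"` or `"dumbbell"`.
#' @param seed integer seed (controls only the small jitter of the extended
#'   geometry; all geometries are reproducible for a fixed seed).
#' @return a [structure3d()]; for `"dumbbell"` the attribute `"clusters"`
#'   records the two domain index sets and the linker.
#' @export
build_toy_chain <- function(n_res, geometry = c("extended", "helix", "dumbbell"),
                            seed = 1) {
  geometry <- match.arg(geometry)
  if (!is.numeric(n_res) || n_res < 3) stop("'n_res' must be >= 3")
  n_res <- as.integer(n_res)
  xyz <- switch(geometry,
    extended = {
      jit <- with_seed(seed, matrix(stats::runif(n_res * 2, -0.1, 0.1), ncol = 2))
      cbind((seq_len(n_res) - 1) * 3.8,
            0.3 * rep_len(c(-1, 1), n_res) + jit[, 1], jit[, 2])
    },
    helix = {
      t <- (seq_len(n_res) - 1) * 100 * pi / 180
      cbind(2.3 * cos(t), 2.3 * sin(t), (seq_len(n_res) - 1) * 1.5)
    },
    dumbbell = {
      n_link <- if (n_res >= 11) 3L else 1L
      n1 <- (n_res - n_link) %/% 2L
      n2 <- n_res - n_link - n1
      half_link <- (n_link - 1) * 3.8 / 2
      b1 <- blob_lattice(n1)
      b2 <- blob_lattice(n2)
      gap <- 5
      c1 <- -(half_link + gap + max(b1[, 1]))
      c2 <- (half_link + gap - min(b2[, 1]))
      link_x <- if (n_link == 1L) 0 else seq(-half_link, half_link, length.out = n_link)
      rbind(sweep(b1[order(b1[, 1]), , drop = FALSE], 2, c(c1, 0, 0), `+`),
            cbind(link_x, 0, 0),
            sweep(b2[order(b2[, 1]), , drop = FALSE], 2, c(c2, 0, 0), `+`))
    })
  s <- structure3d(toy_atoms(n_res), xyz)
  attr(s, "geometry") <- geometry
  if (geometry == "dumbbell") {
    n_link <- if (n_res >= 11) 3L else 1L
    n1 <- (n_res - n_link) %/% 2L
    attr(s, "clusters") <- list(domain1 = seq_len(n1),
                                linker = n1 + seq_len(n_link),
                                domain2 = (n1 + n_link + 1):n_res)
  }
  s
}

#' Gaussian-network model over a structure
#'
#' Builds a Kirchhoff (connectivity) matrix from inter-node contacts within
#' `cutoff` and prescribes an isotropic per-node displacement covariance equal
#' to `scale` times the Kirchhoff pseudo-inverse, applied independently to
#' each Cartesian axis.  This gives closed-form expectations for B-factors,
#' cross-correlations and principal modes with minimal machinery.
#'
#' @param structure a [structure3d()] whose atoms are the network nodes
#'   (typically a [build_toy_chain()] alpha-carbon chain).
#' @param cutoff spring cutoff distance in Angstrom.
#' @param scale temperature scale factor (Angstrom^2); `0` freezes the model.
#' @return an object of class `gnm_model` with fields `structure`, `cutoff`,
#'   `scale`, `kirchhoff`, `covariance` (Angstrom^2) and `correlation`.
#' @export
gnm_model <- function(structure, cutoff = 7.0, scale = 1.0) {
  stopifnot(inherits(structure, "structure3d"))
  stop_if_not_scalar_number(cutoff, "cutoff")
  stop_if_not_scalar_number(scale, "scale")
  if (cutoff <= 0) stop("'cutoff' must be positive")
  if (scale < 0) stop("'scale' must be non-negative")
  xyz <- structure$xyz
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  k <- -(d <= cutoff) * 1
  dimnames(k) <- NULL
  diag(k) <- 0
  diag(k) <- -rowSums(k)
  if (!all(abs(rowSums(k)) < 1e-10)) stop("Kirchhoff row sums must be zero")
  e <- eigen(k, symmetric = TRUE)
  nzero <- sum(e$values < max(e$values) * 1e-10)
  if (nzero != 1L)
    stop("contact graph at cutoff ", cutoff, " Angstrom is not connected (",
         nzero, " zero modes)")
  inv <- e$values
  inv[seq_len(n - 1)] <- 1 / inv[seq_len(n - 1)]
  inv[n] <- 0
  cov <- scale * (e$vectors %*% (inv * t(e$vectors)))
  cov <- (cov + t(cov)) / 2
  corr <- if (scale > 0) stats::cov2cor(cov) else diag(n)
  obj <- list(structure = structure, cutoff = cutoff, scale = scale,
              kirchhoff = k, covariance = cov, correlation = corr)
  class(obj) <- "gnm_model"
  obj
}

#' @export
print.gnm_model <- function(x, ...) {
  cat(sprintf("gnm_model: %d nodes, cutoff %.2f A, scale %.3g A^2\n",
              nrow(x$covariance), x$cutoff, x$scale))
  invisible(x)
}

#' Sample a Gaussian fluctuation ensemble from a GNM
#'
#' Frames are the model's mean structure plus zero-mean Gaussian displacements
#' whose per-axis covariance is exactly the model's prescribed covariance,
#' drawn independently for x, y and z (isotropic model).  The analytic
#' covariance and correlation are returned alongside the ensemble so oracle
#' tests never have to re-derive them.
#'
#' @param model a [gnm_model()].
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed; identical seeds give bit-identical ensembles.
#' @return list with `ensemble` (a [conf_ensemble()]), `covariance` and
#'   `correlation` (the exact per-axis matrices used).
#' @export
sample_gaussian_ensemble <- function(model, n_frames, seed = 1) {
  stopifnot(inherits(model, "gnm_model"))
  if (!is.numeric(n_frames) || n_frames < 2) stop("'n_frames' must be >= 2")
  n_frames <- as.integer(n_frames)
  cov <- model$covariance
  if (!all(is.finite(cov)) || !isTRUE(all.equal(cov, t(cov), tolerance = 1e-8)))
    stop("invalid covariance: must be finite and symmetric")
  n <- nrow(cov)
  e <- eigen(cov, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("invalid covariance: not positive semidefinite")
  l <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)
  coords <- with_seed(seed, {
    arr <- array(NA_real_, c(n, 3L, n_frames))
    for (ax in 1:3) {
      z <- matrix(stats::rnorm(n * n_frames), n, n_frames)
      arr[, ax, ] <- model$structure$xyz[, ax] + l %*% z
    }
    arr
  })
  list(ensemble = conf_ensemble(model$structure, coords),
       covariance = cov, correlation = model$correlation)
}

#' Rigid two-domain hinge ensemble
#'
#' Two internally rigid lattice domains twist about the inter-domain hinge
#' axis (the x axis through the hinge): per frame a relative angle is drawn
#' uniformly in [-max_angle, +max_angle] degrees and the two bodies are
#' counter-rotated by half of it each, so the motion carries no net rotation
#' or translation.  Hinge residues sit on the axis between the domains and
#' therefore move only with the thermal jitter; the domain lattices are
#' offset from the axis so that every domain atom genuinely moves.
#' Intra-domain pairwise distances are constant across frames by construction
#' (exactly so when `noise = 0`).
#'
#' @param n_per_domain residues per domain (>= 3).
#' @param hinge_len number of hinge residues (>= 1).
#' @param max_angle maximum relative rotation, degrees, in (0, 180).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param noise standard deviation (Angstrom) of isotropic thermal jitter
#'   added to every atom in every frame; default 0 keeps the motion purely
#'   rigid.
#' @return a [conf_ensemble()]; attribute `"domains"` holds the residue index
#'   sets (`domain1`, `hinge`, `domain2`) and `"angles"` the per-frame angles.
#' @export
make_hinge_ensemble <- function(n_per_domain, hinge_len = 1, max_angle = 30,
                                n_frames = 100, seed = 1, noise = 0) {
  if (!is.numeric(hinge_len) || hinge_len < 1)
    stop("'hinge_len' must be >= 1")
  if (!is.numeric(max_angle) || max_angle <= 0 || max_angle >= 180)
    stop("'max_angle' must be in (0, 180) degrees")
  if (!is.numeric(n_per_domain) || n_per_domain < 3)
    stop("'n_per_domain' must be >= 3")
  if (!is.numeric(n_frames) || n_frames < 1) stop("'n_frames' must be >= 1")
  n_per_domain <- as.integer(n_per_domain)
  hinge_len <- as.integer(hinge_len)
  n_frames <- as.integer(n_frames)

  spacing <- 3.8
  gap <- 5
  half_link <- (hinge_len - 1) * spacing / 2
  hinge_x <- if (hinge_len == 1L) 0 else seq(-half_link, half_link, length.out = hinge_len)
  b <- blob_lattice(n_per_domain)
  off <- half_link + gap + max(b[, 1])
  # domain centers sit off the twist axis by (1.7, 1.1): with a 3.8 A lattice
  # no domain atom can come closer than ~2 A to the axis, so every domain
  # residue genuinely moves under the twist
  axis_off <- c(0, 1.7, 1.1)
  d1 <- sweep(b[order(b[, 1]), , drop = FALSE], 2, c(-off, 0, 0) + axis_off, `+`)
  # domain 2 mirrors domain 1 through the hinge plane so both inner faces
  # present the same contact surface to the hinge
  bm <- b
  bm[, 1] <- -bm[, 1]
  d2 <- sweep(bm[order(bm[, 1]), , drop = FALSE], 2, c(off, 0, 0) + axis_off, `+`)
  xyz <- rbind(d1, cbind(hinge_x, 0, 0), d2)
  n <- nrow(xyz)
  idx_d1 <- seq_len(n_per_domain)
  idx_h <- n_per_domain + seq_len(hinge_len)
  idx_d2 <- (n_per_domain + hinge_len + 1):n
  body1 <- c(idx_d1, idx_h[xyz[idx_h, 1] < 0])
  body2 <- c(idx_d2, idx_h[xyz[idx_h, 1] > 0])

  sim <- with_seed(seed, {
    ang <- stats::runif(n_frames, -max_angle, max_angle) * pi / 180
    arr <- array(NA_real_, c(n, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      fr <- xyz
      fr[body1, ] <- fr[body1, , drop = FALSE] %*% rot_x(-ang[f] / 2)
      fr[body2, ] <- fr[body2, , drop = FALSE] %*% rot_x(+ang[f] / 2)
      if (noise > 0) fr <- fr + matrix(stats::rnorm(n * 3, 0, noise), n, 3)
      arr[, , f] <- fr
    }
    list(coords = arr, angles = ang * 180 / pi)
  })
  ens <- conf_ensemble(structure3d(toy_atoms(n), xyz), sim$coords)
  attr(ens, "domains") <- list(domain1 = idx_d1, hinge = idx_h, domain2 = idx_d2)
  attr(ens, "angles") <- sim$angles
  ens
}

# Documented side-chain contact counts of the all-atom fixture.  These are the
# hand-derived ground truth for the geometry laid out in make_contact_fixture
# (atoms on unit-spaced lines, inter-residue offsets chosen so each pair
# distance is unambiguous against the 4.5 Angstrom cutoff).
.fixture_counts <- data.frame(
  res_i = c(1L, 1L, 2L, 3L),
  res_j = c(2L, 3L, 3L, 5L),
  n_ij = c(9L, 3L, 9L, 1L),
  excluded = c(TRUE, FALSE, TRUE, FALSE)
)

#' Deterministic all-atom contact fixture
#'
#' A six-residue toy structure whose side-chain heavy-atom contact counts at
#' the 4.5 Angstrom cutoff are hand-countable from the construction and
#' shipped as a sidecar manifest:
#' three valines whose 3-atom side chains lie on parallel unit-spaced lines
#' (residues 1-2 and 2-3 are sequence neighbors with 9 atom-pair contacts
#' each, flagged excluded; residues 1 and 3 are offset by 4.45 Angstrom so
#' exactly the 3 aligned pairs fall inside the cutoff), an alanine far away
#' (residue 4, no contacts), an alanine whose CB sits 4.45 Angstrom from one
#' atom of residue 3 (one contact), and a distant glycine (residue 6,
#' alpha-carbon fallback, no contacts).
#'
#' @param dir optional directory; when given, `fixture.pdb` and
#'   `fixture_manifest.tsv` are written there.
#' @return list with `structure` (a [structure3d()]), `manifest` (data frame
#'   of documented pairwise counts and exclusion flags) and `expected_edges`
#'   (residue-number pairs that survive the default interaction-strength
#'   threshold of 3 percent).
#' @export
make_contact_fixture <- function(dir = NULL) {
  sc_line <- function(y) cbind(0:2, y, 0)
  bb <- function(x0, y0) rbind(c(x0, y0, 5), c(x0 + 1.5, y0, 5),
                               c(x0 + 3, y0, 5), c(x0 + 3, y0 + 1.2, 5))
  bbn <- c("N", "CA", "C", "O")
  res <- list(
    list(resname = "VAL", names = c(bbn, "CB", "CG1", "CG2"),
         xyz = rbind(bb(0, 0), sc_line(0))),
    list(resname = "VAL", names = c(bbn, "CB", "CG1", "CG2"),
         xyz = rbind(bb(10, 2), sc_line(2))),
    list(resname = "VAL", names = c(bbn, "CB", "CG1", "CG2"),
         xyz = rbind(bb(-10, 4.45), sc_line(4.45))),
    list(resname = "ALA", names = c(bbn, "CB"),
         xyz = rbind(bb(50, 0), c(50, 0, 0))),
    list(resname = "ALA", names = c(bbn, "CB"),
         xyz = rbind(bb(10, 8.9), c(0, 8.9, 0))),
    list(resname = "GLY", names = bbn, xyz = bb(60, 0))
  )
  atoms <- do.call(rbind, lapply(seq_along(res), function(i) {
    r <- res[[i]]
    data.frame(serial = 0L, name = r$names, resname = r$resname, chain = "A",
               resno = i, icode = "",
               element = substr(r$names, 1, 1), stringsAsFactors = FALSE)
  }))
  atoms$serial <- seq_len(nrow(atoms))
  xyz <- do.call(rbind, lapply(res, `[[`, "xyz"))
  s <- structure3d(atoms, xyz)

  manifest <- .fixture_counts
  nt <- default_normalization()
  rn <- vapply(res, `[[`, character(1), "resname")
  manifest$I_ij <- 100 * manifest$n_ij /
    sqrt(nt[rn[manifest$res_i]] * nt[rn[manifest$res_j]])
  manifest$edge <- !manifest$excluded & manifest$I_ij > 3.0
  rownames(manifest) <- NULL
  expected_edges <- manifest[manifest$edge, c("res_i", "res_j")]

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_multimodel_pdb(s, file.path(dir, "fixture.pdb"))
    utils::write.table(manifest, file.path(dir, "fixture_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(structure = s, manifest = manifest, expected_edges = expected_edges)
}

#' Graph with planted clique communities
#'
#' Builds a chain of complete subgraphs in which consecutive cliques share
#' exactly `shared_nodes` nodes, then relabels nodes by a seeded permutation.
#' The planted clique memberships are recorded so community detection has an
#' exact oracle.
#'
#' @param clique_sizes integer vector of clique sizes (each >= 3).
#' @param shared_nodes nodes shared by consecutive cliques
#'   (0 <= shared_nodes < min clique size).
#' @param seed integer seed for the label permutation.
#' @return object of class `planted_graph`: `n_nodes`, `edges` (two-column
#'   matrix), `cliques` (list of planted node sets), `shared_nodes`.
#' @export
make_planted_community_graph <- function(clique_sizes, shared_nodes = 0, seed = 1) {
  if (any(clique_sizes < 3)) stop("every clique size must be >= 3")
  if (shared_nodes < 0 || shared_nodes >= min(clique_sizes))
    stop("'shared_nodes' must satisfy 0 <= shared_nodes < min clique size")
  clique_sizes <- as.integer(clique_sizes)
  shared_nodes <- as.integer(shared_nodes)
  cliques <- list()
  nxt <- 1L
  prev <- integer(0)
  for (s in clique_sizes) {
    shared <- if (length(prev)) utils::tail(prev, shared_nodes) else integer(0)
    new <- nxt + seq_len(s - length(shared)) - 1L
    nxt <- nxt + s - length(shared)
    cl <- c(shared, new)
    cliques[[length(cliques) + 1L]] <- cl
    prev <- cl
  }
  n <- nxt - 1L
  perm <- with_seed(seed, sample.int(n))
  cliques <- lapply(cliques, function(cl) sort(perm[cl]))
  edges <- unique(do.call(rbind, lapply(cliques, function(cl) {
    t(utils::combn(sort(cl), 2))
  })))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  obj <- list(n_nodes = n, edges = edges, cliques = cliques,
              shared_nodes = shared_nodes)
  class(obj) <- "planted_graph"
  obj
}

#' Planted community memberships of a planted graph
#'
#' For a [make_planted_community_graph()] whose cliques all have size `k`,
#' returns the node sets expected from k-clique percolation under the given
#' adjacency rule: consecutive planted cliques merge when their shared-node
#' count reaches the rule's threshold.
#'
#' @param graph a `planted_graph`.
#' @param rule `"k-1"`, `"k-2"` or `"either"` (shared >= k-2, the relaxed
#'   adjacency rule).
#' @return list of sorted node vectors, one per expected community.
#' @export
planted_memberships <- function(graph, rule = c("either", "k-1", "k-2")) {
  rule <- match.arg(rule)
  sizes <- lengths(graph$cliques)
  if (length(unique(sizes)) != 1L)
    stop("planted memberships require uniform clique sizes")
  k <- sizes[1]
  need <- if (rule == "k-1") k - 1L else k - 2L
  merge_next <- graph$shared_nodes >= need
  groups <- list()
  cur <- graph$cliques[[1]]
  for (i in seq_along(graph$cliques)[-1]) {
    if (merge_next) cur <- union(cur, graph$cliques[[i]])
    else {
      groups[[length(groups) + 1L]] <- sort(cur)
      cur <- graph$cliques[[i]]
    }
  }
  groups[[length(groups) + 1L]] <- sort(cur)
  groups
}

#' @export
print.planted_graph <- function(x, ...) {
  cat(sprintf("planted_graph: %d nodes, %d edges, %d planted cliques (shared %d)\n",
              x$n_nodes, nrow(x$edges), length(x$cliques), x$shared_nodes))
  invisible(x)
}
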