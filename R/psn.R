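# Protein structure networks from side-chain contacts: interaction strengths,
# I_min scanning, ensemble edge occupancy, and hub identification.
#
# Residues are nodes; two residues are connected when their normalized
# side-chain contact strength
#
#     I_ij = 100 * n_ij / sqrt(N_i * N_j)   [percent]
#
# exceeds the interaction cutoff I_min, where n_ij counts distinct side-chain
# heavy-atom pairs within the distance cutoff and N_i is a residue-type
# normalization.  Non-covalent interactions between sequence neighbors are
# ignored.  Over an ensemble, an edge is dynamically stable when it is intact
# in more than the occupancy-threshold fraction of snapshots (strict).

# Residue-type normalization factors N_i.  The original normalization values
# are residue-type maximal contact capacities from large-scale surveys of
# protein structures; the published table is not reproduced here, so these
# defaults are a documented stand-in proportional to side-chain size.  They
# are fully overridable via psn_config(normalization = ...), and an
# "empirical" mode instead uses the maximum contact count observed per
# residue type in the input ensemble.
.default_norm <- c(
  ALA = 55.76, ARG = 93.75, ASN = 73.41, ASP = 75.16, CYS = 54.95,
  GLN = 78.13, GLU = 78.81, GLY = 47.36, HIS = 83.74, ILE = 67.99,
  LEU = 72.25, LYS = 69.61, MET = 69.26, PHE = 93.31, PRO = 51.33,
  SER = 61.31, THR = 63.71, TRP = 106.70, TYR = 100.71, VAL = 62.37)

#' Default residue-type normalization table
#'
#' Named vector of N_i values used in the interaction-strength normalization
#' I_ij = 100 n_ij / sqrt(N_i N_j).  These package defaults are residue-type
#' contact capacities proportional to side-chain size; override them via
#' [psn_config()] when a calibrated table is available, or use the
#' `"empirical"` normalization mode.
#'
#' @return named numeric vector over the 20 standard residue types.
#' @export
default_normalization <- function() .default_norm

#' Configuration for protein structure network construction
#'
#' @param cutoff side-chain atom-pair distance cutoff, Angstrom (default 4.5).
#' @param i_min interaction-strength cutoff I_min, percent (default 3.0);
#'   edges require I_ij strictly greater than `i_min`.
#' @param occupancy_threshold fraction of snapshots in which an edge must be
#'   intact to count as dynamically stable, strict (default 0.75).
#' @param hub_degree minimum degree for a node to be a hub (default 4).
#' @param normalization named N_i vector, or `"default"`, or `"empirical"`
#'   (N_i = maximum observed contact count of that residue type).
#' @param n_snapshots number of evenly spaced snapshots used for occupancy
#'   when the ensemble has more frames (default 500).
#' @return list of class `psn_config`.
#' @export
psn_config <- function(cutoff = 4.5, i_min = 3.0, occupancy_threshold = 0.75,
                       hub_degree = 4, normalization = "default",
                       n_snapshots = 500) {
  if (cutoff <= 0) stop("'cutoff' must be positive")
  if (i_min < 0) stop("'i_min' must be >= 0")
  if (occupancy_threshold <= 0 || occupancy_threshold > 1)
    stop("'occupancy_threshold' must be in (0, 1]")
  if (is.character(normalization) && length(normalization) == 1L &&
      normalization == "default")
    normalization <- default_normalization()
  obj <- list(cutoff = cutoff, i_min = i_min,
              occupancy_threshold = occupancy_threshold,
              hub_degree = as.integer(hub_degree),
              normalization = normalization,
              n_snapshots = as.integer(n_snapshots))
  class(obj) <- "psn_config"
  obj
}

#' Side-chain contact counts for one conformation
#'
#' n_ij = number of distinct atom pairs (one atom from residue i, one from
#' residue j) within `cutoff`.  Counts are symmetric; pairs of sequence
#' neighbors (adjacent residues of the same chain) are counted but flagged
#' excluded, since covalent neighbors never form network edges.
#'
#' @param frame a [structure3d()] (or single-frame ensemble).
#' @param selection a side-chain-heavy [select_residue_atoms()] selection
#'   (default: computed from `frame`).
#' @param cutoff contact distance cutoff, Angstrom.
#' @return object of class `contact_counts`: integer matrix `n` (residues x
#'   residues), logical matrix `excluded`, and the residue table.
#' @export
sidechain_contacts <- function(frame, selection = NULL, cutoff = 4.5) {
  if (inherits(frame, "conf_ensemble")) {
    if (n_frames(frame) != 1L)
      stop("sidechain_contacts expects a single conformation")
    frame <- ensemble_frame(frame, 1L)
  }
  stopifnot(inherits(frame, "structure3d"))
  if (is.null(selection)) selection <- select_residue_atoms(frame, "sidechain")
  rt <- selection$residues
  nres <- nrow(rt)
  n <- contact_count_matrix(frame$xyz, selection$atom_idx, cutoff)
  same_chain <- outer(rt$chain, rt$chain, "==")
  pos_diff <- abs(outer(rt$chain_pos, rt$chain_pos, "-"))
  excluded <- same_chain & pos_diff <= 1L
  dimnames(n) <- list(rt$key, rt$key)
  dimnames(excluded) <- dimnames(n)
  obj <- list(n = n, excluded = excluded, residues = rt, cutoff = cutoff)
  class(obj) <- "contact_counts"
  obj
}

# Count atom pairs within cutoff for every residue pair given per-residue atom
# index lists.  Returns an integer residue x residue matrix (diagonal zero).
contact_count_matrix <- function(xyz, atom_idx, cutoff) {
  nres <- length(atom_idx)
  atoms <- unlist(atom_idx)
  res_of <- rep(seq_len(nres), lengths(atom_idx))
  x <- xyz[atoms, , drop = FALSE]
  d <- as.matrix(stats::dist(x))
  within <- d <= cutoff
  diag(within) <- FALSE
  n <- matrix(0L, nres, nres)
  hit <- which(within, arr.ind = TRUE)
  hit <- hit[res_of[hit[, 1]] < res_of[hit[, 2]], , drop = FALSE]
  if (nrow(hit)) {
    ri <- res_of[hit[, 1]]
    rj <- res_of[hit[, 2]]
    tab <- table(factor(ri, levels = seq_len(nres)),
                 factor(rj, levels = seq_len(nres)))
    n <- matrix(as.integer(tab), nres, nres)
    n <- n + t(n)
  }
  n
}

#' Interaction strengths from contact counts
#'
#' I_ij = 100 * n_ij / sqrt(N_i * N_j), in percent.  Zero where n_ij = 0.
#'
#' @param counts a [sidechain_contacts()] result.
#' @param config a [psn_config()]; its normalization table must cover every
#'   residue type present (an uncovered type is an error naming it).  With
#'   `normalization = "empirical"`, N_i is the maximum observed contact count
#'   of that residue type in `counts` (floored at 1).
#' @return numeric matrix of class `interaction_strength` (percent), with the
#'   exclusion mask and residue table attached as attributes.
#' @export
interaction_strength <- function(counts, config = psn_config()) {
  stopifnot(inherits(counts, "contact_counts"))
  rt <- counts$residues
  norm <- config$normalization
  if (is.character(norm) && length(norm) == 1L && norm == "empirical") {
    norm <- empirical_normalization(list(counts$n), rt)
  }
  types <- unique(toupper(rt$resname))
  miss <- setdiff(types, names(norm))
  if (length(miss))
    stop("normalization table does not cover residue type(s): ",
         paste(miss, collapse = ", "))
  n_i <- norm[toupper(rt$resname)]
  if (any(n_i <= 0)) stop("normalization factors must be positive")
  i_mat <- 100 * counts$n / sqrt(outer(n_i, n_i))
  dimnames(i_mat) <- dimnames(counts$n)
  attr(i_mat, "excluded") <- counts$excluded
  attr(i_mat, "residues") <- rt
  attr(i_mat, "normalization") <- norm
  class(i_mat) <- c("interaction_strength", "matrix")
  i_mat
}

# Empirical N_i: max observed n_ij per residue type across a list of count
# matrices, floored at 1 so strengths stay finite.
empirical_normalization <- function(count_list, rt) {
  types <- toupper(rt$resname)
  best <- stats::setNames(rep(1, length(unique(types))), unique(types))
  for (n in count_list) {
    m <- apply(n, 1, max)
    for (ty in names(best))
      best[ty] <- max(best[ty], m[types == ty])
  }
  best
}

#' Construct a residue contact network
#'
#' An edge is drawn between residues i and j when I_ij > I_min (strict) and
#' the pair is not a same-chain sequence-neighbor pair.
#'
#' @param i_mat an [interaction_strength()] matrix (or plain symmetric matrix
#'   with an `excluded` attribute / residue dimnames).
#' @param config a [psn_config()].
#' @return object of class `contact_network`: residue table, edge table
#'   (`i`, `j` residue indices, `I_ij`, plus `occupancy`/`stable` when built
#'   from an ensemble), and the configuration.
#' @export
build_network <- function(i_mat, config = psn_config()) {
  rt <- attr(i_mat, "residues")
  if (is.null(rt)) {
    keys <- rownames(i_mat) %||% as.character(seq_len(nrow(i_mat)))
    rt <- data.frame(chain = "A", resno = seq_len(nrow(i_mat)), icode = "",
                     resname = "UNK", key = keys,
                     chain_pos = seq_len(nrow(i_mat)), stringsAsFactors = FALSE)
  }
  excluded <- attr(i_mat, "excluded")
  if (is.null(excluded)) {
    same_chain <- outer(rt$chain, rt$chain, "==")
    pos_diff <- abs(outer(rt$chain_pos, rt$chain_pos, "-"))
    excluded <- same_chain & pos_diff <= 1L
  }
  m <- unclass(i_mat)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("interaction-strength matrix must be symmetric")
  sel <- which(upper.tri(m) & m > config$i_min & !excluded, arr.ind = TRUE)
  edges <- data.frame(i = sel[, 1], j = sel[, 2],
                      I_ij = m[sel], stringsAsFactors = FALSE)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  contact_network(rt, edges, config)
}

#' Low-level contact-network constructor
#'
#' @param residues residue table (`chain`, `resno`, `icode`, `resname`, `key`,
#'   `chain_pos`).
#' @param edges data frame with residue-index columns `i`, `j` and optionally
#'   `I_ij`, `n_ij`, `occupancy`, `stable`.
#' @param config a [psn_config()].
#' @param snapshots optional logical matrix (edges x snapshots) of per-snapshot
#'   edge presence, used for community-stability reporting.
#' @return a `contact_network`.
#' @export
contact_network <- function(residues, edges, config = psn_config(),
                            snapshots = NULL) {
  stopifnot(all(c("i", "j") %in% names(edges)))
  if (nrow(edges)) {
    swap <- edges$i > edges$j
    tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
    if (any(edges$i == edges$j)) stop("self-edges are not allowed")
  }
  edges$key_i <- residues$key[edges$i]
  edges$key_j <- residues$key[edges$j]
  obj <- list(residues = residues, edges = edges, config = config,
              snapshots = snapshots)
  class(obj) <- "contact_network"
  obj
}

#' @export
print.contact_network <- function(x, ...) {
  st <- if (!is.null(x$edges$stable)) sprintf(", %d stable", sum(x$edges$stable))
        else ""
  cat(sprintf("contact_network: %d residues, %d edges%s (I_min = %g%%)\n",
              nrow(x$residues), nrow(x$edges), st, x$config$i_min))
  invisible(x)
}

#' Adjacency matrix of a contact network
#'
#' @param network a `contact_network`.
#' @param stable_only use only occupancy-stable edges (default: stable edges
#'   when occupancy information is present, otherwise all edges).
#' @return logical adjacency matrix with residue keys as dimnames.
#' @export
adjacency_matrix <- function(network, stable_only = NULL) {
  n <- nrow(network$residues)
  a <- matrix(FALSE, n, n, dimnames = list(network$residues$key,
                                           network$residues$key))
  e <- network$edges
  if (is.null(stable_only)) stable_only <- !is.null(e$stable)
  if (stable_only && !is.null(e$stable)) e <- e[e$stable, , drop = FALSE]
  if (nrow(e)) {
    a[cbind(e$i, e$j)] <- TRUE
    a[cbind(e$j, e$i)] <- TRUE
  }
  a
}

#' Largest-cluster scan over an I_min grid
#'
#' For each I_min in the ascending grid, the size of the largest connected
#' component of the network built at that cutoff.  The percolation-style
#' transition estimate is the grid point with the largest drop from its
#' predecessor; when the cluster size never drops the transition is flagged
#' undefined (`NA`).
#'
#' @param i_mat an [interaction_strength()] matrix.
#' @param grid ascending vector of I_min values (length >= 2).
#' @param config a [psn_config()] (normalization/exclusion context).
#' @return data frame (`i_min`, `largest_cluster`) with attribute
#'   `"transition"`.
#' @export
imin_scan <- function(i_mat, grid, config = psn_config()) {
  if (length(grid) < 2L) stop("'grid' must contain at least 2 I_min values")
  if (is.unsorted(grid)) stop("'grid' must be sorted ascending")
  sizes <- vapply(grid, function(im) {
    cfg <- config
    cfg$i_min <- im
    net <- build_network(i_mat, cfg)
    if (!nrow(net$edges)) return(if (nrow(net$residues)) 1L else 0L)
    g <- igraph::graph_from_edgelist(as.matrix(net$edges[, c("i", "j")]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, nrow(net$residues) - igraph::vcount(g))
    as.integer(max(igraph::components(g)$csize))
  }, integer(1))
  drops <- -diff(sizes)
  transition <- if (all(drops <= 0)) NA_real_ else grid[which.max(drops) + 1L]
  out <- data.frame(i_min = grid, largest_cluster = sizes)
  attr(out, "transition") <- transition
  out
}

#' Ensemble contact network with edge occupancy
#'
#' Evaluates the interaction network on evenly spaced snapshots of the
#' ensemble (deterministic subsampling to `config$n_snapshots` when the
#' ensemble is longer).  Per-edge occupancy is the fraction of evaluated
#' snapshots with I_ij > I_min; an edge is dynamically stable when its
#' occupancy strictly exceeds the occupancy threshold.  The returned network
#' contains every pair observed as an edge in at least one snapshot, with
#' mean interaction strength over the snapshots where present.
#'
#' @param ensemble a [conf_ensemble()] with >= 2 frames.
#' @param config a [psn_config()].
#' @param selection side-chain selection (default: computed from the
#'   ensemble's topology).
#' @return a `contact_network` with `occupancy` and `stable` edge columns and
#'   the per-snapshot presence matrix stored for community-stability
#'   reporting.
#' @export
ensemble_network <- function(ensemble, config = psn_config(), selection = NULL) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  nf <- n_frames(ensemble)
  if (nf < 2L) stop("ensemble network requires >= 2 frames")
  if (is.null(selection)) selection <- select_residue_atoms(ensemble, "sidechain")
  rt <- selection$residues
  snap_idx <- if (nf > config$n_snapshots)
    unique(round(seq(1, nf, length.out = config$n_snapshots))) else seq_len(nf)
  ns <- length(snap_idx)

  count_list <- vector("list", ns)
  for (s in seq_len(ns)) {
    count_list[[s]] <- contact_count_matrix(
      ensemble$coords[, , snap_idx[s], drop = TRUE],
      selection$atom_idx, config$cutoff)
  }
  cfg <- config
  if (is.character(cfg$normalization) && length(cfg$normalization) == 1L &&
      cfg$normalization == "empirical")
    cfg$normalization <- empirical_normalization(count_list, rt)

  same_chain <- outer(rt$chain, rt$chain, "==")
  pos_diff <- abs(outer(rt$chain_pos, rt$chain_pos, "-"))
  excluded <- same_chain & pos_diff <= 1L

  nres <- nrow(rt)
  present_count <- matrix(0L, nres, nres)
  i_sum <- matrix(0, nres, nres)
  presence_by_snap <- vector("list", ns)
  n_i <- cfg$normalization[toupper(rt$resname)]
  miss <- is.na(n_i)
  if (any(miss))
    stop("normalization table does not cover residue type(s): ",
         paste(unique(toupper(rt$resname)[miss]), collapse = ", "))
  denom <- sqrt(outer(n_i, n_i))
  for (s in seq_len(ns)) {
    i_mat <- 100 * count_list[[s]] / denom
    present <- i_mat > cfg$i_min & !excluded
    present_count <- present_count + present
    i_sum <- i_sum + i_mat * present
    presence_by_snap[[s]] <- present
  }
  occupancy <- present_count / ns
  ever <- which(upper.tri(occupancy) & occupancy > 0, arr.ind = TRUE)
  edges <- data.frame(i = ever[, 1], j = ever[, 2],
                      n_ij = NA_real_,
                      I_ij = i_sum[ever] / pmax(present_count[ever], 1L),
                      occupancy = occupancy[ever])
  edges$stable <- edges$occupancy > cfg$occupancy_threshold
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  # mean contact count over snapshots where the edge is present
  n_sum <- Reduce(`+`, count_list)
  edges$n_ij <- n_sum[cbind(edges$i, edges$j)] / ns
  snapshots <- if (nrow(edges))
    do.call(cbind, lapply(presence_by_snap,
                          function(p) p[cbind(edges$i, edges$j)]))
  else matrix(FALSE, 0, ns)
  net <- contact_network(rt, edges, cfg, snapshots = snapshots)
  attr(net, "snapshot_frames") <- snap_idx
  net
}

#' Identify hub residues
#'
#' Hubs are nodes whose degree (number of incident edges) is at least
#' `threshold`; sorted by degree descending, ties broken by residue key.
#'
#' @param network a `contact_network`.
#' @param threshold minimum hub degree (default from the network's config).
#' @param stable_only see [adjacency_matrix()].
#' @return data frame with `key`, `chain`, `resno`, `resname`, `degree`.
#' @export
find_hubs <- function(network, threshold = NULL, stable_only = NULL) {
  threshold <- threshold %||% network$config$hub_degree
  a <- adjacency_matrix(network, stable_only)
  deg <- rowSums(a)
  rt <- network$residues
  hubs <- data.frame(key = rt$key, chain = rt$chain, resno = rt$resno,
                     resname = rt$resname, degree = as.integer(deg),
                     stringsAsFactors = FALSE)
  hubs <- hubs[hubs$degree >= threshold, , drop = FALSE]
  hubs <- hubs[order(-hubs$degree, hubs$key), , drop = FALSE]
  rownames(hubs) <- NULL
  hubs
}

#' Write a contact-network edge list as TSV
#'
#' Columns: chain_i, res_i, chain_j, res_j, n_ij, I_ij, occupancy, stable.
#'
#' @param network a `contact_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  e <- network$edges
  rt <- network$residues
  out <- data.frame(chain_i = rt$chain[e$i], res_i = rt$resno[e$i],
                    chain_j = rt$chain[e$j], res_j = rt$resno[e$j],
                    n_ij = if (!is.null(e$n_ij)) sprintf("%.6g", e$n_ij) else NA,
                    I_ij = sprintf("%.10g", e$I_ij),
                    occupancy = if (!is.null(e$occupancy))
                      sprintf("%.6g", e$occupancy) else NA,
                    stable = if (!is.null(e$stable)) e$stable else NA)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a contact network as node-link JSON
#'
#' @param network a `contact_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  rt <- network$residues
  e <- network$edges
  obj <- list(
    nodes = data.frame(id = rt$key, chain = rt$chain, resno = rt$resno,
                       resname = rt$resname, stringsAsFactors = FALSE),
    links = data.frame(source = e$key_i, target = e$key_j,
                       I_ij = e$I_ij,
                       occupancy = e$occupancy %||% rep(NA_real_, nrow(e)),
                       stable = e$stable %||% rep(NA, nrow(e)),
                       stringsAsFactors = FALSE),
    config = list(cutoff = network$config$cutoff, i_min = network$config$i_min,
                  occupancy_threshold = network$config$occupancy_threshold))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
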