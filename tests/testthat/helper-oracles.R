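# Independent oracles and small constructors used across the test files.
# Every oracle here is deliberately naive (double loops, exhaustive
# enumeration) and shares no code with the package implementation paths it
# checks.

# Build an ensemble of single-atom (alpha-carbon) residues from a list of
# n x 3 coordinate matrices.
make_point_ensemble <- function(frames, chain = "A", resname = "GLY") {
  n <- nrow(frames[[1]])
  atoms <- data.frame(serial = seq_len(n), name = "CA", resname = resname,
                      chain = chain, resno = seq_len(n), icode = "",
                      element = "C", stringsAsFactors = FALSE)
  conf_ensemble(structure3d(atoms, frames[[1]]), frames)
}

# Naive force constants: per frame and residue, average distance to all
# admissible residues by an explicit double loop; two-pass variance.
# Alpha-carbon representation, single chain assumed.
naive_force_constants <- function(ensemble, exclusion = 1, k_b = 1.987e-3,
                                  temperature = 300, factor = 3) {
  sel <- select_residue_atoms(ensemble, "calpha")
  idx <- unlist(sel$atom_idx)
  nres <- length(idx)
  nf <- n_frames(ensemble)
  d <- matrix(NA_real_, nf, nres)
  for (f in seq_len(nf)) {
    x <- ensemble$coords[idx, , f, drop = TRUE]
    for (i in seq_len(nres)) {
      acc <- c()
      for (j in seq_len(nres)) {
        if (abs(i - j) <= exclusion) next
        acc <- c(acc, sqrt(sum((x[i, ] - x[j, ])^2)))
      }
      d[f, i] <- mean(acc)
    }
  }
  k <- numeric(nres)
  for (i in seq_len(nres)) {
    m <- mean(d[, i])
    v <- mean((d[, i] - m)^2)
    k[i] <- if (v > 0) factor * k_b * temperature / v else Inf
  }
  k
}

# Random undirected weighted graph as a weight matrix (Inf = no edge).
random_weight_graph <- function(n, p, seed, wmin = 0.1, wmax = 2) {
  set.seed(seed)
  w <- matrix(Inf, n, n)
  diag(w) <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) w[i, j] <- w[j, i] <- stats::runif(1, wmin, wmax)
  }
  w
}

random_edge_graph <- function(n, p, seed) {
  w <- random_weight_graph(n, p, seed)
  which(is.finite(w) & upper.tri(w), arr.ind = TRUE)
}

# Exhaustive enumeration of all simple paths between s and t.
brute_simple_paths <- function(w, s, t) {
  n <- nrow(w)
  paths <- list()
  lens <- numeric(0)
  rec <- function(u, visited, path, len) {
    if (u == t) {
      paths[[length(paths) + 1L]] <<- path
      lens[length(lens) + 1L] <<- len
      return()
    }
    for (v in seq_len(n)) {
      if (visited[v] || !is.finite(w[u, v]) || v == u) next
      visited[v] <- TRUE
      rec(v, visited, c(path, v), len + w[u, v])
      visited[v] <- FALSE
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  rec(s, visited, s, 0)
  list(paths = paths, lengths = lens)
}

# All-pairs shortest distances and minimum-weight path counts by exhaustive
# path enumeration (tie tolerance 1e-9 relative).
brute_shortest <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  g <- matrix(0, n, n)
  diag(d) <- 0
  diag(g) <- 1
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    bp <- brute_simple_paths(w, s, t)
    if (!length(bp$lengths)) next
    dmin <- min(bp$lengths)
    cnt <- sum(bp$lengths <= dmin + 1e-9 * max(1, dmin))
    d[s, t] <- d[t, s] <- dmin
    g[s, t] <- g[t, s] <- cnt
  }
  list(dist = d, counts = g)
}

# Normalized betweenness from exhaustive shortest-path enumeration.
brute_betweenness <- function(w) {
  n <- nrow(w)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    bp <- brute_simple_paths(w, s, t)
    if (!length(bp$lengths)) next
    dmin <- min(bp$lengths)
    sel <- which(bp$lengths <= dmin + 1e-9 * max(1, dmin))
    for (pi in sel) {
      mid <- bp$paths[[pi]]
      mid <- mid[-c(1, length(mid))]
      b[mid] <- b[mid] + 1 / length(sel)
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

# Exhaustive k-clique enumeration over all C(n, k) node subsets.
brute_k_cliques <- function(edges, n, k) {
  adj <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    adj[edges] <- TRUE
    adj[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  if (n < k) return(list())
  subsets <- utils::combn(n, k)
  out <- list()
  for (c_ in seq_len(ncol(subsets))) {
    v <- subsets[, c_]
    pr <- utils::combn(v, 2)
    if (all(adj[t(pr)])) out[[length(out) + 1L]] <- v
  }
  out
}

# Brute-force clique percolation: pairwise intersections + BFS components.
brute_percolation <- function(cliques, k, rule) {
  need <- if (rule == "k-1") k - 1L else k - 2L
  nc <- length(cliques)
  if (!nc) return(list())
  adj <- matrix(FALSE, nc, nc)
  for (a in seq_len(nc)) for (b in seq_len(nc)) {
    if (a != b && length(intersect(cliques[[a]], cliques[[b]])) >= need)
      adj[a, b] <- TRUE
  }
  seen <- rep(FALSE, nc)
  comms <- list()
  for (s in seq_len(nc)) {
    if (seen[s]) next
    queue <- s
    comp <- integer(0)
    seen[s] <- TRUE
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, u)
      nx <- which(adj[u, ] & !seen)
      seen[nx] <- TRUE
      queue <- c(queue, nx)
    }
    comms[[length(comms) + 1L]] <- sort(unique(unlist(cliques[comp])))
  }
  comms
}

# Canonical form for comparing community/clique lists regardless of order.
canon_sets <- function(sets) {
  sort(vapply(sets, function(v) paste(sort(v), collapse = ","), character(1)))
}

# Variance of the mean-distance observable d_i under the analytic covariance,
# estimated by direct Monte-Carlo with MASS::mvrnorm (fresh seed, no package
# code).
oracle_di_variance <- function(mean_xyz, covariance, exclusion, n, seed) {
  set.seed(seed)
  nres <- nrow(mean_xyz)
  dx <- MASS::mvrnorm(n, rep(0, nres), covariance)
  dy <- MASS::mvrnorm(n, rep(0, nres), covariance)
  dz <- MASS::mvrnorm(n, rep(0, nres), covariance)
  v <- numeric(nres)
  for (i in seq_len(nres)) {
    js <- setdiff(seq_len(nres), max(1, i - exclusion):min(nres, i + exclusion))
    di <- rowMeans(vapply(js, function(j) {
      sqrt((mean_xyz[i, 1] - mean_xyz[j, 1] + dx[, i] - dx[, j])^2 +
           (mean_xyz[i, 2] - mean_xyz[j, 2] + dy[, i] - dy[, j])^2 +
           (mean_xyz[i, 3] - mean_xyz[j, 3] + dz[, i] - dz[, j])^2)
    }, numeric(n)))
    v[i] <- mean((di - mean(di))^2)
  }
  v
}

occupancy_toy <- function(d_on, n_on, d_off, n_off) {
  # residues 1 and 3 toggle between contact (d_on) and no contact (d_off);
  # residue 2 is parked far away so only the non-neighbor pair (1,3) matters
  mk <- function(d) rbind(c(0, 0, 0), c(500, 500, 0), c(d, 0, 0))
  make_point_ensemble(c(replicate(n_on, mk(d_on), simplify = FALSE),
                        replicate(n_off, mk(d_off), simplify = FALSE)))
}

toy_comm_graph <- function(w, c_min = 0.5) {
  # wrap a weight matrix as a comm_graph with C = exp(-w) so edge_weight
  # round-trips the given weights
  n <- nrow(w)
  rt <- data.frame(chain = "A", resno = seq_len(n), icode = "",
                   resname = "GLY", key = paste0("A:", seq_len(n)),
                   chain_pos = seq_len(n), stringsAsFactors = FALSE)
  idx <- which(is.finite(w) & upper.tri(w), arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      key_i = rt$key[idx[, 1]], key_j = rt$key[idx[, 2]],
                      C = exp(-w[idx]), w = w[idx],
                      weak = exp(-w[idx]) < c_min, stringsAsFactors = FALSE)
  structure(list(residues = rt, edges = edges, c_min = c_min, floor = 1e-6),
            class = "comm_graph")
}
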