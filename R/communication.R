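# Correlation-weighted communication graphs: shortest paths (Floyd-Warshall
# with path counting), degree, betweenness, and suboptimal path ensembles.
#
# Edge weights follow the information-flow convention w_ij = -ln|C_ij|: a
# fully correlated contact (|C| = 1) costs nothing to traverse, an
# uncorrelated one is heavily penalized (floored so weights stay finite).

#' Correlation-derived edge weight
#'
#' w = -ln(max(|C|, floor)).  C = 1 gives w = 0; C = 0.5 gives
#' w = ln 2 = 0.6931; C below the floor is capped at -ln(floor) and flagged
#' via the `"capped"` attribute.
#'
#' @param c_ij correlation value(s) in `[-1, 1]` (a small numerical overshoot
#'   is tolerated; more is an error).
#' @param floor positive lower bound on `|C|` (default `1e-6`).
#' @return numeric weight(s) with logical attribute `"capped"`.
#' @export
edge_weight <- function(c_ij, floor = 1e-6) {
  if (floor <= 0) stop("'floor' must be positive")
  if (any(abs(c_ij) > 1 + 1e-8)) stop("|C_ij| exceeds 1 beyond tolerance")
  a <- pmin(abs(c_ij), 1)
  w <- -log(pmax(a, floor))
  attr(w, "capped") <- a < floor
  w
}

#' Build the correlation-weighted communication graph
#'
#' Nodes are the residues of the (occupancy-stable) contact network; each
#' stable contact edge gets weight w = -ln|C_ij| from the cross-correlation
#' matrix.  Edges with |C_ij| < `c_min` are marked weakly correlated: they
#' are excluded from explicit source-target path searches (where the
#' sufficiently-correlated-intermediates criterion applies) but retained for
#' betweenness, where low-correlation contacts still carry flow and are
#' penalized by their weight.
#'
#' @param network a `contact_network` (stable edges used when occupancy is
#'   present).
#' @param c_mat a [cross_correlation()] matrix covering all network residues
#'   (matched by residue key; a missing node is an error).
#' @param c_min correlation threshold for the path-search filter
#'   (default 0.5).
#' @param floor see [edge_weight()].
#' @return object of class `comm_graph`: residue table, edge table
#'   (`i`, `j`, `C`, `w`, `weak`), `c_min`, `floor`.
#' @export
build_comm_graph <- function(network, c_mat, c_min = 0.5, floor = 1e-6) {
  stopifnot(inherits(network, "contact_network"))
  rt <- network$residues
  keys <- rownames(c_mat)
  if (is.null(keys)) {
    if (nrow(c_mat) != nrow(rt))
      stop("unnamed correlation matrix must match the network's residue count")
    keys <- rt$key
    dimnames(c_mat) <- list(keys, keys)
  }
  pos <- match(rt$key, keys)
  if (anyNA(pos))
    stop("residue(s) missing from the correlation matrix: ",
         paste(rt$key[is.na(pos)], collapse = ", "))
  e <- network$edges
  if (!is.null(e$stable)) e <- e[e$stable, , drop = FALSE]
  cc <- unclass(c_mat)[cbind(pos[e$i], pos[e$j])]
  w <- edge_weight(cc, floor)
  edges <- data.frame(i = e$i, j = e$j, key_i = rt$key[e$i],
                      key_j = rt$key[e$j], C = cc, w = as.numeric(w),
                      weak = abs(cc) < c_min, stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  obj <- list(residues = rt, edges = edges, c_min = c_min, floor = floor)
  class(obj) <- "comm_graph"
  obj
}

#' @export
print.comm_graph <- function(x, ...) {
  cat(sprintf("comm_graph: %d residues, %d edges (%d weakly correlated, c_min = %g)\n",
              nrow(x$residues), nrow(x$edges), sum(x$edges$weak), x$c_min))
  invisible(x)
}

# Weight matrix of a comm_graph (Inf where no edge, 0 diagonal).
comm_weight_matrix <- function(graph, filter_weak = FALSE) {
  n <- nrow(graph$residues)
  w <- matrix(Inf, n, n, dimnames = list(graph$residues$key, graph$residues$key))
  diag(w) <- 0
  e <- graph$edges
  if (filter_weak) e <- e[!e$weak, , drop = FALSE]
  if (nrow(e)) {
    w[cbind(e$i, e$j)] <- e$w
    w[cbind(e$j, e$i)] <- e$w
  }
  w
}

#' All-pairs shortest path lengths and path counts
#'
#' Floyd-Warshall over the weighted graph, propagating the number of distinct
#' minimum-weight paths alongside the distances.  Two path lengths are
#' considered tied when they agree within a relative tolerance of 1e-9.
#' Disconnected pairs have infinite distance and count 0.
#'
#' @param graph a `comm_graph`, or a numeric weight matrix (`Inf` = no edge,
#'   non-negative weights).
#' @param filter_weak exclude weakly correlated edges (default `FALSE`;
#'   centrality uses the unfiltered graph).
#' @return list with `dist` (N x N), `counts` (shortest-path counts g_jk) and
#'   `keys`.
#' @export
all_pairs_shortest_paths <- function(graph, filter_weak = FALSE) {
  w <- if (inherits(graph, "comm_graph")) comm_weight_matrix(graph, filter_weak)
       else as.matrix(graph)
  if (any(w < 0)) stop("negative edge weights are not allowed")
  n <- nrow(w)
  d <- w
  g <- matrix(0, n, n)
  g[is.finite(w) & w > 0 | (is.finite(w) & row(w) != col(w))] <- 1
  g[!is.finite(w)] <- 0
  diag(d) <- 0
  diag(g) <- 1
  tol <- 1e-9
  for (k in seq_len(n)) {
    dk <- d[, k]
    dkj <- d[k, ]
    alt <- outer(dk, dkj, `+`)
    cnt <- outer(g[, k], g[k, ])
    eps <- tol * pmax(1, abs(alt))
    better <- is.finite(alt) & alt < d - eps
    equal <- is.finite(alt) & abs(alt - d) <= eps
    # never route a pair through one of its own endpoints
    better[k, ] <- FALSE; better[, k] <- FALSE
    equal[k, ] <- FALSE; equal[, k] <- FALSE
    diag(better) <- FALSE; diag(equal) <- FALSE
    d[better] <- alt[better]
    g[better] <- cnt[better]
    g[equal] <- g[equal] + cnt[equal]
  }
  keys <- rownames(w) %||% as.character(seq_len(n))
  list(dist = d, counts = g, keys = keys)
}

#' Degree centrality of a contact network
#'
#' D_i = sum_j a_ij, the adjacency row sum.
#'
#' @param network a `contact_network`.
#' @param stable_only see [adjacency_matrix()].
#' @return a [residue_profile()] of integer degrees.
#' @export
degree_centrality <- function(network, stable_only = NULL) {
  a <- adjacency_matrix(network, stable_only)
  residue_profile(network$residues, rowSums(a), "degree")
}

#' Normalized betweenness centrality
#'
#' b_i = sum over unordered pairs (j, k), j != i != k, of g_jk(i) / g_jk --
#' the fraction of minimum-weight paths between j and k passing through i --
#' normalized by (N-1)(N-2)/2 so values lie in [0, 1].  Endpoints are never
#' counted as pass-through nodes.  Computed on the full weighted graph
#' (weakly correlated edges included; their weight already penalizes them).
#'
#' @param graph a `comm_graph` or weight matrix.
#' @return a [residue_profile()] of normalized betweenness (plain numeric
#'   vector when a weight matrix is supplied).
#' @export
betweenness_centrality <- function(graph) {
  ap <- all_pairs_shortest_paths(graph, filter_weak = FALSE)
  d <- ap$dist
  g <- ap$counts
  n <- nrow(d)
  if (n < 3) {
    warning("betweenness needs >= 3 nodes; returning zeros")
    b <- rep(0, n)
  } else {
    b <- numeric(n)
    tol <- 1e-9
    for (i in seq_len(n)) {
      alt <- outer(d[, i], d[i, ], `+`)
      eps <- tol * pmax(1, abs(d))
      on_path <- is.finite(alt) & is.finite(d) & abs(alt - d) <= eps
      on_path[i, ] <- FALSE
      on_path[, i] <- FALSE
      diag(on_path) <- FALSE
      contrib <- matrix(0, n, n)
      idx <- on_path & g > 0
      contrib[idx] <- (outer(g[, i], g[i, ])[idx]) / g[idx]
      b[i] <- sum(contrib) / 2
    }
    b <- b / ((n - 1) * (n - 2) / 2)
  }
  if (inherits(graph, "comm_graph"))
    residue_profile(graph$residues, b, "betweenness")
  else b
}

#' Closeness centrality (inverse mean shortest-path distance)
#'
#' Exposed as the trivial derived quantity 1 / mean(d(i, j)) over the
#' finite-distance partners of each node; no dedicated analysis is built on
#' it.  Nodes with no finite partner get 0.
#'
#' @param graph a `comm_graph` or weight matrix.
#' @return a [residue_profile()] (plain numeric for a weight matrix).
#' @export
closeness_centrality <- function(graph) {
  d <- all_pairs_shortest_paths(graph)$dist
  cl <- vapply(seq_len(nrow(d)), function(i) {
    dd <- d[i, -i]
    dd <- dd[is.finite(dd)]
    if (!length(dd) || mean(dd) == 0) 0 else 1 / mean(dd)
  }, numeric(1))
  if (inherits(graph, "comm_graph")) residue_profile(graph$residues, cl, "closeness")
  else cl
}

# O(N^2) Dijkstra distances from one source over a weight matrix.
dijkstra_dist <- function(w, source) {
  n <- nrow(w)
  dist <- rep(Inf, n)
  dist[source] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    relax <- which(is.finite(w[u, ]) & !done)
    dist[relax] <- pmin(dist[relax], dist[u] + w[u, relax])
  }
  dist
}

#' Optimal and suboptimal paths between two residues
#'
#' Enumerates every simple path from `source` to `target` whose length (sum
#' of edge weights) is within `tolerance` of the optimal length, by
#' depth-first search with branch-and-bound pruning on the remaining-distance
#' lower bound.  The default tolerance 0.69 is the weight of a C = 0.5 edge,
#' so one such link of slack is allowed.  Weakly correlated edges (|C| below
#' the graph's `c_min`) are excluded from the search by default, implementing
#' the sufficiently-correlated-intermediates criterion.
#'
#' @param graph a `comm_graph`.
#' @param source,target residue keys (or indices); must differ.
#' @param tolerance length slack above the optimum (default 0.69).
#' @param filter_weak drop weakly correlated edges (default `TRUE`).
#' @param cap hard limit on enumerated paths (default 1e5); hitting it sets
#'   the `overflow` flag, and the ensemble (including the optimal-path counts
#'   derived from it) is then a truncation of the true ensemble.
#' @return object of class `path_ensemble`: `paths` (list of key vectors,
#'   shortest first), `lengths`, `l_opt`, `g` (count of optimal paths),
#'   `g_through` (per-node counts of optimal paths passing through),
#'   `overflow`, `disconnected`.
#' @export
suboptimal_paths <- function(graph, source, target, tolerance = 0.69,
                             filter_weak = TRUE, cap = 1e5) {
  stopifnot(inherits(graph, "comm_graph"))
  keys <- graph$residues$key
  resolve <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    i <- match(x, keys)
    if (is.na(i)) stop("residue '", x, "' not in graph")
    i
  }
  s <- resolve(source)
  t_ <- resolve(target)
  if (s == t_) stop("source and target must differ")
  w <- comm_weight_matrix(graph, filter_weak)
  n <- nrow(w)
  h <- dijkstra_dist(w, t_)  # admissible remaining-distance bound
  l_opt <- h[s]
  if (!is.finite(l_opt)) {
    out <- list(source = keys[s], target = keys[t_], paths = list(),
                lengths = numeric(0), l_opt = Inf, tolerance = tolerance,
                g = 0L, g_through = stats::setNames(integer(n), keys),
                overflow = FALSE, disconnected = TRUE)
    class(out) <- "path_ensemble"
    return(out)
  }
  budget <- l_opt + tolerance + 1e-9
  nbrs <- lapply(seq_len(n), function(i) {
    jj <- which(is.finite(w[i, ]) & seq_len(n) != i)
    jj[order(w[i, jj])]
  })
  paths <- list()
  lengths <- numeric(0)
  overflow <- FALSE
  visited <- rep(FALSE, n)
  path <- integer(n + 1)

  dfs <- function(u, len, depth) {
    if (overflow) return()
    if (u == t_) {
      if (length(paths) >= cap) {
        overflow <<- TRUE
        return()
      }
      paths[[length(paths) + 1L]] <<- path[seq_len(depth)]
      lengths[length(lengths) + 1L] <<- len
      return()
    }
    for (v in nbrs[[u]]) {
      if (visited[v]) next
      nl <- len + w[u, v]
      if (nl + h[v] > budget) next
      visited[v] <<- TRUE
      path[depth + 1L] <<- v
      dfs(v, nl, depth + 1L)
      visited[v] <<- FALSE
      if (overflow) return()
    }
  }
  visited[s] <- TRUE
  path[1] <- s
  dfs(s, 0, 1L)

  ord <- order(lengths)
  paths <- paths[ord]
  lengths <- lengths[ord]
  is_opt <- lengths <= l_opt + 1e-9 * max(1, l_opt)
  g_through <- integer(n)
  for (p in paths[is_opt]) {
    mid <- p[-c(1, length(p))]
    g_through[mid] <- g_through[mid] + 1L
  }
  out <- list(source = keys[s], target = keys[t_],
              paths = lapply(paths, function(p) keys[p]),
              lengths = lengths, l_opt = l_opt, tolerance = tolerance,
              g = sum(is_opt), g_through = stats::setNames(g_through, keys),
              overflow = overflow, disconnected = FALSE)
  class(out) <- "path_ensemble"
  out
}

#' @export
print.path_ensemble <- function(x, ...) {
  if (x$disconnected) {
    cat(sprintf("path_ensemble: %s -> %s DISCONNECTED\n", x$source, x$target))
    return(invisible(x))
  }
  cat(sprintf("path_ensemble: %s -> %s, %d path(s) within %.3g of L_opt = %.4g (%d optimal)%s\n",
              x$source, x$target, length(x$paths), x$tolerance, x$l_opt,
              x$g, if (x$overflow) " [OVERFLOW: cap hit]" else ""))
  invisible(x)
}

#' Write centrality profiles as TSV
#'
#' Columns: chain, resno, resname, degree, betweenness.
#'
#' @param degree a [degree_centrality()] profile.
#' @param betweenness a [betweenness_centrality()] profile over the same
#'   residues.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centrality <- function(degree, betweenness, path) {
  stopifnot(identical(degree$key, betweenness$key))
  out <- data.frame(chain = degree$chain, resno = degree$resno,
                    resname = degree$resname,
                    degree = as.integer(degree$value),
                    betweenness = sprintf("%.12e", betweenness$value))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a path ensemble as JSON
#'
#' @param pe a `path_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paths_json <- function(pe, path) {
  obj <- list(source = pe$source, target = pe$target, l_opt = pe$l_opt,
              tolerance = pe$tolerance, n_paths = length(pe$paths),
              n_optimal = pe$g, overflow = pe$overflow,
              disconnected = pe$disconnected,
              paths = lapply(seq_along(pe$paths), function(i) {
                list(length = pe$lengths[i], nodes = pe$paths[[i]])
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
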