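# k-clique enumeration and clique-percolation communities.
#
# A k-clique community is the union of all k-cliques reachable from one
# another through adjacent k-cliques.  The relaxed adjacency rule treats two
# k-cliques as adjacent when they share k-1 OR k-2 nodes (i.e. at least k-2);
# the standard rule requires k-1 shared nodes.

# Coerce the various graph representations to a two-column edge matrix plus
# node count.
as_edge_matrix <- function(x, stable_only = NULL) {
  if (inherits(x, "contact_network")) {
    e <- x$edges
    if (is.null(stable_only)) stable_only <- !is.null(e$stable)
    if (stable_only && !is.null(e$stable)) e <- e[e$stable, , drop = FALSE]
    list(edges = cbind(e$i, e$j), n = nrow(x$residues), keys = x$residues$key)
  } else if (inherits(x, "planted_graph")) {
    list(edges = x$edges, n = x$n_nodes, keys = as.character(seq_len(x$n_nodes)))
  } else if (is.matrix(x) && ncol(x) == 2L) {
    n <- if (nrow(x)) max(x) else 0L
    list(edges = x, n = n, keys = as.character(seq_len(n)))
  } else stop("cannot interpret graph input of class ", paste(class(x), collapse = "/"))
}

#' Enumerate all k-cliques of a graph
#'
#' Complete subgraphs of exactly size `k`, each reported once as a sorted node
#' tuple, in lexicographic order.  Enumeration uses a pivoting clique
#' traversal (via igraph) with size filtering.
#'
#' @param x a `contact_network` (stable edges by default), `planted_graph`, or
#'   two-column edge matrix.
#' @param k clique size (>= 3).
#' @param stable_only for contact networks, restrict to occupancy-stable
#'   edges (default when occupancy is present).
#' @return list of sorted integer node vectors.
#' @export
enumerate_k_cliques <- function(x, k, stable_only = NULL) {
  if (k < 3) stop("'k' must be >= 3")
  g <- as_edge_matrix(x, stable_only)
  if (!nrow(g$edges)) return(list())
  ig <- igraph::graph_from_edgelist(as.matrix(g$edges), directed = FALSE)
  if (igraph::vcount(ig) < g$n) ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
  cl <- igraph::cliques(ig, min = k, max = k)
  cl <- lapply(cl, function(v) sort(as.integer(v)))
  if (!length(cl)) return(list())
  ord <- order(vapply(cl, function(v) paste(sprintf("%09d", v), collapse = ""),
                      character(1)))
  cl[ord]
}

# Minimal union-find for clique components.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Assemble k-clique percolation communities
#'
#' Communities are the connected components of the clique-adjacency graph:
#' two k-cliques are adjacent when their node intersection meets the rule
#' (`"k-1"`: at least k-1 shared nodes; `"k-2"`/`"either"`: at least k-2, the
#' relaxed rule).  A community's node set is the union of its member cliques.
#'
#' @param cliques list of k-cliques from [enumerate_k_cliques()].
#' @param k the clique size.
#' @param rule adjacency rule: `"either"` (default, shared >= k-2), `"k-1"`,
#'   or `"k-2"`.
#' @param keys optional node labels recorded on the result.
#' @return object of class `community_set`: `k`, `rule`, `communities` (list
#'   of sorted node vectors, largest first), `member_cliques` (list of clique
#'   index vectors), `cliques`.
#' @export
clique_percolation <- function(cliques, k, rule = c("either", "k-1", "k-2"),
                               keys = NULL) {
  rule <- match.arg(rule)
  if (length(cliques) && any(lengths(cliques) != k))
    stop("all cliques must have size k = ", k)
  need <- if (rule == "k-1") k - 1L else k - 2L
  nc <- length(cliques)
  parent <- seq_len(nc)
  if (nc > 1L) {
    nodes <- sort(unique(unlist(cliques)))
    b <- matrix(0L, nc, length(nodes))
    for (ci in seq_len(nc)) b[ci, match(cliques[[ci]], nodes)] <- 1L
    shared <- tcrossprod(b)
    adj <- which(shared >= need & upper.tri(shared), arr.ind = TRUE)
    for (r in seq_len(nrow(adj))) {
      a <- uf_find(parent, adj[r, 1])
      bb <- uf_find(parent, adj[r, 2])
      if (a != bb) parent[max(a, bb)] <- min(a, bb)
    }
  }
  root <- vapply(seq_len(nc), function(i) uf_find(parent, i), integer(1))
  groups <- split(seq_len(nc), root)
  communities <- lapply(groups, function(g) sort(unique(unlist(cliques[g]))))
  ord <- order(-lengths(communities),
               vapply(communities, function(v) v[1], integer(1)))
  obj <- list(k = as.integer(k), rule = rule,
              communities = unname(communities[ord]),
              member_cliques = unname(groups[ord]),
              cliques = cliques, keys = keys)
  class(obj) <- "community_set"
  obj
}

#' @export
print.community_set <- function(x, ...) {
  cat(sprintf("community_set: k = %d, rule %s, %d communities (sizes: %s)\n",
              x$k, x$rule, length(x$communities),
              paste(lengths(x$communities), collapse = ", ")))
  if (!is.null(x$simultaneous))
    cat("  simultaneous-presence fractions:",
        paste(signif(x$simultaneous, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Communities of a contact network
#'
#' Convenience wrapper: enumerates k-cliques on the network (stable edges when
#' occupancy is present) and assembles percolation communities for each k,
#' plus the union of member nodes across the requested k values.
#'
#' @param network a `contact_network`.
#' @param k clique sizes (default `c(3, 4)`).
#' @param rule adjacency rule, see [clique_percolation()].
#' @return list with one `community_set` per k (named `k3`, `k4`, ...) and
#'   `union_nodes`, the sorted union of all community members.
#' @export
psn_communities <- function(network, k = c(3, 4), rule = "either") {
  out <- list()
  for (kk in k) {
    cl <- enumerate_k_cliques(network, kk)
    out[[paste0("k", kk)]] <- clique_percolation(cl, kk, rule,
                                                 keys = network$residues$key)
  }
  out$union_nodes <- sort(unique(unlist(lapply(
    out[paste0("k", k)], function(cs) unlist(cs$communities)))))
  out
}

#' Dynamically stable communities of an ensemble network
#'
#' Communities are computed on the occupancy-stable edge network (edges intact
#' in strictly more than `occupancy_threshold` of the snapshots).  Because an
#' "intact" multi-edge community admits two readings (every edge individually
#' stable vs. all edges present at once), each community additionally reports
#' the fraction of snapshots in which all of its member-clique edges are
#' simultaneously present.
#'
#' @param network an [ensemble_network()] result (must carry the per-snapshot
#'   presence matrix for simultaneous fractions; otherwise they are `NA`).
#' @param k clique size.
#' @param rule adjacency rule, see [clique_percolation()].
#' @param occupancy_threshold stability threshold (default from the network
#'   config).
#' @return a `community_set` with an extra `simultaneous` vector.
#' @export
stable_communities <- function(network, k, rule = "either",
                               occupancy_threshold = NULL) {
  stopifnot(inherits(network, "contact_network"))
  e <- network$edges
  if (is.null(e$occupancy))
    stop("network carries no occupancy information; use ensemble_network()")
  thr <- occupancy_threshold %||% network$config$occupancy_threshold
  stable <- e$occupancy > thr
  sub <- contact_network(network$residues, e[stable, , drop = FALSE],
                         network$config)
  cl <- enumerate_k_cliques(sub, k, stable_only = FALSE)
  cs <- clique_percolation(cl, k, rule, keys = network$residues$key)

  edge_id <- paste(e$i, e$j)
  cs$simultaneous <- vapply(seq_along(cs$communities), function(ci) {
    cl_idx <- cs$member_cliques[[ci]]
    pairs <- unique(do.call(rbind, lapply(cs$cliques[cl_idx], function(v) {
      t(utils::combn(v, 2))
    })))
    rows <- match(paste(pairs[, 1], pairs[, 2]), edge_id)
    if (anyNA(rows) || is.null(network$snapshots)) return(NA_real_)
    pres <- network$snapshots[rows, , drop = FALSE]
    mean(colSums(pres) == nrow(pres))
  }, numeric(1))
  cs
}

#' Write community sets as plain text and JSON
#'
#' One community per line in the text listing: k, rule, then member residue
#' keys.
#'
#' @param community_sets list of `community_set`s (e.g. [psn_communities()]).
#' @param path_txt plain-text output path.
#' @param path_json optional JSON output path.
#' @return `path_txt`, invisibly.
#' @export
write_communities <- function(community_sets, path_txt, path_json = NULL) {
  if (inherits(community_sets, "community_set"))
    community_sets <- list(community_sets)
  lines <- character(0)
  for (cs in community_sets) {
    if (!inherits(cs, "community_set")) next
    for (ci in seq_along(cs$communities)) {
      mem <- cs$communities[[ci]]
      lab <- if (!is.null(cs$keys)) cs$keys[mem] else as.character(mem)
      lines <- c(lines, paste(cs$k, cs$rule, paste(lab, collapse = ","),
                              sep = "\t"))
    }
  }
  writeLines(c("k\trule\tmembers", lines), path_txt)
  if (!is.null(path_json)) {
    obj <- lapply(Filter(function(z) inherits(z, "community_set"),
                         community_sets), function(cs) {
      list(k = cs$k, rule = cs$rule,
           communities = lapply(cs$communities, function(mem) {
             if (!is.null(cs$keys)) cs$keys[mem] else mem
           }),
           simultaneous = cs$simultaneous %||% NULL)
    })
    jsonlite::write_json(obj, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path_txt)
}
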