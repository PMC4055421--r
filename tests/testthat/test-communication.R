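# Correlation-weighted communication graphs, shortest paths, centrality,
# suboptimal path ensembles.


test_that("edge weights follow w = -ln|C| with a floor", {
  expect_equal(as.numeric(edge_weight(0.5)), log(2), tolerance = 1e-12)
  expect_equal(as.numeric(edge_weight(1.0)), 0)
  expect_equal(as.numeric(edge_weight(-0.5)), log(2), tolerance = 1e-12)
  w0 <- edge_weight(0)
  expect_equal(as.numeric(w0), -log(1e-6))
  expect_true(attr(w0, "capped"))
  expect_false(attr(edge_weight(0.5), "capped"))
  expect_error(edge_weight(1.2), "exceeds 1")
})

test_that("communication graphs are restricted to stable contacts", {
  rt <- data.frame(chain = "A", resno = 1:4, icode = "", resname = "GLY",
                   key = paste0("A:", 1:4), chain_pos = 1:4,
                   stringsAsFactors = FALSE)
  edges <- data.frame(i = c(1, 1, 2), j = c(3, 4, 4), I_ij = 10,
                      occupancy = c(1, 1, 0.5), stable = c(TRUE, TRUE, FALSE))
  net <- contact_network(rt, edges, psn_config())
  cm <- diag(4)
  cm[1, 3] <- cm[3, 1] <- 0.8
  cm[1, 4] <- cm[4, 1] <- 0.3
  cm[2, 4] <- cm[4, 2] <- 0.9
  dimnames(cm) <- list(rt$key, rt$key)
  g <- build_comm_graph(net, cm, c_min = 0.5)
  # unstable contact dropped; absent contacts never become edges
  expect_identical(paste(g$edges$i, g$edges$j), c("1 3", "1 4"))
  expect_equal(g$edges$w[1], -log(0.8), tolerance = 1e-12)
  expect_identical(g$edges$weak, c(FALSE, TRUE))

  cm_small <- cm[1:3, 1:3]
  expect_error(build_comm_graph(net, cm_small, 0.5), "A:4")
})

test_that("shortest paths and counts match small closed-form cases", {
  w <- matrix(Inf, 3, 3)
  diag(w) <- 0
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  w[1, 3] <- w[3, 1] <- 3
  ap <- all_pairs_shortest_paths(w)
  expect_equal(ap$dist[1, 3], 2)
  expect_equal(ap$counts[1, 3], 1)

  w4 <- matrix(Inf, 4, 4)
  diag(w4) <- 0
  for (p in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    w4[p[1], p[2]] <- w4[p[2], p[1]] <- 1
  ap4 <- all_pairs_shortest_paths(w4)
  expect_equal(ap4$dist[1, 3], 2)
  expect_equal(ap4$counts[1, 3], 2)

  expect_error(all_pairs_shortest_paths(matrix(c(0, -1, -1, 0), 2)),
               "negative")
})

test_that("distances and counts equal exhaustive enumeration on random graphs", {
  for (seed in 1:25) {
    n <- sample(5:9, 1)
    w <- random_weight_graph(n, 0.45, seed + 300)
    ap <- all_pairs_shortest_paths(w)
    bs <- brute_shortest(w)
    expect_equal(ap$dist, bs$dist, tolerance = 1e-9)
    expect_equal(ap$counts, bs$counts)
    # metric properties
    expect_equal(ap$dist, t(ap$dist))
    for (k in seq_len(n))
      expect_true(all(ap$dist <= outer(ap$dist[, k], ap$dist[k, ], `+`) + 1e-9))
  }
})

test_that("betweenness matches canonical values and the enumeration oracle", {
  # 3-node path: middle node carries the single pair
  wp <- matrix(Inf, 3, 3)
  diag(wp) <- 0
  wp[1, 2] <- wp[2, 1] <- 1
  wp[2, 3] <- wp[3, 2] <- 1
  expect_equal(betweenness_centrality(wp), c(0, 1, 0))

  # star with 4 leaves: center 1, leaves 0
  ws <- matrix(Inf, 5, 5)
  diag(ws) <- 0
  ws[1, 2:5] <- ws[2:5, 1] <- 1
  expect_equal(betweenness_centrality(ws), c(1, 0, 0, 0, 0))

  # 5-cycle: every node 1/6
  wc <- matrix(Inf, 5, 5)
  diag(wc) <- 0
  for (i in 1:5) {
    j <- i %% 5 + 1
    wc[i, j] <- wc[j, i] <- 1
  }
  expect_equal(betweenness_centrality(wc), rep(1 / 6, 5))

  for (seed in 1:25) {
    n <- sample(5:9, 1)
    w <- random_weight_graph(n, 0.45, seed + 400)
    expect_equal(betweenness_centrality(w), brute_betweenness(w),
                 tolerance = 1e-9)
  }
})

test_that("betweenness agrees with an independent graph library", {
  for (seed in c(7, 19)) {
    n <- 10
    w <- random_weight_graph(n, 0.4, seed + 500)
    idx <- which(is.finite(w) & upper.tri(w), arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(idx, directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    ref <- igraph::betweenness(g, weights = w[idx]) / ((n - 1) * (n - 2) / 2)
    expect_equal(betweenness_centrality(w), unname(ref), tolerance = 1e-9)
  }
})

test_that("removing a zero-betweenness node leaves other distances intact", {
  # append a pendant leaf: it lies on no through-path, so its betweenness is
  # zero and deleting it must not perturb any other pair
  w <- random_weight_graph(7, 0.5, 611)
  n <- nrow(w) + 1L
  w <- rbind(cbind(w, Inf), Inf)
  diag(w) <- 0
  w[1, n] <- w[n, 1] <- 0.7
  b <- betweenness_centrality(w)
  expect_equal(b[n], 0)
  d_before <- all_pairs_shortest_paths(w)$dist[-n, -n]
  d_after <- all_pairs_shortest_paths(w[-n, -n])$dist
  expect_equal(d_after, d_before, tolerance = 1e-12)
})

test_that("degree centrality is the adjacency row sum", {
  rt <- data.frame(chain = "A", resno = 1:5, icode = "", resname = "GLY",
                   key = paste0("A:", 1:5), chain_pos = 1:5,
                   stringsAsFactors = FALSE)
  path3 <- contact_network(rt[1:3, ], data.frame(i = c(1, 2), j = c(2, 3)),
                           psn_config())
  expect_equal(degree_centrality(path3)$value, c(1, 2, 1))
  k5 <- contact_network(rt, as.data.frame(t(utils::combn(5, 2)) |>
                                            `colnames<-`(c("i", "j"))),
                        psn_config())
  expect_equal(degree_centrality(k5)$value, rep(4, 5))
})

test_that("suboptimal path ensembles honor the length tolerance", {
  # second-best path is exactly 0.5 longer than the optimum
  w <- matrix(Inf, 4, 4)
  diag(w) <- 0
  w[1, 2] <- w[2, 1] <- 1
  w[2, 4] <- w[4, 2] <- 1
  w[1, 3] <- w[3, 1] <- 1.25
  w[3, 4] <- w[4, 3] <- 1.25
  g <- toy_comm_graph(w, c_min = 0)
  pe <- suboptimal_paths(g, "A:1", "A:4", tolerance = 0.69)
  expect_length(pe$paths, 2L)
  expect_equal(pe$lengths, c(2, 2.5))
  expect_identical(pe$paths[[1]], c("A:1", "A:2", "A:4"))
  expect_equal(pe$g, 1L)
  expect_equal(unname(pe$g_through["A:2"]), 1L)

  pe0 <- suboptimal_paths(g, "A:1", "A:4", tolerance = 0)
  expect_length(pe0$paths, 1L)

  # disconnected pair
  w2 <- matrix(Inf, 3, 3)
  diag(w2) <- 0
  w2[1, 2] <- w2[2, 1] <- 1
  pe_d <- suboptimal_paths(toy_comm_graph(w2, 0), "A:1", "A:3")
  expect_true(pe_d$disconnected)
  expect_length(pe_d$paths, 0L)

  # the enumeration cap trips the overflow flag
  wk <- matrix(0.01, 6, 6)
  diag(wk) <- 0
  pe_cap <- suboptimal_paths(toy_comm_graph(wk, 0), "A:1", "A:6",
                             tolerance = 5, cap = 3)
  expect_true(pe_cap$overflow)
  expect_length(pe_cap$paths, 3L)
})

test_that("path ensembles equal brute-force length-bounded enumeration", {
  for (seed in 1:20) {
    n <- sample(5:9, 1)
    w <- random_weight_graph(n, 0.5, seed + 700)
    g <- toy_comm_graph(w, c_min = 0)
    bp <- brute_simple_paths(w, 1, n)
    pe <- suboptimal_paths(g, 1, n, tolerance = 0.69)
    if (!length(bp$lengths)) {
      expect_true(pe$disconnected)
      next
    }
    keep <- bp$lengths <= min(bp$lengths) + 0.69 + 1e-9
    expect_equal(sort(pe$lengths), sort(bp$lengths[keep]), tolerance = 1e-9)
    got <- vapply(pe$paths, function(p) paste(sub("A:", "", p), collapse = "-"),
                  character(1))
    want <- vapply(bp$paths[keep], paste, character(1), collapse = "-")
    expect_setequal(got, want)
  }
})

test_that("weakly correlated edges are skipped in path search only", {
  rt <- data.frame(chain = "A", resno = 1:3, icode = "", resname = "GLY",
                   key = paste0("A:", 1:3), chain_pos = 1:3,
                   stringsAsFactors = FALSE)
  net <- contact_network(rt, data.frame(i = c(1, 2), j = c(3, 3), I_ij = 10),
                         psn_config())
  cm <- diag(3)
  cm[1, 3] <- cm[3, 1] <- 0.3   # weak
  cm[2, 3] <- cm[3, 2] <- 0.9
  dimnames(cm) <- list(rt$key, rt$key)
  g <- build_comm_graph(net, cm, c_min = 0.5)
  pe <- suboptimal_paths(g, "A:1", "A:2")
  expect_true(pe$disconnected)  # the weak 1-3 link is filtered out
  pe_all <- suboptimal_paths(g, "A:1", "A:2", filter_weak = FALSE)
  expect_false(pe_all$disconnected)
  # betweenness still lets flow cross the weak edge
  b <- betweenness_centrality(g)
  expect_gt(b$value[3], 0)
})

test_that("a single bridge between two communities attains top betweenness", {
  # two K4s joined only through node 9
  set.seed(5)
  w <- matrix(Inf, 9, 9)
  diag(w) <- 0
  for (pr in utils::combn(1:4, 2, simplify = FALSE))
    w[pr[1], pr[2]] <- w[pr[2], pr[1]] <- stats::runif(1, 0.2, 0.4)
  for (pr in utils::combn(5:8, 2, simplify = FALSE))
    w[pr[1], pr[2]] <- w[pr[2], pr[1]] <- stats::runif(1, 0.2, 0.4)
  for (v in c(1, 2, 5, 6)) w[v, 9] <- w[9, v] <- 0.3
  b <- betweenness_centrality(w)
  expect_identical(which.max(b), 9L)
})

test_that("closeness is the inverse mean distance to reachable nodes", {
  wp <- matrix(Inf, 3, 3)
  diag(wp) <- 0
  wp[1, 2] <- wp[2, 1] <- 1
  wp[2, 3] <- wp[3, 2] <- 1
  # middle node: mean distance 1; ends: mean(1, 2) = 1.5
  expect_equal(closeness_centrality(wp), c(1 / 1.5, 1, 1 / 1.5))
  # isolated node gets 0
  wi <- matrix(Inf, 2, 2)
  diag(wi) <- 0
  expect_equal(closeness_centrality(wi), c(0, 0))
})
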