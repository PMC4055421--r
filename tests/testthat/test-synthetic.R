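# Generator determinism and the analytic structure the generators promise.

test_that("toy chains are deterministic and validate their arguments", {
  expect_identical(build_toy_chain(10, "extended", seed = 1)$xyz,
                   build_toy_chain(10, "extended", seed = 1)$xyz)
  expect_false(identical(build_toy_chain(10, "extended", seed = 1)$xyz,
                         build_toy_chain(10, "extended", seed = 2)$xyz))
  expect_error(build_toy_chain(2, "extended"), "n_res")
  expect_error(build_toy_chain(10, "banana"))
})

test_that("dumbbell geometry separates two compact clusters", {
  s <- build_toy_chain(43, "dumbbell")
  cl <- attr(s, "clusters")
  c1 <- colMeans(s$xyz[cl$domain1, ])
  c2 <- colMeans(s$xyz[cl$domain2, ])
  r1 <- max(sqrt(rowSums(sweep(s$xyz[cl$domain1, ], 2, c1)^2)))
  r2 <- max(sqrt(rowSums(sweep(s$xyz[cl$domain2, ], 2, c2)^2)))
  expect_gt(sqrt(sum((c1 - c2)^2)), max(r1, r2))
})

test_that("the GNM prescribes a valid covariance", {
  g <- gnm_model(build_toy_chain(12, "helix"), cutoff = 7, scale = 0.5)
  expect_equal(rowSums(g$kirchhoff), rep(0, 12), tolerance = 1e-10)
  ev <- eigen(g$kirchhoff, symmetric = TRUE)$values
  expect_equal(sum(ev < 1e-8), 1L)  # connected: exactly one zero mode
  expect_equal(g$covariance, t(g$covariance))
  expect_true(min(eigen(g$covariance, symmetric = TRUE)$values) > -1e-10)
  # disconnected model is refused
  expect_error(gnm_model(build_toy_chain(40, "dumbbell"), cutoff = 4),
               "not connected")
})

test_that("the Gaussian sampler matches its own analytic covariance", {
  g <- gnm_model(build_toy_chain(10, "helix"), cutoff = 7, scale = 0.5)
  n <- 8000
  gs <- sample_gaussian_ensemble(g, n, seed = 11)
  # per-axis empirical covariance vs the returned analytic matrix, each entry
  # within 5 standard errors of its sampling distribution
  for (ax in 1:3) {
    x <- t(gs$ensemble$coords[, ax, ])
    emp <- stats::var(x) * (n - 1) / n
    se <- sqrt((outer(diag(gs$covariance), diag(gs$covariance)) +
                gs$covariance^2) / n)
    expect_lt(max(abs(emp - gs$covariance) / se), 5)
  }
  # sample means converge to the mean structure
  m <- apply(gs$ensemble$coords, c(1, 2), mean)
  expect_lt(max(abs(m - g$structure$xyz)), 5 * sqrt(max(diag(gs$covariance)) / n))
})

test_that("Gaussian sampling is reproducible and honors a frozen model", {
  g <- gnm_model(build_toy_chain(6, "helix"), cutoff = 7, scale = 0.3)
  a <- sample_gaussian_ensemble(g, 50, seed = 7)
  b <- sample_gaussian_ensemble(g, 50, seed = 7)
  expect_identical(a$ensemble$coords, b$ensemble$coords)

  g0 <- gnm_model(build_toy_chain(6, "helix"), cutoff = 7, scale = 0)
  z <- sample_gaussian_ensemble(g0, 10, seed = 1)
  for (f in 1:10)
    expect_equal(z$ensemble$coords[, , f], g0$structure$xyz,
                 ignore_attr = TRUE)
  expect_error(sample_gaussian_ensemble(g, 1), "n_frames")
})

test_that("hinge ensembles keep domains rigid and move only across the hinge", {
  h <- make_hinge_ensemble(6, hinge_len = 2, max_angle = 40, n_frames = 25,
                           seed = 3)
  dom <- attr(h, "domains")
  pair_dist_var <- function(i, j) {
    d <- sqrt(colSums((h$coords[i, , ] - h$coords[j, , ])^2))
    stats::var(d)
  }
  # any intra-domain pair: distance variance zero (machine precision)
  expect_lt(pair_dist_var(dom$domain1[1], dom$domain1[4]), 1e-20)
  expect_lt(pair_dist_var(dom$domain2[2], dom$domain2[5]), 1e-20)
  # a cross-domain pair fluctuates
  expect_gt(pair_dist_var(dom$domain1[1], dom$domain2[6]), 1e-4)
  # vanishing angle: all frames collapse onto one structure
  h0 <- make_hinge_ensemble(6, hinge_len = 2, max_angle = 1e-9, n_frames = 5,
                            seed = 3)
  expect_lt(max(abs(sweep(h0$coords, c(1, 2), h0$coords[, , 1]))), 1e-8)
  expect_error(make_hinge_ensemble(6, hinge_len = 0), "hinge_len")
  # determinism
  expect_identical(make_hinge_ensemble(5, 1, 30, 10, seed = 9)$coords,
                   make_hinge_ensemble(5, 1, 30, 10, seed = 9)$coords)
})

test_that("superposing onto one domain zeroes that domain's RMSF", {
  h <- make_hinge_ensemble(6, hinge_len = 1, max_angle = 50, n_frames = 15,
                           seed = 2)
  dom <- attr(h, "domains")
  rt <- residue_table(h)
  sel <- structure(list(mode = "calpha",
                        residues = rt[dom$domain1, ],
                        atom_idx = as.list(dom$domain1)),
                   class = "residue_selection")
  sup <- superpose(h, sel)
  x <- sup$coords[dom$domain1, , , drop = FALSE]
  m <- apply(x, c(1, 2), mean)
  rmsf <- sqrt(apply(sweep(x, c(1, 2), m)^2, 1, mean) * 3)
  expect_lt(max(rmsf), 1e-6)
})

test_that("generators emit valid multi-model PDB through the ensemble reader", {
  h <- make_hinge_ensemble(4, 1, 30, 4, seed = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(h, path)
  back <- read_multimodel_pdb(path)
  expect_equal(n_frames(back), 4)
  expect_equal(back$coords, h$coords, tolerance = 1e-3)
})

test_that("the contact fixture's manifest matches a brute-force recount", {
  fx <- make_contact_fixture()
  sel <- select_residue_atoms(fx$structure, "sidechain")
  xyz <- fx$structure$xyz
  nres <- nrow(sel$residues)
  # independent O(n^2) recount of side-chain atom pairs within 4.5 A
  count <- function(i, j) {
    cnt <- 0L
    for (a in sel$atom_idx[[i]]) for (b in sel$atom_idx[[j]]) {
      if (sqrt(sum((xyz[a, ] - xyz[b, ])^2)) <= 4.5) cnt <- cnt + 1L
    }
    cnt
  }
  for (r in seq_len(nrow(fx$manifest))) {
    expect_identical(count(fx$manifest$res_i[r], fx$manifest$res_j[r]),
                     as.integer(fx$manifest$n_ij[r]))
  }
  # every pair not listed in the manifest has no contacts
  listed <- paste(fx$manifest$res_i, fx$manifest$res_j)
  for (i in 1:(nres - 1)) for (j in (i + 1):nres) {
    if (!(paste(i, j) %in% listed)) expect_identical(count(i, j), 0L)
  }
  # residue 4 was placed beyond the cutoff from everything
  expect_true(all(fx$manifest$res_i != 4 & fx$manifest$res_j != 4))
})

test_that("planted community graphs encode their construction", {
  pg <- make_planted_community_graph(c(4, 4), shared_nodes = 3, seed = 2)
  expect_identical(pg$n_nodes, 5L)
  # each planted clique is complete in the edge list
  ekey <- paste(pg$edges[, 1], pg$edges[, 2])
  for (cl in pg$cliques) {
    pr <- t(utils::combn(sort(cl), 2))
    expect_true(all(paste(pr[, 1], pr[, 2]) %in% ekey))
  }
  expect_identical(canon_sets(planted_memberships(pg, "k-1")),
                   canon_sets(list(1:5)))

  pg0 <- make_planted_community_graph(c(4, 4), shared_nodes = 0, seed = 2)
  expect_identical(pg0$n_nodes, 8L)
  expect_length(planted_memberships(pg0, "k-1"), 2L)

  expect_error(make_planted_community_graph(c(4, 4), shared_nodes = 4),
               "shared_nodes")
  expect_error(make_planted_community_graph(c(2, 4), 1), "clique size")
  expect_identical(make_planted_community_graph(c(3, 3), 1, seed = 5)$edges,
                   make_planted_community_graph(c(3, 3), 1, seed = 5)$edges)
})
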