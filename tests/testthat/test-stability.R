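# Force-constant profiling, B-factors, and residue-depth profiles.

test_that("the force constant evaluates the stated fluctuation formula", {
  # two point residues; separation alternates so Var(d_i) = 0.1 A^2 exactly
  s <- sqrt(0.1)
  frames <- list(rbind(c(0, 0, 0), c(10 - s, 0, 0)),
                 rbind(c(0, 0, 0), c(10 + s, 0, 0)))
  ens <- make_point_ensemble(frames)
  cfg <- stability_config(exclusion = 0)
  fc <- force_constants(mean_distance_series(ens, config = cfg), cfg)
  k_expected <- 3 * 1.987e-3 * 300 / 0.1  # = 17.883
  expect_equal(fc$value, rep(k_expected, 2), tolerance = 1e-12)
  expect_equal(fc$d_mean, rep(10, 2), tolerance = 1e-12)
  # the scale factor is a configuration constant, not hard-wired
  cfg1 <- stability_config(exclusion = 0, factor = 1)
  fc1 <- force_constants(mean_distance_series(ens, config = cfg1), cfg1)
  expect_equal(fc1$value, fc$value / 3, tolerance = 1e-12)
})

test_that("distance series respect exclusion windows and report degeneracies", {
  frames <- list(rbind(c(0, 0, 0), c(5, 0, 0)), rbind(c(0, 0, 0), c(5, 0, 0.1)))
  ens <- make_point_ensemble(frames)
  cfg0 <- stability_config(exclusion = 0)
  ds <- mean_distance_series(ens, config = cfg0)
  expect_equal(ds$d[1, ], c(5, 5), tolerance = 1e-12)
  # 3-residue chain under exclusion 1: the middle residue has no partners
  ch3 <- make_point_ensemble(list(build_toy_chain(3, "extended")$xyz,
                                  build_toy_chain(3, "extended")$xyz + 0.1))
  expect_error(mean_distance_series(ch3, config = stability_config()), "A:2")
  # single frame carries no fluctuations
  expect_error(mean_distance_series(make_point_ensemble(frames[1]),
                                    config = cfg0), "single frame")
})

test_that("zero-variance residues are flagged rigid, and k is monotone in variance", {
  xyz <- build_toy_chain(5, "extended")$xyz
  ens <- make_point_ensemble(list(xyz, xyz, xyz))
  fc <- force_constant_profile(ens)
  expect_true(all(fc$rigid))
  expect_true(all(is.na(fc$value)))

  k_of_var <- function(v) {
    s <- sqrt(v)
    frames <- list(rbind(c(0, 0, 0), c(10 - s, 0, 0)),
                   rbind(c(0, 0, 0), c(10 + s, 0, 0)))
    cfg <- stability_config(exclusion = 0)
    force_constants(mean_distance_series(make_point_ensemble(frames),
                                         config = cfg), cfg)$value[1]
  }
  ks <- vapply(c(0.05, 0.1, 0.5, 2), k_of_var, numeric(1))
  expect_true(all(diff(ks) < 0))
})

test_that("force constants are invariant under per-frame rigid transforms", {
  g <- gnm_model(build_toy_chain(10, "helix"), cutoff = 7, scale = 0.4)
  ens <- sample_gaussian_ensemble(g, 60, seed = 21)$ensemble
  fc0 <- force_constant_profile(ens)$value
  moved <- ens
  set.seed(99)
  for (f in seq_len(n_frames(ens))) {
    r <- psnet:::random_rotation()
    shift <- stats::rnorm(3, 0, 20)
    moved$coords[, , f] <- sweep(ens$coords[, , f] %*% r, 2, shift, `+`)
  }
  fc1 <- force_constant_profile(moved)$value
  expect_lt(max(abs(fc1 - fc0) / fc0), 1e-9)
})

test_that("optimized force constants equal the naive double-loop oracle", {
  g <- gnm_model(build_toy_chain(9, "helix"), cutoff = 7, scale = 0.4)
  ens <- sample_gaussian_ensemble(g, 40, seed = 13)$ensemble
  fc <- force_constant_profile(ens)$value
  oracle <- naive_force_constants(ens)
  expect_lt(max(abs(fc - oracle) / oracle), 1e-10)
})

test_that("hinge-flanking residues are stiffer than distal domain residues", {
  h <- make_hinge_ensemble(10, hinge_len = 1, max_angle = 40, n_frames = 60,
                           seed = 6, noise = 0.05)
  dom <- attr(h, "domains")
  fc <- force_constant_profile(h)
  flank <- c(utils::tail(dom$domain1, 1), dom$hinge, dom$domain2[1])
  distal <- c(utils::head(dom$domain1, 3), utils::tail(dom$domain2, 3))
  expect_gt(min(fc$value[flank]), stats::median(fc$value[distal]))
})

test_that("B-factors reproduce the closed form and scale quadratically", {
  # node 1 displaced by +/-(0.5, 0.5, 0.5): per-frame MSD 0.75 A^2 exactly
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  d <- c(0.5, 0.5, 0.5)
  f1 <- base; f1[1, ] <- f1[1, ] + d
  f2 <- base; f2[1, ] <- f2[1, ] - d
  ens <- make_point_ensemble(list(f1, f2))
  b <- bfactors(ens)
  expect_equal(b$value, c(8 * pi^2 / 3 * 0.75, 0, 0), tolerance = 1e-12)

  f1b <- base; f1b[1, ] <- f1b[1, ] + 2 * d
  f2b <- base; f2b[1, ] <- f2b[1, ] - 2 * d
  b2 <- bfactors(make_point_ensemble(list(f1b, f2b)))
  expect_equal(b2$value[1], 4 * b$value[1], tolerance = 1e-12)

  expect_warning(b0 <- bfactors(make_point_ensemble(list(base))), "single")
  expect_equal(b0$value, c(0, 0, 0))
})

test_that("isotropic Gaussian fluctuations give B = 8 pi^2 sigma^2", {
  # single free node with per-axis variance 0.25 A^2, plus a distant anchor
  set.seed(42)
  n <- 4000
  frames <- lapply(seq_len(n), function(f) {
    rbind(c(0, 0, 0) + stats::rnorm(3, 0, 0.5), c(50, 0, 0))
  })
  b <- bfactors(make_point_ensemble(frames))
  expect_equal(b$value[1], 8 * pi^2 * 0.25, tolerance = 0.1)
})

test_that("residue depth behaves like a distance below the accessible surface", {
  # two far-apart atoms are each effectively isolated: depth = r_vdw + probe
  at <- data.frame(serial = 1:2, name = "CA", resname = "GLY", chain = "A",
                   resno = 1:2, icode = "", element = "C",
                   stringsAsFactors = FALSE)
  iso <- as_ensemble(structure3d(at, rbind(c(0, 0, 0), c(100, 0, 0))))
  dp <- residue_depth_profile(iso, probe_radius = 1.4, n_sphere_points = 64)
  expect_equal(dp$value, rep(1.70 + 1.4, 2), tolerance = 1e-9)

  # the center of an octahedral cluster is strictly deeper than the shell
  center <- c(0, 0, 0)
  shell <- rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0),
                 c(0, 0, 3), c(0, 0, -3))
  at7 <- data.frame(serial = 1:7, name = "CA", resname = "GLY", chain = "A",
                    resno = 1:7, icode = "", element = "C",
                    stringsAsFactors = FALSE)
  clus <- as_ensemble(structure3d(at7, rbind(center, shell)))
  dpc <- residue_depth_profile(clus, n_sphere_points = 128)
  expect_gt(dpc$value[1], max(dpc$value[2:7]))

  # sphere-point discretization is converged well below 0.1 A
  dpc2 <- residue_depth_profile(clus, n_sphere_points = 256)
  expect_lt(max(abs(dpc2$value - dpc$value)), 0.1)

  one <- structure3d(at7[1, ], matrix(0, 1, 3))
  expect_error(residue_depth_profile(as_ensemble(one)), ">= 2 atoms")
})

test_that("differential depth is antisymmetric and localizes burial changes", {
  at7 <- data.frame(serial = 1:7, name = "CA", resname = "GLY", chain = "A",
                    resno = 1:7, icode = "", element = "C",
                    stringsAsFactors = FALSE)
  shell <- rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0),
                 c(0, 0, 3), c(0, 0, -3))
  buried <- as_ensemble(structure3d(at7, rbind(c(0, 0, 0), shell)))
  exposed <- as_ensemble(structure3d(at7, rbind(c(50, 0, 0), shell)))
  da <- residue_depth_profile(buried, n_sphere_points = 96)
  db <- residue_depth_profile(exposed, n_sphere_points = 96)

  expect_equal(differential_depth(da, da)$value, rep(0, 7))
  dd <- differential_depth(da, db)
  rev_dd <- differential_depth(db, da)
  expect_equal(dd$value, -rev_dd$value, tolerance = 1e-12)
  # residue 1 is buried only in state a: the positive peak sits there
  expect_gt(dd$value[1], 0.5)
  expect_equal(which.max(dd$value), 1L)

  expect_error(differential_depth(da[1:3, ], da[4:7, ]), "no residues")
})
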