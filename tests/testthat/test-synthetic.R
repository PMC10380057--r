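test_that("Markov sampler is seeded, stochastic-matrix-checked and frequency-correct", {
  expect_error(generate_markov_series(matrix(c(0.5, 0.2, 0.5, 0.9), 2), 10),
               "stochastic")
  expect_equal(generate_markov_series(diag(3), 50, seed = 2),
               rep(generate_markov_series(diag(3), 1, seed = 2), 50))
  s1 <- generate_markov_series(matrix(0.5, 2, 2), 1000, seed = 3)
  s2 <- generate_markov_series(matrix(0.5, 2, 2), 1000, seed = 3)
  expect_identical(s1, s2)
  s <- generate_markov_series(matrix(0.5, 2, 2), 1e5, seed = 4)
  trans <- table(s[-length(s)], s[-1])
  freq <- trans / rowSums(trans)
  expect_lt(max(abs(freq - 0.5)), 0.01)
})

test_that("geometry engine reproduces a chain from its own measured dihedrals", {
  set.seed(71)
  phi <- matrix(runif(20, -180, 180), 20, 1)
  psi <- matrix(runif(20, -180, 180), 20, 1)
  co <- build_backbone(phi, psi)
  ens <- traj_ensemble(bb_topology(20), co)
  d <- ctna:::backbone_dihedrals(ens)
  phi2 <- phi; psi2 <- psi
  phi2[-1, 1] <- d$phi[-1, 1]
  psi2[-20, 1] <- d$psi[-20, 1]
  co2 <- build_backbone(phi2, psi2)
  expect_lt(rmsd_superposed(co[, , 1], co2[, , 1]), 1e-3)
  ## bonded distances at the ideal values
  m <- co[, , 1]
  bond_len <- sqrt(rowSums((m[-1, ] - m[-nrow(m), ])^2))
  expect_lt(max(abs(bond_len - rep(c(1.458, 1.525, 1.329), 20)[1:59])), 1e-3)
})

test_that("realized macrostates drive the descriptors as designed", {
  pure_helix <- macrostate_spec(list(macrostate_pattern(42, "helix")),
                                matrix(1, 1, 1), n_frames = 40, seed = 72)
  ss_h <- project_trajectory(realize_trajectory(pure_helix))
  expect_true(all(ss_h$raw$Nalpha >= 30))

  hairpin <- macrostate_spec(list(macrostate_pattern(42, "hairpin")),
                             matrix(1, 1, 1), n_frames = 40, seed = 73)
  ss_p <- project_trajectory(realize_trajectory(hairpin))
  expect_true(all(ss_p$raw$Nbeta >= 8))

  coil <- macrostate_spec(list(macrostate_pattern(42, "coil")),
                          matrix(1, 1, 1), n_frames = 40, seed = 74)
  ss_c <- project_trajectory(realize_trajectory(coil))
  expect_true(all(ss_c$raw$Nalpha == 0 & ss_c$raw$Nbeta == 0))
  ## hairpin is compact relative to the extended coil (distributional)
  expect_lt(quantile(ss_p$raw$dNC, 0.95), quantile(ss_c$raw$dNC, 0.05))
  expect_lt(median(ss_p$raw$dNC) + 20, median(ss_c$raw$dNC))
})

test_that("trajectory realization is reproducible and collision-screened", {
  spec <- abeta_like_spec(n_frames = 25, seed = 75)
  e1 <- realize_trajectory(spec)
  e2 <- realize_trajectory(spec)
  expect_identical(e1$coords, e2$coords)
  expect_identical(attr(e1, "macrostates"), attr(e2, "macrostates"))
  ## no nonbonded pair below 1.5 Angstrom survives screening
  for (f in seq_len(n_frames(e1))) {
    D <- as.matrix(dist(e1$coords[, , f]))
    D[abs(row(D) - col(D)) <= 3] <- Inf
    expect_gt(min(D), 1.5)
  }
})

test_that("water generator spans the order spectrum with correct limits", {
  dl <- generate_water_configuration("diamond_lattice", n = 216)
  expect_equal(dl$n, 216)
  op <- orientational_order(dl$coords, dl$box)
  expect_true(all(abs(op$q - 1) < 1e-10))
  ## requested n is rounded to whole cells with a message
  expect_message(generate_water_configuration("diamond_lattice", n = 300),
                 "sites")
  ## increasing jitter strictly decreases mean tetrahedrality
  qs <- vapply(c(0, 0.15, 0.35, 0.7), function(sg) {
    w <- generate_water_configuration("perturbed_lattice", n = 216,
                                      jitter = sg, seed = 76)
    orientational_order(w$coords, w$box)$Q
  }, numeric(1))
  expect_true(all(diff(qs) < 0))
  ## ideal gas: Q near zero
  ig <- generate_water_configuration("ideal_gas", n = 3000, seed = 77)
  opi <- orientational_order(ig$coords, ig$box, centers = 1:2000)
  expect_lt(abs(opi$Q), 0.03)   # ~3 standard errors at 2000 centers
})

test_that("neighbor search for q uses all oxygens, not only vicinity members", {
  ## center at the origin surrounded by a tetrad; a vicinity that contains
  ## only the center must still find the four outside neighbors
  u <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  pts <- rbind(matrix(0, 1, 3), 2.8 * u, matrix(50, 3, 3))
  op <- orientational_order(pts, box = NULL, centers = 1)
  expect_equal(op$Q, 1, tolerance = 1e-10)
})

test_that("ideal-gas translational order converges to zero with averaging", {
  cfg1 <- generate_water_configuration("ideal_gas", n = 4000, density = 0.2,
                                       seed = 78)
  rdf1 <- compute_rdf(cfg1$coords, cfg1$box, bin_width = 0.2)
  T1 <- translational_order(rdf1)
  cfgs <- lapply(1:5, function(i)
    generate_water_configuration("ideal_gas", n = 4000, density = 0.2,
                                 seed = 78 + i)$coords)
  T5 <- translational_order(compute_rdf(cfgs, cfg1$box, bin_width = 0.2))
  expect_lt(T5, T1)      # averaging drives T toward the ideal-gas limit 0
  expect_lt(T5, 0.02)
})

test_that("renewal traces are seed-reproducible with the designed on-fraction", {
  tr1 <- generate_hbond_traces(n_bonds = 150, n_frames = 1500, seed = 79)
  tr2 <- generate_hbond_traces(n_bonds = 150, n_frames = 1500, seed = 79)
  expect_identical(tr1$h, tr2$h)
  ## renewal-reward: occupancy ~ E[on] / (E[on] + E[off])
  beta <- 0.5; tau <- 10; off <- 200
  tr <- generate_hbond_traces(n_bonds = 400, n_frames = 4000, dt = 0.5,
                              beta = beta, tau = tau, off_scale = off,
                              seed = 80)
  p_expected <- tau * gamma(1 + 1 / beta) / (tau * gamma(1 + 1 / beta) + off)
  expect_equal(mean(tr$h), p_expected, tolerance = 0.15)
})

test_that("ion placement respects the box, the shell and the overlap rule", {
  box <- c(20, 20, 20)
  ref <- rbind(c(10, 10, 10), c(5, 5, 5))
  iu <- generate_ion_system(ref, 500, "uniform", box = box, seed = 81)
  expect_true(all(iu >= 0 & iu <= 20))
  expect_gt(min(ctna:::cross_dist(iu, ref, box)), 1)
  ish <- generate_ion_system(ref, 500, "shell", box = box, r0 = 3,
                             width = 0.2, seed = 82)
  dmin <- apply(ctna:::cross_dist(ish, ref, box), 1, min)
  expect_true(all(dmin >= 3 - 0.11 & dmin <= 3 + 0.11))
  expect_error(generate_ion_system(ref, 10, "shell", box = box, r0 = 15),
               "half the box")
})
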