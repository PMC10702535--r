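# Sampling machinery: Metropolis criterion, move proposals, ensembles,
# determinism and energy bookkeeping.

test_that("Metropolis criterion handles the limit cases", {
  expect_true(metropolis_accept(-5))
  expect_true(metropolis_accept(0))
  expect_false(metropolis_accept(Inf))
  expect_error(metropolis_accept(NaN), "NaN")
})

test_that("Metropolis acceptance rate matches the Boltzmann factor", {
  # dU = kT ln 2 must be accepted half of the time
  du <- kT(298.15) * log(2)
  set.seed(31)
  acc <- mean(vapply(1:2e4, function(i) metropolis_accept(du),
                     logical(1)))
  # 3 sigma binomial band around 0.5
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 2e4))
})

test_that("runs are deterministic given the seed", {
  tpl <- build_caffeine_template(gamma = calibrated_defaults$gamma_geometry)
  set.seed(5)
  st <- mc_state(tpl, 60, n = 12)
  r1 <- run_mc(st, move_params(), quick_protocol(seed = 77,
                                                 widom_stride = 50))
  r2 <- run_mc(st, move_params(), quick_protocol(seed = 77,
                                                 widom_stride = 50))
  expect_identical(r1$state$positions, r2$state$positions)
  expect_identical(r1$energy, r2$energy)
  expect_identical(r1$widom_samples, r2$widom_samples)
  r3 <- run_mc(st, move_params(), quick_protocol(seed = 78))
  expect_false(identical(r1$state$positions, r3$state$positions))
})

test_that("zero production returns the initial state and empty traces", {
  tpl <- bead_template(2)
  set.seed(6)
  st <- mc_state(tpl, 50, n = 5)
  run <- run_mc(st, move_params(),
                run_protocol(equilibration = 0, production = 0,
                             rdf_stride = 10, widom_stride = 10, seed = 1))
  expect_equal(run$state$positions, st$positions, tolerance = 1e-12)
  expect_length(run$widom_samples, 0)
  expect_equal(run$rdf_frames, 0)
})

test_that("non-interacting systems accept every move", {
  set.seed(7)
  st <- generate_toy_system("ideal", n = 30, box_length = 50)
  run <- run_mc(st, move_params(), quick_protocol(seed = 2))
  acc <- run$acceptance
  expect_equal(acc$ratio[acc$move == "translate"], 1)
  # cluster moves can still be vetoed by the membership guard even
  # without interactions; every energetic decision is an accept
  expect_gt(acc$ratio[acc$move == "cluster"], 0.5)
})

test_that("single-molecule displacements respect the proposal bound", {
  tpl <- bead_template(2, wca_epsilon = 0)
  dmax <- 1.5
  set.seed(8)
  pos <- matrix(25, 1, 3)
  for (k in 1:100) {
    st <- mc_state(tpl, 50, positions = pos)
    run <- run_mc(st, move_params(translate = dmax, rotate = 0.3,
                                  w_cluster = 0),
                  run_protocol(equilibration = 0, production = 1,
                               seed = k))
    d <- run$state$positions[1, ] - pos[1, ]
    d <- d - 50 * round(d / 50)
    expect_lte(sqrt(sum(d^2)), dmax + 1e-12)
    pos <- run$state$positions
  }
})

test_that("sampled pair distribution obeys the Boltzmann weight at low density", {
  # dilute single-bead WCA+SASA fluid: g(r) ~ exp(-beta u(r))
  tpl <- bead_template(group_radius = 2, probe_radius = 1.4,
                       wca_epsilon = 0.5, gamma = 0.03)
  set.seed(9)
  st <- mc_state(tpl, 60, n = 25)
  run <- run_mc(st, move_params(translate = 5, w_cluster = 0),
                run_protocol(equilibration = 5e4, production = 1.5e6,
                             rdf_stride = 10, seed = 41))
  g <- rdf(run)
  pt <- pair_table(tpl)
  uofr <- function(r) wca_energy(pt$sigma[1, 1], pt$eps[1, 1], r) +
    sasa_pair_energy(r, pt$R[1], pt$R[1], pt$gamma[1, 1], 0, salt_field())
  sel <- g$r > 2 & g$r < 12
  gb <- exp(-uofr(g$r[sel]) / kT(298.15))
  expect_lt(mean(abs(g$g[sel] - gb)), 0.06)
  # repulsive core is empty
  expect_true(all(g$g[g$r < 3] < 1e-3))
})

test_that("adding cluster moves leaves the pair structure unchanged", {
  # the membership guard keeps the cluster move in detailed balance: the
  # equilibrium pair structure of an attractive dimer-forming system must
  # be the same with and without cluster moves in the move mix
  # (cluster-only sampling would not be ergodic across the threshold)
  tpl <- bead_template(group_radius = 2, probe_radius = 1.4,
                       wca_epsilon = 0.5, gamma = 0.05)
  set.seed(10)
  st <- mc_state(tpl, 35, n = 2)
  pr <- function(w_t, w_c, seed)
    run_mc(st, move_params(translate = 4, cluster_translate = 4,
                           cluster_threshold = 8,
                           w_translate = w_t, w_cluster = w_c),
           run_protocol(equilibration = 5e4, production = 1e6,
                        rdf_stride = 10, seed = seed))
  ga <- rdf(pr(1, 0, 51))
  gb <- rdf(pr(1, 2, 52))
  wa <- sum(ga$counts * ga$r) / sum(ga$counts)
  wb <- sum(gb$counts * gb$r) / sum(gb$counts)
  expect_lt(abs(wa - wb) / wa, 0.05)
})

test_that("a fully clustered system accepts every cluster move", {
  set.seed(11)
  st <- generate_toy_system("dimer", separation = 6, box_length = 60)
  run <- run_mc(st, move_params(w_translate = 0, w_cluster = 1,
                                cluster_threshold = 20),
                quick_protocol(seed = 3))
  acc <- run$acceptance
  expect_equal(acc$ratio[acc$move == "cluster"], 1)
  expect_equal(run$du_accum, 0, tolerance = 1e-9)
})

test_that("grand-canonical ideal gas reproduces the activity", {
  tpl <- bead_template(2, wca_epsilon = 0)
  set.seed(12)
  st <- mc_state(tpl, 60, n = 0, ensemble = "grand", activity = 0.05)
  run <- run_mc(st, move_params_gc(),
                run_protocol(equilibration = 1e5, production = 1e6,
                             density_stride = 200, seed = 13))
  d <- mean_density(run)
  expect_lt(abs(d$molar - 0.05), 3 * d$se)
  expect_lt(abs(d$molar - 0.05) / 0.05, 0.05)
})

test_that("grand-canonical density obeys the one-body Boltzmann factor", {
  tpl <- bead_template(2, wca_epsilon = 0, tfe = 1)
  salt <- salt_field(c_s = 1, eps_tfe = 0.005)
  u1 <- monomer_transfer_energy(tpl, salt)
  expect_gt(u1, 0)
  set.seed(13)
  st <- mc_state(tpl, 60, n = 0, salt = salt, ensemble = "grand",
                 activity = 0.05)
  run <- run_mc(st, move_params_gc(),
                run_protocol(equilibration = 1e5, production = 1e6,
                             density_stride = 200, seed = 14))
  d <- mean_density(run)
  expected <- 0.05 * exp(-u1 / kT(298.15))
  expect_lt(abs(d$molar - expected), 3 * d$se)
})

test_that("deletions at N = 0 are counted as rejected", {
  tpl <- bead_template(2, wca_epsilon = 0)
  set.seed(14)
  st <- mc_state(tpl, 60, n = 0, ensemble = "grand", activity = 1e-9)
  run <- run_mc(st, move_params_gc(),
                run_protocol(equilibration = 0, production = 2e4, seed = 15))
  acc <- run$acceptance
  del <- acc[acc$move == "delete", ]
  expect_gt(del$attempts, 0)
  expect_gte(nrow(run$state$positions), 0)
})

test_that("energy bookkeeping does not drift over a long run", {
  tpl <- build_caffeine_template(gamma = calibrated_defaults$gamma_geometry)
  set.seed(15)
  st <- mc_state(tpl, 60, n = 15, salt = salt_field(0.3, 0.01))
  run <- run_mc(st, move_params(),
                run_protocol(equilibration = 0, production = 5e5, seed = 16))
  expect_lt(abs(run$energy - run$energy_incremental), 1e-6)
})
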