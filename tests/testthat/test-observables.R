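# Estimators: RDF, KB integrals, preferential binding, pressure, Widom
# and grand-canonical excess chemical potentials.

test_that("block-averaged errors are sane for iid samples", {
  set.seed(21)
  x <- rnorm(4096)
  se <- block_se(x)
  expect_gt(se, 0.5 / sqrt(4096))
  expect_lt(se, 3 / sqrt(4096))
  expect_true(is.na(block_se(numeric(1))))
})

test_that("ideal-gas RDF is flat at unity", {
  set.seed(22)
  st <- generate_toy_system("ideal", n = 60, box_length = 50)
  run <- run_mc(st, move_params(translate = 10, w_cluster = 0),
                run_protocol(equilibration = 1e4, production = 5e5,
                             rdf_stride = 20, seed = 23))
  g <- rdf(run)
  sel <- g$r > 2   # skip near-empty innermost bins
  expect_lt(max(abs(g$g[sel] - 1)), 0.15)
  expect_lt(abs(mean(g$g[sel]) - 1), 0.01)
})

test_that("two fixed molecules populate a single RDF bin", {
  tpl <- bead_template(2, wca_epsilon = 0)
  st <- mc_state(tpl, 50, positions = rbind(c(10, 25, 25), c(17.3, 25, 25)))
  run <- run_mc(st, move_params(translate = 1e-9, rotate = 1e-9,
                                w_cluster = 0),
                run_protocol(equilibration = 0, production = 1e4,
                             rdf_stride = 10, seed = 24))
  g <- rdf(run)
  expect_equal(sum(g$counts > 0), 1)
  expect_equal(g$r[g$counts > 0], 7.375, tolerance = 0.26)
})

test_that("KB integral of closed-form RDFs is exact", {
  r <- seq(0.125, 25, by = 0.25)
  flat <- kb_integral(r, rep(1, length(r)), window = c(16, 20))
  expect_equal(flat$plateau, 0, tolerance = 1e-12)
  expect_true(all(abs(flat$G) < 1e-12))

  a <- 5
  step <- kb_integral(r, as.numeric(r >= a), window = c(16, 20))
  expect_equal(step$plateau, -4 / 3 * pi * a^3, tolerance = 0.02)

  expect_error(kb_integral(r[r < 15], rep(1, sum(r < 15))), "window")
  # estimator is linear in (g - 1)
  g2 <- 1 + 2 * (as.numeric(r >= a) - 1)
  lin <- kb_integral(r, g2, window = c(16, 20))
  expect_equal(lin$plateau, 2 * step$plateau, tolerance = 1e-12)
})

test_that("preferential binding arithmetic follows the definitions", {
  expect_equal(gamma23_from_kb(300, 300, 1e-3), 0)
  expect_equal(gamma23_from_kb(-200, 300, 1e-3), -0.5)
  r <- 1:10
  out <- gamma23_from_counts(r, N23 = rep(5, 10), N21 = rep(100, 10),
                             N3_0 = 20, N1_0 = 1000)
  expect_equal(out$gamma, rep(3, 10))
  expect_equal(out$plateau, 3)
  bulk <- gamma23_from_counts(r, N23 = 0.02 * (1:10), N21 = 1:10,
                              N3_0 = 2, N1_0 = 100)
  expect_equal(bulk$gamma, rep(0, 10))
  expect_error(gamma23_from_counts(r, 1:10, 1:10, 0, 10), "positive")
})

test_that("the two preferential-binding estimators agree on synthetic shells", {
  # shell amplitude and frame count sized so that Poisson noise on the
  # plateau sits well below the stated tolerances
  ens <- generate_shell_ensemble(n_frames = 2000, r_max = 30,
                                 amplitude = 3, seed = 31)
  sc <- shell_counts(ens)
  # route 1: KB integrals of the radial distribution functions
  G23 <- kb_integral(sc$r, sc$g3, window = c(16, 20))$plateau
  G21 <- kb_integral(sc$r, sc$g1, window = c(16, 20))$plateau
  gam_kb <- gamma23_from_kb(G23, G21, ens$rho3)
  # route 2: running coordination numbers
  gam_ct <- gamma23_from_counts(sc$r, sc$N23, sc$N21, sc$N3_0, sc$N1_0,
                                plateau_range = c(16, 20))$plateau
  # analytic ground truth of the generating profile
  truth <- ens$rho3 * ens$amplitude *
    integrate(function(r) exp(-(r - ens$r0)^2 / (2 * ens$width^2)) *
                4 * pi * r^2, 0, 30)$value
  expect_equal(gam_kb, gam_ct, tolerance = 0.1)
  expect_equal(gam_ct, truth, tolerance = 0.15)
  # depletion shells give negative binding
  dep <- generate_shell_ensemble(n_frames = 4000, amplitude = -0.9,
                                 seed = 32)
  sd_ <- shell_counts(dep)
  gam_dep <- gamma23_from_counts(sd_$r, sd_$N23, sd_$N21, sd_$N3_0,
                                 sd_$N1_0,
                                 plateau_range = c(16, 20))$plateau
  truth_dep <- -0.9 * truth / 3
  expect_lt(gam_dep, 0)
  expect_equal(gam_dep, truth_dep, tolerance = 0.3)
})

test_that("virtual-volume pressure vanishes for the ideal gas", {
  set.seed(25)
  st <- generate_toy_system("ideal", n = 60, box_length = 50)
  run <- run_mc(st, move_params(translate = 10, w_cluster = 0),
                run_protocol(equilibration = 1e4, production = 5e5,
                             pressure_stride = 10,
                             volume_perturbation = 5, seed = 26))
  pv <- virtual_volume_pressure(run)
  # the 5e-8 floor admits the O(dV/V) estimator bias
  expect_lt(abs(pv$p_ex), 3 * pv$se + 5e-8)
  expect_equal(pv$phi, 1, tolerance = 1e-3)
})

test_that("low-density WCA fluid matches second-virial predictions", {
  # one run checks three estimators against the numeric B2 oracle:
  # mu_ex ~ 2 B2 rho, p_ex ~ B2 rho^2 kT, and phi = 1 + B2 rho
  tpl <- bead_template(group_radius = 2, probe_radius = 1.4,
                       wca_epsilon = 0.5, gamma = 0)
  pt <- pair_table(tpl)
  b2 <- b2_virial(function(r) wca_energy(pt$sigma[1, 1], pt$eps[1, 1], r))
  expect_gt(b2, 0)  # repulsive particles
  n <- 40; L <- 55
  rho <- n / L^3
  set.seed(27)
  st <- mc_state(tpl, L, n = n)
  run <- run_mc(st, move_params(translate = 8, w_cluster = 0),
                run_protocol(equilibration = 5e4, production = 2e6,
                             widom_stride = 10, widom_inserts = 10,
                             pressure_stride = 20,
                             volume_perturbation = 10, seed = 28))
  w <- widom_mu_ex(run)
  expect_equal(w$mu_ex, 2 * b2 * rho, tolerance = 0.1)
  pv <- virtual_volume_pressure(run)
  expect_equal(pv$phi, 1 + b2 * rho, tolerance = 0.01)
  expect_equal(osmotic_coefficient(pv$p_ex, rho, 298.15), pv$phi,
               tolerance = 1e-6)
})

test_that("attractive systems have negative excess pressure", {
  tpl <- build_caffeine_template(gamma = calibrated_defaults$gamma_geometry)
  set.seed(28)
  st <- mc_state(tpl, 80, n = 30)
  run <- run_mc(st, move_params(),
                run_protocol(equilibration = 1e5, production = 1e6,
                             pressure_stride = 20,
                             volume_perturbation = 50, seed = 29))
  pv <- virtual_volume_pressure(run)
  expect_lt(pv$p_ex, 0)
  expect_lt(pv$phi, 1)
})

test_that("osmotic coefficient arithmetic follows the definition", {
  expect_equal(osmotic_coefficient(0, 1e-4, 300), 1)
  p_id <- 1e-4 * kT(300)
  expect_equal(osmotic_coefficient(-0.3 * p_id, 1e-4, 300), 0.7)
})

test_that("Widom sampling is exact for ideal and one-body systems", {
  set.seed(29)
  st <- generate_toy_system("ideal", n = 20, box_length = 50)
  run <- run_mc(st, move_params(translate = 10, w_cluster = 0),
                run_protocol(equilibration = 0, production = 1e5,
                             widom_stride = 10, seed = 30))
  expect_equal(widom_mu_ex(run)$mu_ex, 0)

  # constant insertion energy: mu_ex = beta u1 exactly
  tpl <- bead_template(2, wca_epsilon = 0, tfe = 1)
  salt <- salt_field(c_s = 0.8, eps_tfe = 0.01)
  u1 <- monomer_transfer_energy(tpl, salt)
  # no molecules present: every insertion costs exactly u1
  st2 <- mc_state(tpl, 50, n = 0, salt = salt)
  run2 <- run_mc(st2, move_params(translate = 10, w_cluster = 0),
                 run_protocol(equilibration = 0, production = 2e4,
                              widom_stride = 10, seed = 31))
  expect_equal(widom_mu_ex(run2)$mu_ex, u1 / kT(298.15),
               tolerance = 1e-10)
})

test_that("GC density difference equals the Widom difference", {
  # delta mu_ex = ln(rho_wat/rho_salt) from two GC runs must agree with
  # the Widom route at the matched state points (one-body salt field)
  tpl <- bead_template(2.2, wca_epsilon = 0.5, tfe = 1)
  salt <- salt_field(c_s = 1, eps_tfe = 0.004)
  act <- 0.04
  gc <- function(s, seed) {
    set.seed(seed)
    st <- mc_state(tpl, 55, n = 0, salt = s, ensemble = "grand",
                   activity = act)
    run_mc(st, move_params_gc(),
           run_protocol(equilibration = 2e5, production = 1.5e6,
                        density_stride = 300, widom_stride = 50,
                        seed = seed))
  }
  r_wat <- gc(salt_field(), 61)
  r_salt <- gc(salt, 62)
  d_wat <- mean_density(r_wat); d_salt <- mean_density(r_salt)
  dmu_gc <- delta_mu_ex_gc(d_wat$molar, d_salt$molar)
  w_wat <- widom_mu_ex(r_wat); w_salt <- widom_mu_ex(r_salt)
  dmu_widom <- w_salt$mu_ex - w_wat$mu_ex
  se <- sqrt(d_wat$se^2 / d_wat$molar^2 + d_salt$se^2 / d_salt$molar^2 +
               w_wat$se^2 + w_salt$se^2)
  expect_lt(abs(dmu_gc - dmu_widom), 3 * se + 0.02)
  expect_error(delta_mu_ex_gc(0, 1), "positive")
  expect_equal(delta_mu_ex_gc(0.069, 0.0345), log(2))
  expect_equal(delta_mu_ex_gc(3, 3), 0)
})
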