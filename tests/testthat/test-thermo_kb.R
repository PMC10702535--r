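# Ternary activity models, Gibbs-Duhem consistency, Kirkwood-Buff
# inversion and the excess-chemical-potential fit.

# printed coefficient sets for the two salt archetypes
model_out <- activity_model(A2 = -7.2399, B2 = 24.9741, C1 = 0.8061,
                            C2 = -8.0176, A3 = -0.3506, B3 = 0.2087,
                            nu3 = 3, V3 = 16.62)
model_in <- activity_model(A2 = -7.2399, B2 = 24.9741, C1 = -1.1145,
                           C2 = 6.1971, A3 = -0.6216, B3 = 0.4754,
                           nu3 = 2, V3 = 40.96)

test_that("solute activity coefficient reproduces printed arithmetic", {
  expect_equal(ln_gamma2(0, 0, model_out), 0)
  # A2 * 0.05 + B2 * 0.0025 at the salt-free boundary
  expect_equal(ln_gamma2(0.05, 0, model_out), -0.29955975,
               tolerance = 1e-10)
  # the salting-out constant is the salt derivative of ln gamma_2
  m2 <- 0.05
  h <- 1e-6
  dnum <- (ln_gamma2(m2, h, model_out) - ln_gamma2(m2, 0, model_out)) / h
  expect_equal(dnum, ks_model(m2, model_out), tolerance = 1e-6)
  # printed sodium-sulfate row: 3.84 - 28.59 * 0.05 = 2.41
  tab2 <- activity_model(C1 = 3.84, C2 = -28.59)
  expect_equal(ks_model(0.05, tab2), 2.4105, tolerance = 1e-12)
})

test_that("salt activity model has the right limits and derivative", {
  expect_equal(ln_gamma3(0, model_out), 0)
  ideal <- activity_model(nu3 = 3)
  expect_equal(ln_gamma3(0.3, ideal), 0)
  expect_equal(salt_nonideality(0.25, ideal), 1)
  # nonideality factor equals 1 + d ln gamma3 / d ln m3 numerically
  m3 <- 0.3; h <- 1e-6
  d <- (ln_gamma3(m3 + h, model_out) - ln_gamma3(m3 - h, model_out)) /
    (2 * h)
  expect_equal(salt_nonideality(m3, model_out), 1 + m3 * d,
               tolerance = 1e-6)
})

test_that("water activity reduces to the ideal Gibbs-Duhem limit", {
  ideal <- activity_model(nu3 = 3)
  expect_equal(ln_a1(0, 0, ideal), 0)
  expect_equal(ln_a1(0.05, 0.1, ideal),
               -sasa_constants$M1_water * 0.35, tolerance = 1e-12)
})

test_that("Gibbs-Duhem residual vanishes along random composition paths", {
  set.seed(41)
  for (k in 1:5) {
    mod <- activity_model(A2 = rnorm(1, 0, 5), B2 = rnorm(1, 0, 20),
                          C1 = rnorm(1), C2 = rnorm(1, 0, 10),
                          A3 = rnorm(1, 0, 0.5), B3 = rnorm(1, 0, 0.5),
                          nu3 = sample(2:3, 1))
    # path (m2(t), m3(t)); check m1 d(mu1) + m2 d(mu2) + nu3 m3 d(mu3) = 0
    t <- runif(1, 0.2, 0.8)
    m2 <- 0.02 + 0.03 * t; m3 <- 0.4 * t + 0.05
    dm2 <- 0.03; dm3 <- 0.4
    h <- 1e-6
    num <- function(f) (f(m2 + h * dm2, m3 + h * dm3) -
                          f(m2 - h * dm2, m3 - h * dm3)) / (2 * h)
    dmu1 <- num(function(a, b) ln_a1(a, b, mod))
    dmu2 <- num(function(a, b) log(a) + ln_gamma2(a, b, mod))
    dmu3 <- num(function(a, b) log(b) + ln_gamma3(b, mod, m2 = a))
    resid <- dmu1 / mod$M1 + m2 * dmu2 + mod$nu3 * m3 * dmu3
    expect_lt(abs(resid), 1e-6 * max(abs(c(dmu2 * m2, 1))))
  }
})

test_that("activity derivative matrix matches finite differences", {
  set.seed(42)
  for (mod in list(model_out, model_in)) {
    m2 <- runif(1, 0.01, 0.05); m3 <- runif(1, 0.05, 0.5)
    mu <- activity_derivative_matrix(m2, m3, mod)
    h <- 1e-7
    d22 <- (log(m2 + h) + ln_gamma2(m2 + h, m3, mod) -
              log(m2 - h) - ln_gamma2(m2 - h, m3, mod)) / (2 * h)
    d23 <- (ln_gamma2(m2, m3 + h, mod) -
              ln_gamma2(m2, m3 - h, mod)) / (2 * h)
    d33 <- mod$nu3 *
      (log(m3 + h) + ln_gamma3(m3 + h, mod, m2) -
         log(m3 - h) - ln_gamma3(m3 - h, mod, m2)) / (2 * h)
    expect_equal(mu["solute", "solute"], d22, tolerance = 1e-5)
    expect_equal(mu["solute", "salt"], d23, tolerance = 1e-5)
    expect_equal(mu["salt", "salt"], d33, tolerance = 1e-5)
    # cross-Maxwell symmetry
    expect_equal(mu["solute", "salt"], mu["salt", "solute"],
                 tolerance = 1e-12)
  }
})

test_that("forward KB map reproduces ideal-gas closed forms", {
  rho <- c(0.03, 1e-4, 3e-4)
  fw <- kb_forward(matrix(0, 3, 3), rho)
  expect_equal(fw$kt_kappa, 1 / sum(rho), tolerance = 1e-12)
  expect_equal(fw$Vbar_A3, rep(1 / sum(rho), 3), tolerance = 1e-12)
  # d(beta mu_2)/d m2 = rho1 M1 (1/rho2 - 1/sum(rho))
  M1 <- sasa_constants$M1_water
  expect_equal(fw$mu[2, 2], rho[1] * M1 * (1 / rho[2] - 1 / sum(rho)),
               tolerance = 1e-10)
})

test_that("KB inversion round-trips the thermodynamic inputs", {
  for (mod in list(model_out, model_in)) {
    kb <- kb_invert(0.02, 0.2, mod)
    expect_lt(kb$residual, 1e-8)
    expect_equal(kb$G, t(kb$G), tolerance = 1e-9)
    fw <- kb_forward(kb$G, kb$rho_num)
    mu <- activity_derivative_matrix(0.02, 0.2, mod)
    expect_equal(fw$mu[2, 2], mu["solute", "solute"], tolerance = 1e-8)
    expect_equal(fw$mu[2, 3], mu["solute", "salt"], tolerance = 1e-8)
    expect_equal(fw$mu[3, 3], mu["salt", "salt"], tolerance = 1e-8)
    expect_equal(fw$Vbar_cm3[2], mod$V2, tolerance = 1e-8)
    expect_equal(fw$Vbar_cm3[3], mod$V3, tolerance = 1e-8)
    # N_ij / rho_j = N_ji / rho_i by construction of symmetric G
    expect_equal(kb$N[1, 2] / kb$rho_num[2], kb$N[2, 1] / kb$rho_num[1],
                 tolerance = 1e-9)
  }
})

test_that("KB surfaces are finite and smooth over the printed grid", {
  grid <- kb_invert_grid(c(0.01, 0.03, 0.05), c(0.1, 0.3, 0.5), model_out)
  expect_true(all(is.finite(grid$G_A3)))
  g22 <- grid[grid$i == "solute" & grid$j == "solute", ]
  # smooth: the solute-solute surface varies gradually along m3
  for (m2v in unique(g22$m2)) {
    s <- g22[g22$m2 == m2v, ]
    expect_lt(max(abs(diff(s$G_A3))) / max(abs(s$G_A3)), 1)
  }
})

test_that("near infinite dilution G12 approaches kT kappa - V2", {
  mod <- activity_model(nu3 = 2)  # ideal-solution coefficients
  kb <- kb_invert(1e-4, 1e-4, mod)
  ktk <- kb$kt_kappa
  V2 <- mod$V2 * 1e24 / sasa_constants$N_av
  expect_equal(kb$G["water", "solute"], ktk - V2, tolerance = 0.02)
})

test_that("activity-model fit recovers generating coefficients", {
  gen <- model_out
  grid <- expand.grid(m2 = seq(0.005, 0.05, by = 0.005),
                      m3 = c(0, 0.1, 0.25, 0.5))
  grid$mu_ex <- ln_gamma2(grid$m2, grid$m3, gen)
  fit <- fit_activity_model(grid, nu3 = 3)
  expect_equal(unname(coef(fit)), c(gen$A2, gen$B2, gen$C1, gen$C2),
               tolerance = 1e-8)

  # noisy recovery stays within two fitted standard errors (most of the
  # time; checked over replicates)
  set.seed(43)
  hits <- replicate(100, {
    g <- grid
    g$mu_ex <- g$mu_ex + rnorm(nrow(g), 0, 0.01)
    g$se <- 0.01
    f <- fit_activity_model(g, nu3 = 3)
    abs(coef(f) - c(gen$A2, gen$B2, gen$C1, gen$C2)) <= 2 * f$se
  })
  # per-coefficient 2-sigma coverage: near nominal for the binary
  # coefficients; the interaction coefficients run lower because the
  # two-stage scheme freezes (A2, B2) and does not propagate their
  # uncertainty into stage two
  cov <- rowMeans(hits)
  expect_true(all(cov[c("A2", "B2")] > 0.85))
  expect_true(all(cov[c("C1", "C2")] > 0.70))
  expect_error(fit_activity_model(grid[grid$m3 > 0, ]), "salt-free")
})

test_that("salting-out constant from preferential binding is consistent", {
  expect_equal(ks_from_gamma23(0, 0.2, activity_model(nu3 = 2)), 0)
  # ideal salt reduces to the plain proportionality
  expect_equal(ks_from_gamma23(-0.05, 0.25, activity_model(nu3 = 2)),
               0.05 / 0.25)
  # round trip through KB inversion: the preferential-binding relation
  # recovers C1 + C2 m2 in the low-concentration regime
  for (mod in list(model_out, model_in)) {
    m2 <- 0.005; m3 <- 0.05
    kb <- kb_invert(m2, m3, mod)
    rho3_ion <- mod$nu3 * kb$rho_num[3]
    gam <- gamma23_from_kb(kb$G["solute", "salt"],
                           kb$G["solute", "water"], rho3_ion)
    ks <- ks_from_gamma23(gam, m3, mod)
    expect_equal(ks, ks_model(m2, mod), tolerance = 0.1)
    # sign contract: depletion means salting-out and vice versa
    expect_equal(sign(-gam), sign(ks))
  }
  # the zero-salt limit from KB integrals directly
  mod <- model_out
  kb <- kb_invert(0.005, 0.02, mod)
  ks0 <- ks_from_gamma23(m3 = 0, model = mod,
                         G23 = kb$G["solute", "salt"],
                         G21 = kb$G["solute", "water"])
  expect_equal(ks0, ks_model(0.005, mod), tolerance = 0.15)
})
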