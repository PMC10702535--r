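# Independent oracles and small fixtures used across the suite.

# Monte-Carlo surface-point estimate of the total exposed area of two
# spheres: uniform points on each sphere, excluding points inside the
# other sphere.  Independent of the analytic lens formula.
mc_area_oracle <- function(R, r, d, n = 1e6) {
  one <- function(Ra, ca, Rb, cb) {
    p <- matrix(stats::rnorm(3 * n), n, 3)
    p <- p / sqrt(rowSums(p^2)) * Ra
    p[, 1] <- p[, 1] + ca
    keep <- (p[, 1] - cb)^2 + p[, 2]^2 + p[, 3]^2 >= Rb^2
    mean(keep) * 4 * pi * Ra^2
  }
  one(R, 0, r, d) + one(r, d, R, 0)
}

# brute-force O(N^2) total energy in plain R: WCA + shifted SASA pair
# terms under the molecule-based minimum image, plus N one-body terms.
# Independent re-implementation of the compiled engine's energy.
r_system_energy <- function(state) {
  tpl <- state$template
  salt <- state$salt
  L <- state$box_length
  n <- nrow(state$positions)
  pt <- pair_table(tpl)
  beads <- lapply(seq_len(n), function(i) {
    R <- sasamc:::quat_to_matrix(state$quaternions[i, ])
    sasamc:::template_coords(tpl) %*% t(R)
  })
  u <- n * monomer_transfer_energy(tpl, salt)
  nb <- nrow(tpl$beads)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      dcom <- state$positions[j, ] - state$positions[i, ]
      dcom <- dcom - L * round(dcom / L)
      for (a in seq_len(nb)) {
        for (b in seq_len(nb)) {
          dv <- beads[[j]][b, ] + dcom - beads[[i]][a, ]
          rij <- sqrt(sum(dv^2))
          u <- u + wca_energy(pt$sigma[a, b], pt$eps[a, b], rij) +
            sasa_pair_energy(rij, pt$R[a], pt$R[b], pt$gamma[a, b],
                             pt$tfe[a, b], salt)
        }
      }
    }
  }
  u
}

# numeric second virial coefficient of a spherically symmetric pair
# potential u(r), A^3
b2_virial <- function(ufun, temperature = 298.15, upper = 30) {
  beta <- 1 / sasamc::kT(temperature)
  -0.5 * stats::integrate(function(r) (exp(-beta * ufun(r)) - 1) *
                            4 * pi * r^2,
                          lower = 0, upper = upper,
                          subdivisions = 2000, rel.tol = 1e-9)$value
}

# short-hand protocols for quick engine runs in tests
quick_protocol <- function(..., seed = 1) {
  run_protocol(equilibration = 2e4, production = 2e5, seed = seed, ...)
}
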