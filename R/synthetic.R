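# Seeded synthetic-data generators that make every analysis layer
# testable without external downloads, plus small toy systems for the
# sampling property suites.

# run a block of code with a private RNG stream, restoring the caller's
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic osmometry table
#'
#' Emulates the structure of a ternary osmometry data set: two binary
#' curves (polynomials through the ideal leading terms) plus the
#' interaction surface \code{(C1 + C2 m2) m2 m3}, with optional Gaussian
#' noise.  Deterministic for a given seed.
#'
#' @param C1,C2 solute-salt interaction coefficients (1/molal, 1/molal^2)
#' @param b2 solute binary curvature coefficients \code{c(quadratic,
#'   cubic)}: \code{Osm(m2, 0) = m2 + b2[1] m2^2 + b2[2] m2^3}
#' @param b3 salt binary curvature coefficients:
#'   \code{Osm(0, m3) = nu3 m3 + b3[1] m3^2 + b3[2] m3^3}
#' @param nu3 ions per salt formula unit
#' @param m2_grid solute molalities, mol/kg (experimental-style window)
#' @param m3_grid salt molalities, mol/kg
#' @param sigma Gaussian noise standard deviation, mol/kg
#' @param seed RNG seed
#' @param label salt label
#' @return an \code{\link{osm_table}} with binary and ternary rows
#' @export
generate_synthetic_osm_table <- function(C1, C2, b2 = c(0, 0),
                                         b3 = c(0, 0), nu3 = 2,
                                         m2_grid = c(0.010, 0.025, 0.050,
                                                     0.075),
                                         m3_grid = seq(0.1, 0.5, by = 0.1),
                                         sigma = 0, seed = 1,
                                         label = "synthetic") {
  stopifnot(sigma >= 0)
  osm2 <- function(m2) m2 + b2[1] * m2^2 + b2[2] * m2^3
  osm3 <- function(m3) nu3 * m3 + b3[1] * m3^2 + b3[2] * m3^3
  grid <- rbind(data.frame(m2 = m2_grid, m3 = 0),
                data.frame(m2 = 0, m3 = m3_grid),
                expand.grid(m2 = m2_grid, m3 = m3_grid))
  osm <- osm2(grid$m2) + osm3(grid$m3) +
    (C1 + C2 * grid$m2) * grid$m2 * grid$m3
  if (sigma > 0)
    osm <- with_seed(seed, osm + stats::rnorm(length(osm), 0, sigma))
  osm_table(grid$m2, grid$m3, pmax(osm, 0),
            stderr = max(sigma, 1e-12), label = label)
}

#' Single-bead molecule template
#'
#' Minimal template for toy systems and estimator cross-checks.
#'
#' @param group_radius physical bead radius, A
#' @param probe_radius probe radius added for the SASA radius, A
#' @param wca_epsilon WCA well depth, kJ/mol (0 disables repulsion)
#' @param gamma surface tension, kJ/mol/A^2 (0 disables the SASA term)
#' @param tfe TFE site weight
#' @return a \code{mol_template} with one bead
#' @export
bead_template <- function(group_radius = 2, probe_radius = 1.4,
                          wca_epsilon = 0.5, gamma = 0, tfe = 0) {
  beads <- data.frame(name = "B", x = 0, y = 0, z = 0,
                      group_radius = group_radius,
                      sasa_radius = group_radius + probe_radius,
                      wca_sigma = 2 * group_radius,
                      wca_epsilon = wca_epsilon,
                      gamma = gamma, tfe = tfe,
                      stringsAsFactors = FALSE)
  tpl <- structure(list(beads = beads, probe_radius = probe_radius),
                   class = "mol_template")
  tpl$reference_areas <- reference_areas(tpl)
  tpl$monomer_sasa <- sum(tpl$reference_areas)
  tpl
}

#' Generate a toy simulation state
#'
#' Reproducible fixtures for the sampling property suites: an ideal
#' (non-interacting) gas, a WCA-only fluid, or a two-molecule dimer at a
#' prescribed separation.
#'
#' @param kind \code{"ideal"}, \code{"wca"} or \code{"dimer"}
#' @param n number of molecules (ideal/wca)
#' @param box_length cubic box edge, A
#' @param separation dimer COM separation, A
#' @param group_radius bead radius of the toy particle, A
#' @param temperature temperature, K
#' @param seed RNG seed for the placement
#' @param ... further arguments to \code{\link{mc_state}}
#' @return an \code{mc_state}
#' @export
generate_toy_system <- function(kind = c("ideal", "wca", "dimer"),
                                n = 100, box_length = 100, separation = 5,
                                group_radius = 2, temperature = 298.15,
                                seed = 1, ...) {
  kind <- match.arg(kind)
  with_seed(seed, switch(
    kind,
    ideal = {
      tpl <- bead_template(group_radius, wca_epsilon = 0)
      pos <- matrix(stats::runif(3 * n, 0, box_length), n, 3)
      mc_state(tpl, box_length, positions = pos,
               temperature = temperature, ...)
    },
    wca = {
      tpl <- bead_template(group_radius, wca_epsilon = 0.5)
      mc_state(tpl, box_length, n = n, temperature = temperature, ...)
    },
    dimer = {
      tpl <- build_caffeine_template()
      c0 <- box_length / 2
      pos <- rbind(c(c0 - separation / 2, c0, c0),
                   c(c0 + separation / 2, c0, c0))
      mc_state(tpl, box_length, positions = pos,
               temperature = temperature, ...)
    }))
}

#' Generate a synthetic solvation-shell ensemble
#'
#' Poisson-sampled radial configurations of cosolute ions and water
#' around a solute fixed at the origin: water at uniform bulk density,
#' ions with a Gaussian enrichment (or depletion) shell on top of their
#' bulk density.  Used to cross-validate the two preferential-binding
#' estimators against a known ground truth.
#'
#' @param n_frames number of statistically independent frames
#' @param r_max radial extent of the sampled sphere, A
#' @param rho3 bulk ion number density, 1/A^3
#' @param rho1 bulk water number density, 1/A^3
#' @param amplitude relative amplitude of the ion shell (negative for
#'   depletion)
#' @param r0 shell center, A
#' @param width shell Gaussian width, A
#' @param seed RNG seed
#' @return object of class \code{shell_ensemble} with pooled radial
#'   distances and the generating parameters
#' @export
generate_shell_ensemble <- function(n_frames = 200, r_max = 30,
                                    rho3 = 5e-4, rho1 = 0.033,
                                    amplitude = 0.8, r0 = 6, width = 1.5,
                                    seed = 1) {
  stopifnot(r_max > 0, rho3 > 0, rho1 > 0, amplitude > -1)
  dr <- 0.1
  edges <- seq(0, r_max, by = dr)
  mid <- edges[-1] - dr / 2
  shellV <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  prof3 <- rho3 * (1 + amplitude * exp(-(mid - r0)^2 / (2 * width^2)))
  with_seed(seed, {
    n3 <- stats::rpois(length(mid), n_frames * prof3 * shellV)
    n1 <- stats::rpois(length(mid), n_frames * rho1 * shellV)
    samp <- function(counts) {
      u <- stats::runif(sum(counts))
      lo <- rep(edges[-length(edges)], counts)
      hi <- rep(edges[-1], counts)
      (lo^3 + u * (hi^3 - lo^3))^(1 / 3)
    }
    structure(list(dist3 = samp(n3), dist1 = samp(n1),
                   n_frames = n_frames, r_max = r_max,
                   rho3 = rho3, rho1 = rho1, amplitude = amplitude,
                   r0 = r0, width = width),
              class = "shell_ensemble")
  })
}

#' Radial estimator inputs from a shell ensemble
#'
#' Per-frame averaged radial distribution functions and running
#' coordination numbers of ions and water around the solute, the inputs
#' of the two preferential-binding estimators.
#'
#' @param ensemble a \code{shell_ensemble}
#' @param dr histogram bin width, A
#' @param totals \code{"bulk"} derives the total particle numbers from
#'   the bulk densities (the sampled sphere is a window into a much
#'   larger system, so the bulk ratio is the correct reference);
#'   \code{"sampled"} uses the in-window counts, which carry a
#'   finite-size bias of order \code{Gamma / N3_0}
#' @return list with \code{r}, \code{g3}, \code{g1}, running counts
#'   \code{N23}, \code{N21}, and totals \code{N3_0}, \code{N1_0}
#' @export
shell_counts <- function(ensemble, dr = 0.25,
                         totals = c("bulk", "sampled")) {
  totals <- match.arg(totals)
  stopifnot(inherits(ensemble, "shell_ensemble"))
  edges <- seq(0, ensemble$r_max, by = dr)
  mid <- edges[-1] - dr / 2
  shellV <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  h3 <- graphics::hist(ensemble$dist3, breaks = edges, plot = FALSE)$counts /
    ensemble$n_frames
  h1 <- graphics::hist(ensemble$dist1, breaks = edges, plot = FALSE)$counts /
    ensemble$n_frames
  V <- 4 / 3 * pi * ensemble$r_max^3
  if (totals == "bulk") {
    n3_0 <- ensemble$rho3 * V
    n1_0 <- ensemble$rho1 * V
  } else {
    n3_0 <- length(ensemble$dist3) / ensemble$n_frames
    n1_0 <- length(ensemble$dist1) / ensemble$n_frames
  }
  list(r = mid,
       g3 = h3 / (shellV * ensemble$rho3),
       g1 = h1 / (shellV * ensemble$rho1),
       N23 = cumsum(h3), N21 = cumsum(h1),
       N3_0 = n3_0, N1_0 = n1_0)
}
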