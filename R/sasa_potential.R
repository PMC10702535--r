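# Energy model: two-sphere overlap area, SASA pair potential with
# transfer-free-energy scaling, WCA repulsion and the one-body transfer
# term for grand-canonical sampling.

#' Salt (cosolute) field descriptor
#'
#' Only the product \code{eps_tfe * c_s} enters pair and one-body
#' energies, so a salt is described by its molar concentration and a
#' salt-specific TFE coefficient.  Positive \code{eps_tfe} strengthens
#' bead-bead attraction with concentration (salting-out); negative values
#' weaken it (salting-in).
#'
#' @param c_s molar concentration of the added cosolute, mol/L
#' @param eps_tfe salt-specific transfer-free-energy coefficient,
#'   kJ/mol/A^2/M, applied to beads in proportion to their TFE site weight
#' @return object of class \code{salt_field}
#' @export
salt_field <- function(c_s = 0, eps_tfe = 0) {
  stopifnot(is.numeric(c_s), length(c_s) == 1, c_s >= 0,
            is.numeric(eps_tfe), length(eps_tfe) == 1, is.finite(eps_tfe))
  structure(list(c_s = c_s, eps_tfe = eps_tfe), class = "salt_field")
}

#' Total exposed surface area of two spheres
#'
#' For center separation \code{d} between spheres of radii \code{R} and
#' \code{r}: the two full sphere areas when separated, the two areas
#' minus the lens caps when overlapping, and the larger sphere's area
#' when one sphere is engulfed (continuity clamp).  Vectorized over
#' \code{d}.
#'
#' @param R,r sphere radii, Angstrom (order irrelevant)
#' @param d center-to-center separation, Angstrom
#' @return total exposed area, A^2
#' @export
two_sphere_area <- function(R, r, d) {
  if (any(R <= 0) || any(r <= 0)) stop("sphere radii must be positive")
  if (any(d < 0)) stop("separation must be non-negative")
  Rb <- pmax(R, r); rs <- pmin(R, r)
  full <- 4 * pi * (Rb^2 + rs^2)
  out <- ifelse(d >= Rb + rs, full,
         ifelse(d <= Rb - rs, 4 * pi * Rb^2, {
           h1 <- (rs - Rb + d) * (rs + Rb - d) / (2 * d)  # cap on sphere R
           h2 <- (Rb - rs + d) * (Rb + rs - d) / (2 * d)  # cap on sphere r
           full - 2 * pi * (Rb * h1 + rs * h2)
         }))
  out
}

#' Weeks-Chandler-Andersen repulsive energy
#'
#' Lennard-Jones potential truncated at its minimum \code{2^(1/6) sigma}
#' and shifted to zero; purely repulsive and continuous at the cutoff.
#' Vectorized over \code{rij}.
#'
#' @param sigma LJ diameter, Angstrom
#' @param eps LJ well depth, kJ/mol
#' @param rij separation, Angstrom; \code{rij = 0} gives \code{Inf}
#' @return energy in kJ/mol
#' @export
wca_energy <- function(sigma, eps, rij) {
  stopifnot(all(sigma > 0), all(eps >= 0), all(rij >= 0))
  if (all(eps == 0)) return(rep(0, length(rij)))
  rc <- 2^(1 / 6) * sigma
  ifelse(rij == 0, Inf,
         ifelse(rij >= rc, 0, {
           sr6 <- (sigma / pmax(rij, 1e-300))^6
           4 * eps * (sr6^2 - sr6) + eps
         }))
}

#' SASA pair energy between two beads
#'
#' \code{(gamma_ij + eps_ij_tfe * c_s) * [A(d) - A(contact)]}: the change
#' of the two-sphere exposed area relative to non-overlapping separation,
#' weighted by the effective surface tension.  Exactly zero for
#' \code{d >= Ri + Rj}; negative (attractive) for overlapping beads when
#' the prefactor is positive.
#'
#' @param d separation, Angstrom (vectorized)
#' @param Ri,Rj SASA radii of the two beads, Angstrom
#' @param gamma_ij pair surface tension (arithmetic mean), kJ/mol/A^2
#' @param tfe_ij pair TFE site weight (arithmetic mean), dimensionless
#' @param salt a \code{\link{salt_field}}
#' @return energy in kJ/mol
#' @export
sasa_pair_energy <- function(d, Ri, Rj, gamma_ij, tfe_ij = 0,
                             salt = salt_field()) {
  pref <- gamma_ij + tfe_ij * salt$eps_tfe * salt$c_s
  pref * (two_sphere_area(Ri, Rj, d) - 4 * pi * (Ri^2 + Rj^2))
}

#' Pair interaction table for a template
#'
#' Precomputes, for every bead-type pair, the Lorentz mixing diameter,
#' the WCA well depth, the arithmetic-mean surface tension and TFE site
#' weight, and the SASA contact distance \code{Ri + Rj}.
#'
#' @param template a \code{mol_template}
#' @return list of nb x nb matrices \code{sigma}, \code{eps},
#'   \code{gamma}, \code{tfe}, \code{contact} plus per-bead radii
#' @export
pair_table <- function(template) {
  b <- template$beads
  list(sigma   = outer(b$wca_sigma, b$wca_sigma, function(a, b) (a + b) / 2),
       eps     = outer(b$wca_epsilon, b$wca_epsilon, function(a, b) (a + b) / 2),
       gamma   = outer(b$gamma, b$gamma, function(a, b) (a + b) / 2),
       tfe     = outer(b$tfe, b$tfe, function(a, b) (a + b) / 2),
       contact = outer(b$sasa_radius, b$sasa_radius, "+"),
       R       = b$sasa_radius)
}

#' One-body transfer energy of an isolated molecule
#'
#' Excess free energy of transferring a single molecule from pure water
#' into the cosolute solution: \code{c_s * sum_i eps_i_tfe * A_i_ref}.
#' Pose independent; linear in the cosolute concentration.  It matters
#' for grand-canonical sampling and Widom insertions; in canonical
#' averages it is an additive constant.
#'
#' @param template a \code{mol_template}
#' @param salt a \code{\link{salt_field}}
#' @return energy in kJ/mol
#' @export
monomer_transfer_energy <- function(template, salt) {
  salt$c_s * salt$eps_tfe * sum(template$beads$tfe * template$reference_areas)
}

#' Total potential energy of a system state
#'
#' Sum of WCA plus shifted SASA pair terms over all intermolecular bead
#' pairs under the molecule-based minimum-image convention, plus
#' \code{N} times the one-body transfer energy.  Intramolecular pairs are
#' excluded (the template is rigid).  Computed by the compiled engine;
#' an independent R double loop used in the test-suite serves as oracle.
#'
#' @param state an \code{mc_state}
#' @return energy in kJ/mol (\code{Inf} for hard overlaps, never NaN)
#' @export
system_energy <- function(state) {
  n <- nrow(state$positions)
  u1 <- monomer_transfer_energy(state$template, state$salt)
  if (n == 0) return(0)
  if (n == 1) return(u1)
  cpp <- template_cpp_pack(state$template, state$salt)
  total_energy_cpp(cpp, t(state$positions),
                   quats_to_rot9(state$quaternions),
                   state$box_length) + n * u1
}

# flatten template + salt into the plain-list layout the C++ engine expects
template_cpp_pack <- function(template, salt) {
  pt <- pair_table(template)
  list(body    = t(template_coords(template)),
       sigma   = pt$sigma,
       eps     = pt$eps,
       pref    = pt$gamma + pt$tfe * salt$eps_tfe * salt$c_s,
       contact = pt$contact)
}
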