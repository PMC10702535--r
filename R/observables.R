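# Estimators over sampled configurations: radial distribution functions,
# Kirkwood-Buff integrals, preferential binding, virtual-volume pressure,
# osmotic coefficient, Widom and grand-canonical excess chemical
# potentials, and block-averaged standard errors.

#' Block-averaged standard error of the mean
#'
#' Standard error of the mean of a correlated series, estimated by block
#' averaging with automatic block-length doubling; the largest block
#' estimate with at least 8 blocks is returned (conservative for
#' correlated MC samples).
#'
#' @param x numeric sample vector
#' @return standard error of \code{mean(x)}
#' @export
block_se <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  se <- stats::sd(x) / sqrt(n)
  b <- 2
  while (n %/% b >= 8) {
    nb <- n %/% b
    bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
    se <- max(se, stats::sd(bm) / sqrt(nb))
    b <- b * 2
  }
  se
}

#' Radial distribution function from a run
#'
#' Normalizes the accumulated COM-COM pair histogram by the ideal-gas
#' shell counts using the exact per-frame \code{N(N-1)/(2V)} pair density
#' (valid in both canonical and grand-canonical ensembles).
#'
#' @param run an \code{mc_run} sampled with \code{rdf_stride > 0}
#' @return data.frame with bin centers \code{r} (A), \code{g} and raw
#'   \code{counts}
#' @export
rdf <- function(run) {
  if (run$rdf_frames == 0) stop("run carries no RDF samples")
  dr <- run$rdf_dr
  nb <- length(run$rdf_counts)
  edges <- dr * (0:nb)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
  g <- run$rdf_counts / (run$rdf_norm * shell)
  data.frame(r = edges[-(nb + 1)] + dr / 2, g = g, counts = run$rdf_counts)
}

#' Running Kirkwood-Buff integral and its plateau
#'
#' \code{G(R) = integral_0^R [g(r) - 1] 4 pi r^2 dr} by the trapezoidal
#' rule; the thermodynamic value is the mean of \code{G(R)} over the
#' plateau window (default 16-20 A).
#'
#' @param r distances, A (bin centers)
#' @param g radial distribution function values
#' @param window plateau window \code{c(lo, hi)} in A
#' @return list with \code{r}, running \code{G} (A^3) and \code{plateau}
#' @export
kb_integral <- function(r, g, window = c(16, 20)) {
  stopifnot(length(r) == length(g), length(window) == 2)
  if (max(r) < window[2])
    stop("RDF range (", max(r), " A) shorter than the plateau window; ",
         "use a larger box")
  f <- (g - 1) * 4 * pi * r^2
  # trapezoid from r = 0 (g(0+) integrand -> 0)
  rr <- c(0, r)
  ff <- c(0, f)
  G <- cumsum(diff(rr) * (ff[-length(ff)] + ff[-1]) / 2)
  sel <- r >= window[1] & r <= window[2]
  list(r = r, G = G, plateau = mean(G[sel]), window = window)
}

#' Preferential binding coefficient from KB integrals
#'
#' \code{Gamma_23 = rho_3 (G_23 - G_21)} with \code{rho_3} the cosolute
#' ion number density.
#'
#' @param G23 solute-cosolute KB integral, A^3
#' @param G21 solute-water KB integral, A^3
#' @param rho3 ion number density, 1/A^3
#' @return preferential binding coefficient (dimensionless)
#' @export
gamma23_from_kb <- function(G23, G21, rho3) {
  stopifnot(rho3 >= 0)
  rho3 * (G23 - G21)
}

#' Preferential binding coefficient from running coordination numbers
#'
#' \code{Gamma_23(r) = N_23(r) - (N_3^0/N_1^0) N_21(r)}, read off at a
#' plateau distance beyond the solute surface.
#'
#' @param r distances, A
#' @param N23 running cosolute coordination number
#' @param N21 running water coordination number
#' @param N3_0,N1_0 total cosolute / water numbers in the system
#' @param plateau_range distance window for the plateau read-off; default
#'   the last 20 percent of the sampled range
#' @return list with running \code{gamma} and its \code{plateau}
#' @export
gamma23_from_counts <- function(r, N23, N21, N3_0, N1_0,
                                plateau_range = NULL) {
  if (N3_0 <= 0 || N1_0 <= 0) stop("total particle numbers must be positive")
  stopifnot(length(r) == length(N23), length(r) == length(N21))
  gam <- N23 - (N3_0 / N1_0) * N21
  if (is.null(plateau_range))
    plateau_range <- c(stats::quantile(r, 0.8), max(r))
  sel <- r >= plateau_range[1] & r <= plateau_range[2]
  list(r = r, gamma = gam, plateau = mean(gam[sel]),
       plateau_range = plateau_range)
}

#' Excess pressure from virtual volume perturbations
#'
#' Virtual-perturbation estimator
#' \code{p = (kT/dV) ln < (1 + dV/V)^N exp(-beta dU) >} evaluated from the
#' samples accumulated during a run (isotropic scaling of box and
#' molecular centers of mass, rigid molecules), minus the ideal pressure
#' of the mean density.
#'
#' @param run an \code{mc_run} sampled with \code{pressure_stride > 0}
#' @return list with \code{p_ex}, block-averaged \code{se}, \code{p_id}
#'   and \code{phi} (osmotic coefficient), pressures in kJ/mol/A^3
#' @export
virtual_volume_pressure <- function(run) {
  x <- run$pressure_samples
  if (length(x) == 0) stop("run carries no virtual-volume samples")
  kt <- kT(run$state$temperature)
  dV <- run$manifest$protocol$volume_perturbation
  V <- run$state$box_length^3
  w <- exp(x)
  p_tot <- kt / dV * log(mean(w))
  p_id <- run$pressure_mean_n / V * kt
  se <- kt / dV * block_se(w) / mean(w)
  phi <- if (p_id > 0) p_tot / p_id else NA_real_
  list(p_ex = p_tot - p_id, se = se, p_id = p_id, phi = phi)
}

#' Osmotic coefficient from excess pressure
#'
#' \code{phi = (p_id + p_ex)/p_id} with \code{p_id = rho kT}.
#'
#' @param p_ex excess pressure, kJ/mol/A^3
#' @param rho number density, 1/A^3
#' @param temperature temperature, K
#' @return osmotic coefficient (dimensionless)
#' @export
osmotic_coefficient <- function(p_ex, rho, temperature) {
  stopifnot(rho > 0)
  p_id <- rho * kT(temperature)
  (p_id + p_ex) / p_id
}

#' Widom excess chemical potential
#'
#' \code{mu_ex = -ln < exp(-beta dU_insert) >} in kT units, from the
#' trial-insertion samples of a run.  The insertion energy includes the
#' one-body transfer term.
#'
#' @param run an \code{mc_run} sampled with \code{widom_stride > 0}
#' @return list with \code{mu_ex} (kT), block-averaged \code{se} and the
#'   number of insertion samples
#' @export
widom_mu_ex <- function(run) {
  w <- run$widom_samples
  if (length(w) == 0) stop("run carries no Widom samples")
  m <- mean(w)
  if (m == 0) {
    warning("all trial insertions overlapped; mu_ex is a lower bound")
    return(list(mu_ex = Inf, se = NA_real_, n = length(w)))
  }
  list(mu_ex = -log(m), se = block_se(w) / m, n = length(w))
}

#' Excess chemical potential difference from grand-canonical densities
#'
#' \code{delta mu_ex = ln(rho_wat / rho_salt)} in kT, for two runs at the
#' same solute activity in water and in salt solution.
#'
#' @param rho_wat solute density in pure water (any consistent unit)
#' @param rho_salt solute density in the salt solution (same unit)
#' @return excess chemical potential difference, kT
#' @export
delta_mu_ex_gc <- function(rho_wat, rho_salt) {
  if (rho_wat <= 0 || rho_salt <= 0) stop("densities must be positive")
  log(rho_wat / rho_salt)
}

#' Mean solute density of a run
#'
#' @param run an \code{mc_run} sampled with \code{density_stride > 0}
#' @return list with mean density in mol/L, block-averaged \code{se} and
#'   the mean particle number
#' @export
mean_density <- function(run) {
  n <- run$density_trace
  if (length(n) == 0) stop("run carries no density samples")
  V <- run$state$box_length^3
  conv <- 1 / (V * sasa_constants$molar_to_num)
  list(molar = mean(n) * conv, se = block_se(n) * conv, mean_n = mean(n))
}
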