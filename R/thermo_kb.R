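# Ternary solution thermodynamics: activity-coefficient models for
# solute and salt, Gibbs-Duhem-consistent water activity, Kirkwood-Buff
# inversion, and fitting of simulated excess-chemical-potential grids.
#
# Component labels: 1 = water, 2 = solute (caffeine), 3 = salt.
# All activity models derive from a single excess-Gibbs-energy generator
#   G_ex/RT = A2 m2^2/2 + B2 m2^3/3 + C1 m2 m3 + C2 m2^2 m3 / 2
#           + nu3 (A3 m3^2/2 + B3 m3^3/3)
# so that ln gamma_2 = dG/dm2, nu3 ln gamma_3 = dG/dm3 and ln a1 follows
# exactly from the Gibbs-Duhem relation; cross-Maxwell symmetry holds by
# construction.

#' Activity-coefficient model of a ternary water-solute-salt solution
#'
#' @param A2,B2 solute binary coefficients (1/molal, 1/molal^2)
#' @param C1 solute-salt interaction coefficient (1/molal); equal to the
#'   infinite-dilution salting-out constant
#' @param C2 solute-salt-solute coefficient (1/molal^2); the salting-out
#'   constant is \code{k_s(m2) = C1 + C2 m2}
#' @param A3,B3 salt binary coefficients
#' @param nu3 ions per salt formula unit (2 or 3 for the salts considered)
#' @param M1 water molar mass, kg/mol
#' @param temperature temperature, K (37 C default, the osmometry
#'   condition)
#' @param V1,V2,V3 infinite-dilution partial molar volumes, cm^3/mol
#' @return object of class \code{activity_model}
#' @export
activity_model <- function(A2 = 0, B2 = 0, C1 = 0, C2 = 0, A3 = 0, B3 = 0,
                           nu3 = 2, M1 = sasa_constants$M1_water,
                           temperature = 310.15,
                           V1 = 18.14, V2 = 145.9, V3 = 16.62) {
  stopifnot(nu3 >= 1, all(is.finite(c(A2, B2, C1, C2, A3, B3))),
            V1 > 0, V2 > 0, V3 > 0)
  structure(list(A2 = A2, B2 = B2, C1 = C1, C2 = C2, A3 = A3, B3 = B3,
                 nu3 = nu3, M1 = M1, temperature = temperature,
                 V1 = V1, V2 = V2, V3 = V3),
            class = "activity_model")
}

#' @export
print.activity_model <- function(x, ...) {
  cat("Ternary activity model (1 = water, 2 = solute, 3 = salt)\n")
  cat(sprintf("  A2 = %.4f  B2 = %.4f   (solute-solute)\n", x$A2, x$B2))
  cat(sprintf("  C1 = %.4f  C2 = %.4f   (solute-salt; k_s = C1 + C2 m2)\n",
              x$C1, x$C2))
  cat(sprintf("  A3 = %.4f  B3 = %.4f   nu3 = %d (salt-salt)\n",
              x$A3, x$B3, x$nu3))
  cat(sprintf("  T = %.2f K, Vbar = (%.2f, %.1f, %.2f) cm^3/mol\n",
              x$temperature, x$V1, x$V2, x$V3))
  invisible(x)
}

#' Solute activity coefficient
#'
#' \code{ln gamma_2 = A2 m2 + B2 m2^2 + C1 m3 + C2 m2 m3}.  Its salt
#' derivative at fixed \code{m2} is the salting-out constant
#' \code{k_s(m2) = C1 + C2 m2}.
#'
#' @param m2 solute molality, mol/kg (vectorized)
#' @param m3 salt molality, mol/kg (vectorized)
#' @param model an \code{\link{activity_model}}
#' @return ln gamma_2
#' @export
ln_gamma2 <- function(m2, m3, model) {
  model$A2 * m2 + model$B2 * m2^2 + model$C1 * m3 + model$C2 * m2 * m3
}

#' Salting-out constant of the activity model
#'
#' @param m2 solute molality, mol/kg
#' @param model an \code{\link{activity_model}}
#' @return \code{k_s(m2) = C1 + C2 m2}, 1/molal
#' @export
ks_model <- function(m2, model) model$C1 + model$C2 * m2

#' Mean ionic activity coefficient of the salt
#'
#' Binary part \code{A3 m3 + B3 m3^2} plus, at nonzero solute molality,
#' the cross term \code{(C1 m2 + C2 m2^2/2)/nu3} required by Gibbs-Duhem
#' consistency with the solute model.
#'
#' @param m3 salt molality, mol/kg
#' @param model an \code{\link{activity_model}}
#' @param m2 solute molality, mol/kg (default 0: binary salt solution)
#' @return ln gamma_3 (mean ionic)
#' @export
ln_gamma3 <- function(m3, model, m2 = 0) {
  model$A3 * m3 + model$B3 * m3^2 +
    (model$C1 * m2 + model$C2 * m2^2 / 2) / model$nu3
}

#' Salt nonideality factor
#'
#' \code{1 + d ln gamma_3 / d ln m3} evaluated on the binary salt curve.
#'
#' @param m3 salt molality, mol/kg
#' @param model an \code{\link{activity_model}}
#' @return dimensionless factor (1 for an ideal salt)
#' @export
salt_nonideality <- function(m3, model) {
  1 + m3 * (model$A3 + 2 * model$B3 * m3)
}

#' Water activity by Gibbs-Duhem integration
#'
#' Exact closed form obtained by integrating the Gibbs-Duhem relation
#' for the activity models of both solutes; reduces to the ideal limit
#' \code{ln a1 = -M1 (m2 + nu3 m3)} when all coefficients vanish.
#'
#' @param m2 solute molality, mol/kg (vectorized)
#' @param m3 salt molality, mol/kg (vectorized)
#' @param model an \code{\link{activity_model}}
#' @return ln a1
#' @export
ln_a1 <- function(m2, m3, model) {
  -model$M1 * osmolality_model(m2, m3, model)
}

#' Osmolality of the model solution
#'
#' \code{Osm = -ln a1 / M1}; the ternary surface decomposes exactly into
#' the two binary curves plus the residual \code{(C1 + C2 m2) m2 m3}.
#'
#' @param m2 solute molality, mol/kg (vectorized)
#' @param m3 salt molality, mol/kg (vectorized)
#' @param model an \code{\link{activity_model}}
#' @return osmolality, mol/kg
#' @export
osmolality_model <- function(m2, m3, model) {
  with(model,
       m2 + nu3 * m3 + A2 * m2^2 / 2 + 2 / 3 * B2 * m2^3 +
         C1 * m2 * m3 + C2 * m2^2 * m3 +
         nu3 * (A3 * m3^2 / 2 + 2 / 3 * B3 * m3^3))
}

#' Composition to densities
#'
#' Converts molalities to number densities using the solution volume from
#' infinite-dilution partial molar volumes (per kg of water).
#'
#' @param m2 solute molality, mol/kg
#' @param m3 salt molality, mol/kg
#' @param model an \code{\link{activity_model}} (supplies the volumes)
#' @return list with molar concentrations \code{molar} (mol/L, components
#'   1,2,3), number densities \code{num} (1/A^3) and the solution volume
#'   per kg water \code{V_cm3}
#' @export
molality_to_density <- function(m2, m3, model) {
  n1 <- 1 / model$M1                       # mol water per kg
  V <- n1 * model$V1 + m2 * model$V2 + m3 * model$V3  # cm^3 per kg water
  molar <- c(n1, m2, m3) / V * 1000
  list(molar = molar, num = molar * sasa_constants$molar_to_num, V_cm3 = V)
}

#' Chemical-potential derivative matrix of the model
#'
#' Returns the 3 x 3 matrix \code{d(beta mu_j)/d m_k} at constant T, p
#' (rows j = water, solute, salt; columns k likewise).  Solute rows are
#' analytic from the activity models; the water row follows from
#' Gibbs-Duhem.  Cross-Maxwell symmetry
#' \code{d(beta mu_2)/d m3 = d(beta mu_3)/d m2} holds by construction.
#'
#' @param m2 solute molality, mol/kg (> 0)
#' @param m3 salt molality, mol/kg (> 0)
#' @param model an \code{\link{activity_model}}
#' @return 3 x 3 numeric matrix, units 1/molal
#' @export
activity_derivative_matrix <- function(m2, m3, model) {
  stopifnot(m2 > 0, m3 > 0)
  mu22 <- 1 / m2 + model$A2 + 2 * model$B2 * m2 + model$C2 * m3
  mu23 <- model$C1 + model$C2 * m2
  mu33 <- model$nu3 * (1 / m3 + model$A3 + 2 * model$B3 * m3)
  mu2 <- c(mu22, mu23)
  mu3 <- c(mu23, mu33)
  # Gibbs-Duhem: sum_i m_i d(beta mu_i) = 0 per kg water, water "molality"
  # being 1/M1
  mu1 <- -model$M1 * (m2 * mu2 + m3 * mu3)
  out <- rbind(c(NA, mu1), c(NA, mu2), c(NA, mu3))
  # water column from the symmetry of second derivatives of G per kg
  out[, 1] <- NA
  dimnames(out) <- list(c("water", "solute", "salt"),
                        c("water", "solute", "salt"))
  out
}

# ---- Kirkwood-Buff forward map and inversion -------------------------

# kT * kappa_T in A^3 from kappa_T in 1/Pa
kt_kappa_A3 <- function(kappaT, temperature) {
  1.380649e-23 * temperature * kappaT * 1e30
}

#' Forward Kirkwood-Buff map
#'
#' From KB integrals and number densities to thermodynamic derivatives,
#' via the particle-number fluctuation matrix
#' \code{B_ij = rho_i delta_ij + rho_i rho_j G_ij} and its inverse
#' \code{A}: the isothermal compressibility
#' \code{kT kappa_T = 1 / sum_ij rho_i rho_j A_ij}, partial molar volumes
#' \code{Vbar_i = kT kappa_T sum_j rho_j A_ij}, and constant-pressure
#' chemical-potential derivatives
#' \code{d(beta mu_j)/d m_k = rho_1 M1 [A_jk - Vbar_j Vbar_k/(kT kappa_T)]}.
#'
#' @param G symmetric 3 x 3 matrix of KB integrals, A^3
#' @param rho_num component number densities, 1/A^3 (water, solute, salt)
#' @param M1 water molar mass, kg/mol
#' @return list with \code{mu} (3 x 3, 1/molal), \code{Vbar_A3}
#'   (A^3/molecule), \code{Vbar_cm3} (cm^3/mol) and \code{kt_kappa}
#'   (A^3)
#' @export
kb_forward <- function(G, rho_num, M1 = sasa_constants$M1_water) {
  stopifnot(all(dim(G) == c(3, 3)), length(rho_num) == 3, all(rho_num > 0))
  B <- diag(rho_num) + outer(rho_num, rho_num) * G
  A <- solve(B)
  ktk <- 1 / sum(outer(rho_num, rho_num) * A)
  Vbar <- ktk * as.vector(A %*% rho_num)
  mu <- rho_num[1] * M1 * (A - outer(Vbar, Vbar) / ktk)
  list(mu = mu, Vbar_A3 = Vbar,
       Vbar_cm3 = Vbar * sasa_constants$N_av / 1e24, kt_kappa = ktk)
}

#' Kirkwood-Buff inversion of the ternary solution
#'
#' Recovers all six independent KB integrals from the activity model's
#' chemical-potential derivatives, the infinite-dilution partial molar
#' volumes and the isothermal compressibility, by direct closed-form
#' reconstruction of the inverse fluctuation matrix: the solute block
#' follows from \code{A_jk = mu_jk/(rho_1 M1) + Vbar_j Vbar_k/(kT kappa_T)},
#' the water row/column from the partial-molar-volume sums, and
#' \code{B = A^-1} yields \code{G_ij = (B_ij - rho_i delta_ij)/(rho_i rho_j)}.
#' The compressibility relation is satisfied identically by this
#' construction, and the forward map (\code{\link{kb_forward}})
#' reproduces every input to numerical precision (round-trip contract).
#'
#' @param m2 solute molality, mol/kg (> 0)
#' @param m3 salt molality, mol/kg (> 0)
#' @param model an \code{\link{activity_model}}
#' @param kappaT isothermal compressibility, 1/Pa (pure-water value by
#'   default, treated as composition independent)
#' @return object of class \code{kb_matrix}: \code{G} (A^3),
#'   \code{G_cm3} (cm^3/mol), excess coordination numbers \code{N}
#'   (\code{N_ij = G_ij rho_j}), densities and diagnostics
#' @export
kb_invert <- function(m2, m3, model, kappaT = 4.46e-10) {
  stopifnot(m2 > 0, m3 > 0)
  dens <- molality_to_density(m2, m3, model)
  rho <- dens$num
  ktk <- kt_kappa_A3(kappaT, model$temperature)
  mu <- activity_derivative_matrix(m2, m3, model)
  Vb <- c(NA, model$V2, model$V3) * 1e24 / sasa_constants$N_av  # A^3
  Vb[1] <- (1 - rho[2] * Vb[2] - rho[3] * Vb[3]) / rho[1]
  if (Vb[1] <= 0)
    stop("implied water partial molar volume is not positive at m2 = ",
         m2, ", m3 = ", m3)
  A <- matrix(0, 3, 3)
  for (j in 2:3) {
    for (k in 2:3) {
      A[j, k] <- mu[j, k] / (rho[1] * model$M1) + Vb[j] * Vb[k] / ktk
    }
  }
  for (i in 2:3)
    A[i, 1] <- (Vb[i] / ktk - rho[2] * A[i, 2] - rho[3] * A[i, 3]) / rho[1]
  A[1, 2:3] <- A[2:3, 1]
  A[1, 1] <- (Vb[1] / ktk - rho[2] * A[1, 2] - rho[3] * A[1, 3]) / rho[1]
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1e-14)
    stop("KB inversion: ill-conditioned derivative matrix (rcond = ",
         format(rc, digits = 3), ") at m2 = ", m2, ", m3 = ", m3)
  B <- solve(A)
  G <- (B - diag(rho)) / outer(rho, rho)
  G <- (G + t(G)) / 2
  # round-trip diagnostic against the forward map
  fw <- kb_forward(G, rho, model$M1)
  pred <- c(fw$mu[2, 2], fw$mu[2, 3], fw$mu[3, 3],
            fw$Vbar_A3[2], fw$Vbar_A3[3], fw$kt_kappa)
  target <- c(mu[2, 2], mu[2, 3], mu[3, 3], Vb[2], Vb[3], ktk)
  resid <- max(abs((pred - target) / pmax(abs(target), 1e-12)))
  dimnames(G) <- list(c("water", "solute", "salt"),
                      c("water", "solute", "salt"))
  structure(list(G = G, G_cm3 = G * sasa_constants$N_av / 1e24,
                 N = G * rep(rho, each = 3), rho_num = rho,
                 rho_molar = dens$molar, m2 = m2, m3 = m3,
                 kt_kappa = ktk, residual = resid, rcond = rc),
            class = "kb_matrix")
}

#' @export
print.kb_matrix <- function(x, ...) {
  cat(sprintf("KB matrix at m2 = %.4g, m3 = %.4g mol/kg (residual %.2g)\n",
              x$m2, x$m3, x$residual))
  cat("G_ij (cm^3/mol):\n")
  print(round(x$G_cm3, 2))
  invisible(x)
}

#' KB integrals over a composition grid
#'
#' @param m2_grid,m3_grid molality grids (values > 0), mol/kg
#' @param model an \code{\link{activity_model}}
#' @param ... passed to \code{\link{kb_invert}}
#' @return long-format data.frame (m2, m3, i, j, G_A3, G_cm3)
#' @export
kb_invert_grid <- function(m2_grid, m3_grid, model, ...) {
  comp <- expand.grid(m2 = m2_grid, m3 = m3_grid)
  labs <- c("water", "solute", "salt")
  out <- lapply(seq_len(nrow(comp)), function(k) {
    kb <- kb_invert(comp$m2[k], comp$m3[k], model, ...)
    idx <- which(upper.tri(kb$G, diag = TRUE), arr.ind = TRUE)
    data.frame(m2 = comp$m2[k], m3 = comp$m3[k],
               i = labs[idx[, 1]], j = labs[idx[, 2]],
               G_A3 = kb$G[idx], G_cm3 = kb$G_cm3[idx])
  })
  do.call(rbind, out)
}

# ---- fitting of excess-chemical-potential grids ----------------------

#' Fit the activity model to an excess-chemical-potential grid
#'
#' Two-stage weighted least squares on \code{mu_ex = ln gamma_2} (kT):
#' the solute binary coefficients (A2, B2) are determined from the
#' salt-free slice only (independent of the TFE value), then frozen while
#' (C1, C2) are fitted to the full grid.
#'
#' @param data data.frame with columns \code{m2}, \code{m3},
#'   \code{mu_ex} (kT) and optionally \code{se}
#' @param nu3,temperature passed to the returned
#'   \code{\link{activity_model}}
#' @param ... further arguments to \code{\link{activity_model}}
#' @return object of class \code{activity_fit}
#' @export
fit_activity_model <- function(data, nu3 = 2, temperature = 310.15, ...) {
  stopifnot(all(c("m2", "m3", "mu_ex") %in% names(data)))
  if (!"se" %in% names(data) || all(is.na(data$se)) || any(data$se <= 0))
    data$se <- 1
  bin <- data[data$m3 == 0, , drop = FALSE]
  if (nrow(bin) < 2) stop("need at least two salt-free points for (A2, B2)")
  f1 <- stats::lm(mu_ex ~ 0 + m2 + I(m2^2), data = bin,
                  weights = 1 / bin$se^2)
  A2 <- unname(stats::coef(f1)[1])
  B2 <- unname(stats::coef(f1)[2])
  tern <- data[data$m3 > 0, , drop = FALSE]
  if (nrow(tern) < 2) stop("need at least two salt points for (C1, C2)")
  tern$resid <- tern$mu_ex - A2 * tern$m2 - B2 * tern$m2^2
  f2 <- stats::lm(resid ~ 0 + m3 + I(m2 * m3), data = tern,
                  weights = 1 / tern$se^2)
  C1 <- unname(stats::coef(f2)[1])
  C2 <- unname(stats::coef(f2)[2])
  cov <- matrix(0, 4, 4,
                dimnames = list(c("A2", "B2", "C1", "C2"),
                                c("A2", "B2", "C1", "C2")))
  cov[1:2, 1:2] <- stats::vcov(f1)
  cov[3:4, 3:4] <- stats::vcov(f2)
  model <- activity_model(A2 = A2, B2 = B2, C1 = C1, C2 = C2, nu3 = nu3,
                          temperature = temperature, ...)
  structure(list(model = model,
                 coef = c(A2 = A2, B2 = B2, C1 = C1, C2 = C2),
                 se = sqrt(diag(cov)), cov = cov,
                 stage1 = f1, stage2 = f2, data = data),
            class = "activity_fit")
}

#' @export
coef.activity_fit <- function(object, ...) object$coef

#' @export
print.activity_fit <- function(x, ...) {
  cat("Two-stage activity-model fit (mu_ex = RT ln gamma_2)\n")
  tab <- data.frame(estimate = x$coef, se = x$se)
  print(round(tab, 4))
  invisible(x)
}

#' Salting-out constant from the preferential binding coefficient
#'
#' \code{k_s = -Gamma_23 (1 + d ln gamma_3/d ln m3) / m3}, with
#' \code{Gamma_23} in the ion-number convention; the nonideality factor
#' comes from the binary salt activity model.  Negative \code{Gamma_23}
#' (salt depletion) gives positive \code{k_s} (salting-out).  At zero
#' salt concentration the limit is evaluated from the KB integrals:
#' \code{k_s(0) = -nu3 rho_1 M1 (G23 - G21)}.
#'
#' @param gamma23 preferential binding coefficient (ion convention)
#' @param m3 salt molality, mol/kg
#' @param model an \code{\link{activity_model}}
#' @param G23,G21 KB integrals (A^3), used for the \code{m3 = 0} limit
#' @param rho1 water number density, 1/A^3 (default: pure water from the
#'   model volumes)
#' @return salting-out constant, 1/molal
#' @export
ks_from_gamma23 <- function(gamma23 = NULL, m3, model,
                            G23 = NULL, G21 = NULL, rho1 = NULL) {
  if (m3 > 0) {
    if (is.null(gamma23)) stop("gamma23 required for m3 > 0")
    return(-gamma23 * salt_nonideality(m3, model) / m3)
  }
  if (is.null(G23) || is.null(G21))
    stop("the m3 = 0 limit needs the KB integrals G23 and G21")
  if (is.null(rho1))
    rho1 <- molality_to_density(0, 0, model)$num[1]
  -model$nu3 * rho1 * model$M1 * (G23 - G21)
}
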