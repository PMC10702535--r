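# Vapor-pressure-osmometry style analysis: water activity, residual
# osmolality of ternary solutions, salting-out constants with error
# propagation, and the in-silico osmometry pipeline driven by the
# activity model (or a fitted simulation grid).

#' Water activity from osmolality
#'
#' \code{ln a1 = -M1 Osm} with the water molar mass M1.
#'
#' @param osm osmolality, mol/kg (vectorized)
#' @param M1 water molar mass, kg/mol
#' @return ln a1
#' @export
osm_to_ln_a1 <- function(osm, M1 = sasa_constants$M1_water) {
  stopifnot(all(osm >= 0))
  -M1 * osm
}

#' Osmolality from water activity (inverse map)
#'
#' @param lna1 ln a1 (vectorized)
#' @param M1 water molar mass, kg/mol
#' @return osmolality, mol/kg
#' @export
ln_a1_to_osm <- function(lna1, M1 = sasa_constants$M1_water) -lna1 / M1

#' Construct an osmolality table
#'
#' @param m2 solute molality, mol/kg
#' @param m3 salt molality, mol/kg
#' @param osm measured osmolality, mol/kg
#' @param stderr standard error of \code{osm}, mol/kg
#' @param label salt identity label
#' @return data.frame of class \code{osm_table}
#' @export
osm_table <- function(m2, m3, osm, stderr = 0, label = "salt") {
  stopifnot(all(osm >= 0), all(m2 >= 0), all(m3 >= 0))
  out <- data.frame(m2 = m2, m3 = m3, osm = osm, stderr = stderr,
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("osm_table", "data.frame")
  out
}

# fit a binary osmolality curve through the origin; returns a predictor
# with standard errors
binary_curve <- function(m, osm, w, order = 2) {
  stopifnot(order >= 1)
  X <- stats::poly(m, degree = order, raw = TRUE)
  fit <- stats::lm(osm ~ 0 + X, weights = w)
  rng <- range(m)
  function(mnew) {
    if (any(mnew < rng[1] - 1e-12 | mnew > rng[2] + 1e-12))
      stop("ternary composition outside binary coverage (",
           format(rng[1]), " - ", format(rng[2]),
           " mol/kg); refusing to extrapolate")
    Xn <- outer(mnew, seq_len(order), `^`)
    colnames(Xn) <- colnames(X)
    pr <- Xn %*% stats::coef(fit)
    se <- sqrt(rowSums((Xn %*% stats::vcov(fit)) * Xn))
    list(osm = as.vector(pr), se = as.vector(se))
  }
}

#' Residual osmolality of ternary solutions
#'
#' \code{dOsm(m2, m3) = Osm(m2, m3) - Osm(m2, 0) - Osm(0, m3)}.  The two
#' binary curves are interpolated with low-order polynomials through the
#' origin (quadratic by default) fitted to the table's binary rows;
#' ternary points outside the binary coverage are an error (no
#' extrapolation).  Standard errors combine the three terms in
#' quadrature.
#'
#' @param table an \code{\link{osm_table}} containing binary rows
#'   (\code{m3 = 0} and \code{m2 = 0}) and ternary rows
#' @param order polynomial order of the binary interpolation
#' @return data.frame with \code{m2}, \code{m3}, \code{dosm},
#'   \code{stderr} and \code{label} for every ternary row
#' @export
residual_osmolality <- function(table, order = 2) {
  stopifnot(inherits(table, "data.frame"),
            all(c("m2", "m3", "osm", "stderr", "label") %in% names(table)))
  bin2 <- table[table$m3 == 0 & table$m2 > 0, , drop = FALSE]
  tern <- table[table$m2 > 0 & table$m3 > 0, , drop = FALSE]
  if (nrow(bin2) < order + 1)
    stop("need at least ", order + 1, " solute binary rows (m3 = 0)")
  if (nrow(tern) == 0) stop("no ternary rows in the table")
  w2 <- if (all(bin2$stderr > 0)) 1 / bin2$stderr^2 else rep(1, nrow(bin2))
  p2 <- binary_curve(bin2$m2, bin2$osm, w2, order)
  out <- lapply(unique(tern$label), function(lab) {
    bin3 <- table[table$m2 == 0 & table$m3 > 0 & table$label == lab, ,
                  drop = FALSE]
    if (nrow(bin3) < order + 1)
      stop("need at least ", order + 1, " salt binary rows (m2 = 0) for '",
           lab, "'")
    w3 <- if (all(bin3$stderr > 0)) 1 / bin3$stderr^2 else rep(1, nrow(bin3))
    p3 <- binary_curve(bin3$m3, bin3$osm, w3, order)
    tt <- tern[tern$label == lab, , drop = FALSE]
    b2 <- p2(tt$m2)
    b3 <- p3(tt$m3)
    data.frame(m2 = tt$m2, m3 = tt$m3,
               dosm = tt$osm - b2$osm - b3$osm,
               stderr = sqrt(tt$stderr^2 + b2$se^2 + b3$se^2),
               label = lab, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit the salting-out constant and its solute-concentration dependence
#'
#' Weighted least squares of the residual osmolality surface
#' \code{dOsm = (C1 + C2 m2) m2 m3}, giving the salting-out constant
#' \code{k_s(m2) = C1 + C2 m2} with 95 percent confidence intervals
#' (2 sigma).  With a single distinct solute molality the concentration
#' dependence is not identifiable and \code{C2} is fixed to zero with a
#' warning.
#'
#' @param dosm data.frame from \code{\link{residual_osmolality}} (or with
#'   columns \code{m2}, \code{m3}, \code{dosm}, optional \code{stderr})
#' @param omit_lowest_m2 drop the lowest solute concentration before
#'   fitting (noisiest points)
#' @return object of class \code{ks_fit} with coefficients, standard
#'   errors and 95 percent CIs
#' @export
fit_ks <- function(dosm, omit_lowest_m2 = FALSE) {
  stopifnot(all(c("m2", "m3", "dosm") %in% names(dosm)))
  d <- dosm
  if (omit_lowest_m2) {
    lows <- min(d$m2)
    d <- d[d$m2 > lows, , drop = FALSE]
  }
  if (nrow(d) < 1) stop("no data left to fit")
  w <- if ("stderr" %in% names(d) && all(d$stderr > 0)) 1 / d$stderr^2
       else rep(1, nrow(d))
  single_m2 <- length(unique(d$m2)) < 2
  if (single_m2) {
    warning("single solute concentration: C2 fixed to 0 (reduced model)")
    fit <- stats::lm(dosm ~ 0 + I(m2 * m3), data = d, weights = w)
    cf <- c(unname(stats::coef(fit)), 0)
    se <- c(sqrt(stats::vcov(fit)[1, 1]), NA)
  } else {
    fit <- stats::lm(dosm ~ 0 + I(m2 * m3) + I(m2^2 * m3), data = d,
                     weights = w)
    cf <- unname(stats::coef(fit))
    se <- unname(sqrt(diag(stats::vcov(fit))))
  }
  structure(list(C1 = cf[1], C2 = cf[2], se = c(C1 = se[1], C2 = se[2]),
                 ci95 = rbind(C1 = cf[1] + c(-2, 2) * se[1],
                              C2 = cf[2] + c(-2, 2) * se[2]),
                 lm = fit, n = nrow(d), single_m2 = single_m2,
                 omit_lowest_m2 = omit_lowest_m2),
            class = "ks_fit")
}

#' @export
coef.ks_fit <- function(object, ...) c(C1 = object$C1, C2 = object$C2)

#' @export
print.ks_fit <- function(x, ...) {
  cat("Salting-out constant fit: dOsm = (C1 + C2 m2) m2 m3\n")
  cat(sprintf("  C1 = %.4f +/- %.4f (95%% CI %.4f - %.4f) 1/molal\n",
              x$C1, 2 * x$se[1], x$ci95[1, 1], x$ci95[1, 2]))
  if (!x$single_m2)
    cat(sprintf("  C2 = %.4f +/- %.4f (95%% CI %.4f - %.4f) 1/molal^2\n",
                x$C2, 2 * x$se[2], x$ci95[2, 1], x$ci95[2, 2]))
  cat(sprintf("  n = %d records\n", x$n))
  invisible(x)
}

#' Evaluate the fitted salting-out constant
#'
#' @param object a \code{ks_fit}
#' @param m2 solute molality, mol/kg (vectorized)
#' @param ... unused
#' @return \code{k_s(m2) = C1 + C2 m2}
#' @export
predict.ks_fit <- function(object, m2 = 0, ...) object$C1 + object$C2 * m2

#' In-silico osmometry experiment
#'
#' Generates an osmolality table from an activity model (e.g. one fitted
#' to a simulated excess-chemical-potential grid), then runs it through
#' exactly the same residual-osmolality and salting-out analysis as an
#' experimental table.  Since only the product of TFE coefficient and
#' salt concentration enters the underlying simulations, the surface can
#' be rescaled to an arbitrary TFE value via \code{tfe_scale}.
#'
#' @param model an \code{\link{activity_model}} or \code{activity_fit}
#' @param m2_grid,m3_grid composition grids, mol/kg
#' @param tfe_scale rescaling factor applied to the solute-salt
#'   coefficients (universal-curve rescaling)
#' @param label salt label for the generated table
#' @param order binary interpolation order (cubic by default: the model's
#'   binary osmolality curves are cubic polynomials, so the
#'   interpolation is exact and the pipeline round-trips the generating
#'   coefficients)
#' @return list with the generated \code{table}, residual \code{dosm}
#'   records and the \code{ks_fit}
#' @export
in_silico_vpo <- function(model, m2_grid = seq(0.01, 0.05, by = 0.01),
                          m3_grid = seq(0.1, 0.5, by = 0.1),
                          tfe_scale = 1, label = "model", order = 3) {
  if (inherits(model, "activity_fit")) model <- model$model
  stopifnot(inherits(model, "activity_model"))
  if (tfe_scale != 1) {
    model$C1 <- model$C1 * tfe_scale
    model$C2 <- model$C2 * tfe_scale
  }
  grid <- rbind(expand.grid(m2 = m2_grid, m3 = m3_grid),
                data.frame(m2 = m2_grid, m3 = 0),
                data.frame(m2 = 0, m3 = m3_grid))
  tab <- osm_table(grid$m2, grid$m3,
                   osmolality_model(grid$m2, grid$m3, model),
                   stderr = 0, label = label)
  dosm <- residual_osmolality(tab, order = order)
  list(table = tab, dosm = dosm, fit = fit_ks(dosm))
}
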