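# Metropolis-Hastings sampling driver: system state construction, move
# parameters, run protocols, and the R front-end to the compiled engine.

#' Metropolis acceptance decision
#'
#' Accepts with probability \code{min(1, exp(-beta*dU + bias))}.  An
#' infinite energy change is always rejected; a NaN energy change is a
#' hard error (it indicates an energy bug, never a legitimate state).
#'
#' @param delta_u energy change, kJ/mol
#' @param bias additional dimensionless log-factor (e.g. ensemble weights)
#' @param temperature temperature, K
#' @return logical: accept the move?
#' @export
metropolis_accept <- function(delta_u, bias = 0, temperature = 298.15) {
  if (is.nan(delta_u)) stop("NaN energy change passed to metropolis_accept")
  if (delta_u == Inf) return(FALSE)
  x <- -beta_of(temperature) * delta_u + bias
  if (x >= 0) return(TRUE)
  stats::runif(1) < exp(x)
}

#' Move-set parameters
#'
#' Defaults follow the canonical-ensemble protocol: 2.5 A maximum
#' translation and 0.5 rad maximum rotation for single-molecule moves,
#' a cluster move (7.5 A, 1.0 rad) built by transitive closure of
#' COM distances below 6.5 A, with a detailed-balance membership guard.
#' Grand-canonical runs conventionally use larger single-molecule steps
#' (10 A, 1 rad); see \code{\link{move_params_gc}}.
#'
#' @param translate maximum translational displacement, A
#' @param rotate maximum rotation angle, rad
#' @param cluster_translate maximum cluster translation, A
#' @param cluster_rotate maximum cluster rotation, rad
#' @param cluster_threshold COM-distance threshold defining clusters, A
#' @param w_translate,w_cluster,w_gc relative attempt weights of the
#'   move types (GC weight only used in grand-canonical runs)
#' @return object of class \code{move_params}
#' @export
move_params <- function(translate = 2.5, rotate = 0.5,
                        cluster_translate = 7.5, cluster_rotate = 1.0,
                        cluster_threshold = 6.5,
                        w_translate = 1, w_cluster = 0.2, w_gc = 0) {
  stopifnot(translate > 0, rotate > 0,
            w_translate >= 0, w_cluster >= 0, w_gc >= 0)
  structure(list(translate = translate, rotate = rotate,
                 cluster_translate = cluster_translate,
                 cluster_rotate = cluster_rotate,
                 cluster_threshold = cluster_threshold,
                 w_translate = w_translate, w_cluster = w_cluster,
                 w_gc = w_gc),
            class = "move_params")
}

#' Grand-canonical move parameters
#'
#' Single-molecule translation/rotation (10 A, 1 rad) plus insertion and
#' deletion attempts with equal weight.
#' @param w_gc relative weight of insertion/deletion attempts
#' @export
move_params_gc <- function(w_gc = 1) {
  move_params(translate = 10, rotate = 1, w_cluster = 0, w_gc = w_gc)
}

#' Run protocol: iteration counts, sampling strides and seed
#'
#' One "iteration" is one attempted MC move.  Default strides follow the
#' simulation protocol: RDF sampled every 10 moves at 0.25 A resolution,
#' Widom insertion with 25 trial inserts every 10 moves, virtual-volume
#' pressure every 10 moves.
#'
#' @param equilibration number of equilibration moves
#' @param production number of production moves
#' @param rdf_stride RDF sampling stride in moves (0 disables)
#' @param rdf_dr RDF bin width, A
#' @param widom_stride Widom sampling stride (0 disables)
#' @param widom_inserts trial insertions per Widom sample
#' @param pressure_stride virtual-volume sampling stride (0 disables)
#' @param volume_perturbation virtual volume change, A^3
#' @param density_stride particle-number sampling stride (0 disables)
#' @param energy_stride energy-trace stride (0 disables)
#' @param seed integer master seed for the engine RNG
#' @return object of class \code{run_protocol}
#' @export
run_protocol <- function(equilibration = 5e4, production = 1e6,
                         rdf_stride = 0, rdf_dr = 0.25,
                         widom_stride = 0, widom_inserts = 25,
                         pressure_stride = 0, volume_perturbation = 50,
                         density_stride = 0, energy_stride = 1000,
                         seed = 1) {
  stopifnot(equilibration >= 0, production >= 0, seed == floor(seed))
  structure(list(equilibration = equilibration, production = production,
                 rdf_stride = rdf_stride, rdf_dr = rdf_dr,
                 widom_stride = widom_stride, widom_inserts = widom_inserts,
                 pressure_stride = pressure_stride,
                 volume_perturbation = volume_perturbation,
                 density_stride = density_stride,
                 energy_stride = energy_stride, seed = seed),
            class = "run_protocol")
}

#' Construct a simulation state
#'
#' Places \code{n} molecules at random non-clashing positions (rejection
#' sampling on COM distances) with uniformly random orientations in a
#' periodic cubic box, or accepts explicit positions/orientations.
#'
#' @param template a \code{mol_template}
#' @param box_length cubic box edge, A
#' @param n number of molecules (ignored when \code{positions} given)
#' @param positions optional N x 3 matrix of COM positions, A
#' @param quaternions optional N x 4 matrix of unit quaternions (w,x,y,z)
#' @param temperature temperature, K
#' @param salt a \code{\link{salt_field}}
#' @param ensemble \code{"canonical"} or \code{"grand"}
#' @param activity molar activity of the solute (mol/L), grand canonical
#' @return object of class \code{mc_state}
#' @export
mc_state <- function(template, box_length, n = 0, positions = NULL,
                     quaternions = NULL, temperature = 298.15,
                     salt = salt_field(), ensemble = c("canonical", "grand"),
                     activity = NULL) {
  ensemble <- match.arg(ensemble)
  if (ensemble == "grand" && is.null(activity))
    stop("grand-canonical state requires an activity")
  if (is.null(positions)) {
    # clash-free placement: beyond this COM distance no bead pair can
    # sit inside its repulsive core
    off <- sqrt(max(rowSums(template_coords(template)^2)))
    dmin <- max(template$beads$wca_sigma) + 2 * off
    positions <- place_random(n, box_length, min(dmin, box_length / 3))
  } else {
    positions <- as.matrix(positions)
    positions <- positions %% box_length
  }
  n <- nrow(positions)
  if (is.null(quaternions)) {
    quaternions <- t(vapply(seq_len(max(n, 1)), function(i) {
      q <- stats::rnorm(4); q / sqrt(sum(q^2))
    }, numeric(4)))[seq_len(n), , drop = FALSE]
  }
  structure(list(template = template, box_length = box_length,
                 positions = positions,
                 quaternions = as.matrix(quaternions),
                 temperature = temperature, salt = salt,
                 ensemble = ensemble, activity = activity),
            class = "mc_state")
}

# random COM placement with a minimum-distance rejection criterion
place_random <- function(n, L, dmin, max_tries = 20000L) {
  pos <- matrix(0, n, 3)
  if (n == 0) return(pos)
  k <- 1L
  tries <- 0L
  while (k <= n) {
    p <- stats::runif(3, 0, L)
    ok <- TRUE
    if (k > 1) {
      d <- sweep(pos[seq_len(k - 1), , drop = FALSE], 2, p)
      d <- d - L * round(d / L)
      ok <- min(rowSums(d^2)) > dmin^2
    }
    tries <- tries + 1L
    if (ok) {
      pos[k, ] <- p
      k <- k + 1L
      tries <- 0L
    } else if (tries > max_tries) {
      stop("could not place ", n, " molecules at box length ", L)
    }
  }
  pos
}

#' @export
print.mc_state <- function(x, ...) {
  cat(sprintf("MC state: %d molecules, box %.1f A, %s ensemble, T = %.2f K\n",
              nrow(x$positions), x$box_length, x$ensemble, x$temperature))
  cat(sprintf("  salt: c_s = %.3f M, eps_TFE = %.4f kJ/mol/A^2/M\n",
              x$salt$c_s, x$salt$eps_tfe))
  if (x$ensemble == "grand")
    cat(sprintf("  activity: %.4f M\n", x$activity))
  invisible(x)
}

#' Run a Monte Carlo simulation
#'
#' Executes equilibration followed by production with the configured move
#' set, accumulating the requested observables.  Fully reproducible given
#' the protocol seed.
#'
#' @param state an \code{\link{mc_state}}
#' @param moves a \code{\link{move_params}} (grand-canonical states
#'   default to \code{\link{move_params_gc}()})
#' @param protocol a \code{\link{run_protocol}}
#' @return object of class \code{mc_run}: final state, acceptance
#'   statistics, observable accumulators and a run manifest
#' @export
run_mc <- function(state, moves = NULL, protocol = run_protocol()) {
  stopifnot(inherits(state, "mc_state"), inherits(protocol, "run_protocol"))
  if (is.null(moves))
    moves <- if (state$ensemble == "grand") move_params_gc() else move_params()
  grand <- state$ensemble == "grand"
  u1 <- monomer_transfer_energy(state$template, state$salt)
  cpp <- template_cpp_pack(state$template, state$salt)
  rot0 <- quats_to_rot9(state$quaternions)
  a_num <- if (grand) state$activity * sasa_constants$molar_to_num else 0

  res <- run_mc_cpp(cpp, t(state$positions), rot0, state$box_length,
                    beta_of(state$temperature), u1, grand, a_num,
                    list(dtrans = moves$translate, drot = moves$rotate,
                         cl_dtrans = moves$cluster_translate,
                         cl_drot = moves$cluster_rotate,
                         cl_threshold = moves$cluster_threshold,
                         w_trans = moves$w_translate,
                         w_cluster = moves$w_cluster, w_gc = moves$w_gc),
                    list(equilibration = protocol$equilibration,
                         production = protocol$production,
                         rdf_stride = as.integer(protocol$rdf_stride),
                         rdf_dr = protocol$rdf_dr,
                         widom_stride = as.integer(protocol$widom_stride),
                         widom_inserts = as.integer(protocol$widom_inserts),
                         pressure_stride = as.integer(protocol$pressure_stride),
                         dV = protocol$volume_perturbation,
                         density_stride = as.integer(protocol$density_stride),
                         energy_stride = as.integer(protocol$energy_stride),
                         seed = protocol$seed))
  if (!is.finite(res$energy) && res$n > 0 && is.nan(res$energy))
    stop("energy diverged to NaN during the run")

  final <- state
  final$positions <- t(res$com)
  final$quaternions <- rot9_to_quats(res$rot)

  acc <- data.frame(move = c("translate", "cluster", "insert", "delete"),
                    attempts = res$attempts, accepts = res$accepts,
                    ratio = ifelse(res$attempts > 0,
                                   res$accepts / res$attempts, NA))
  structure(list(state = final, initial_n = nrow(state$positions),
                 energy = res$energy,
                 energy_incremental = res$energy_incremental,
                 du_accum = res$du_accum,
                 acceptance = acc,
                 rdf_counts = res$rdf_counts, rdf_dr = res$rdf_dr,
                 rdf_norm = res$rdf_norm, rdf_frames = res$rdf_frames,
                 widom_samples = res$widom_samples,
                 pressure_samples = res$pressure_samples,
                 pressure_mean_n = res$pressure_mean_n,
                 density_trace = res$density_trace,
                 energy_trace = res$energy_trace,
                 one_body = u1,
                 manifest = list(protocol = unclass(protocol),
                                 moves = unclass(moves),
                                 box_length = state$box_length,
                                 temperature = state$temperature,
                                 salt = unclass(state$salt),
                                 ensemble = state$ensemble,
                                 activity = state$activity,
                                 package_version =
                                   as.character(utils::packageVersion("sasamc")))),
            class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("MC run: %d -> %d molecules, U = %.3f kJ/mol\n",
              x$initial_n, nrow(x$state$positions), x$energy))
  print(x$acceptance, row.names = FALSE)
  invisible(x)
}

quats_to_rot9 <- function(q) {
  n <- nrow(q)
  out <- matrix(0, 9, n)
  for (i in seq_len(n)) out[, i] <- as.vector(t(quat_to_matrix(q[i, ])))
  out
}

rot9_to_quats <- function(rot9) {
  n <- ncol(rot9)
  out <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    R <- matrix(rot9[, i], 3, 3, byrow = TRUE)
    tr <- sum(diag(R))
    if (tr > 0) {
      s <- sqrt(tr + 1) * 2
      q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
             (R[2, 1] - R[1, 2]) / s)
    } else {
      k <- which.max(diag(R))
      i1 <- k; i2 <- k %% 3 + 1; i3 <- i2 %% 3 + 1
      s <- sqrt(1 + R[i1, i1] - R[i2, i2] - R[i3, i3]) * 2
      q <- numeric(4)
      q[1] <- (R[i3, i2] - R[i2, i3]) / s
      q[i1 + 1] <- 0.25 * s
      q[i2 + 1] <- (R[i2, i1] + R[i1, i2]) / s
      q[i3 + 1] <- (R[i1, i3] + R[i3, i1]) / s
    }
    out[i, ] <- q / sqrt(sum(q^2))
  }
  out
}
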