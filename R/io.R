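# File formats: XYZ trajectories (one pseudo-atom per bead), YAML/JSON
# run configurations, template config blocks and JSON run manifests.

#' Bead coordinates of every molecule in a state
#'
#' @param state an \code{mc_state}
#' @return list with \code{labels} (bead names recycled per molecule) and
#'   \code{coords} (matrix, A)
#' @export
state_bead_coords <- function(state) {
  n <- nrow(state$positions)
  tplc <- template_coords(state$template)
  coords <- do.call(rbind, lapply(seq_len(n), function(i) {
    R <- quat_to_matrix(state$quaternions[i, ])
    sweep(tplc %*% t(R), 2, state$positions[i, ], "+")
  }))
  if (n == 0) coords <- matrix(0, 0, 3)
  list(labels = rep(state$template$beads$name, n), coords = coords)
}

#' Write an XYZ trajectory
#'
#' Standard XYZ: atom count line, then a comment line carrying the box
#' length and frame index, then one line per bead with the bead label in
#' the element field.  Coordinates are written to 1e-5 A.
#'
#' @param frames list of frames, each a list with \code{labels} and
#'   \code{coords} (e.g. from \code{\link{state_bead_coords}})
#' @param path output file
#' @param box_length box edge recorded on the comment line, A
#' @export
write_xyz <- function(frames, path, box_length = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(sprintf("box %.5f frame %d", box_length, k), con)
    if (nrow(fr$coords) > 0)
      writeLines(sprintf("%s %.5f %.5f %.5f", fr$labels,
                         fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]),
                 con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ file written by \code{\link{write_xyz}} (or any
#'   standard XYZ file)
#' @return list of frames with \code{labels}, \code{coords} and the
#'   parsed \code{comment} line
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("malformed XYZ at line ", i, ": expected an atom count")
    na <- as.integer(lines[i])
    if (i + 1 + na > length(lines) + ifelse(na == 0, 1, 0))
      if (i + 1 + na - 1 > length(lines))
        stop("malformed XYZ at line ", i, ": truncated frame")
    comment <- lines[i + 1]
    labs <- character(na)
    coords <- matrix(0, na, 3)
    for (k in seq_len(na)) {
      parts <- strsplit(trimws(lines[i + 1 + k]), "\\s+")[[1]]
      if (length(parts) < 4)
        stop("malformed XYZ at line ", i + 1 + k)
      labs[k] <- parts[1]
      coords[k, ] <- as.numeric(parts[2:4])
    }
    frames[[length(frames) + 1]] <- list(labels = labs, coords = coords,
                                         comment = comment)
    i <- i + 2L + na
  }
  frames
}

#' Serialize a molecule template to a config block
#'
#' @param template a \code{mol_template}
#' @return character vector of config lines (human readable, parseable
#'   by \code{\link{template_from_config}})
#' @export
template_to_config <- function(template) {
  b <- template$beads
  c(sprintf("probe_radius %.6f", template$probe_radius),
    "name x y z group_radius sasa_radius wca_sigma wca_epsilon gamma tfe",
    sprintf("%s %.6f %.6f %.6f %.6f %.6f %.6f %.6f %.6f %.6f",
            b$name, b$x, b$y, b$z, b$group_radius, b$sasa_radius,
            b$wca_sigma, b$wca_epsilon, b$gamma, b$tfe))
}

#' Parse a molecule template from a config block
#'
#' @param lines character vector from \code{\link{template_to_config}}
#' @return a \code{mol_template}
#' @export
template_from_config <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  probe <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]][2])
  cols <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  rows <- lapply(lines[-(1:2)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  beads <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(beads) <- cols
  beads[-1] <- lapply(beads[-1], as.numeric)
  tpl <- structure(list(beads = beads, probe_radius = probe),
                   class = "mol_template")
  tpl$reference_areas <- reference_areas(tpl)
  tpl$monomer_sasa <- sum(tpl$reference_areas)
  tpl
}

config_schema <- list(
  ensemble = "canonical", box_length = 250, n_molecules = 100,
  activity = NULL,
  temperature = 298.15,
  salt = list(c_s = 0, eps_tfe = 0),
  template = list(probe_radius = 1.4, gamma = 0.0502, eps_wca = 0.5),
  moves = list(translate = 2.5, rotate = 0.5, cluster_translate = 7.5,
               cluster_rotate = 1.0, cluster_threshold = 6.5,
               w_translate = 1, w_cluster = 0.2, w_gc = 1),
  protocol = list(equilibration = 5e4, production = 1e6,
                  rdf_stride = 10, rdf_dr = 0.25,
                  widom_stride = 10, widom_inserts = 25,
                  pressure_stride = 10, volume_perturbation = 5,
                  density_stride = 1000, energy_stride = 1000,
                  seed = 1))

# overlay user values on the schema defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(defaults) && !(path == "" && key == "activity"))
      stop("unknown config key: ", paste0(path, key))
    if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      defaults[key] <- list(merge_config(defaults[[key]], user[[key]],
                                         paste0(path, key, ".")))
    } else {
      # single-bracket assignment keeps explicit NULLs in place
      defaults[key] <- list(user[[key]])
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' YAML (or JSON) file validated against the configuration schema;
#' missing keys are filled with the protocol defaults, unknown keys are
#' rejected.
#'
#' @param path config file
#' @return validated configuration list
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user) || length(user) == 0) stop("empty config file: ", path)
  cfg <- merge_config(config_schema, user)
  if (!cfg$ensemble %in% c("canonical", "grand"))
    stop("config ensemble must be 'canonical' or 'grand'")
  if (cfg$ensemble == "grand" && is.null(cfg$activity))
    stop("grand-canonical config requires an activity")
  cfg
}

#' Write a configuration to YAML
#'
#' @param config configuration list
#' @param path output file
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Execute a run described by a configuration
#'
#' @param config list from \code{\link{load_config}}
#' @param seed overrides the protocol seed when non-NULL
#' @param out_dir output directory: run manifest (JSON), observable
#'   traces (CSV), final frame (XYZ) and log
#' @return the \code{mc_run}, invisibly
#' @export
run_from_config <- function(config, seed = NULL, out_dir = NULL) {
  if (!is.null(seed)) config$protocol$seed <- seed
  tpl <- do.call(build_caffeine_template, config$template)
  with_seed(config$protocol$seed, {
    st <- mc_state(tpl, config$box_length,
                   n = if (config$ensemble == "grand") 0 else config$n_molecules,
                   temperature = config$temperature,
                   salt = do.call(salt_field, config$salt),
                   ensemble = config$ensemble, activity = config$activity)
    moves <- move_params(translate = config$moves$translate,
                         rotate = config$moves$rotate,
                         cluster_translate = config$moves$cluster_translate,
                         cluster_rotate = config$moves$cluster_rotate,
                         cluster_threshold = config$moves$cluster_threshold,
                         w_translate = config$moves$w_translate,
                         w_cluster = config$moves$w_cluster,
                         w_gc = if (config$ensemble == "grand")
                           config$moves$w_gc else 0)
    run <- run_mc(st, moves, do.call(run_protocol, config$protocol))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(run$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_xyz(list(state_bead_coords(run$state)),
              file.path(out_dir, "final.xyz"), run$state$box_length)
    if (length(run$energy_trace))
      utils::write.csv(data.frame(sample = seq_along(run$energy_trace),
                                  energy = run$energy_trace),
                       file.path(out_dir, "energy.csv"), row.names = FALSE)
    if (length(run$density_trace))
      utils::write.csv(data.frame(sample = seq_along(run$density_trace),
                                  n = run$density_trace),
                       file.path(out_dir, "density.csv"), row.names = FALSE)
    if (run$rdf_frames > 0) {
      gr <- rdf(run)
      utils::write.csv(gr, file.path(out_dir, "rdf.csv"),
                       row.names = FALSE)
    }
    writeLines(c(sprintf("seed %d", config$protocol$seed),
                 utils::capture.output(print(run$acceptance))),
               file.path(out_dir, "run.log"))
  }
  invisible(run)
}
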