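# Configuration, file I/O and the run_command() entry point tying the
# analysis stages into reproducible runs. Angles are degrees and energies mJ
# in every file; every run writes a JSON manifest (package version, command,
# parameters, seed) sufficient to reproduce it exactly.

BODY_CONFIG_KEYS <- list(
  animal = c("schema_version", "model", "mass", "dimensions", "wing_mass",
             "wing_cut_height", "hinge_frac"),
  ellipsoid = c("schema_version", "model", "mass", "dimensions"),
  robot = c("schema_version", "model", "semi_axes", "part_masses", "placement"))

#' Read a body-model configuration (YAML)
#'
#' Versioned schema; unknown keys are rejected. `model` selects the builder:
#' `"animal"` (rigid ellipsoid + wing shell slices), `"ellipsoid"` (plain
#' solid ellipsoid) or `"robot"` (shell + motors + pendulum-leg composite).
#' Dimensions are full lengths in mm (`length`, `width`, `thickness`),
#' masses in g.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return An [articulated_body()].
#' @export
read_body_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$schema_version) || cfg$schema_version != 1) {
    rlang::abort("body config must declare schema_version: 1",
                 class = "selfright_config_error")
  }
  model <- cfg$model %||% rlang::abort("body config must name a model",
                                       class = "selfright_config_error")
  if (!model %in% names(BODY_CONFIG_KEYS)) {
    rlang::abort(paste("unknown model type:", model),
                 class = "selfright_config_error")
  }
  unknown <- setdiff(names(cfg), BODY_CONFIG_KEYS[[model]])
  if (length(unknown)) {
    rlang::abort(paste("unknown body config keys:", paste(unknown, collapse = ", ")),
                 class = "selfright_config_error")
  }
  spec_from_dims <- function() {
    d <- cfg$dimensions
    if (is.null(d$length) || is.null(d$width) || is.null(d$thickness)) {
      rlang::abort("dimensions must give length, width, thickness (mm)",
                   class = "selfright_config_error")
    }
    ellipsoid_spec(d$length / 2, d$width / 2, d$thickness / 2, cfg$mass)
  }
  switch(model,
    animal = build_animal_model(spec_from_dims(),
                                wing_mass = cfg$wing_mass %||% 0,
                                wing_cut_height = cfg$wing_cut_height %||% 0.5,
                                hinge_frac = cfg$hinge_frac %||% 0.5),
    ellipsoid = build_ellipsoid_body(spec_from_dims()),
    robot = {
      pm <- unlist(cfg$part_masses %||% robot_part_masses())
      build_robot_model(semi_axes = unlist(cfg$semi_axes %||% c(130, 110, 21.5)),
                        part_masses = pm,
                        placement = cfg$placement %||% list())
    })
}

#' Write a body-model configuration to YAML
#' @param config A config list (see [read_body_config()]).
#' @param path Output path.
#' @export
write_body_config <- function(config, path) {
  read_body_config(config)  # validate before writing
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Export a landscape grid to long-form CSV
#'
#' Columns `theta_wing_deg`, `pitch_deg`, `roll_deg`, `z_com_mm`,
#' `energy_mJ`; values round-trip at full double precision.
#' @param grid A `landscape_grid`.
#' @param path Output CSV path.
#' @export
write_landscape_csv <- function(grid, path) {
  readr::write_csv(tidy(grid), path)
  invisible(path)
}

#' Read a landscape grid from long-form CSV
#' @param path CSV written by [write_landscape_csv()].
#' @param mass,gravity Body mass (g) and gravity (m/s^2) to attach; inferred
#'   from energy = m g z if omitted.
#' @export
read_landscape_csv <- function(path, mass = NULL, gravity = 9.81) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  pitch <- sort(unique(df$pitch_deg))
  roll <- sort(unique(df$roll_deg))
  o <- order(df$roll_deg, df$pitch_deg)
  Z <- matrix(df$z_com_mm[o], length(pitch), length(roll))
  E <- matrix(df$energy_mJ[o], length(pitch), length(roll))
  if (is.null(mass)) {
    k <- which.max(df$z_com_mm)
    mass <- df$energy_mJ[k] / (gravity * df$z_com_mm[k] * 1e-3)
  }
  structure(
    list(pitch = pitch, roll = roll, z_com = Z, energy = E,
         theta_wing = df$theta_wing_deg[1], theta_leg = 0,
         mass = mass, gravity = gravity, ground = FALSE,
         body_name = "from_csv"),
    class = "landscape_grid")
}

#' Read an orientation trace CSV
#'
#' Expects columns `time_s`, `yaw_deg`, `pitch_deg`, `roll_deg`.
#' @param path CSV path.
#' @export
read_orientation_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "yaw_deg", "pitch_deg", "roll_deg")
  if (!all(need %in% names(df))) {
    rlang::abort(paste("orientation CSV needs columns:",
                       paste(need, collapse = ", ")),
                 class = "selfright_config_error")
  }
  df
}

#' Read a long-form marker-track CSV
#'
#' Expects columns `time_s`, `marker`, `x_mm`, `y_mm`, `z_mm`.
#' @param path CSV path.
#' @export
read_track_csv <- function(path) {
  marker_track(readr::read_csv(path, show_col_types = FALSE))
}

#' Run one pipeline command with on-disk inputs and outputs
#'
#' @param config A named list (`RunConfig`):
#'   * `command`: one of `"landscape"`, `"barriers"`, `"energetics"`,
#'     `"correlate"`, `"similarity"`, `"simulate"`, `"synth"`;
#'   * `body`: body-config YAML path or list (where required);
#'   * `out_dir`: output directory (created if missing);
#'   * `seed`: integer seed, recorded in the manifest;
#'   * command-specific parameters (grid steps, input CSV paths,
#'     amplitudes), see the individual functions.
#' @return Invisibly, a list with `status = 0` and the written `artifacts`.
#'   Any failure removes partial outputs and signals a classed error.
#' @export
run_command <- function(config) {
  command <- config$command %||%
    rlang::abort("config$command is required", class = "selfright_config_error")
  out_dir <- config$out_dir %||%
    rlang::abort("config$out_dir is required", class = "selfright_config_error")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p)
    written <<- c(written, p)
    p
  }
  result <- tryCatch({
    switch(command,
      landscape = {
        body <- read_body_config(config$body)
        g <- compute_landscape(body, config$theta_wing %||% 0,
                               config$pitch_step %||% 1,
                               config$roll_step %||% config$pitch_step %||% 1,
                               config$theta_leg %||% 0)
        emit(tidy(g), "landscape.csv")
        emit(find_minima(g), "minima.csv")
      },
      barriers = {
        body <- read_body_config(config$body)
        tw <- config$theta_wing_grid %||% seq(0, 90, by = 5)
        cv <- barriers_vs_wing_opening(body, tw,
                                       pitch_step = config$pitch_step %||% 1,
                                       psi_step = config$psi_step %||% 1)
        emit(tibble::as_tibble(cv), "barrier_curves.csv")
      },
      energetics = {
        track <- read_track_csv(config$track_csv)
        model <- animal_ke_model(
          spec = if (!is.null(config$body)) {
            d <- read_body_config(config$body)
            ellipsoid_spec(d$parts[[1]]$dims$a, d$parts[[1]]$dims$b,
                           d$parts[[1]]$dims$c, d$total_mass)
          } else animal_spec(),
          sphere_mass = config$sphere_mass %||% 0)
        tr <- filter_track(track, config$cutoff %||% 25, config$order %||% 6)
        trace <- ke_pitch_roll(animal_segment_states(tr, model))
        emit(trace, "energy_trace.csv")
      },
      correlate = {
        f <- readr::read_csv(config$f_csv, show_col_types = FALSE)
        g2 <- readr::read_csv(config$g_csv %||% config$f_csv,
                              show_col_types = FALSE)
        rate <- 1 / stats::median(diff(f[[1]]))
        emit(xcorr_normalized(f[[2]], g2[[2]], rate), "correlation.csv")
      },
      similarity = {
        an <- config$animal; rb <- config$robot
        sf <- scale_factors(similarity_spec(an$mass, an$density),
                            similarity_spec(rb$mass, rb$density))
        emit(sf, "similarity.csv")
      },
      simulate = {
        body <- read_body_config(config$body)
        curves <- barriers_vs_wing_opening(
          body, config$theta_wing_grid %||% seq(0, 90, by = 10),
          pitch_step = config$pitch_step %||% 2,
          psi_step = config$psi_step %||% 3)
        ens <- simulate_attempts(curves, config$theta_wing %||% 72,
                                 config$theta_leg %||% 30,
                                 ke_coef = config$ke_coef %||% 40 / 45^2,
                                 cv = config$cv %||% 0.3,
                                 n = config$n %||% 1000, seed = seed)
        emit(ens$attempts, "attempts.csv")
        emit(glance(ens), "ensemble_summary.csv")
      },
      synth = {
        sp <- synth_spec(seed = seed,
                         noise_sd = config$noise_sd %||% 0.1,
                         duration = config$duration %||% 0.5,
                         sphere_mass = config$sphere_mass %||% 0.14)
        mt <- gen_marker_tracks(sp)
        emit(tibble::as_tibble(mt$track), "markers.csv")
        emit(tibble::as_tibble(mt$truth), "truth.csv")
        ot <- gen_orientation_trace(sp, config$outcome %||% "fail")
        emit(ot$trace, "orientation.csv")
        emit(ot$wing, "wing_profile.csv")
      },
      rlang::abort(paste("unknown command:", command),
                   class = "selfright_config_error"))
    manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(
      list(package = "selfright",
           version = as.character(utils::packageVersion("selfright")),
           command = command, seed = seed,
           params = config[setdiff(names(config), c("command", "out_dir"))]),
      manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
    written <- c(written, manifest)
    list(status = 0L, artifacts = written)
  }, error = function(e) {
    unlink(written)
    rlang::abort(paste("run_command failed:", conditionMessage(e)),
                 class = "selfright_run_error", parent = e)
  })
  invisible(result)
}
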