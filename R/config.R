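# Configuration and reproduction driver. All physical constants live here
# with explicit SI unit suffixes (_m, _N, _W, _m_s) in key names; every value
# can be overridden from a YAML file, and load_config() records which keys
# were user-set versus defaulted.

#' Default run configuration
#'
#' The full set of model constants: cuboid dimensions, drag measurement
#' source and fit options, energetics constants, fin kinematics, scenario
#' and elongation sweeps, the pitch grid, active-sensing baseline, seed and
#' output directory. Defaults are the reference study conditions (see the
#' methods vignette); `theta_max_rad` (0.524 rad, ~30 degrees) is a typical
#' undulation excursion supplied here, in the config layer, because thrust
#' magnitudes — unlike thrust ratios — depend on it.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    cuboid = list(height_m = 0.125, length_m = 0.269, width_m = 0.116,
                  label = "electrosensory"),
    drag = list(
      measurements_csv = NULL,     # NULL -> packaged measured tow table
      velocity_exponent = 2,
      v_ref_m_s = 0.15,
      # measured forces are paired to angles monotonically; the pairing is
      # config data, not code
      pitch_assignment_deg = c(0, 15, 30)
    ),
    energetics = list(thrust_power_W = 0.3e-3,
                      prey_density_per_m3 = 5e3,
                      prey_energy_J = c(1, 2)),
    fin = list(theta_max_rad = 0.524,
               freq_hz = c(2, 3, 4, 5, 6),
               fin_length_m = 0.127,
               fin_height_m = 0.01,
               wavelength_m = 0.127 / 2,
               C_const = 86.03,
               rho_water_kg_m3 = 1000,
               heave_ratio = 0.25,
               fin_base_deg = rad2deg(atan(0.25))),
    scenarios = c("natural", "clamp_area", "clamp_drag"),
    elongation_factors = c(1.0, 4.0),  # the natural L/H is always included
    pitch = list(min_deg = 0, max_deg = 85, step_deg = 0.1),
    synthetic = list(pitch_deg = c(0, 15, 30),
                     speeds_m_s = c(0.10, 0.12, 0.15),
                     replicates = 10,
                     noise_sd_N = 0.45e-3,
                     heteroscedastic = FALSE),
    active_sensing = list(baseline_J = 80, range_old_m = 0.03,
                          range_new_m = 0.06),
    seed = 1L,
    out_dir = "pitchsense-output"
  )
}

collect_unknown_keys <- function(user, def, path = character()) {
  bad <- character(0)
  for (nm in names(user)) {
    here <- paste(c(path, nm), collapse = "$")
    if (!nm %in% names(def)) {
      bad <- c(bad, here)
    } else if (is.list(user[[nm]]) && is.list(def[[nm]])) {
      bad <- c(bad, collect_unknown_keys(user[[nm]], def[[nm]], c(path, nm)))
    }
  }
  bad
}

leaf_paths <- function(x, path = character()) {
  if (!is.list(x)) return(paste(path, collapse = "$"))
  unlist(lapply(names(x), function(nm) leaf_paths(x[[nm]], c(path, nm))),
         use.names = FALSE)
}

positive_leaves <- c(
  "cuboid$height_m", "cuboid$length_m", "cuboid$width_m",
  "drag$velocity_exponent", "drag$v_ref_m_s",
  "energetics$thrust_power_W", "energetics$prey_density_per_m3",
  "energetics$prey_energy_J",
  "fin$fin_length_m", "fin$fin_height_m", "fin$wavelength_m",
  "fin$C_const", "fin$rho_water_kg_m3",
  "pitch$step_deg",
  "synthetic$replicates",
  "active_sensing$baseline_J", "active_sensing$range_old_m",
  "active_sensing$range_new_m"
)

get_path <- function(cfg, path) {
  for (nm in strsplit(path, "$", fixed = TRUE)[[1]]) cfg <- cfg[[nm]]
  cfg
}

validate_config <- function(cfg) {
  bad <- character(0)
  for (p in positive_leaves) {
    v <- get_path(cfg, p)
    if (is.null(v) || any(!is.finite(v)) || any(v <= 0)) bad <- c(bad, p)
  }
  for (p in c("fin$theta_max_rad", "synthetic$noise_sd_N")) {
    v <- get_path(cfg, p)
    if (is.null(v) || any(!is.finite(v)) || any(v < 0)) bad <- c(bad, p)
  }
  if (length(bad)) {
    stop_config("non-positive or non-finite physical constant(s): ",
                paste(bad, collapse = ", "))
  }
  if (!all(cfg$scenarios %in% c("natural", "clamp_area", "clamp_drag"))) {
    stop_config("scenarios must be drawn from natural, clamp_area, clamp_drag")
  }
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file, validates it against the [default_config()] schema
#' (unknown keys — including mistyped unit suffixes — raise an error listing
#' every offending key), merges it over the defaults, checks that physical
#' constants are positive, and records per-key provenance (`"user"` versus
#' `"default"`) in the `provenance` attribute. A missing or empty file
#' yields the full default configuration.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return A validated configuration list with a `provenance` attribute.
#' @export
load_config <- function(path = NULL) {
  def <- default_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop_config("config file must be a YAML mapping")
  }
  bad <- collect_unknown_keys(user, def)
  if (length(bad)) {
    stop_config("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  cfg <- modifyList(def, user)
  validate_config(cfg)
  user_leaves <- if (length(user)) leaf_paths(user) else character(0)
  prov <- setNames(rep("default", length(leaf_paths(def))), leaf_paths(def))
  prov[names(prov) %in% user_leaves] <- "user"
  attr(cfg, "provenance") <- prov
  cfg
}

config_tow_data <- function(cfg) {
  if (is.null(cfg$drag$measurements_csv)) {
    measured_tow_data()
  } else {
    read_tow_csv(cfg$drag$measurements_csv)
  }
}

#' Run the full default analysis pipeline
#'
#' Fits the drag law from the configured tow measurements, then writes to
#' `out_dir`: projected-area curves and energy curves for every scenario and
#' elongation factor, the thrust-versus-pitch family, the active-sensing
#' range-scaling table, and `summary.json` with the headline quantities
#' (reference thrust power, energy per prey at neutral pitch, area ratios at
#' 30 degrees and at the maximizing pitch, the natural elongation factor,
#' the movable-sensorium saving factor, the optimal pitch, and the
#' fourth-power range-scaling numbers). Every summary value is computed by
#' the package's functions at run time. Outputs are deterministic given the
#' configuration (filenames fixed, no timestamps).
#'
#' @param config a configuration list from [load_config()] /
#'   [default_config()].
#' @param out_dir output directory; created (with a message) if missing.
#'   Defaults to `config$out_dir`.
#' @return Invisibly, a list with `summary` (the headline quantities) and
#'   `files` (paths written).
#' @export
reproduce <- function(config = load_config(), out_dir = config$out_dir) {
  validate_config(config)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory: ", out_dir)
  }
  set.seed(config$seed)

  cub <- cuboid_sensorium(config$cuboid$height_m, config$cuboid$length_m,
                          config$cuboid$width_m, config$cuboid$label)
  tow <- config_tow_data(config)
  if (length(unique(tow$speed_m_s)) > 1L) {
    tow <- normalize_tow_speed(tow, config$drag$v_ref_m_s,
                               config$drag$velocity_exponent)
  }
  fit <- fit_drag_curve(tow, velocity_exponent = config$drag$velocity_exponent)
  message(sprintf("drag fit covers pitch <= %g deg; larger angles are extrapolated",
                  fit$max_fit_pitch_deg))
  ecfg <- energetics_config(config$energetics$thrust_power_W,
                            config$energetics$prey_density_per_m3,
                            config$energetics$prey_energy_J)
  grid <- seq(config$pitch$min_deg, config$pitch$max_deg,
              by = config$pitch$step_deg)
  elong <- sort(unique(c(config$elongation_factors, elongation_factor(cub))))

  files <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    files[[length(files) + 1L]] <<- p
    p
  }

  # area curves per elongation factor
  areas <- do.call(rbind, lapply(elong, function(e) {
    cbind(elongation = e, area_curve(with_elongation(cub, e), grid))
  }))
  put(areas, "area_curves.csv")

  # energy curves: scenario x elongation
  energies <- do.call(rbind, lapply(config$scenarios, function(sc) {
    do.call(rbind, lapply(elong, function(e) {
      ec <- energy_curve(ecfg, fit, with_elongation(cub, e),
                         search_scenario(sc), grid)
      cbind(scenario = sc, elongation = e, as.data.frame(ec))
    }))
  }))
  put(energies, "energy_curves.csv")

  # thrust family
  fin <- fin_kinematics(theta_max_rad = config$fin$theta_max_rad,
                        fin_length_m = config$fin$fin_length_m,
                        fin_height_m = config$fin$fin_height_m,
                        wavelength_m = config$fin$wavelength_m,
                        C_const = config$fin$C_const,
                        rho_water_kg_m3 = config$fin$rho_water_kg_m3,
                        heave_ratio = config$fin$heave_ratio,
                        fin_base_deg = config$fin$fin_base_deg)
  put(thrust_curve(fin, config$fin$freq_hz, seq(0, 90, by = 1)),
      "thrust_curves.csv")

  # active-sensing range scaling
  as_cfg <- config$active_sensing
  mult <- c(1, 1.5, 2, 3)
  put(data.frame(
    range_m = as_cfg$range_old_m * mult,
    range_multiple = mult,
    energy_factor = active_sensing_energy_factor(as_cfg$range_old_m * mult,
                                                 as_cfg$range_old_m),
    energy_J = active_sensing_energy_cost(as_cfg$baseline_J,
                                          as_cfg$range_old_m * mult,
                                          as_cfg$range_old_m)
  ), "active_sensing.csv")

  # headline summary — every number computed by the operations above
  a_max <- area_maximizing_pitch(cub)
  nat <- search_scenario("natural")
  e0 <- energy_per_prey(ecfg, fit, cub, 0, nat)
  opt <- optimal_pitch(ecfg, fit, cub, nat, grid)
  e_opt <- energy_per_prey(ecfg, fit, cub, opt, nat)
  e_clamp_max <- energy_per_prey(ecfg, fit, cub, a_max,
                                 search_scenario("clamp_drag"))
  summary <- list(
    reference_thrust_power_mW = reference_thrust_power(fit) * 1e3,
    energy_per_prey_0deg_uJ = e0 * 1e6,
    area_ratio_30deg_pct = 100 * area_ratio(cub, 30),
    area_max_pitch_deg = a_max,
    area_ratio_max_pct = 100 * area_ratio(cub, a_max),
    elongation_factor = elongation_factor(cub),
    optimal_pitch_deg = opt,
    energy_at_optimal_pitch_uJ = e_opt * 1e6,
    energy_saving_at_optimum_pct = 100 * (1 - e_opt / e0),
    movable_sensorium_saving_factor = e0 / e_clamp_max,
    active_sensing_doubling_factor =
      active_sensing_energy_factor(as_cfg$range_new_m, as_cfg$range_old_m),
    active_sensing_doubling_cost_J =
      active_sensing_energy_cost(as_cfg$baseline_J, as_cfg$range_new_m,
                                 as_cfg$range_old_m)
  )
  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sj, auto_unbox = TRUE, digits = NA)
  files[[length(files) + 1L]] <- sj

  invisible(list(summary = summary, files = unlist(files)))
}
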