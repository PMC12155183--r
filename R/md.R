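#' MD run configuration
#'
#' @param n_molecules number of water molecules (>= 2)
#' @param density g/cm^3; the cubic box edge follows from
#'   `L = (n M_w / (N_A rho))^(1/3)`. Reference state points: 0.997 (26 C),
#'   0.994 (34 C), 0.969 (103 C under 25 MPa).
#' @param target_temperature K
#' @param timestep fs (default 0.1)
#' @param n_production_steps production steps (strict NVE)
#' @param annealing data.frame with columns `temperature` (K) and `steps`;
#'   NULL selects the default three-stage schedule (target+150, target+50,
#'   target) with `annealing_stage_steps` steps each.
#' @param annealing_stage_steps steps per default annealing stage
#' @param rescale_every velocity-rescaling interval during annealing, steps
#' @param store_interval fs between stored frames (default 1)
#' @param seed RNG seed for placement and initial velocities
#' @param integrator `"velocity-verlet"` (default) or `"yoshida4"`, a
#'   4th-order symplectic composition of velocity-Verlet substeps at the same
#'   timestep (three force evaluations per step; tighter energy conservation)
#' @return object of class `md_config`
#' @export
md_config <- function(n_molecules, density = 0.997, target_temperature = 299,
                      timestep = 0.1, n_production_steps = 10000,
                      annealing = NULL, annealing_stage_steps = 2000,
                      rescale_every = 50, store_interval = 1, seed = 1,
                      integrator = c("velocity-verlet", "yoshida4")) {
  stopifnot(n_molecules >= 2, density > 0, target_temperature > 0,
            timestep > 0, n_production_steps >= 1,
            store_interval >= timestep - 1e-12)
  integrator <- match.arg(integrator)
  if (is.null(annealing)) {
    # cool through two hot stages, then hold at the target long enough for
    # structural relaxation so production shows no temperature trend
    annealing <- data.frame(
      temperature = target_temperature + c(150, 50, 0),
      steps = annealing_stage_steps * c(1, 1, 6))
  }
  if (nrow(annealing) > 0)
    stopifnot(all(annealing$temperature > 0), all(annealing$steps >= 0))
  structure(list(
    n_molecules = n_molecules, density = density,
    target_temperature = target_temperature, timestep = timestep,
    n_production_steps = n_production_steps, annealing = annealing,
    rescale_every = rescale_every, store_interval = store_interval,
    seed = seed, integrator = integrator
  ), class = "md_config")
}

#' Box edge length from molecule count and density
#' @param n_molecules number of molecules
#' @param density g/cm^3
#' @return edge length, nm
#' @export
box_edge_from_density <- function(n_molecules, density) {
  wc <- water_constants
  v_cm3 <- n_molecules * wc$M_water / (wc$N_A * density)
  (v_cm3)^(1 / 3) * 1e7  # cm -> nm
}

# gas-phase molecule geometry: O at origin, H's in the xz plane
gas_phase_sites <- function(params) {
  th <- params$theta_e_rad
  rbind(c(0, 0, 0),
        params$r_e * c(sin(th / 2), 0, cos(th / 2)),
        params$r_e * c(-sin(th / 2), 0, cos(th / 2)))
}

random_rotation <- function() {
  # uniform rotation via a normalized quaternion
  qv <- stats::rnorm(4)
  qv <- qv / sqrt(sum(qv^2))
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

#' Build an initial configuration of randomly placed gas-phase molecules
#'
#' Molecules at equilibrium gas-phase geometry are placed at random positions
#' and orientations in the box, rejecting placements that put any O-O pair
#' closer than `clash_distance`.
#'
#' @param n_molecules number of molecules (>= 2)
#' @param density g/cm^3
#' @param seed RNG seed
#' @param params a [potential_params()] (supplies the gas-phase geometry)
#' @param clash_distance minimum O-O distance, nm
#' @param max_tries placement attempts per molecule before giving up
#' @return an [md_frame()]
#' @export
build_initial_configuration <- function(n_molecules, density, seed = 1,
                                        params = potential_params(),
                                        clash_distance = 0.24,
                                        max_tries = 2000) {
  stopifnot(n_molecules >= 2, density > 0)
  L <- box_edge_from_density(n_molecules, density)
  box <- simulation_box(L)
  base <- gas_phase_sites(params)
  set.seed(seed)
  o_pos <- matrix(NA_real_, n_molecules, 3)
  pos <- matrix(NA_real_, 3 * n_molecules, 3)
  for (m in seq_len(n_molecules)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- stats::runif(3, 0, L)
      if (m > 1) {
        d <- minimum_image_displacement(
          o_pos[seq_len(m - 1), , drop = FALSE],
          matrix(cand, m - 1, 3, byrow = TRUE), box)
        if (min(sqrt(rowSums(d^2))) < clash_distance) next
      }
      R <- random_rotation()
      sites <- base %*% t(R)
      pos[3 * (m - 1) + 1:3, ] <- sweep(sites, 2, cand, `+`)
      o_pos[m, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed)
      stop("packing failed for molecule ", m,
           ": lower the density or the molecule count")
  }
  md_frame(pos, box, time = 0)
}

#' Sample Boltzmann velocities for a frame
#'
#' Per-site Gaussian components with variance k_B T / m; the net linear
#' momentum is removed afterwards.
#'
#' @param frame an [md_frame()]
#' @param temperature K (> 0)
#' @param seed RNG seed
#' @return the frame with velocities set
#' @export
sample_boltzmann_velocities <- function(frame, temperature, seed = 1) {
  stopifnot(inherits(frame, "md_frame"))
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive")
  set.seed(seed)
  n <- 3 * frame$n_molecules
  m <- site_masses(frame$n_molecules)
  sd_v <- sqrt(water_constants$kB * temperature *
                 water_constants$kJ_per_internal / m)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd_v
  mom <- colSums(v * m)
  v <- sweep(v, 2, mom / sum(m))
  frame$velocities <- v
  frame
}

#' Run an NVE simulation with annealing equilibration
#'
#' Velocity-Verlet integration at the configured timestep. Velocity rescaling
#' is applied only during the annealing schedule; the production run is
#' strictly NVE. Frames (positions and velocities) are stored every
#' `store_interval` fs; the energy report covers the production run only.
#'
#' @param config an [md_config()]
#' @param params a [potential_params()]
#' @param initial_frame optional starting [md_frame()] with velocities; when
#'   NULL, a configuration is built and Boltzmann velocities are drawn at the
#'   first annealing temperature (or the target when the schedule is empty).
#' @return list with `trajectory` (a [water_trajectory()]) and `energy`
#'   (an `energy_report`)
#' @export
run_nve <- function(config, params = potential_params(), initial_frame = NULL) {
  stopifnot(inherits(config, "md_config"))
  if (is.null(initial_frame)) {
    frame <- build_initial_configuration(config$n_molecules, config$density,
                                         seed = config$seed, params = params)
    T0 <- if (nrow(config$annealing) > 0) config$annealing$temperature[1]
          else config$target_temperature
    frame <- sample_boltzmann_velocities(frame, T0, seed = config$seed + 1)
  } else {
    frame <- initial_frame
    if (is.null(frame$velocities))
      stop("initial_frame must carry velocities")
  }
  params <- resolve_potential_params(params, frame$box)
  q <- site_charges(frame$n_molecules, params$q_H)
  m <- site_masses(frame$n_molecules)
  anneal <- cbind(config$annealing$temperature, config$annealing$steps,
                  rep(config$rescale_every, nrow(config$annealing)))
  if (nrow(config$annealing) == 0) anneal <- matrix(0, 0, 3)
  store_every <- max(1L, as.integer(round(config$store_interval / config$timestep)))
  res <- .cpp_run_md(frame$positions, frame$velocities, m, q, unclass(params),
                     frame$box$edge_length, config$timestep, anneal,
                     as.integer(config$n_production_steps), store_every,
                     store_every,
                     if (identical(config$integrator, "yoshida4")) 1L else 0L)
  traj <- water_trajectory(res$positions, frame$box, res$times,
                           velocities = res$velocities)
  energy <- as.data.frame(res$energy)
  report <- structure(list(
    energy = energy,
    mean_temperature = mean(energy$T_inst),
    sd_temperature = stats::sd(energy$T_inst),
    dE_over_E = (max(energy$E_tot) - min(energy$E_tot)) / abs(mean(energy$E_tot)),
    target_temperature = config$target_temperature,
    n_production_steps = config$n_production_steps,
    timestep = config$timestep
  ), class = "energy_report")
  list(trajectory = traj, energy = report)
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("NVE production: %d steps at %g fs\n",
              x$n_production_steps, x$timestep))
  cat(sprintf("  temperature: (%.1f +/- %.1f) K (target %.1f K)\n",
              x$mean_temperature, x$sd_temperature, x$target_temperature))
  cat(sprintf("  total-energy stability dE/E = %.3g\n", x$dE_over_E))
  invisible(x)
}

#' Write an energy report as CSV (per-step table) plus JSON summary
#' @param report an `energy_report` from [run_nve()]
#' @param csv_path path for the per-step table
#' @param json_path optional path for the JSON summary
#' @return `csv_path`, invisibly
#' @export
write_energy_report <- function(report, csv_path, json_path = NULL) {
  stopifnot(inherits(report, "energy_report"))
  utils::write.csv(report$energy, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      mean_temperature = report$mean_temperature,
      sd_temperature = report$sd_temperature,
      dE_over_E = report$dE_over_E,
      target_temperature = report$target_temperature,
      n_production_steps = report$n_production_steps,
      timestep_fs = report$timestep
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
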