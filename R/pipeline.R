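## End-to-end orchestration: simulate a cohort, build and register maps, test
## reproducibility, quantify domains and coverage, analyze coupling networks
## and arrest behavior, and write every numeric result to an output
## directory. Used by the command-line wrapper (inst/scripts) and by the
## determinism tests.

pipeline_protocols <- function(cfg) {
  p <- cfg$protocol
  base <- function(direction) stim_protocol(
    frame_rate_hz = p$frame_rate_hz, f_stim_hz = p$f_stim_hz,
    f_rot_rpm = p$f_rot_rpm, f_analysis_hz = p$f_analysis_hz,
    n_repeats = p$n_repeats, n_cycles = p$n_cycles,
    span_azimuth_deg = p$span_azimuth_deg,
    span_elevation_deg = p$span_elevation_deg, direction = direction)
  list(azimuth = base("rightward"), elevation = base("downward"),
       orientation = base("ccw"))
}

# simulate one animal's sessions and reconstruct its maps
simulate_animal_maps <- function(cfg, seed, with_orientation = TRUE) {
  prots <- pipeline_protocols(cfg)
  grid <- cfg$imaging$grid
  one_axis <- function(axis) {
    prot <- prots[[axis]]
    span <- if (axis == "azimuth") prot$span_azimuth_deg
            else prot$span_elevation_deg
    truth <- imaging_truth(
      position_map_deg = gradient_position_map(grid, span, axis),
      delay_s = 1.5, noise_sd = cfg$sim$noise_sd,
      drift_amp = cfg$sim$drift_amp, seed = seed)
    ses <- make_retinotopy_sessions(truth, prot)
    fwd <- extract_fourier_component(
      remove_slow_components(ses$forward, prot$f_stim_hz), prot$f_stim_hz)
    rev <- extract_fourier_component(
      remove_slow_components(ses$reverse, prot$f_stim_hz), prot$f_stim_hz)
    retinotopy_from_pair(fwd, rev, span, axis)
  }
  out <- list(azimuth = one_axis("azimuth"),
              elevation = one_axis("elevation"))
  if (with_orientation) {
    prot <- prots$orientation
    truth <- imaging_truth(
      orientation_map_deg = patch_orientation_map(grid),
      delay_s = 1.5, noise_sd = cfg$sim$noise_sd,
      drift_amp = cfg$sim$drift_amp, seed = seed + 5000L)
    ses <- make_orientation_sessions(truth, prot)
    ccw <- extract_fourier_component(
      remove_slow_components(ses$ccw, prot$f_analysis_hz),
      prot$f_analysis_hz)
    cw <- extract_fourier_component(
      remove_slow_components(ses$cw, prot$f_analysis_hz),
      prot$f_analysis_hz)
    out$orientation <- orientation_from_pair(ccw, cw)
  }
  out
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates a cohort of animals (retinotopy and orientation sessions),
#' reconstructs and registers their maps, computes pixel-wise
#' Moore-Rayleigh reproducibility, selective-domain fractions and
#' visual-field coverage, simulates dye-coupling networks across injection
#' depths and summarizes their geometry, simulates arrest-assay trials and
#' summarizes the speed-modulation index. All numeric outputs are written as
#' TSV/JSON under `out_dir` together with a run log (seed, configuration,
#' package versions); rerunning with the same configuration and seed
#' produces byte-identical numeric outputs.
#'
#' @param cfg a [default_config()]-style configuration. The optional entries
#'   `sim$n_animals` (default 5), `sim$noise_sd`, `sim$drift_amp`,
#'   `sim$n_networks`, `sim$n_trials` control the simulation scale.
#' @param out_dir output directory (created if missing), or `NULL` to skip
#'   writing.
#' @param stages character vector of stages to run, subset of
#'   `c("maps", "coupling", "behavior")`; `"all"` selects everything.
#' @return a list of results per stage, invisibly when writing.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = NULL,
                         stages = "all") {
  if (identical(stages, "all")) stages <- c("maps", "coupling", "behavior")
  sim <- cfg$sim
  if (is.null(sim)) sim <- list()
  sim$n_animals <- sim$n_animals %||% 5L
  sim$noise_sd <- sim$noise_sd %||% 0.3
  sim$drift_amp <- sim$drift_amp %||% 1
  sim$n_networks <- sim$n_networks %||% 20L
  sim$n_trials <- sim$n_trials %||% 6L
  cfg$sim <- sim
  seed <- as.integer(cfg$seed)
  res <- list()

  if ("maps" %in% stages) {
    animals <- lapply(seq_len(sim$n_animals), function(k)
      simulate_animal_maps(cfg, seed + k))
    reg <- register_group(lapply(animals, function(a)
      list(azimuth = a$azimuth, elevation = a$elevation)))
    avg_az <- average_registered_maps(reg$azimuth)
    border <- detect_structure_border(avg_az$magnitude)
    az <- pixelwise_reproducibility(reg$azimuth, cfg$stats$alpha, border,
                                    cfg$stats$n_mc, seed)
    el <- pixelwise_reproducibility(reg$elevation, cfg$stats$alpha, border,
                                    cfg$stats$n_mc, seed)
    ori_group <- apply_transforms(lapply(animals, `[[`, "orientation"),
                                  reg$transforms)
    ori <- pixelwise_reproducibility(ori_group, cfg$stats$alpha, border,
                                     cfg$stats$n_mc, seed)
    res$maps <- list(
      transforms = reg$transforms,
      domains = list(
        azimuth = selective_domain_fraction(az, cfg$imaging$pixel_pitch_um),
        elevation = selective_domain_fraction(el,
                                              cfg$imaging$pixel_pitch_um),
        orientation = selective_domain_fraction(
          ori, cfg$imaging$pixel_pitch_um)),
      coverage = visual_field_coverage(az, el, cfg$coverage$cell_deg),
      delay_estimate_s = mean(vapply(animals, function(a)
        a$azimuth$delay_estimate_s, numeric(1))))
  }

  if ("coupling" %in% stages) {
    depths <- seq(100, 600, length.out = sim$n_networks)
    nets <- lapply(seq_along(depths), function(i)
      make_coupling_network(300, 200, 200, depths[i],
                            seed = seed + 100L + i))
    ext <- lapply(nets, function(nw)
      directional_extents(nw$network, "max"))
    reg_d <- extent_vs_depth_regression(
      depths, vapply(ext, `[[`, numeric(1), "dorsal"))
    reg_v <- extent_vs_depth_regression(
      depths, vapply(ext, `[[`, numeric(1), "ventral"))
    res$coupling <- list(
      n_cells = vapply(nets, function(nw)
        count_coupled_cells(nw$network), integer(1)),
      ratio_mean = mean(vapply(ext, function(e)
        directional_ratio(e), numeric(1))),
      dorsal_regression = unclass(reg_d)[c("slope", "intercept", "R_squared",
                                           "F_statistic", "p_value")],
      ventral_regression = unclass(reg_v)[c("slope", "intercept",
                                            "R_squared", "F_statistic",
                                            "p_value")])
  }

  if ("behavior" %in% stages) {
    b <- cfg$behavior
    cm_per_px <- NULL  # generator tracks carry their own px_per_cm
    indices <- vapply(seq_len(sim$n_trials), function(k) {
      tr <- make_arrest_trajectory(v_baseline_cms = 10,
                                   arrest_fraction = 0.8,
                                   flash_time_s = 10, duration_s = 20,
                                   noise_sd = 1, dropout_rate = 0.02,
                                   seed = seed + 200L + k)
      cleaned <- clean_track(tr$track, b$likelihood_threshold,
                             b$smooth_window)
      sp <- compute_speed(cleaned, "barycenter", b$sg_window, b$sg_order)
      arrest_metrics(sp, tr$flash_onsets_s[1],
                     b$baseline_window_s, b$arrest_delay_s,
                     b$arrest_window_s, b$min_baseline_cms)$modulation_index
    }, numeric(1))
    res$behavior <- c(group_summary(indices), list(indices = indices))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    summarize <- res
    if (!is.null(summarize$maps))
      summarize$maps$coverage$grid <-
        summarize$maps$coverage$points <- NULL
    jsonlite::write_json(summarize, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log <- list(seed = seed,
                config = unclass(cfg),
                r_version = R.version.string,
                package_version =
                  as.character(utils::packageVersion("collimap")),
                stages = stages)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
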