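default_scenario <- function() {
  list(
    name = "custom",
    seed = 1L,
    stages = c("kinetics", "spectral", "fcs", "gp", "flim"),
    kinetics = list(k_blue = 0.04, k_bleach_red = 0.12, k_bleach_blue = 0,
                    brightness_ratio_blue = 0.02, replenishment = FALSE,
                    n_frames = 30L),
    spectrum = list(lambda_max_red = 660, w_red = 55, shift_nm = 22,
                    w_blue = 55, a = 0.24, blue_emission_ratio = 1,
                    total_counts = 2e5, frames = c(0L, 2L, 5L, 10L, 20L, 30L),
                    poisson = TRUE),
    trace = list(n_molecules = 5, omega0 = 240, diffusion_coeff = 1,
                 box_size = 1500, T = 0, tau_triplet = 5e-6,
                 counts_per_molecule = 3e4, bin_time = 1e-4, duration = 10),
    # two measurements per spot in each of three independent experiments
    fcs = list(frames = c(0L, 10L), m = 16L, n_segments = 10L,
               n_repeats = 6L),
    image = list(gp_true = 0.2, counts = 500, dims = c(48L, 48L),
                 threshold_fraction = 0.2, background_fraction = 0.02,
                 saturation = 65535),
    flim = list(dyes_per_antibody = 2L, tau_unquenched = 3.5,
                tau_quenched = 2.3, bleach_prob = 0.12,
                yield_quenched = 0.35, n_antibodies = 4000L, n_frames = 10L,
                photons_per_unit_intensity = 2, method = "mean_arrival")
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    here <- if (nzchar(path)) paste0(path, "$", key) else key
    if (!key %in% names(base))
      stopf("unknown scenario config key: %s", here)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]]))
        stopf("config key %s must be a list", here)
      base[[key]] <- merge_config(base[[key]], override[[key]], here)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Build a scenario configuration
#'
#' A scenario is the full parameter tree for one simulate-and-analyze run:
#' sections `kinetics`, `spectrum`, `trace`, `fcs`, `image`, `flim`, plus
#' the stage list and the global seed (every per-stage random stream is
#' derived deterministically from it). Unknown keys are rejected.
#'
#' Note the two brightness parameters: `kinetics$brightness_ratio_blue` is
#' the molecular brightness of the photoblued species relative to reference
#' dyes under blue/green excitation (the FCS Q comparison, typically
#' 0.01-0.05), whereas `spectrum$blue_emission_ratio` is its relative
#' emission under the spectral-imaging excitation, where the photoblued
#' species can contribute up to half the collected emission.
#'
#' @param ... overrides of the default tree (named, possibly nested lists).
#' @param base configuration to override (default [scenario_preset()]
#'   defaults).
#' @return a validated `scenario_config` list.
#' @export
scenario_config <- function(..., base = default_scenario()) {
  cfg <- merge_config(base, list(...))
  unknown <- setdiff(cfg$stages,
                     c("kinetics", "spectral", "fcs", "gp", "flim"))
  if (length(unknown))
    stopf("unknown stage(s): %s", paste(unknown, collapse = ", "))
  structure(cfg, class = c("scenario_config", "list"))
}

#' Named scenario presets
#'
#' Presets encode the experimental arms as kinetic regimes:
#' \describe{
#'   \item{star_red_confocal}{strongly photoblueing red dye: ~20 percent of
#'     the initial pool converted after ten frames, blued species ~50x
#'     dimmer under 488 nm excitation.}
#'   \item{atto647n_confocal}{photoblueing red dye whose antibody conjugates
#'     additionally show the multi-dye quenching lifetime rise.}
#'   \item{atto655_confocal}{photostable control: negligible conversion.}
#'   \item{nr12a_cells}{standard membrane polarity probe; photoblueing
#'     biases the GP readout upward.}
#'   \item{nr4a_exchangeable}{exchangeable (PAINT-mode) version of the same
#'     probe: the pool is replenished every frame, no GP bias.}
#'   \item{oxygen_depleted}{star_red kinetics with the conversion rate
#'     suppressed tenfold (photoblueing needs oxygen); bleaching rates
#'     unchanged.}
#' }
#'
#' @param name preset name.
#' @param ... further overrides applied on top of the preset.
#' @return a `scenario_config`.
#' @export
scenario_preset <- function(name = c("star_red_confocal", "atto647n_confocal",
                                     "atto655_confocal", "nr12a_cells",
                                     "nr4a_exchangeable", "oxygen_depleted"),
                            ...) {
  name <- match.arg(name)
  base <- switch(name,
    star_red_confocal = scenario_config(name = name),
    atto647n_confocal = scenario_config(
      name = name,
      kinetics = list(k_blue = 0.035, k_bleach_red = 0.1)),
    atto655_confocal = scenario_config(
      name = name,
      kinetics = list(k_blue = 0.002, k_bleach_red = 0.04)),
    nr12a_cells = scenario_config(
      name = name,
      stages = c("kinetics", "gp"),
      kinetics = list(k_blue = 0.04, k_bleach_red = 0.03,
                      k_bleach_blue = 0.01, brightness_ratio_blue = 1),
      spectrum = list(lambda_max_red = 635, shift_nm = 25)),
    nr4a_exchangeable = scenario_config(
      name = name,
      stages = c("kinetics", "gp"),
      kinetics = list(k_blue = 0.04, k_bleach_red = 0.03,
                      k_bleach_blue = 0.01, brightness_ratio_blue = 1,
                      replenishment = TRUE),
      spectrum = list(lambda_max_red = 635, shift_nm = 25)),
    oxygen_depleted = scenario_config(
      name = name,
      kinetics = list(k_blue = 0.004))
  )
  if (...length()) scenario_config(..., base = base) else base
}

#' Read a scenario configuration from YAML or JSON
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file containing (partial)
#'   scenario overrides; unknown keys are rejected.
#' @return a validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stopf("%s: config must be .yaml/.yml or .json", path)
  if (!is.null(raw$stages)) raw$stages <- unlist(raw$stages)
  do.call(scenario_config, raw)
}

#' Synthesize an illumination series of emission spectra
#'
#' Forward model behind the spectral stage: the reference dye (component 1)
#' decays as `f_red(t)`, the photoblued species (component 2, peak shifted
#' `shift_nm` to the blue) grows as `f_blue(t)` weighted by its relative
#' emission brightness.
#'
#' @param kinetics a [photo_kinetics()].
#' @param frames integer frame indices at which spectra are recorded
#'   (0 = pre-irradiation).
#' @param spectrum list of spectral parameters (see [scenario_config()]
#'   section `spectrum`).
#' @param bins a [spectral_binning()].
#' @param seed integer seed for per-frame Poisson noise; NULL = noiseless.
#' @return list with `initial` (frame-0 spectrum), `spectra` (list along
#'   `frames`), `fraction_true` (area fraction of the photoblued species per
#'   frame), `trajectory`.
#' @export
synth_spectral_series <- function(kinetics, frames,
                                  spectrum = default_scenario()$spectrum,
                                  bins = spectral_binning(), seed = NULL) {
  stopifnot(inherits(kinetics, "photo_kinetics"), all(frames >= 0))
  traj <- simulate_photoconversion(kinetics, max(frames))
  unit_red <- lognormal_component(1, spectrum$lambda_max_red, spectrum$w_red,
                                  spectrum$a)
  unit_blue <- lognormal_component(1, spectrum$lambda_max_red -
                                     spectrum$shift_nm,
                                   spectrum$w_blue, spectrum$a)
  amp_unit <- spectrum$total_counts / component_area(unit_red, bins)
  area_r <- component_area(unit_red, bins)
  area_b <- component_area(unit_blue, bins)
  make <- function(frame, noise_seed) {
    f_red <- traj$f_red[traj$frame == frame]
    f_blue <- traj$f_blue[traj$frame == frame] * spectrum$blue_emission_ratio
    comps <- list(
      lognormal_component(amp_unit * f_red, spectrum$lambda_max_red,
                          spectrum$w_red, spectrum$a),
      lognormal_component(amp_unit * f_blue,
                          spectrum$lambda_max_red - spectrum$shift_nm,
                          spectrum$w_blue, spectrum$a))
    synth_spectrum(comps, bins, noise_seed = noise_seed)
  }
  spectra <- lapply(seq_along(frames), function(i)
    make(frames[i], if (is.null(seed)) NULL else derive_seed(seed, i)))
  f_r <- traj$f_red[match(frames, traj$frame)]
  f_b <- traj$f_blue[match(frames, traj$frame)] * spectrum$blue_emission_ratio
  fraction_true <- ifelse(f_r * area_r + f_b * area_b > 0,
                          f_b * area_b / (f_r * area_r + f_b * area_b), 0)
  list(initial = make(0L, if (is.null(seed)) NULL else derive_seed(seed, 0L)),
       spectra = spectra, fraction_true = fraction_true, trajectory = traj)
}

#' Run a full simulate-and-analyze scenario
#'
#' Executes the stages selected in the configuration — kinetics trajectory,
#' spectral series + unmixing, FCS traces + correlation + model fits
#' (molecule percentages and brightness), GP image stack + GP time series,
#' and the multi-dye FLIM series — all seeded from the scenario seed. Any
#' stage whose fit flags non-convergence aborts with an error naming the
#' stage.
#'
#' @param cfg a [scenario_config()] or [scenario_preset()].
#' @param out_dir optional directory; when given, every table is written as
#'   CSV along with the resolved configuration (JSON).
#' @return a `run_report`: list with `name`, `tables` (data.frames),
#'   `provenance` (config hash, seed, package version).
#' @export
run_scenario <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  seed <- cfg$seed
  pk <- photo_kinetics(cfg$kinetics$k_blue, cfg$kinetics$k_bleach_red,
                       cfg$kinetics$k_bleach_blue,
                       cfg$kinetics$brightness_ratio_blue,
                       cfg$kinetics$replenishment)
  n_frames <- cfg$kinetics$n_frames
  tables <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  if ("kinetics" %in% cfg$stages) tables$fractions <- stage("kinetics", {
    as.data.frame(simulate_photoconversion(pk, n_frames))
  })

  if ("spectral" %in% cfg$stages) tables$blue_fraction <- stage("spectral", {
    frames <- cfg$spectrum$frames[cfg$spectrum$frames <= n_frames]
    series <- synth_spectral_series(
      pk, frames, cfg$spectrum,
      seed = if (isTRUE(cfg$spectrum$poisson)) derive_seed(seed, 200L))
    fit <- blue_fraction_series(series$spectra, series$initial,
                                a_fixed = cfg$spectrum$a)
    if (any(!fit$converged)) stopf("spectral unmixing did not converge")
    data.frame(frame = frames, fraction_blue = fit$fraction_blue,
               fraction_true = series$fraction_true,
               lambda_max_blue = fit$lambda_max_blue,
               shift_nm = fit$shift_nm, residual_rms = fit$residual_rms)
  })

  if ("fcs" %in% cfg$stages) tables$fcs <- stage("fcs", {
    traj <- simulate_photoconversion(pk, n_frames)
    tr <- cfg$trace
    run_channel <- function(frame, channel) {
      f <- if (channel == "red") traj$f_red[traj$frame == frame]
           else traj$f_blue[traj$frame == frame]
      cpm <- tr$counts_per_molecule *
        if (channel == "red") 1 else pk$brightness_ratio_blue
      n_eff <- tr$n_molecules * f
      if (n_eff < 0.05)
        return(data.frame(frame = frame, channel = channel,
                          n_effective = n_eff, N_fit = NA_real_,
                          tau_D_fit = NA_real_, Q = NA_real_,
                          converged = NA))
      sc <- trace_sim_config(n_molecules = n_eff, omega0 = tr$omega0,
                             diffusion_coeff = tr$diffusion_coeff,
                             box_size = tr$box_size, T = tr$T,
                             tau_triplet = tr$tau_triplet,
                             counts_per_molecule = cpm,
                             bin_time = tr$bin_time, duration = tr$duration)
      # repeat measurements of the same spot; curves averaged before fitting
      curve <- average_curves(lapply(seq_len(cfg$fcs$n_repeats), function(r) {
        trace <- simulate_fcs_trace(
          sc, seed = derive_seed(seed, 100L + 17L * frame + 2L * r +
                                   (channel == "blue")))
        correlate_multi_tau(trace, m = cfg$fcs$m,
                            n_segments = cfg$fcs$n_segments)
      }))
      fit <- fit_curve(curve, use_triplet = tr$T > 0,
                       fixed = c(list(alpha = 1),
                                 if (tr$T > 0) list(tau_triplet =
                                                      tr$tau_triplet)))
      data.frame(frame = frame, channel = channel, n_effective = n_eff,
                 N_fit = fit$params$N, tau_D_fit = fit$params$tau_D,
                 Q = fit$Q, converged = fit$converged)
    }
    rows <- do.call(rbind, unlist(lapply(cfg$fcs$frames, function(f)
      list(run_channel(f, "red"), run_channel(f, "blue"))),
      recursive = FALSE))
    if (any(!rows$converged, na.rm = TRUE)) stopf("FCS fit did not converge")
    N0 <- rows$N_fit[rows$frame == 0L & rows$channel == "red"]
    rows$percent_of_initial <- molecule_percentage(rows$N_fit, N0)
    rows
  })

  if ("gp" %in% cfg$stages) tables$gp_series <- stage("gp", {
    img <- cfg$image
    stack <- synth_two_channel_stack(
      gp_true = img$gp_true, kinetics = pk, n_frames = n_frames,
      counts = img$counts, saturation = img$saturation,
      background_fraction = img$background_fraction, dims = img$dims,
      seed = derive_seed(seed, 300L))
    as.data.frame(gp_change_series(stack, img$threshold_fraction))
  })

  if ("flim" %in% cfg$stages) tables$lifetime_series <- stage("flim", {
    fl <- cfg$flim
    ab <- antibody_ensemble_config(fl$dyes_per_antibody, fl$tau_unquenched,
                                   fl$tau_quenched, fl$bleach_prob,
                                   fl$yield_quenched, fl$n_antibodies)
    ds <- antibody_decay_series(ab, fl$n_frames,
                                fl$photons_per_unit_intensity,
                                seed = derive_seed(seed, 400L))
    lt <- lifetime_series(ds$decays, fl$method)
    if (any(!lt$converged)) stopf("lifetime estimation did not converge")
    data.frame(lt, true_mean_lifetime = ds$truth$mean_lifetime,
               total_intensity = ds$truth$total_intensity)
  })

  report <- structure(
    list(name = cfg$name, tables = tables,
         provenance = list(config_hash = rlang::hash(unclass(cfg)),
                           seed = seed,
                           package_version =
                             as.character(utils::packageVersion("photoblueR")))),
    class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables))
      write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE, quote = FALSE)
    jsonlite::write_json(c(unclass(cfg),
                           list(provenance = report$provenance)),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
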