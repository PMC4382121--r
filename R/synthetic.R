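#' Canonical 42-peak whole-serum N-glycan template
#'
#' Glucose-unit positions and geometric mean percent areas of the 42
#' matched peaks of a whole-serum 2-AB N-glycan HILIC-UHPLC profile,
#' split into neutral (peaks 1-16, largely IgG-type) and charged
#' (sialylated, peaks 17-42) regions. The percent areas are geometric
#' means, so they sum to slightly under 100 (97.93); the simulator
#' renormalizes per-sample profiles to exactly 100.
#'
#' @return data.frame: peak (1-42), gu, mean_pct, neutral.
#' @export
glycan_peak_template <- function() {
  gu <- c(5.89, 5.98, 6.19, 6.32, 6.61, 6.75, 6.88, 6.99, 7.07, 7.25,
          7.42, 7.65, 7.72, 7.81, 8.04, 8.15,
          8.49, 8.64, 8.75, 8.90, 9.13, 9.37, 9.55, 9.77, 9.93, 10.16,
          10.30, 10.44, 10.55, 10.70, 10.88, 11.05, 11.26, 11.40, 11.51,
          11.65, 11.79, 11.95, 12.09, 12.17, 12.38, 12.50)
  pct <- c(0.13, 1.54, 0.85, 0.35, 0.09, 1.50, 0.58, 0.59, 1.27, 0.39,
           0.06, 1.26, 0.36, 0.45, 1.19, 0.37,
           8.05, 0.18, 0.76, 4.05, 2.19, 4.39, 1.35, 36.29, 0.52, 5.33,
           2.37, 1.20, 0.29, 0.08, 1.14, 0.61, 0.91, 0.24, 0.30, 5.91,
           0.46, 0.55, 2.32, 6.05, 0.62, 0.79)
  data.frame(peak = seq_along(gu), gu = gu, mean_pct = pct,
             neutral = seq_along(gu) <= 16L)
}

#' Default linear glucose-unit to retention-time map
#'
#' Maps GU 5.89 to 16.0 min and GU 12.50 to 38.0 min, the elution window
#' of the whole-serum profile on the emulated column/gradient.
#'
#' @return Function GU -> minutes (strictly increasing).
#' @export
default_rt_model <- function() {
  function(gu) 16.0 + (gu - 5.89) * (38.0 - 16.0) / (12.50 - 5.89)
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: per-patient
#' glycan profiles drawn around the 42-peak template with log-normal
#' inter-individual variation, small log-normal intra-individual (tube)
#' perturbations, optional multiplicative tube effects, retention-time
#' jitter per peak, a rigid per-sample time shift, a slow sinusoidal
#' baseline and white detector noise.
#'
#' @param n_patients Number of patients (default 10).
#' @param tubes_per_patient Tubes drawn per patient (default 3).
#' @param template data.frame with columns gu and mean_pct (default
#'   [glycan_peak_template()]); mean_pct must sum to within 90-110.
#' @param inter_individual_log_sd SD of the per-patient log-normal
#'   perturbation (default 0.3: individuals differ markedly).
#' @param intra_individual_log_sd SD of the per-tube log-normal
#'   perturbation (default 0.02: repeat tubes nearly identical).
#' @param tube_effect Optional tubes x peaks matrix of multiplicative
#'   factors (default all 1 = no tube effect).
#' @param rt_model Strictly increasing GU -> minutes function (default
#'   [default_rt_model()]).
#' @param peak_width_min Gaussian peak sigma in minutes (default 0.05).
#' @param rt_jitter_sd_min Per-peak apex jitter SD in minutes (default
#'   0.02).
#' @param shift_sd_min Per-sample rigid time shift SD in minutes (default
#'   0.05).
#' @param baseline_amplitude Amplitude of the slow sinusoidal baseline in
#'   intensity units of the rendered trace (default 0.3; peak heights run
#'   ~0.5-290 on this scale).
#' @param baseline_period_min Baseline period in minutes (default 15).
#' @param noise_sd White-noise SD in the same units (default 0.05).
#' @param grid_step_min Sampling interval in minutes (default 0.005).
#' @param pad_min Time padding beyond the outermost template peaks
#'   (default 2 min).
#' @param seed Integer seed driving all draws (default 1).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 10L,
                              tubes_per_patient = 3L,
                              template = glycan_peak_template(),
                              inter_individual_log_sd = 0.3,
                              intra_individual_log_sd = 0.02,
                              tube_effect = NULL,
                              rt_model = default_rt_model(),
                              peak_width_min = 0.05,
                              rt_jitter_sd_min = 0.02,
                              shift_sd_min = 0.05,
                              baseline_amplitude = 0.3,
                              baseline_period_min = 15,
                              noise_sd = 0.05,
                              grid_step_min = 0.005,
                              pad_min = 2,
                              seed = 1L) {
  stopifnot(n_patients >= 1L, tubes_per_patient >= 1L,
            all(c("gu", "mean_pct") %in% names(template)),
            inter_individual_log_sd >= 0, intra_individual_log_sd >= 0,
            peak_width_min > 0, rt_jitter_sd_min >= 0, shift_sd_min >= 0,
            baseline_amplitude >= 0, baseline_period_min > 0,
            noise_sd >= 0, grid_step_min > 0, pad_min >= 0)
  if (any(diff(template$gu) <= 0)) {
    stop("template GU values must be strictly increasing")
  }
  s <- sum(template$mean_pct)
  if (s < 90 || s > 110) {
    stop("template percent areas sum to ", round(s, 2),
         "; expected a total near 100")
  }
  rt <- rt_model(template$gu)
  if (any(diff(rt) <= 0)) stop("rt_model must be strictly increasing over the template")
  K <- nrow(template)
  if (is.null(tube_effect)) {
    tube_effect <- matrix(1, tubes_per_patient, K)
  }
  stopifnot(nrow(tube_effect) == tubes_per_patient, ncol(tube_effect) == K,
            all(tube_effect > 0))
  structure(
    list(n_patients = as.integer(n_patients),
         tubes_per_patient = as.integer(tubes_per_patient),
         template = template,
         inter_individual_log_sd = inter_individual_log_sd,
         intra_individual_log_sd = intra_individual_log_sd,
         tube_effect = tube_effect, rt_model = rt_model,
         peak_width_min = peak_width_min,
         rt_jitter_sd_min = rt_jitter_sd_min,
         shift_sd_min = shift_sd_min,
         baseline_amplitude = baseline_amplitude,
         baseline_period_min = baseline_period_min,
         noise_sd = noise_sd, grid_step_min = grid_step_min,
         pad_min = pad_min, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Derived 31-bit child seed so per-sample draws are stable when n changes.
.child_seed <- function(seed, stream, index) {
  (as.double(seed) * 48271 + stream * 69621 + index * 16807) %% 2147483647
}

.patient_letters <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(outer(LETTERS, LETTERS, paste0)))[seq_len(n)]
}

#' Simulate true per-sample glycan profiles
#'
#' Patient profile = template x exp(N(0, inter_sd^2)) per peak,
#' renormalized to 100; sample profile = patient profile x
#' exp(N(0, intra_sd^2)) x tube factor, renormalized to 100.
#'
#' @param config A [simulation_config()].
#' @return List: `samples` (data.frame sample_id, patient, tube),
#'   `true_pct` (samples x peaks matrix of true percent areas),
#'   `patient_profiles` (patients x peaks), `config`.
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  K <- nrow(config$template)
  letters_ <- .patient_letters(config$n_patients)
  base <- config$template$mean_pct / sum(config$template$mean_pct) * 100
  profiles <- matrix(NA_real_, config$n_patients, K,
                     dimnames = list(letters_, NULL))
  for (p in seq_len(config$n_patients)) {
    set.seed(.child_seed(config$seed, 1, p))
    prof <- base * exp(stats::rnorm(K, 0, config$inter_individual_log_sd))
    profiles[p, ] <- prof / sum(prof) * 100
  }
  ids <- character(0L)
  pat <- character(0L)
  tube <- integer(0L)
  true_pct <- matrix(NA_real_, config$n_patients * config$tubes_per_patient, K)
  i <- 0L
  for (p in seq_len(config$n_patients)) {
    for (tb in seq_len(config$tubes_per_patient)) {
      i <- i + 1L
      set.seed(.child_seed(config$seed, 2, i))
      x <- profiles[p, ] *
        exp(stats::rnorm(K, 0, config$intra_individual_log_sd)) *
        config$tube_effect[tb, ]
      true_pct[i, ] <- x / sum(x) * 100
      ids[i] <- paste0(letters_[p], tb)
      pat[i] <- letters_[p]
      tube[i] <- tb
    }
  }
  rownames(true_pct) <- ids
  list(samples = data.frame(sample_id = ids, patient = pat, tube = tube,
                            stringsAsFactors = FALSE),
       true_pct = true_pct, patient_profiles = profiles, config = config)
}

# Render a sum-of-Gaussians trace on the uniform grid, plus baseline and
# noise. `areas` are in percent units; the trace integrates to ~sum(areas)
# before baseline/noise.
.render_trace <- function(time, apex, areas, width, baseline_amp,
                          baseline_period, baseline_phase, noise_sd) {
  y <- numeric(length(time))
  for (k in seq_along(apex)) {
    y <- y + areas[k] * stats::dnorm(time, apex[k], width)
  }
  if (baseline_amp > 0) {
    y <- y + baseline_amp *
      (1 + sin(2 * pi * time / baseline_period + baseline_phase)) / 2
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(time), 0, noise_sd)
  y
}

#' Render one sample's chromatogram from true areas
#'
#' The trace is a sum of Gaussians of the given areas at apex times
#' `rt_model(GU) + per-peak jitter + per-sample shift`, plus a slow
#' sinusoidal baseline and white noise, sampled on the uniform grid.
#'
#' @param areas True areas (percent units), one per template peak.
#' @param config A [simulation_config()].
#' @param sample_id Sample identifier.
#' @param jitter Per-peak apex jitter in minutes (default none).
#' @param shift Rigid time shift in minutes (default 0).
#' @param baseline_phase Phase of the sinusoidal baseline (default 0).
#' @param noise_seed Optional seed set just before the noise draw.
#' @return A [chromatogram()]; attribute `apex` holds the true apex times.
#' @export
render_chromatogram <- function(areas, config, sample_id = "S1",
                                jitter = rep(0, length(areas)), shift = 0,
                                baseline_phase = 0, noise_seed = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            length(areas) == nrow(config$template))
  rt <- config$rt_model(config$template$gu)
  apex <- rt + jitter + shift
  if (length(apex) > 1L && min(diff(sort(apex))) < 2 * config$grid_step_min) {
    stop("template peaks closer than 2 grid steps; unresolvable")
  }
  time <- seq(min(rt) - config$pad_min, max(rt) + config$pad_min,
              by = config$grid_step_min)
  if (!is.null(noise_seed)) set.seed(noise_seed)
  y <- .render_trace(time, apex, areas, config$peak_width_min,
                     config$baseline_amplitude, config$baseline_period_min,
                     baseline_phase, config$noise_sd)
  ch <- chromatogram(sample_id, time, y)
  attr(ch, "apex") <- apex
  ch
}

#' Render a glucose homopolymer ladder trace
#'
#' Equal-area Gaussian peaks at integer GU positions with the same width,
#' baseline and noise model as the samples, but no jitter or shift (it is
#' the external calibration standard).
#'
#' @param config A [simulation_config()].
#' @param gu_values Integer GU positions (default 4:14, bracketing the
#'   5.89-12.50 GU template).
#' @return A [chromatogram()] with sample_id `"ladder"`; attribute `gu`
#'   holds the GU of each rendered peak.
#' @export
render_ladder <- function(config, gu_values = 4:14) {
  stopifnot(inherits(config, "simulation_config"))
  rt <- config$rt_model(gu_values)
  time <- seq(min(rt) - config$pad_min, max(rt) + config$pad_min,
              by = config$grid_step_min)
  set.seed(.child_seed(config$seed, 3, 1))
  y <- .render_trace(time, rt, rep(100 / length(rt), length(rt)),
                     config$peak_width_min, config$baseline_amplitude,
                     config$baseline_period_min, 0, config$noise_sd)
  ch <- chromatogram("ladder", time, y, meta = list(group = "ladder"))
  attr(ch, "gu") <- gu_values
  ch
}

#' Simulate a complete synthetic dataset with ground truth
#'
#' Draws per-patient profiles and per-tube perturbations, renders every
#' sample trace plus one ladder trace, and returns the sample sheet and
#' the exact truth (true percent areas, apex times, shifts, jitters)
#' alongside. With `dir` set, everything is written through the package's
#' text formats.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory.
#' @return List: `chromatograms` (named list), `ladder`, `sheet`,
#'   `truth` (list: samples, true_pct, patient_profiles, apex, shift,
#'   jitter), `config`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  prof <- simulate_profiles(config)
  n <- nrow(prof$samples)
  K <- nrow(config$template)
  chroms <- vector("list", n)
  names(chroms) <- prof$samples$sample_id
  apex <- matrix(NA_real_, n, K,
                 dimnames = list(prof$samples$sample_id, NULL))
  jitter <- apex
  shift <- stats::setNames(numeric(n), prof$samples$sample_id)
  for (i in seq_len(n)) {
    set.seed(.child_seed(config$seed, 4, i))
    jit <- stats::rnorm(K, 0, config$rt_jitter_sd_min)
    sh <- stats::rnorm(1L, 0, config$shift_sd_min)
    phase <- stats::runif(1L, 0, 2 * pi)
    ch <- render_chromatogram(prof$true_pct[i, ], config,
                              sample_id = prof$samples$sample_id[i],
                              jitter = jit, shift = sh,
                              baseline_phase = phase,
                              noise_seed = .child_seed(config$seed, 5, i))
    ch$meta <- list(patient = prof$samples$patient[i],
                    tube = prof$samples$tube[i])
    chroms[[i]] <- ch
    apex[i, ] <- attr(ch, "apex")
    jitter[i, ] <- jit
    shift[i] <- sh
  }
  ladder <- render_ladder(config)
  sheet <- data.frame(prof$samples, group = NA_character_,
                      stringsAsFactors = FALSE)
  truth <- list(samples = prof$samples, true_pct = prof$true_pct,
                patient_profiles = prof$patient_profiles,
                apex = apex, shift = shift, jitter = jitter)
  out <- list(chromatograms = chroms, ladder = ladder, sheet = sheet,
              truth = truth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(chroms)) {
      write_chromatogram(chroms[[id]], file.path(dir, paste0(id, ".csv")))
    }
    write_chromatogram(ladder, file.path(dir, "ladder.csv"))
    write_sample_sheet(sheet, file.path(dir, "samples.csv"))
    utils::write.csv(data.frame(sample_id = rownames(prof$true_pct),
                                prof$true_pct, check.names = FALSE),
                     file.path(dir, "truth_percent.csv"), row.names = FALSE)
    utils::write.csv(data.frame(sample_id = names(shift),
                                shift_min = as.numeric(shift)),
                     file.path(dir, "truth_shift.csv"), row.names = FALSE)
  }
  out
}
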