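#' Foam phantom specification
#'
#' Describes the bubbled-foam test phantom: how many air bubbles the needle
#' crosses per centimetre of travel, and how thick the foam block is. Each
#' crossed bubble emits one acoustic event, so `bubble_density * thickness`
#' (rounded) is the number of events generated during forward motion.
#'
#' @param bubble_density Events (bubbles) per cm of needle travel, >= 0.
#'   The two reference foams used for detector validation have densities of
#'   about 20/cm and 9/cm.
#' @param thickness Foam thickness in cm, > 0.
#' @return A `foam_spec` object.
#' @export
foam_spec <- function(bubble_density = 20, thickness = 3) {
  stopifnot(is.numeric(bubble_density), bubble_density >= 0,
            is.numeric(thickness), thickness > 0)
  structure(list(bubble_density = bubble_density, thickness = thickness),
            class = "foam_spec")
}

#' Needle insertion motion profile
#'
#' Timing of a single manual insertion: silence, an initiation pulse, the
#' approach to the foam surface, forward motion through the foam, a dwell
#' with the needle stationary, and retraction. Forward-motion duration is
#' `10 * thickness_cm / speed_mm_s` seconds.
#'
#' @param speed Forward insertion speed in mm/s (manual insertions run at
#'   roughly 5-10 mm/s).
#' @param pre_roll Seconds of background noise before the initiation pulse.
#' @param approach Seconds between the initiation pulse and foam entry (L1).
#' @param dwell Seconds the needle rests between forward stop (L2) and
#'   retraction start (L3).
#' @param retraction_speed Retraction speed in mm/s; defaults to `speed`.
#' @return An `insertion_profile` object.
#' @export
insertion_profile <- function(speed = 7, pre_roll = 0.5, approach = 1.5,
                              dwell = 1.0, retraction_speed = speed) {
  stopifnot(speed > 0, pre_roll >= 0, approach > 0, dwell >= 0,
            retraction_speed > 0)
  structure(list(speed = speed, pre_roll = pre_roll, approach = approach,
                 dwell = dwell, retraction_speed = retraction_speed),
            class = "insertion_profile")
}

#' Injected temperature-to-spectrum effect
#'
#' Parameterizes how temperature is encoded in each acoustic event. Events
#' are exponentially damped sinusoids; their centre frequency is
#' `base_frequency + slope * (T - reference_temperature)` and their decay
#' constant `decay_tau + decay_slope * (T - reference_temperature)`. With a
#' non-zero `slope` the event spectral centroid is strictly monotone in
#' temperature, which is the property the downstream regressor must recover.
#'
#' @param base_frequency Centre frequency in Hz at the reference temperature.
#' @param slope Centre-frequency shift in Hz per degree C.
#' @param decay_tau Exponential decay constant in seconds at the reference
#'   temperature.
#' @param decay_slope Decay-constant shift in s per degree C.
#' @param amplitude Peak event amplitude (dimensionless, relative to
#'   full-scale 1.0). The default is 10x the default background noise sigma
#'   so the mean-plus-sigma envelope threshold separates events cleanly.
#' @param reference_temperature Temperature (degrees C) at which
#'   `base_frequency` and `decay_tau` apply.
#' @param burst_duration Event duration in seconds.
#' @return A `temperature_effect` object.
#' @export
temperature_effect <- function(base_frequency = 4000, slope = 50,
                               decay_tau = 0.002, decay_slope = 0,
                               amplitude = 0.05, reference_temperature = 20,
                               burst_duration = 0.008) {
  stopifnot(base_frequency > 0, decay_tau > 0, amplitude >= 0,
            burst_duration > 0)
  structure(list(base_frequency = base_frequency, slope = slope,
                 decay_tau = decay_tau, decay_slope = decay_slope,
                 amplitude = amplitude,
                 reference_temperature = reference_temperature,
                 burst_duration = burst_duration),
            class = "temperature_effect")
}

#' Synthetic dataset configuration
#'
#' @param sample_rate Audio sample rate in Hz; must exceed twice the 20 kHz
#'   upper analysis frequency.
#' @param noise_sigma Standard deviation of the white Gaussian background.
#' @param seed Master seed for dataset generation.
#' @param temp_groups Temperature groups in degrees C.
#' @param recordings_per_group Recordings generated per group.
#' @param within_group_drift Maximum waterbath cooldown within a group, in
#'   degrees C (at most 1.4); hotter groups drift more.
#' @param max_duration Safety cap on a single recording's duration (s).
#' @return A `synth_config` object.
#' @export
synth_config <- function(sample_rate = 48000, noise_sigma = 0.005,
                         seed = 1L, temp_groups = seq(20, 55, by = 5),
                         recordings_per_group = 22L,
                         within_group_drift = 1.4, max_duration = 60) {
  stopifnot(sample_rate > 2 * 20000, noise_sigma >= 0,
            recordings_per_group >= 0, within_group_drift >= 0,
            within_group_drift <= 1.4, max_duration > 0)
  structure(list(sample_rate = sample_rate, noise_sigma = noise_sigma,
                 seed = as.integer(seed), temp_groups = temp_groups,
                 recordings_per_group = as.integer(recordings_per_group),
                 within_group_drift = within_group_drift,
                 max_duration = max_duration),
            class = "synth_config")
}

#' Single acoustic event waveform
#'
#' A short damped oscillatory burst with a small uniform amplitude jitter
#' (drawn from the current RNG state). Centre frequency and decay constant
#' shift linearly with temperature according to `effect`.
#'
#' @param temperature Temperature in degrees C.
#' @param effect A [temperature_effect()].
#' @param sample_rate Sample rate in Hz.
#' @return Numeric vector of `round(burst_duration * sample_rate)` samples.
#' @export
event_waveform <- function(temperature, effect, sample_rate) {
  dT <- temperature - effect$reference_temperature
  f <- effect$base_frequency + effect$slope * dT
  tau <- effect$decay_tau + effect$decay_slope * dT
  if (tau <= 0) stop("non-positive decay constant (", signif(tau, 4),
                     " s) at ", temperature, " degrees C")
  if (f <= 0 || f >= sample_rate / 2) {
    stop("event centre frequency ", signif(f, 5),
         " Hz outside (0, sample_rate/2)")
  }
  n <- round(effect$burst_duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  jitter <- stats::runif(1, 0.9, 1.1)
  effect$amplitude * jitter * exp(-t / tau) * sin(2 * pi * f * t)
}

#' Simulate one annotated needle insertion
#'
#' Produces the full phase structure of a recording: background Gaussian
#' noise, a louder broadband initiation pulse, a quiet approach, bubble
#' events during forward motion (`[L1, L2]`), a quiet dwell, and mirrored
#' bubble events during retraction (`[L3, L4]`). Events sit at quasi-regular
#' positions along the needle path (uniform spacing with +/-20% jitter), so
#' the forward event count is exactly `round(bubble_density * thickness)`
#' whatever the insertion speed -- events per cm is speed-invariant.
#'
#' @param foam A [foam_spec()].
#' @param profile An [insertion_profile()].
#' @param temperature Measured temperature in degrees C (the regression
#'   label).
#' @param effect A [temperature_effect()].
#' @param cfg A [synth_config()] (sample rate, noise level, duration cap).
#' @param temperature_group Nominal group label; defaults to `temperature`.
#' @param recording_id Identifier string; autogenerated when `NULL`.
#' @return An `annotated_recording`: waveform, sample rate, L1-L4 (s),
#'   temperature labels, true event times, speed and id.
#' @export
simulate_insertion <- function(foam, profile, temperature, effect,
                               cfg = synth_config(),
                               temperature_group = temperature,
                               recording_id = NULL) {
  sr <- cfg$sample_rate
  pulse_dur <- 0.02
  L1 <- profile$pre_roll + pulse_dur + profile$approach
  fwd_dur <- 10 * foam$thickness / profile$speed
  L2 <- L1 + fwd_dur
  L3 <- L2 + profile$dwell
  ret_dur <- 10 * foam$thickness / profile$retraction_speed
  L4 <- L3 + ret_dur
  duration <- L4 + 0.5
  if (duration > cfg$max_duration) {
    stop("simulated duration ", signif(duration, 4), " s exceeds max_duration ",
         cfg$max_duration, " s")
  }

  n <- round(duration * sr)
  wav <- stats::rnorm(n, 0, cfg$noise_sigma)

  # initiation pulse: broadband, louder than the bubble events
  pn <- round(pulse_dur * sr)
  pidx <- round(profile$pre_roll * sr) + seq_len(pn)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(pn) - 1) / pn)
  wav[pidx] <- wav[pidx] + 4 * effect$amplitude * hann * stats::rnorm(pn)

  n_ev <- round(foam$bubble_density * foam$thickness)
  fwd_times <- numeric(0)
  ret_times <- numeric(0)
  if (n_ev > 0) {
    spacing <- foam$thickness / n_ev
    pos <- (seq_len(n_ev) - 0.5) * spacing +
      stats::runif(n_ev, -0.2, 0.2) * spacing
    pos <- pmin(pmax(pos, 1e-6), foam$thickness - 1e-6)
    fwd_times <- L1 + pos * 10 / profile$speed
    # retraction crosses the same bubbles in reverse order
    ret_times <- sort(L3 + (foam$thickness - pos) * 10 / profile$retraction_speed)
    for (tt in c(fwd_times, ret_times)) {
      ev <- event_waveform(temperature, effect, sr)
      idx <- round(tt * sr) + seq_along(ev)
      idx <- idx[idx >= 1 & idx <= n]
      wav[idx] <- wav[idx] + ev[seq_along(idx)]
    }
  }

  if (is.null(recording_id)) {
    recording_id <- sprintf("rec_T%g_%06d", temperature_group,
                            sample.int(999999L, 1))
  }
  structure(list(
    waveform = wav, sample_rate = sr,
    L1 = L1, L2 = L2, L3 = L3, L4 = L4,
    temperature_group = temperature_group,
    measured_temperature = temperature,
    true_event_times = c(fwd_times, ret_times),
    speed_mm_s = profile$speed,
    recording_id = recording_id
  ), class = "annotated_recording")
}

#' @export
print.annotated_recording <- function(x, ...) {
  cat(sprintf(
    "<annotated_recording %s>\n  %.2f s @ %d Hz | group %g C, measured %.2f C\n  L1=%.3f L2=%.3f L3=%.3f L4=%.3f | %d true events\n",
    x$recording_id, length(x$waveform) / x$sample_rate, x$sample_rate,
    x$temperature_group, x$measured_temperature,
    x$L1, x$L2, x$L3, x$L4, length(x$true_event_times)))
  invisible(x)
}

#' Generate an annotated synthetic dataset
#'
#' For each temperature group, generates `recordings_per_group` insertions.
#' The measured temperature of a recording is the group value minus a
#' cooldown offset drawn uniformly from `[0, drift_g]`, where `drift_g`
#' scales up linearly for hotter groups (waterbaths cool faster when
#' hotter). Per-recording insertion speeds are drawn uniformly from
#' `speed_range`. Generation is reproducible: each recording gets a
#' sub-seed derived from `cfg$seed`, so re-running with the same
#' configuration yields byte-identical audio files and manifest.
#'
#' @param cfg A [synth_config()].
#' @param foam A [foam_spec()].
#' @param effect A [temperature_effect()].
#' @param speed_range Two-element range of forward speeds in mm/s.
#' @param out_dir When non-`NULL`, WAV files (plus one JSON annotation per
#'   recording and a `manifest.csv`) are written there and waveforms are not
#'   kept in memory. When `NULL`, recordings are returned in memory.
#' @param encoding WAV sample encoding, see [write_wav()].
#' @return A list with `manifest` (data.frame, one row per recording) and
#'   `recordings` (list of `annotated_recording`, or `NULL` when written to
#'   disk).
#' @export
generate_dataset <- function(cfg = synth_config(), foam = foam_spec(),
                             effect = temperature_effect(),
                             speed_range = c(5, 10), out_dir = NULL,
                             encoding = "pcm16") {
  if (length(cfg$temp_groups) == 0) stop("temp_groups must be non-empty")
  stopifnot(length(speed_range) == 2, all(speed_range > 0))

  groups <- cfg$temp_groups
  per <- cfg$recordings_per_group
  n_total <- length(groups) * per
  manifest <- data.frame()
  recordings <- list()
  if (n_total == 0) {
    return(list(manifest = manifest, recordings = recordings))
  }

  set.seed(cfg$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  gspan <- diff(range(groups))

  k <- 0L
  rows <- vector("list", n_total)
  for (g in groups) {
    # hotter baths cool faster: drift ceiling scales from 20% to 100%
    scale <- if (gspan > 0) 0.2 + 0.8 * (g - min(groups)) / gspan else 1
    for (r in seq_len(per)) {
      k <- k + 1L
      set.seed(sub_seeds[k])
      offset <- stats::runif(1, 0, cfg$within_group_drift * scale)
      speed <- stats::runif(1, speed_range[1], speed_range[2])
      rec_id <- sprintf("rec_T%02d_%03d", as.integer(g), r)
      rec <- simulate_insertion(
        foam, insertion_profile(speed = speed), temperature = g - offset,
        effect = effect, cfg = cfg, temperature_group = g,
        recording_id = rec_id)

      audio_path <- NA_character_
      ann_path <- NA_character_
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        audio_path <- file.path(out_dir, paste0(rec_id, ".wav"))
        ann_path <- file.path(out_dir, paste0(rec_id, ".json"))
        write_wav(audio_path, rec$waveform, rec$sample_rate, encoding)
        write_annotation(ann_path, rec, seed = sub_seeds[k])
      } else {
        recordings[[rec_id]] <- rec
      }
      rows[[k]] <- data.frame(
        recording_id = rec_id, audio_path = audio_path,
        annotation_path = ann_path, temperature_group = g,
        measured_temperature = rec$measured_temperature,
        L1 = rec$L1, L2 = rec$L2, L3 = rec$L3, L4 = rec$L4,
        speed_mm_s = speed, seed = sub_seeds[k],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    recordings <- NULL
  }
  list(manifest = manifest, recordings = recordings)
}
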