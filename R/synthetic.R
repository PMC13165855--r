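# Synthetic fatigue-EEG generator. Each epoch is 1/f^gamma background
# noise plus amplitude-modulated narrowband oscillations (theta, alpha,
# beta); the fatigued class raises theta and alpha power and suppresses
# beta by configurable dB effects, and every subject carries its own
# band-power offsets and alpha peak shift so between-subject variability
# (the LOSO difficulty) is present by construction.

#' Simulation configuration
#'
#' Defaults emulate a moderately separated multi-subject recording: theta
#' +3 dB and alpha +2 dB elevation with beta -2 dB suppression in the
#' fatigued class, per-subject band offsets up to +/-2 dB, an individual
#' alpha peak drawn per subject in 8.5-12.5 Hz (so the alpha effect lands
#' in different filter-bank sub-bands for different subjects), pink-noise
#' background with exponent 1.
#'
#' @param n_subjects Number of subjects.
#' @param epochs_per_class Epochs per class per subject.
#' @param C Channels.
#' @param fs Sampling rate (Hz).
#' @param T_len Samples per epoch.
#' @param theta_effect_db,alpha_effect_db Power elevation (dB) of the
#'   fatigued class in the theta / alpha oscillation.
#' @param beta_effect_db Power change (dB, negative = suppression) of the
#'   fatigued class in the beta oscillation.
#' @param subject_offset_db Half-range of per-subject log-power offsets
#'   (uniform in +/- this value, per oscillation).
#' @param pink_noise_exponent Spectral exponent gamma of the 1/f^gamma
#'   background.
#' @param noise_scale Overall background noise amplitude (uV RMS, ~1).
#' @param seed Master seed; all draws derive from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_subjects = 4L, epochs_per_class = 50L, C = 8L,
                       fs = 200, T_len = 800L, theta_effect_db = 3,
                       alpha_effect_db = 2, beta_effect_db = -2,
                       subject_offset_db = 2, pink_noise_exponent = 1,
                       noise_scale = 1, seed = 0L) {
  stopifnot(n_subjects >= 1, epochs_per_class >= 1, C >= 1, fs > 0,
            T_len >= 8, subject_offset_db >= 0, noise_scale > 0,
            is.finite(theta_effect_db), is.finite(alpha_effect_db),
            is.finite(beta_effect_db))
  structure(list(n_subjects = as.integer(n_subjects),
                 epochs_per_class = as.integer(epochs_per_class),
                 C = as.integer(C), fs = fs, T_len = as.integer(T_len),
                 theta_effect_db = theta_effect_db,
                 alpha_effect_db = alpha_effect_db,
                 beta_effect_db = beta_effect_db,
                 subject_offset_db = subject_offset_db,
                 pink_noise_exponent = pink_noise_exponent,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "sim_config")
}

# frequency-domain synthesis of 1/f^gamma noise, one channel per row
pink_noise <- function(C, T_len, fs, gamma) {
  nf <- T_len %/% 2L
  f <- seq_len(nf) * fs / T_len
  amp <- 1 / f^(gamma / 2)
  out <- matrix(0, C, T_len)
  for (ch in seq_len(C)) {
    ph <- stats::runif(nf, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = ph)
    full <- c(0, spec, if (T_len %% 2L == 0L) Conj(rev(spec[-nf])) else
      Conj(rev(spec)))
    x <- Re(stats::fft(full, inverse = TRUE)) / T_len
    out[ch, ] <- x / stats::sd(x)
  }
  out
}

# amplitude-modulated narrowband oscillation with random phase; rms ~ amp
narrowband_osc <- function(C, T_len, fs, f0, bw, amp) {
  t <- (seq_len(T_len) - 1L) / fs
  out <- matrix(0, C, T_len)
  for (ch in seq_len(C)) {
    # slow random amplitude envelope (positive, mean 1)
    env <- 1 + 0.5 * sin(2 * pi * stats::runif(1, 0.1, 0.5) * t +
                           stats::runif(1, 0, 2 * pi))
    fr <- f0 + stats::runif(1, -bw / 2, bw / 2)
    out[ch, ] <- amp * sqrt(2) * env *
      sin(2 * pi * fr * t + stats::runif(1, 0, 2 * pi))
  }
  out
}

db_to_amp <- function(db) 10^(db / 20)

#' Simulate a labeled multi-subject fatigue-EEG dataset
#'
#' Generates balanced alert/fatigued epochs for every subject under the
#' class-conditional band-power structure described in [sim_config()].
#' Fully seeded: identical configurations produce bit-identical datasets.
#'
#' @param cfg A [sim_config()].
#' @return An [eeg_dataset()]; attribute `profiles` holds the per-subject
#'   offsets actually drawn.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  profiles <- lapply(seq_len(cfg$n_subjects), function(s) {
    list(subject_id = sprintf("S%02d", s),
         theta_off = stats::runif(1, -cfg$subject_offset_db,
                                  cfg$subject_offset_db),
         alpha_off = stats::runif(1, -cfg$subject_offset_db,
                                  cfg$subject_offset_db),
         beta_off = stats::runif(1, -cfg$subject_offset_db,
                                 cfg$subject_offset_db),
         alpha_peak = stats::runif(1, 8.5, 12.5),
         noise_scale = cfg$noise_scale * stats::runif(1, 0.8, 1.2))
  })
  epochs <- list(); labels <- integer(0); subjects <- character(0)
  base_amp <- c(theta = 0.8, alpha = 0.8, beta = 0.6)
  for (p in profiles) {
    for (lab in c(0L, 1L)) {
      for (e in seq_len(cfg$epochs_per_class)) {
        amp_th <- base_amp["theta"] * db_to_amp(p$theta_off +
                                                  lab * cfg$theta_effect_db)
        amp_al <- base_amp["alpha"] * db_to_amp(p$alpha_off +
                                                  lab * cfg$alpha_effect_db)
        amp_be <- base_amp["beta"] * db_to_amp(p$beta_off +
                                                 lab * cfg$beta_effect_db)
        x <- p$noise_scale *
          pink_noise(cfg$C, cfg$T_len, cfg$fs, cfg$pink_noise_exponent) +
          narrowband_osc(cfg$C, cfg$T_len, cfg$fs, 6, 2, amp_th) +
          narrowband_osc(cfg$C, cfg$T_len, cfg$fs, p$alpha_peak, 2, amp_al) +
          narrowband_osc(cfg$C, cfg$T_len, cfg$fs, 20, 4, amp_be)
        epochs[[length(epochs) + 1L]] <- x
        labels <- c(labels, lab)
        subjects <- c(subjects, p$subject_id)
      }
    }
  }
  ds <- eeg_dataset(epochs, labels, subjects, cfg$fs,
                    channel_names = sprintf("CH%02d", seq_len(cfg$C)))
  attr(ds, "profiles") <- profiles
  ds
}

#' Simulate a deviation-event session
#'
#' Event onsets are spaced uniformly 5-15 s apart; reaction times are
#' drawn from a tight alert distribution (uniform 0.5-1.0 s) or an
#' inflated fatigued distribution (uniform 3.5-5.0 s) according to the
#' per-event intended state. The generator's intent is returned alongside
#' the events so labeling-pipeline output can be compared against ground
#' truth.
#'
#' @param n_events Number of deviation events (>= 2).
#' @param fatigue_trajectory Integer/logical vector (recycled) giving the
#'   intended state per event (1 = fatigued).
#' @param seed Seed.
#' @param gap_range Onset spacing range in seconds.
#' @param alert_rt,fatigued_rt Reaction-time ranges (s) per state.
#' @param subject_id Subject label.
#' @return List with `session` (a [session_events()]) and `intent`
#'   (integer vector).
#' @export
simulate_deviation_session <- function(n_events, fatigue_trajectory = 0L,
                                       seed = 0L, gap_range = c(5, 15),
                                       alert_rt = c(0.5, 1.0),
                                       fatigued_rt = c(3.5, 5.0),
                                       subject_id = "SIM") {
  stopifnot(n_events >= 2L)
  set.seed(seed)
  intent <- as.integer(rep_len(fatigue_trajectory, n_events))
  dep <- cumsum(stats::runif(n_events, gap_range[1], gap_range[2]))
  rt <- ifelse(intent == 1L,
               stats::runif(n_events, fatigued_rt[1], fatigued_rt[2]),
               stats::runif(n_events, alert_rt[1], alert_rt[2]))
  list(session = session_events(dep, dep + rt, subject_id),
       intent = intent)
}

#' Simulate per-epoch eye-tracking durations
#'
#' Draws blink/fixation/saccade/closure durations for 4 s epochs so the
#' expected PERCLOS of epoch `s` equals `closure_trajectory[s]`; optional
#' truncated Gaussian noise perturbs the realized closure fraction. The
#' four durations always sum to at most the epoch length.
#'
#' @param n_epochs Number of epochs.
#' @param closure_trajectory Target PERCLOS per epoch in `[0, 1]`
#'   (recycled).
#' @param seed Seed.
#' @param noise_sd Standard deviation of the closure-fraction noise
#'   (default 0 = deterministic).
#' @param epoch_seconds Epoch length (s).
#' @return Data frame with `epoch_index`, `t_blink`, `t_fixation`,
#'   `t_saccade`, `t_closure`, `intent` (1 when target > 0.5).
#' @export
simulate_eye_epochs <- function(n_epochs, closure_trajectory, seed = 0L,
                                noise_sd = 0, epoch_seconds = 4) {
  set.seed(seed)
  target <- rep_len(closure_trajectory, n_epochs)
  stopifnot(all(target >= 0), all(target <= 1))
  frac <- pmin(pmax(target + stats::rnorm(n_epochs, 0, noise_sd), 0), 1)
  interval <- epoch_seconds * stats::runif(n_epochs, 0.9, 1)
  t_closure <- frac * interval
  open_t <- interval - t_closure
  # split open time into fixation / blink / saccade
  wf <- stats::runif(n_epochs, 0.6, 0.9)
  wb <- stats::runif(n_epochs, 0, 1 - wf)
  data.frame(epoch_index = seq_len(n_epochs) - 1L,
             t_blink = open_t * wb,
             t_fixation = open_t * wf,
             t_saccade = open_t * (1 - wf - wb),
             t_closure = t_closure,
             intent = as.integer(target > 0.5))
}
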