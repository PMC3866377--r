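# Seeded synthetic driving-EEG generator.
#
# Sessions emulate a 5-minute simulated drive: four laps, each with four
# left and four right turns, recorded on the 19-channel 10-20 montage at
# 500 Hz.  Group-specific band-power signatures are planted as narrow-band
# bursts around turn events on top of broadband noise, so the downstream
# band-power / t-ranking / Hopfield pipeline has a known ground truth.

#' Default group band-power signatures
#'
#' Three behavioural groups with distinct delta-band signatures:
#' G1 elevates FP2-delta and O1-delta on right turns; G2 elevates F7-delta
#' on right and P3-delta on left turns; G3 elevates FP2-, P3- and T4-delta
#' on left turns.
#'
#' @param multiplier Band-power multiplier applied during turn epochs
#'   relative to the background power in that band (default 3).
#' @return Data frame with columns `group`, `direction`, `channel`, `band`,
#'   `multiplier`.
#' @export
default_band_signatures <- function(multiplier = 3) {
  data.frame(
    group     = c("G1", "G1", "G2", "G2", "G3", "G3", "G3"),
    direction = c("RIGHT", "RIGHT", "RIGHT", "LEFT", "LEFT", "LEFT", "LEFT"),
    channel   = c("FP2", "O1", "F7", "P3", "FP2", "P3", "T4"),
    band      = c("delta", "delta", "delta", "delta", "delta", "delta", "delta"),
    multiplier = multiplier,
    stringsAsFactors = FALSE
  )
}

#' Default subject-to-group assignment
#'
#' Ten subjects split into the three behavioural groups: subjects 1, 2, 5,
#' 8, 10 in G1; 3 and 6 in G2; 4, 7, 9 in G3.
#'
#' @return Named character vector mapping subject id to group.
#' @export
default_group_assignment <- function() {
  g <- c("G1", "G1", "G2", "G3", "G1", "G2", "G3", "G1", "G3", "G1")
  names(g) <- sprintf("S%02d", 1:10)
  g
}

#' Synthetic-session generator configuration
#'
#' Collects every knob of the synthetic study: turn schedule, montage,
#' sampling rate, group signatures, noise level and artifact rate.  The
#' defaults are the study conditions assumed throughout the package:
#' 5-minute sessions, 4 laps x (4 left + 4 right) turns, 500 Hz, 19-channel
#' 10-20 montage, delta-band group signatures at multiplier 3 on a 10 uV
#' Gaussian background.
#'
#' @param n_subjects Number of subjects.
#' @param group_assignment Named character vector subject -> group.
#' @param laps Laps per session.
#' @param turns_per_direction_per_lap Turns to each side per lap.
#' @param fs Sampling rate (Hz).
#' @param channel_labels Ordered montage labels.
#' @param session_duration Session length in seconds.
#' @param epoch_s Duration of the turn epoch (s); bursts span
#'   `[onset, onset + epoch_s]`.
#' @param band_signatures Data frame as from [default_band_signatures()].
#' @param bands Band definition table, see [default_bands()].
#' @param noise_sd Background noise standard deviation (uV).
#' @param pink If `TRUE`, shape the background noise to a 1/f spectrum.
#' @param artifact_rate High-amplitude transient artifacts per minute.
#' @param event_jitter Event-timing jitter as a fraction of the inter-event
#'   slot (0 = perfectly even spacing).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 10,
                             group_assignment = default_group_assignment(),
                             laps = 4,
                             turns_per_direction_per_lap = 4,
                             fs = 500,
                             channel_labels = CHANNELS_1020,
                             session_duration = 300,
                             epoch_s = 5,
                             band_signatures = default_band_signatures(),
                             bands = default_bands(),
                             noise_sd = 10,
                             pink = FALSE,
                             artifact_rate = 0,
                             event_jitter = 0.1) {
  if (laps < 0 || turns_per_direction_per_lap < 0)
    stop("laps and turns per direction must be >= 0", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  validate_bands(bands)
  group_assignment <- group_assignment[seq_len(min(n_subjects,
                                                   length(group_assignment)))]
  if (length(group_assignment) < n_subjects)
    stop("group_assignment must name every subject", call. = FALSE)
  if (nrow(band_signatures)) {
    if (any(band_signatures$multiplier <= 0))
      stop("signature multipliers must be positive", call. = FALSE)
    bad_ch <- setdiff(band_signatures$channel, channel_labels)
    if (length(bad_ch))
      stop("signature channel(s) not in montage: ",
           paste(bad_ch, collapse = ", "), call. = FALSE)
    bad_b <- setdiff(band_signatures$band, bands$band)
    if (length(bad_b))
      stop("signature band(s) not in band set: ",
           paste(bad_b, collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, group_assignment = group_assignment,
         laps = laps, turns_per_direction_per_lap = turns_per_direction_per_lap,
         fs = fs, channel_labels = channel_labels,
         session_duration = session_duration, epoch_s = epoch_s,
         band_signatures = band_signatures, bands = bands,
         noise_sd = noise_sd, pink = pink, artifact_rate = artifact_rate,
         event_jitter = event_jitter),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Synthetic study config: %d subjects, %d laps x (%d L + %d R) turns\n",
              x$n_subjects, x$laps, x$turns_per_direction_per_lap,
              x$turns_per_direction_per_lap))
  cat(sprintf("  %g s at %g Hz, %d channels; noise sd %g uV%s; %d signature(s)\n",
              x$session_duration, x$fs, length(x$channel_labels), x$noise_sd,
              if (x$pink) " (1/f)" else "", nrow(x$band_signatures)))
  invisible(x)
}

#' Turn-event schedule
#'
#' Lays out `laps x 2 x turns_per_direction_per_lap` turn events, alternating
#' LEFT/RIGHT, evenly spaced within each lap with optional seeded jitter.
#'
#' @param laps Number of laps.
#' @param turns_per_direction_per_lap Turns per direction per lap.
#' @param session_duration Session length (s).
#' @param fs Sampling rate (Hz).
#' @param jitter_frac Uniform jitter amplitude as a fraction of the
#'   inter-event slot (must be < 0.5 to keep onsets strictly increasing);
#'   draws come from the current RNG.
#' @return Data frame of events: `onset_sample` (1-based), `direction`, `lap`.
#' @export
#' @examples
#' ev <- event_schedule(4, 4, 300, 500)
#' table(ev$direction)   # 16 LEFT, 16 RIGHT
event_schedule <- function(laps, turns_per_direction_per_lap,
                           session_duration, fs, jitter_frac = 0) {
  if (laps < 0 || turns_per_direction_per_lap < 0)
    stop("laps and turns per direction must be >= 0", call. = FALSE)
  if (jitter_frac < 0 || jitter_frac >= 0.5)
    stop("jitter_frac must lie in [0, 0.5)", call. = FALSE)
  n_per_lap <- 2L * turns_per_direction_per_lap
  n <- laps * n_per_lap
  if (n == 0L) return(empty_events())
  slot <- session_duration / laps / n_per_lap
  if (slot * fs < 1)
    stop("session too short to schedule ", n, " non-overlapping events",
         call. = FALSE)
  lap <- rep(seq_len(laps), each = n_per_lap)
  k <- rep(seq_len(n_per_lap), times = laps)
  onset_s <- (lap - 1) * (session_duration / laps) + (k - 0.5) * slot
  if (jitter_frac > 0)
    onset_s <- onset_s + runif(n, -jitter_frac, jitter_frac) * slot
  data.frame(
    onset_sample = pmin(pmax(round(onset_s * fs) + 1L, 1L),
                        floor(session_duration * fs)),
    direction = rep(c("LEFT", "RIGHT"), length.out = n_per_lap)[k],
    lap = lap,
    stringsAsFactors = FALSE
  )
}

#' Add a narrow-band burst to one channel
#'
#' Adds a pure sinusoid of the given amplitude and frequency to the named
#' channel inside a time window; every other sample is untouched.  The mean
#' power contributed to the windowed segment is the analytic
#' `amplitude^2 / 2`.
#'
#' @param session An [eeg_session()].
#' @param channel Channel name.
#' @param center_freq Burst frequency (Hz).
#' @param window Numeric `c(start_s, end_s)` within the session.
#' @param amplitude Peak amplitude (uV), `>= 0`.
#' @param phase Phase offset (radians).
#' @return The modified session.
#' @export
inject_band_burst <- function(session, channel, center_freq, window,
                              amplitude, phase = 0) {
  stopifnot(inherits(session, "eeg_session"))
  ch <- match(channel, session$channel_labels)
  if (is.na(ch)) stop("unknown channel: ", channel, call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  n <- ncol(session$data)
  i0 <- max(1L, floor(window[1] * session$fs) + 1L)
  i1 <- min(n, ceiling(window[2] * session$fs))
  if (window[1] < 0 || window[1] >= window[2] || i0 > n)
    stop("burst window out of range", call. = FALSE)
  if (amplitude == 0) return(session)
  idx <- i0:i1
  t <- (idx - 1) / session$fs
  burst <- amplitude * sin(2 * pi * center_freq * t + phase)
  # oscillatory bursts displace no baseline: remove the partial-cycle DC
  burst <- burst - mean(burst)
  session$data[ch, idx] <- session$data[ch, idx] + burst
  session
}

# 1/f-shape a white-noise vector in the frequency domain, preserving its
# standard deviation.  Frequencies below 1 Hz are clamped to avoid the pole.
pink_shape <- function(x, fs) {
  n <- length(x)
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f <- pmin(f, fs - f)           # two-sided frequency axis
  w <- 1 / sqrt(pmax(f, 1))
  w[1] <- 0                      # drop DC
  y <- Re(fft(fft(x) * w, inverse = TRUE)) / n
  y * sd(x) / sd(y)
}

# Power of the white background inside [low, high]; the reference against
# which signature multipliers are defined.  A 1 uV^2 floor keeps bursts
# well-defined for noiseless sessions.
background_band_power <- function(noise_sd, low, high, fs) {
  p <- noise_sd^2 * (high - low) / (fs / 2)
  if (p <= 0) 1 else p
}

#' Generate one synthetic driving-EEG session
#'
#' Deterministic given `(cfg, subject_id, seed)`: Gaussian (optionally
#' 1/f-shaped) background noise, a jittered turn-event schedule, and, for
#' every turn event matching one of the subject's group signatures, a
#' narrow-band burst at the band's centre frequency whose power raises that
#' band to `multiplier` times the background band power over the turn epoch.
#'
#' @param cfg A [generator_config()].
#' @param subject_id Subject id present in `cfg$group_assignment`.
#' @param seed Integer seed for the study; each subject uses a derived
#'   sub-stream.
#' @return An [eeg_session()].
#' @export
#' @examples
#' cfg <- generator_config(session_duration = 60, laps = 1)
#' s <- generate_session(cfg, "S01", seed = 1)
#' s
generate_session <- function(cfg, subject_id, seed) {
  stopifnot(inherits(cfg, "generator_config"))
  idx <- match(subject_id, names(cfg$group_assignment))
  if (is.na(idx)) stop("unknown subject: ", subject_id, call. = FALSE)
  group <- cfg$group_assignment[[idx]]
  n_ch <- length(cfg$channel_labels)
  n <- round(cfg$session_duration * cfg$fs)
  with_seed(derive_seed(seed, idx), {
    data <- matrix(rnorm(n_ch * n, sd = cfg$noise_sd), nrow = n_ch)
    if (cfg$pink && cfg$noise_sd > 0)
      for (ch in seq_len(n_ch)) data[ch, ] <- pink_shape(data[ch, ], cfg$fs)
    events <- event_schedule(cfg$laps, cfg$turns_per_direction_per_lap,
                             cfg$session_duration, cfg$fs,
                             jitter_frac = cfg$event_jitter)
    session <- eeg_session(data, cfg$fs, cfg$channel_labels, events,
                           subject_id = subject_id, group = group)
    sig <- cfg$band_signatures[cfg$band_signatures$group == group, ,
                               drop = FALSE]
    if (nrow(events) && nrow(sig)) {
      for (e in seq_len(nrow(events))) {
        rows <- which(sig$direction == events$direction[e])
        for (r in rows) {
          b <- cfg$bands[cfg$bands$band == sig$band[r], ]
          p_bg <- background_band_power(cfg$noise_sd, b$low, b$high, cfg$fs)
          extra <- (sig$multiplier[r] - 1) * p_bg
          if (extra <= 0) next
          onset_s <- (events$onset_sample[e] - 1) / cfg$fs
          session <- inject_band_burst(
            session, sig$channel[r], (b$low + b$high) / 2,
            c(onset_s, onset_s + cfg$epoch_s),
            amplitude = sqrt(2 * extra), phase = runif(1, 0, 2 * pi))
        }
      }
    }
    if (cfg$artifact_rate > 0) {
      n_art <- rpois(1, cfg$artifact_rate * cfg$session_duration / 60)
      for (a in seq_len(n_art)) {
        ch <- sample(c("FP1", "FP2"), 1)
        t0 <- runif(1, 0, cfg$session_duration - 0.5)
        session <- inject_band_burst(session, ch, 2, c(t0, t0 + 0.5),
                                     amplitude = 80)
      }
    }
    session
  })
}

#' Generate every subject of a synthetic study
#'
#' @inheritParams generate_session
#' @return Named list of [eeg_session()] objects, one per subject.
#' @export
simulate_study <- function(cfg, seed) {
  stopifnot(inherits(cfg, "generator_config"))
  ids <- names(cfg$group_assignment)
  stats::setNames(lapply(ids, function(s) generate_session(cfg, s, seed)), ids)
}
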