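# Band-pass filtering, amplitude screening and epoch extraction.

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (default 1--30 Hz, 2nd order, i.e.
#' 12 dB/octave per pass) to every channel.  With `zero_phase = TRUE` the
#' filter runs forward and backward (`signal::filtfilt`), cancelling phase
#' shifts and doubling the effective roll-off.
#'
#' @param session An [eeg_session()].
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order per pass.
#' @param zero_phase Filter forward-backward (default) or forward only.
#' @return The filtered session; events are untouched.
#' @export
bandpass <- function(session, low = 1, high = 30, order = 2,
                     zero_phase = TRUE) {
  stopifnot(inherits(session, "eeg_session"))
  if (!(low > 0 && low < high && high < session$fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (session$fs / 2), type = "pass")
  for (ch in seq_len(nrow(session$data))) {
    session$data[ch, ] <- if (zero_phase)
      signal::filtfilt(bf, session$data[ch, ])
    else
      as.numeric(signal::filter(bf, session$data[ch, ]))
  }
  session
}

# Split one channel into slow (< split Hz) and fast (>= split Hz) parts
# with zero-phase 2nd-order Butterworth half-band filters.
split_slow_fast <- function(x, fs, split) {
  lp <- signal::butter(2, split / (fs / 2), type = "low")
  slow <- signal::filtfilt(lp, x)
  list(slow = slow, fast = x - slow)
}

#' Amplitude screening of an epoch
#'
#' Decomposes each channel into a slow (< `split` Hz) and a fast component
#' and rejects the epoch if any channel's slow peak exceeds `slow_max` or
#' fast peak exceeds `fast_max` (peak = maximum absolute sample).  The
#' defaults reflect normal alpha/beta amplitude ceilings: 50 uV for slow
#' and 30 uV for fast waves.
#'
#' @param epoch An epoch as returned by [extract_epochs()].
#' @param slow_max,fast_max Peak thresholds in uV.
#' @param split Slow/fast boundary frequency (Hz).
#' @return `TRUE` to keep, `FALSE` to reject.
#' @export
amplitude_screen <- function(epoch, slow_max = 50, fast_max = 30, split = 8) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (slow_max <= 0 || fast_max <= 0)
    stop("thresholds must be positive", call. = FALSE)
  if (ncol(epoch$data) == 0) stop("empty epoch", call. = FALSE)
  for (ch in seq_len(nrow(epoch$data))) {
    parts <- split_slow_fast(epoch$data[ch, ], epoch$fs, split)
    if (max(abs(parts$slow)) > slow_max) return(FALSE)
    if (max(abs(parts$fast)) > fast_max) return(FALSE)
  }
  TRUE
}

#' Extract labeled epochs around turn events
#'
#' Cuts one channels-by-samples epoch per event, spanning
#' `[onset - pre_s, onset + post_s)`.  Events whose window would cross the
#' recording bounds are skipped with a message.
#'
#' @param session An [eeg_session()] with events.
#' @param window Numeric `c(pre_s, post_s)` in seconds.
#' @return List of `eeg_epoch` objects.
#' @export
extract_epochs <- function(session, window = c(0, 5)) {
  stopifnot(inherits(session, "eeg_session"))
  if (!nrow(session$events)) stop("session has no events", call. = FALSE)
  pre <- round(window[1] * session$fs)
  len <- round(sum(window) * session$fs)
  n <- ncol(session$data)
  out <- list()
  skipped <- 0L
  for (e in seq_len(nrow(session$events))) {
    i0 <- session$events$onset_sample[e] - pre
    i1 <- i0 + len - 1L
    if (i0 < 1L || i1 > n) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <- eeg_epoch(
      session$data[, i0:i1, drop = FALSE], session$fs,
      label = session$events$direction[e],
      onset_sample = session$events$onset_sample[e],
      lap = session$events$lap[e])
  }
  if (skipped)
    message(skipped, " event(s) skipped: window exceeds recording bounds")
  out
}

#' Screen a list of epochs
#'
#' Applies [amplitude_screen()] to each epoch and drops rejections,
#' reporting the rejected count.
#'
#' @param epochs List of epochs.
#' @inheritParams amplitude_screen
#' @return The surviving epochs; the number rejected is reported via
#'   `message()` and attached as attribute `"n_rejected"`.
#' @export
screen_epochs <- function(epochs, slow_max = 50, fast_max = 30, split = 8) {
  keep <- vapply(epochs, amplitude_screen, logical(1),
                 slow_max = slow_max, fast_max = fast_max, split = split)
  if (any(!keep)) message(sum(!keep), " epoch(s) rejected by amplitude screening")
  structure(epochs[keep], n_rejected = sum(!keep))
}

#' Artifact-removal hook
#'
#' Placeholder for an independent-component-analysis cleaning pass: accepts
#' a session and a cleaning function and returns the cleaned session.  The
#' default is the identity (synthetic sessions are generated clean, or with
#' transients that the amplitude screen removes).
#'
#' @param session An [eeg_session()].
#' @param fun A function `session -> session`.
#' @return The (possibly cleaned) session.
#' @export
ica_hook <- function(session, fun = identity) {
  out <- fun(session)
  if (!inherits(out, "eeg_session"))
    stop("ICA hook must return an eeg_session", call. = FALSE)
  out
}
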