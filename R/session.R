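# EEG session and epoch containers.

#' Construct an EEG session
#'
#' An `eeg_session` holds a channels-by-samples matrix in microvolts, the
#' sampling rate, ordered channel labels, and the turn-event table.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param events Data frame with columns `onset_sample` (1-based),
#'   `direction` (`"LEFT"`/`"RIGHT"`) and `lap`.
#' @param subject_id Optional subject identifier.
#' @param group Optional group tag (e.g. `"G1"`).
#' @return An object of class `eeg_session`.
#' @export
eeg_session <- function(data, fs, channel_labels = CHANNELS_1020,
                        events = empty_events(), subject_id = NA, group = NA) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric", call. = FALSE)
  if (nrow(data) != length(channel_labels))
    stop("row count (", nrow(data), ") must equal channel label count (",
         length(channel_labels), ")", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar", call. = FALSE)
  events <- as.data.frame(events)
  needed <- c("onset_sample", "direction", "lap")
  if (!all(needed %in% names(events)))
    stop("events must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (nrow(events)) {
    if (any(events$onset_sample < 1L | events$onset_sample > ncol(data)))
      stop("event onsets must lie within the recording", call. = FALSE)
    if (!all(events$direction %in% c("LEFT", "RIGHT")))
      stop("event direction must be LEFT or RIGHT", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         events = events, subject_id = subject_id, group = group),
    class = "eeg_session"
  )
}

empty_events <- function() {
  data.frame(onset_sample = integer(), direction = character(),
             lap = integer(), stringsAsFactors = FALSE)
}

#' @export
print.eeg_session <- function(x, ...) {
  dur <- ncol(x$data) / x$fs
  cat("EEG session", if (!is.na(x$subject_id)) paste0("'", x$subject_id, "'"),
      if (!is.na(x$group)) paste0("(group ", x$group, ")"), "\n")
  cat(sprintf("  %d channels x %d samples (%.1f s at %g Hz)\n",
              nrow(x$data), ncol(x$data), dur, x$fs))
  if (nrow(x$events)) {
    tab <- table(x$events$direction)
    cat(sprintf("  %d turn events (%s)\n", nrow(x$events),
                paste(names(tab), tab, sep = "=", collapse = ", ")))
  } else cat("  no events\n")
  invisible(x)
}

# A single labeled epoch: channels x samples around one turn event.
eeg_epoch <- function(data, fs, label, onset_sample = NA_integer_,
                      lap = NA_integer_) {
  stopifnot(label %in% c("LEFT", "RIGHT"))
  structure(
    list(data = as.matrix(data), fs = fs, label = label,
         onset_sample = onset_sample, lap = lap),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("EEG epoch: %s, %d channels x %d samples at %g Hz\n",
              x$label, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}
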