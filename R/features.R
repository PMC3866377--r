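# FFT absolute band-power (QEEG) features and time-domain electrode means.

#' Absolute band power of a single channel
#'
#' Single-taper (rectangular window by default) periodogram power summed
#' over the frequency bins whose centre lies inside `[low, high]` (closed
#' interval).  The periodogram is normalized so that the total over all
#' bins equals the signal's mean squared value (Parseval convention); the
#' mean is removed before the FFT, so DC carries no power.  Units: uV^2
#' for input in uV.
#'
#' @param x Numeric vector, one channel segment in uV.
#' @param fs Sampling rate (Hz).
#' @param band Numeric `c(low, high)` in Hz, inside `(0, fs/2)`.
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return Absolute power in uV^2.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1/500)[-1]
#' band_power(10 * sin(2 * pi * 10 * t), 500, c(8, 12))  # ~ 50 uV^2
band_power <- function(x, fs, band, window = c("rectangular", "hann")) {
  window <- match.arg(window)
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band must lie strictly inside (0, fs/2)", call. = FALSE)
  p <- periodogram_fold(x, fs, window)
  sum(p$power[p$freq >= band[1] & p$freq <= band[2]])
}

# One-sided folded periodogram: power[k] sums the +/- frequency bins so
# that sum(power) == mean(x^2) of the (tapered, demeaned) signal.
periodogram_fold <- function(x, fs, window = "rectangular") {
  x <- x - mean(x)
  n <- length(x)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    x <- x * w / sqrt(mean(w^2))   # preserve mean-square normalization
  }
  p2 <- Mod(fft(x))^2 / n^2
  half <- floor(n / 2)
  k <- 0:half
  power <- p2[k + 1]
  fold <- k > 0 & k < n - k        # bins with a distinct mirror image
  power[fold] <- power[fold] + p2[n - k[fold] + 1]
  list(freq = k * fs / n, power = power)
}

#' Build the epochs-by-features absolute-power matrix
#'
#' One row per epoch, one column per (channel, band) pair, named in the
#' electrode-number/band-letter convention (`"15d"` = T5, delta).  Columns
#' are channel-major in montage order.
#'
#' @param epochs List of epochs from [extract_epochs()], equal lengths.
#' @param bands Band table, see [default_bands()].
#' @param channel_labels Montage used for feature numbering; defaults to
#'   the channels of the first epoch.
#' @param window Taper passed to [band_power()].
#' @return An object of class `feature_matrix`: list with `values`
#'   (epochs x features matrix), `feature_info` (id/channel/band table) and
#'   `labels` (per-epoch `"LEFT"`/`"RIGHT"`).
#' @export
build_feature_matrix <- function(epochs, bands = default_bands(),
                                 channel_labels = NULL,
                                 window = "rectangular") {
  if (!length(epochs)) stop("no epochs", call. = FALSE)
  lens <- vapply(epochs, function(e) ncol(e$data), 1L)
  if (length(unique(lens)) != 1L)
    stop("epochs must all have the same length", call. = FALSE)
  validate_bands(bands)
  channel_labels <- channel_labels %||% rownames(epochs[[1]]$data)
  n_ch <- length(channel_labels)
  info <- data.frame(
    id = feature_id(rep(channel_labels, each = nrow(bands)),
                    rep(bands$band, times = n_ch),
                    channel_labels = channel_labels),
    channel = rep(channel_labels, each = nrow(bands)),
    band = rep(bands$band, times = n_ch),
    stringsAsFactors = FALSE
  )
  values <- matrix(NA_real_, nrow = length(epochs), ncol = nrow(info),
                   dimnames = list(NULL, info$id))
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    col <- 1L
    for (ch in seq_len(n_ch)) {
      x <- ep$data[ch, ]
      for (b in seq_len(nrow(bands))) {
        values[i, col] <- band_power(x, ep$fs, c(bands$low[b], bands$high[b]),
                                     window = window)
        col <- col + 1L
      }
    }
  }
  feature_matrix(values, info,
                 labels = vapply(epochs, function(e) e$label, ""))
}

#' @rdname build_feature_matrix
#' @param values Epochs x features matrix.
#' @param feature_info Data frame with columns `id`, `channel`, `band`.
#' @param labels Per-epoch class labels.
#' @export
feature_matrix <- function(values, feature_info, labels) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("band powers must be >= 0", call. = FALSE)
  if (nrow(values) != length(labels))
    stop("one label per epoch required", call. = FALSE)
  if (ncol(values) != nrow(feature_info))
    stop("feature_info must describe every column", call. = FALSE)
  colnames(values) <- feature_info$id
  structure(list(values = values, feature_info = feature_info,
                 labels = as.character(labels)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("Feature matrix: %d epochs x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

# Restrict a feature matrix to selected columns / epochs.
subset_features <- function(fm, ids = NULL, rows = NULL) {
  ids <- ids %||% fm$feature_info$id
  j <- match(ids, fm$feature_info$id)
  if (anyNA(j)) stop("unknown feature id(s)", call. = FALSE)
  rows <- rows %||% seq_len(nrow(fm$values))
  feature_matrix(fm$values[rows, j, drop = FALSE],
                 fm$feature_info[j, , drop = FALSE],
                 fm$labels[rows])
}

#' Per-class time-domain electrode means
#'
#' Concatenates the labeled turn epochs of each class, keeps the first
#' `per_class_duration` seconds, and returns the per-electrode mean: at
#' 500 Hz and 50 s per class this averages a 19 x 25000 segment into a
#' 19 x 1 vector per class.
#'
#' @param session An [eeg_session()] with events.
#' @param per_class_duration Seconds of signal per class (default 50).
#' @param epoch_s Seconds of signal counted per turn event.
#' @return Channels x 2 matrix with columns `LEFT` and `RIGHT`.
#' @export
time_domain_means <- function(session, per_class_duration = 50, epoch_s = 5) {
  stopifnot(inherits(session, "eeg_session"))
  epochs <- extract_epochs(session, c(0, epoch_s))
  need <- round(per_class_duration * session$fs)
  out <- matrix(NA_real_, nrow = nrow(session$data), ncol = 2,
                dimnames = list(session$channel_labels, c("LEFT", "RIGHT")))
  for (cls in c("LEFT", "RIGHT")) {
    seg <- do.call(cbind, lapply(Filter(function(e) e$label == cls, epochs),
                                 function(e) e$data))
    if (is.null(seg) || ncol(seg) < need)
      stop("insufficient ", cls, " signal: need ", per_class_duration,
           " s, have ", if (is.null(seg)) 0 else ncol(seg) / session$fs, " s",
           call. = FALSE)
    out[, cls] <- rowMeans(seg[, seq_len(need), drop = FALSE])
  }
  out
}

# Per-epoch mean vector for each epoch (channels x epochs).
epoch_means <- function(epochs) {
  vapply(epochs, function(e) rowMeans(e$data),
         numeric(nrow(epochs[[1]]$data)))
}
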