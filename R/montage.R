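# 10-20 montage and QEEG band definitions shared across the pipeline.

# Electrode order that defines the numeric feature-naming convention
# ("15d" = 15th electrode, T5, delta band).  Occipital leads precede the
# lateral frontal/temporal chain in this numbering.
CHANNELS_1020 <- c(
  "FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
  "F7", "F8", "T3", "T4", "T5", "T6", "FZ", "CZ", "PZ"
)

BAND_LETTERS <- c(delta = "d", theta = "t", alpha = "a",
                  beta = "b", high_beta = "h")

#' Canonical QEEG frequency bands
#'
#' The five absolute-power bands used throughout the pipeline: delta
#' 1--3.5 Hz, theta 4--7.5 Hz, alpha 8--12 Hz, beta 12.5--25 Hz and high
#' beta 25.5--30 Hz.
#'
#' @return A data frame with columns `band`, `low`, `high` (Hz).
#' @export
#' @examples
#' default_bands()
default_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "high_beta"),
    low  = c(1, 4, 8, 12.5, 25.5),
    high = c(3.5, 7.5, 12, 25, 30),
    stringsAsFactors = FALSE
  )
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("band", "low", "high") %in% names(bands)))
  if (any(bands$low >= bands$high))
    stop("band edges must satisfy low < high", call. = FALSE)
  o <- order(bands$low)
  b <- bands[o, ]
  if (nrow(b) > 1 && any(b$low[-1] <= b$high[-nrow(b)]))
    stop("bands must be non-overlapping and increasing", call. = FALSE)
  invisible(bands)
}

#' Feature identifiers in electrode-number/band-letter form
#'
#' Builds ids like `"15d"` (15th electrode, T5, delta) from channel names and
#' band names, or parses such ids back into channel/band.
#'
#' @param channel Channel name(s) from the 10--20 montage (e.g. `"T5"`).
#' @param band Band name(s): delta, theta, alpha, beta, high_beta.
#' @param channel_labels Montage defining the electrode numbering.
#' @return `feature_id()`: a character vector of ids. `parse_feature_id()`:
#'   a data frame with columns `id`, `channel`, `band`.
#' @export
#' @examples
#' feature_id("T5", "delta")           # "15d"
#' parse_feature_id("15d")
feature_id <- function(channel, band, channel_labels = CHANNELS_1020) {
  idx <- match(channel, channel_labels)
  if (anyNA(idx))
    stop("unknown channel(s): ", paste(channel[is.na(idx)], collapse = ", "),
         call. = FALSE)
  letter <- BAND_LETTERS[band]
  if (anyNA(letter))
    stop("unknown band(s): ", paste(band[is.na(letter)], collapse = ", "),
         call. = FALSE)
  paste0(idx, letter)
}

#' @rdname feature_id
#' @param id Feature id(s) such as `"15d"`.
#' @export
parse_feature_id <- function(id, channel_labels = CHANNELS_1020) {
  m <- regmatches(id, regexec("^([0-9]+)([dtabh])$", id))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed feature id(s): ", paste(id[bad], collapse = ", "),
         call. = FALSE)
  idx <- as.integer(vapply(m, `[`, "", 2L))
  if (any(idx < 1L | idx > length(channel_labels)))
    stop("electrode number out of montage range", call. = FALSE)
  letter <- vapply(m, `[`, "", 3L)
  data.frame(
    id = id,
    channel = channel_labels[idx],
    band = names(BAND_LETTERS)[match(letter, BAND_LETTERS)],
    stringsAsFactors = FALSE
  )
}
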