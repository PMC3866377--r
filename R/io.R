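# Session, network and report input/output.
#
# Sessions are stored either as EDF (16-bit, one signal per channel,
# physical dimension uV) or as CSV (samples x channels, header = channel
# labels); either way a JSON sidecar carries the event table and run
# metadata, keeping the waveform format dialect-free.

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_events.json")
}

# Order-insensitive-enough fingerprint of a configuration list; cheap and
# dependency-free, used only to tag outputs for reproducibility checks.
config_fingerprint <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- as.double(utf8ToInt(as.character(s)))
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 997)) %% 4294967296)
}

write_sidecar <- function(session, path, seed = NULL, config = NULL) {
  meta <- list(
    fs = session$fs,
    n_samples = ncol(session$data),
    channel_labels = session$channel_labels,
    subject_id = session$subject_id,
    group = session$group,
    events = session$events,
    seed = seed,
    config_fingerprint = if (!is.null(config)) config_fingerprint(config),
    package_version = as.character(utils::packageVersion("eegcam"))
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) return(NULL)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Write an EEG session to disk
#'
#' `format = "csv"` writes a samples-by-channels table with the channel
#' labels as header; `format = "edf"` writes a 16-bit EDF file with one
#' signal per channel (physical dimension uV, one-second data records).
#' Both formats get a JSON event sidecar (`<stem>_events.json`) holding
#' events, sampling rate, subject/group tags, the seed and a configuration
#' fingerprint.
#'
#' @param session An [eeg_session()].
#' @param path Output file path.
#' @param format `"csv"` or `"edf"`.
#' @param seed,config Optional run metadata recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, format = c("csv", "edf"),
                          seed = NULL, config = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(session, "eeg_session"))
  if (format == "csv") {
    df <- as.data.frame(t(session$data))
    names(df) <- session$channel_labels
    write.csv(df, path, row.names = FALSE)
  } else {
    write_edf(session, path)
  }
  write_sidecar(session, path, seed = seed, config = config)
  invisible(path)
}

#' Read an EEG session from disk
#'
#' Counterpart of [write_session()]; the format is inferred from the file
#' extension unless given.  Events and metadata come from the JSON sidecar
#' when present.
#'
#' @param path File path.
#' @param format `"csv"`, `"edf"`, or `NULL` to infer from the extension.
#' @param fs Sampling rate, required for CSV files without a sidecar.
#' @return An [eeg_session()].
#' @export
read_session <- function(path, format = NULL, fs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- format %||%
    switch(tolower(tools::file_ext(path)), edf = "edf", "csv")
  meta <- read_sidecar(path)
  if (format == "csv") {
    df <- read.csv(path, check.names = FALSE)
    labels <- meta$channel_labels %||% names(df)
    missing <- setdiff(labels, names(df))
    if (length(missing))
      stop("CSV is missing channel column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    fs <- meta$fs %||% fs
    if (is.null(fs))
      stop("sampling rate unknown: no sidecar and no fs argument",
           call. = FALSE)
    data <- t(as.matrix(df[, labels, drop = FALSE]))
  } else {
    edf <- read_edf_raw(path)
    labels <- edf$labels
    fs <- edf$fs
    data <- edf$data
    if (!is.null(meta$n_samples) && meta$n_samples <= ncol(data))
      data <- data[, seq_len(meta$n_samples), drop = FALSE]
  }
  events <- if (!is.null(meta) && length(meta$events))
    as.data.frame(meta$events) else empty_events()
  eeg_session(data, fs, labels, events,
              subject_id = meta$subject_id %||% NA,
              group = meta$group %||% NA)
}

# --- minimal EDF (European Data Format) writer/reader ----------------------
# 256-byte fixed header + 256 bytes per signal, then 16-bit little-endian
# samples in one-second data records.  Enough of the format for round-trip
# storage of synthetic sessions; no annotations dialect.

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

write_edf <- function(session, path) {
  fs <- session$fs
  if (fs != round(fs))
    stop("EDF export needs an integer sampling rate", call. = FALSE)
  n_ch <- nrow(session$data)
  n <- ncol(session$data)
  n_rec <- ceiling(n / fs)
  pad <- n_rec * fs - n
  data <- if (pad > 0) cbind(session$data, matrix(0, n_ch, pad)) else
    session$data
  phys_max <- max(1, ceiling(max(abs(data))))
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(ifelse(is.na(session$subject_id), "X", session$subject_id), 80),
    pad_field("eegcam synthetic session", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + n_ch), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(n_ch, 4),
    paste(vapply(session$channel_labels, pad_field, "", width = 16),
          collapse = ""),
    paste(rep(pad_field("", 80), n_ch), collapse = ""),      # transducer
    paste(rep(pad_field("uV", 8), n_ch), collapse = ""),
    paste(rep(pad_field(-phys_max, 8), n_ch), collapse = ""),
    paste(rep(pad_field(phys_max, 8), n_ch), collapse = ""),
    paste(rep(pad_field(-dig_max, 8), n_ch), collapse = ""),
    paste(rep(pad_field(dig_max, 8), n_ch), collapse = ""),
    paste(rep(pad_field("", 80), n_ch), collapse = ""),      # prefilter
    paste(rep(pad_field(fs, 8), n_ch), collapse = ""),
    paste(rep(pad_field("", 32), n_ch), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round(data[, idx, drop = FALSE] * scale)
    block <- pmin(pmax(block, -dig_max), dig_max)
    # signals are stored sequentially within each record
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(n_ch), function(i) readChar(con, 16), ""))
  rd(80 * n_ch)
  rd(8 * n_ch)                           # physical dimension
  phys_min <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  rd(80 * n_ch)
  spr <- as.integer(vapply(seq_len(n_ch), function(i) rd(8), ""))
  rd(32 * n_ch)
  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates are not supported", call. = FALSE)
  fs <- spr[1] / rec_dur
  data <- matrix(0, n_ch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = n_ch * spr[1], size = 2,
                   endian = "little")
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      matrix(raw, nrow = n_ch, byrow = TRUE)
  }
  for (ch in seq_len(n_ch)) {
    g <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
    data[ch, ] <- phys_min[ch] + (data[ch, ] - dig_min[ch]) * g
  }
  list(data = data, fs = fs, labels = labels)
}

# --- network and table serialization ---------------------------------------

#' Serialize a Hopfield network to JSON
#'
#' `{n, W (row-major), T, stored: [{label, bits}]}`.
#'
#' @param net A [hopfield()] network.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stored <- lapply(seq_len(nrow(net$patterns)), function(i) {
    list(label = if (is.null(net$labels)) NULL else net$labels[i],
         bits = as.integer(net$patterns[i, ]))
  })
  jsonlite::write_json(
    list(n = net$n, W = as.integer(t(net$weights)), T = net$thresholds,
         stored = stored),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  patterns <- do.call(rbind, lapply(x$stored$bits, as.numeric))
  labels <- x$stored$label
  net <- hopfield(patterns, labels = labels, thresholds = as.numeric(x$T))
  W <- matrix(as.integer(x$W), nrow = x$n, byrow = TRUE)
  if (!isTRUE(all.equal(W, unname(net$weights))))
    net$weights <- W                     # honor stored weights if they differ
  net
}

#' Write / read a feature matrix as CSV
#'
#' One row per epoch; columns are the feature ids plus a final `label`
#' column.
#'
#' @param fm A [feature_matrix()].
#' @param path File path.
#' @return `path` (write) or a [feature_matrix()] (read).
#' @export
write_feature_csv <- function(fm, path) {
  df <- as.data.frame(fm$values, check.names = FALSE)
  df$label <- fm$labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @param channel_labels Montage used to parse the feature ids.
#' @export
read_feature_csv <- function(path, channel_labels = CHANNELS_1020) {
  df <- read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("no label column", call. = FALSE)
  ids <- setdiff(names(df), "label")
  feature_matrix(as.matrix(df[, ids, drop = FALSE]),
                 parse_feature_id(ids, channel_labels),
                 df$label)
}

#' Write a performance report as JSON
#'
#' @param report A [performance_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML key/value file mirroring [generator_config()] plus analysis
#' settings; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return List with `generator` (a [generator_config()]) and `analysis`
#'   (filter band, screening thresholds, selection sizes, CV settings).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_keys <- setdiff(names(formals(generator_config)), "channel_labels")
  analysis_defaults <- list(low = 1, high = 30, slow_max = 50, fast_max = 30,
                            split = 8, n_select_channels = 7,
                            n_select_bands = 2, train_frac = 0.7,
                            n_repeats = 10, distortion = 0.15, n_trials = 20,
                            n_group_features = 6)
  unknown <- setdiff(names(y), c(gen_keys, names(analysis_defaults), "seed"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  gen <- y[intersect(names(y), gen_keys)]
  if (!is.null(gen$group_assignment))
    gen$group_assignment <- unlist(gen$group_assignment)
  if (!is.null(gen$band_signatures))
    gen$band_signatures <- as.data.frame(gen$band_signatures)
  analysis <- utils::modifyList(analysis_defaults,
                                y[intersect(names(y), names(analysis_defaults))])
  list(generator = do.call(generator_config, gen), analysis = analysis,
       seed = y$seed %||% 1)
}
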