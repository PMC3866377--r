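# Independent oracles and small fixtures shared across the suite.

# Welch two-sample t statistic, coded directly from the formula.
welch_t_oracle <- function(x, y) {
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  (mean(x) - mean(y)) / se
}

# Hebbian weight matrix by the definitional triple loop.
hebbian_oracle <- function(patterns) {
  n <- ncol(patterns)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (p in seq_len(nrow(patterns)))
      W[i, j] <- W[i, j] + patterns[p, i] * patterns[p, j]
  }
  W
}

# Synchronous update by explicit per-neuron loops (sign(0) -> +1).
sync_oracle <- function(W, thresholds, state) {
  n <- length(state)
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- 0
    for (j in seq_len(n)) h <- h + W[i, j] * state[j]
    out[i] <- if (h - thresholds[i] >= 0) 1 else -1
  }
  out
}

# All 2^n bipolar states.
all_states <- function(n) {
  g <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(g) <- NULL
  g
}

# Brute-force fixed points: states where every neuron already satisfies the
# sign rule (equivalently: no single-neuron update changes anything).
fixed_points_oracle <- function(W, thresholds, n) {
  states <- all_states(n)
  keep <- apply(states, 1, function(s)
    all(sync_oracle(W, thresholds, s) == s))
  states[keep, , drop = FALSE]
}

# Deterministic recall oracle: repeated synchronous updates with cycle cap.
sync_recall_oracle <- function(W, thresholds, probe, max_iter = 40) {
  state <- probe
  for (it in seq_len(max_iter)) {
    new_state <- sync_oracle(W, thresholds, state)
    if (all(new_state == state)) break
    state <- new_state
  }
  state
}

hamming <- function(a, b) sum(a != b)

# A small, fast synthetic study used by several files: 2 laps x 6 turns per
# direction in 150 s, so >= 11 epochs per class survive the boundary skip.
small_config <- function(...) {
  args <- utils::modifyList(
    list(session_duration = 150, laps = 2, turns_per_direction_per_lap = 6,
         event_jitter = 0.05),
    list(...))
  do.call(generator_config, args)
}

# Recovery config: planted effect spanning 7 channels x 2 bands so the
# default two-stage selection is fully informative.
recovery_signatures <- function(multiplier = 3) {
  ch <- c("T5", "FP1", "P3", "O1", "F7", "T4", "FP2")
  data.frame(
    group = "G1",
    direction = rep(c("RIGHT", "LEFT"), c(8, 6)),
    channel = c(ch[1:4], ch[1:4], ch[5:7], ch[5:7]),
    band = rep(c("delta", "alpha", "delta", "alpha"), c(4, 4, 3, 3)),
    multiplier = multiplier,
    stringsAsFactors = FALSE
  )
}

# Feature matrix straight from numbers (bypasses the band-power stage) for
# selection/evaluation tests; values are shifted to stay non-negative.
toy_feature_matrix <- function(values, labels,
                               channels = eegcam:::CHANNELS_1020,
                               bands = default_bands()$band) {
  info <- data.frame(
    id = feature_id(rep(channels, each = length(bands)),
                    rep(bands, times = length(channels))),
    channel = rep(channels, each = length(bands)),
    band = rep(bands, times = length(channels)),
    stringsAsFactors = FALSE
  )
  info <- info[seq_len(ncol(values)), , drop = FALSE]
  feature_matrix(values, info, labels)
}
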