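# Orchestration of the four experiments: time-domain baseline, band-wise
# classification, group-pattern network, and per-subject Monte-Carlo
# cross-validation.

#' Performance report container
#'
#' @param accuracy Pattern-level accuracy in `[0, 1]`.
#' @param bit_accuracy Bit-level performance in `[0, 1]` (or `NA`).
#' @param per_repeat Per-repeat (or per-trial) accuracies.
#' @param n_train,n_test Training and test sizes.
#' @param seed Seed used.
#' @param significance p-value against the chance-level null (exact
#'   binomial unless noted).
#' @param notes Free-text notes.
#' @param extra Optional named list of experiment-specific fields.
#' @return An object of class `performance_report`.
#' @export
performance_report <- function(accuracy, bit_accuracy = NA_real_,
                               per_repeat = numeric(0), n_train = NA,
                               n_test = NA, seed = NULL,
                               significance = NA_real_, notes = "",
                               extra = list()) {
  stopifnot(is.na(accuracy) || (accuracy >= 0 && accuracy <= 1))
  structure(
    c(list(accuracy = accuracy, bit_accuracy = bit_accuracy,
           mean_error = 1 - bit_accuracy, per_repeat = per_repeat,
           n_train = n_train, n_test = n_test, seed = seed,
           significance = significance, notes = notes), extra),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Performance report\n")
  cat(sprintf("  accuracy: %.1f%%", 100 * x$accuracy))
  if (!is.na(x$bit_accuracy))
    cat(sprintf("  |  bit-level: %.1f%% (mean error %.3f)",
                100 * x$bit_accuracy, x$mean_error))
  cat("\n")
  if (length(x$per_repeat) > 1)
    cat(sprintf("  per repeat: %s\n",
                paste(sprintf("%.2f", x$per_repeat), collapse = " ")))
  if (!is.na(x$significance))
    cat(sprintf("  significance vs chance: p = %.3g\n", x$significance))
  if (nzchar(x$notes)) cat("  ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Time-domain baseline classification
#'
#' The simplest pipeline: per-class electrode means over
#' `per_class_duration` seconds of turn signal are binarized into two
#' prototypes (centred by the grand mean of the class means), constant
#' positions are pruned, a two-pattern Hebbian network is trained, and
#' held-out per-epoch mean vectors (up to `n_test_per_class` per class,
#' seeded draw from the epochs not used for the prototypes) are classified.
#'
#' @param session An [eeg_session()] (typically band-passed first).
#' @param per_class_duration Seconds of signal per class prototype.
#' @param epoch_s Turn-epoch duration (s).
#' @param n_test_per_class Maximum test vectors per class (default 10);
#'   capped by the number of held-out epochs available.
#' @param seed Seed for the test-epoch draw and recall order.
#' @return A [performance_report()] with `n_effective` in `extra`.
#' @export
time_domain_baseline <- function(session, per_class_duration = 50,
                                 epoch_s = 5, n_test_per_class = 10,
                                 seed = NULL) {
  means <- time_domain_means(session, per_class_duration, epoch_s)
  center <- rowMeans(means)
  prototypes <- t(sign_bipolar(means - center))   # 2 x channels, L/R rows
  keep <- prune_constant(prototypes)
  net <- hopfield(prototypes[, keep, drop = FALSE], rownames(prototypes))
  epochs <- extract_epochs(session, c(0, epoch_s))
  labels <- vapply(epochs, function(e) e$label, "")
  # the prototype means consumed the first per_class_duration seconds of
  # each class; only later epochs are eligible as held-out probes
  n_proto <- ceiling(per_class_duration / epoch_s)
  held <- lapply(c(LEFT = "LEFT", RIGHT = "RIGHT"), function(cls) {
    idx <- which(labels == cls)
    idx[-seq_len(min(n_proto, length(idx)))]
  })
  if (!length(held$LEFT) || !length(held$RIGHT))
    stop("no held-out epochs left after building the prototypes",
         call. = FALSE)
  with_seed(seed, {
    test_idx <- c(sample_n(held$LEFT, n_test_per_class),
                  sample_n(held$RIGHT, n_test_per_class))
    em <- epoch_means(epochs[test_idx])           # channels x epochs
    probes <- t(sign_bipolar(em - center))[, keep, drop = FALSE]
    pred <- predict(net, probes)
    correct <- sum(pred == labels[test_idx], na.rm = TRUE)
    performance_report(
      accuracy = correct / length(test_idx),
      n_train = 2, n_test = length(test_idx), seed = seed,
      significance = binom.test(correct, length(test_idx), 0.5,
                                alternative = "greater")$p.value,
      notes = sprintf("time-domain baseline, %d effective neurons of %d",
                      length(keep), ncol(prototypes)),
      extra = list(n_effective = length(keep)))
  })
}

# sample at most k elements without replacement (handles length-1 pools).
sample_n <- function(pool, k) {
  k <- min(k, length(pool))
  pool[sample.int(length(pool), k)]
}

#' Single-band Hopfield classification
#'
#' Restricts the feature matrix to one band's channels and evaluates the
#' two-prototype Hebbian classifier on it: a seeded stratified split keeps
#' `train_frac` of each class for binarization centring, pruning and
#' training; held-out epochs (up to `n_test_per_class` per class) are
#' classified.  The report mirrors the band-wise table structure (band,
#' effective neurons, performance).
#'
#' @param fm A [feature_matrix()] containing the band's features.
#' @param band Band name (e.g. `"delta"`).
#' @param n_test_per_class Maximum test epochs per class.
#' @param train_frac Training fraction of each class (default 0.7).
#' @param seed Seed.
#' @return A [performance_report()] with `band` and `n_effective` in
#'   `extra`.
#' @export
bandwise_classification <- function(fm, band, n_test_per_class = 10,
                                    train_frac = 0.7, seed = NULL) {
  ids <- fm$feature_info$id[fm$feature_info$band == band]
  if (!length(ids)) stop("unknown band: ", band, call. = FALSE)
  eval_prototype_holdout(fm, ids, n_test_per_class, train_frac, seed,
                         notes_fmt = paste0("band ", band,
                                            ": %d effective neurons of %d"),
                         extra = list(band = band))
}

# Shared holdout evaluation for the pooled experiments: train the
# two-prototype net on a stratified split of the epochs restricted to
# `ids`, classify held-out epochs binarized with the training centres.
eval_prototype_holdout <- function(fm, ids, n_test_per_class, train_frac,
                                   seed, notes_fmt, extra = list()) {
  left <- which(fm$labels == "LEFT")
  right <- which(fm$labels == "RIGHT")
  with_seed(seed, {
    tr <- c(sample_n(left, round(train_frac * length(left))),
            sample_n(right, round(train_frac * length(right))))
    train_fm <- subset_features(fm, ids, rows = sort(tr))
    bin <- binarize(train_fm)
    keep <- prune_constant(bin$prototypes)
    net <- hopfield(bin$prototypes[, keep, drop = FALSE],
                    rownames(bin$prototypes))
    test_idx <- c(sample_n(setdiff(left, tr), n_test_per_class),
                  sample_n(setdiff(right, tr), n_test_per_class))
    test_fm <- subset_features(fm, ids, rows = test_idx)
    probes <- sign_bipolar(sweep(test_fm$values, 2, bin$center))[
      , keep, drop = FALSE]
    pred <- predict(net, probes)
    correct <- sum(pred == fm$labels[test_idx], na.rm = TRUE)
    performance_report(
      accuracy = correct / length(test_idx),
      n_train = length(tr), n_test = length(test_idx), seed = seed,
      significance = binom.test(correct, length(test_idx), 0.5,
                                alternative = "greater")$p.value,
      notes = sprintf(notes_fmt, length(keep), length(ids)),
      extra = c(extra, list(n_effective = length(keep))))
  })
}

#' Group-level stable patterns
#'
#' Builds the six stable points of the group experiment: for each
#' behavioural group, epochs of that group's subjects are pooled and the
#' LEFT/RIGHT prototypes over the jointly selected features are binarized
#' (centred within the group, so each group's pair is complementary).
#'
#' When `feature_ids` is `NULL` the features are chosen for grouping
#' power: candidates are ranked by their one-way F statistic across the
#' `group x direction` cells, and, because a content-addressable memory
#' needs distinct stable states, lower-ranked candidates are swapped in
#' when two cells would otherwise collapse onto the same pattern.  A
#' warning is emitted if no distinct assignment exists.
#'
#' @param fms Named list of per-subject [feature_matrix()] objects.
#' @param groups Named character vector subject -> group (names matching
#'   `fms`).
#' @param feature_ids Jointly selected feature ids; when `NULL`, selected
#'   by the cell-separation ranking above.
#' @param n_features Number of features when selecting jointly (default 6).
#' @return Matrix of +/-1 patterns, one row per `group.direction` cell
#'   (e.g. `"G1.RIGHT"`), with the selected ids as column names and the
#'   ids in attribute `"feature_ids"`.
#' @export
group_patterns <- function(fms, groups, feature_ids = NULL, n_features = 6) {
  groups <- groups[names(fms)]
  if (anyNA(groups)) stop("every feature matrix needs a group tag", call. = FALSE)
  if (length(unique(groups)) < 2)
    stop("need at least two groups", call. = FALSE)
  pool <- function(sel) {
    feature_matrix(do.call(rbind, lapply(fms[sel], function(f) f$values)),
                   fms[[1]]$feature_info,
                   unlist(lapply(fms[sel], function(f) f$labels)))
  }
  build <- function(ids) {
    cells <- expand.grid(direction = c("LEFT", "RIGHT"),
                         group = sort(unique(groups)),
                         stringsAsFactors = FALSE)
    out <- matrix(NA_real_, nrow = nrow(cells), ncol = length(ids),
                  dimnames = list(paste(cells$group, cells$direction,
                                        sep = "."), ids))
    for (g in unique(groups)) {
      bin <- binarize(pool(which(groups == g)), ids)
      for (dir in rownames(bin$prototypes))
        out[paste(g, dir, sep = "."), ] <- bin$prototypes[dir, ]
    }
    if (anyNA(out)) stop("missing group/direction cell", call. = FALSE)
    out
  }
  if (is.null(feature_ids)) {
    all_fm <- pool(seq_along(fms))
    cell <- paste(rep(groups, vapply(fms, function(f) length(f$labels), 1L)),
                  all_fm$labels, sep = ".")
    f_stat <- apply(all_fm$values, 2, function(v) {
      if (var(v) == 0) return(0)
      unname(stats::oneway.test(v ~ factor(cell),
                                var.equal = TRUE)$statistic)
    })
    cand <- all_fm$feature_info$id[order(-f_stat)]
    feature_ids <- cand[seq_len(n_features)]
    out <- build(feature_ids)
    k <- n_features
    while (anyDuplicated(out) && k < length(cand)) {
      k <- k + 1L
      feature_ids[n_features] <- cand[k]
      out <- build(feature_ids)
    }
  } else {
    out <- build(feature_ids)
  }
  if (anyDuplicated(out))
    warning("duplicate stable points: some group/direction cells share a pattern",
            call. = FALSE)
  attr(out, "feature_ids") <- feature_ids
  out
}

#' Monte-Carlo (random sub-sampling) cross-validation
#'
#' Per repeat: a seeded stratified split keeps `train_frac` of each class
#' for training; feature ranking, two-stage selection, binarization
#' centring, pruning and Hebbian training all use the training split only;
#' the held-out epochs are binarized with the training centres and
#' classified.  The mean over repeats is reported together with per-repeat
#' accuracies and an exact binomial p-value against chance.
#'
#' @param fm A [feature_matrix()].
#' @param train_frac Training fraction (default 0.7).
#' @param n_repeats Number of random splits (default 10).
#' @param n_select_channels,n_select_bands Two-stage selection sizes
#'   (default 7 channels x 2 bands).
#' @param seed Seed; repeat `r` uses a derived sub-stream.
#' @return A [performance_report()] with the per-repeat selected feature
#'   ids in `extra$selected_ids`.
#' @export
monte_carlo_cv <- function(fm, train_frac = 0.7, n_repeats = 10,
                           n_select_channels = 7, n_select_bands = 2,
                           seed = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  left <- which(fm$labels == "LEFT")
  right <- which(fm$labels == "RIGHT")
  if (length(left) < 2 || length(right) < 2)
    stop("need at least 2 epochs per class", call. = FALSE)
  per_repeat <- numeric(n_repeats)
  selected_ids <- vector("list", n_repeats)
  correct_total <- 0L
  n_total <- 0L
  n_train <- n_test <- NA
  for (r in seq_len(n_repeats)) {
    rs <- if (is.null(seed)) NULL else derive_seed(seed, r)
    split <- with_seed(rs, {
      # stratified; clamp so neither split ever loses a class entirely
      k_l <- min(max(round(train_frac * length(left)), 1L), length(left) - 1L)
      k_r <- min(max(round(train_frac * length(right)), 1L), length(right) - 1L)
      tr <- c(sample(left, k_l), sample(right, k_r))
      list(train = sort(tr), test = setdiff(seq_along(fm$labels), tr))
    })
    fit <- fit_split(fm, split$train, n_select_channels, n_select_bands)
    selected_ids[[r]] <- fit$effective_ids
    pred <- classify_split(fit, fm, split$test, seed = rs)
    hits <- sum(pred == fm$labels[split$test], na.rm = TRUE)
    per_repeat[r] <- hits / length(split$test)
    correct_total <- correct_total + hits
    n_total <- n_total + length(split$test)
    n_train <- length(split$train); n_test <- length(split$test)
  }
  performance_report(
    accuracy = mean(per_repeat), per_repeat = per_repeat,
    n_train = n_train, n_test = n_test, seed = seed,
    significance = binom.test(correct_total, n_total, 0.5,
                              alternative = "greater")$p.value,
    notes = sprintf("Monte-Carlo CV: %d repeats, %.0f/%.0f split",
                    n_repeats, 100 * train_frac, 100 * (1 - train_frac)),
    extra = list(selected_ids = selected_ids))
}

# Fit the selection + binarization + Hebbian stack on the training rows
# only (the leakage guard lives here: nothing below sees other rows).
fit_split <- function(fm, train_rows, n_select_channels, n_select_bands) {
  train_fm <- subset_features(fm, rows = train_rows)
  ranked <- rank_features(train_fm)
  sel <- two_stage_select(ranked, n_select_channels, n_select_bands)
  bin <- binarize(train_fm, sel)
  keep <- prune_constant(bin$prototypes)
  net <- hopfield(bin$prototypes[, keep, drop = FALSE],
                  rownames(bin$prototypes))
  list(net = net, selected = sel, keep = keep, center = bin$center,
       effective_ids = sel[keep])
}

classify_split <- function(fit, fm, test_rows, seed = NULL) {
  test_fm <- subset_features(fm, fit$selected, rows = test_rows)
  centred <- sweep(test_fm$values, 2, fit$center)
  probes <- sign_bipolar(centred)[, fit$keep, drop = FALSE]
  predict(fit$net, probes, seed = seed)
}

#' Full per-subject classification pipeline
#'
#' Band-pass filter, epoch around turns, amplitude-screen, keep the first
#' `n_per_class` surviving epochs per class, extract band-power features
#' and run [monte_carlo_cv()].
#'
#' @param session Raw [eeg_session()].
#' @param low,high Filter band (Hz).
#' @param epoch_s Epoch length (s).
#' @param n_per_class Epochs kept per class (default 10).
#' @param bands Band table.
#' @param slow_max,fast_max,split Screening parameters, see
#'   [amplitude_screen()].
#' @param ... Passed to [monte_carlo_cv()] (`train_frac`, `n_repeats`,
#'   selection sizes).
#' @param seed Seed.
#' @return A [performance_report()] for this subject.
#' @export
subject_pipeline <- function(session, low = 1, high = 30, epoch_s = 5,
                             n_per_class = 10, bands = default_bands(),
                             slow_max = 50, fast_max = 30, split = 8, ...,
                             seed = NULL) {
  filtered <- bandpass(session, low, high)
  epochs <- screen_epochs(extract_epochs(filtered, c(0, epoch_s)),
                          slow_max = slow_max, fast_max = fast_max,
                          split = split)
  labels <- vapply(epochs, function(e) e$label, "")
  picked <- c(head(which(labels == "LEFT"), n_per_class),
              head(which(labels == "RIGHT"), n_per_class))
  if (length(picked) < 2 * n_per_class)
    stop("fewer than ", n_per_class, " epochs per class survived screening",
         call. = FALSE)
  fm <- build_feature_matrix(epochs[sort(picked)], bands)
  monte_carlo_cv(fm, ..., seed = seed)
}

#' Run the full synthetic study benchmark
#'
#' Generates every subject of a synthetic study, then runs all four
#' experiments: the time-domain baseline and the pooled band-wise and
#' feature-selected classifications on the pooled feature matrix, the
#' six-pattern group distortion experiment, and the per-subject
#' Monte-Carlo pipelines.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer study seed.
#' @param distortion,n_trials Group-experiment settings (default 15%
#'   distortion, 20 trials).
#' @param n_group_features Jointly selected features for the group network
#'   (default 6).
#' @param n_test_pooled Test epochs per class for the pooled band-wise and
#'   feature-selected experiments (default 50; larger draws tame the
#'   sampling noise of small probe sets when comparing experiments).
#' @return List with elements `time_domain`, `bandwise` (list per band),
#'   `selected` (pooled 14-feature report), `group` (distortion-recall
#'   report), `subjects` (per-subject reports), `mean_subject_accuracy`
#'   and `group_patterns`.
#' @export
evaluate_study <- function(cfg = generator_config(), seed = 1,
                           distortion = 0.15, n_trials = 20,
                           n_group_features = 6, n_test_pooled = 50) {
  sessions <- simulate_study(cfg, seed)
  filtered <- lapply(sessions, bandpass)
  fms <- lapply(filtered, function(s)
    build_feature_matrix(extract_epochs(s, c(0, cfg$epoch_s)), cfg$bands))
  pooled <- feature_matrix(
    do.call(rbind, lapply(fms, function(f) f$values)),
    fms[[1]]$feature_info,
    unlist(lapply(fms, function(f) f$labels)))

  time_domain <- time_domain_baseline(filtered[[1]], epoch_s = cfg$epoch_s,
                                      seed = derive_seed(seed, 101))
  bandwise <- lapply(stats::setNames(nm = cfg$bands$band), function(b)
    bandwise_classification(pooled, b, n_test_per_class = n_test_pooled,
                            seed = derive_seed(seed, 102)))
  selected <- with_seed(derive_seed(seed, 103), {
    left <- which(pooled$labels == "LEFT")
    right <- which(pooled$labels == "RIGHT")
    tr <- sort(c(sample_n(left, round(0.7 * length(left))),
                 sample_n(right, round(0.7 * length(right)))))
    fit <- fit_split(pooled, tr, n_select_channels = 7, n_select_bands = 2)
    test_idx <- c(sample_n(setdiff(left, tr), n_test_pooled),
                  sample_n(setdiff(right, tr), n_test_pooled))
    pred <- classify_split(fit, pooled, test_idx)
    hits <- sum(pred == pooled$labels[test_idx], na.rm = TRUE)
    performance_report(
      accuracy = hits / length(test_idx), n_train = length(tr),
      n_test = length(test_idx), seed = seed,
      significance = binom.test(hits, length(test_idx), 0.5,
                                alternative = "greater")$p.value,
      notes = sprintf("pooled 14-feature classification, %d effective neurons",
                      length(fit$keep)))
  })
  gp <- group_patterns(fms, cfg$group_assignment,
                       n_features = n_group_features)
  gnet <- hopfield(gp, rownames(gp))
  group <- distortion_experiment(gnet, fraction = distortion,
                                 n_trials = n_trials,
                                 seed = derive_seed(seed, 104))
  subjects <- lapply(seq_along(sessions), function(i)
    subject_pipeline(sessions[[i]], epoch_s = cfg$epoch_s, bands = cfg$bands,
                     seed = derive_seed(seed, 200 + i)))
  names(subjects) <- names(sessions)
  list(time_domain = time_domain, bandwise = bandwise, selected = selected,
       group = group, subjects = subjects,
       mean_subject_accuracy = mean(vapply(subjects, `[[`, 1, "accuracy")),
       group_patterns = gp)
}
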