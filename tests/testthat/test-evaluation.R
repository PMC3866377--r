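test_that("Monte-Carlo CV splits 20 epochs into 14 train / 6 test and is seeded", {
  set.seed(51)
  values <- matrix(100 + rnorm(20 * 10), 20, 10)
  labels <- rep(c("LEFT", "RIGHT"), each = 10)
  fm <- toy_feature_matrix(values, labels)
  r <- monte_carlo_cv(fm, n_repeats = 3, n_select_channels = 2,
                      n_select_bands = 2, seed = 9)
  expect_equal(r$n_train, 14)
  expect_equal(r$n_test, 6)
  expect_length(r$per_repeat, 3)
  r2 <- monte_carlo_cv(fm, n_repeats = 3, n_select_channels = 2,
                       n_select_bands = 2, seed = 9)
  expect_identical(r$per_repeat, r2$per_repeat)
  expect_identical(r$extra, r2$extra)

  expect_error(monte_carlo_cv(toy_feature_matrix(values, rep("LEFT", 20))),
               "2 epochs per class")
})

test_that("a noiseless strongly planted class difference classifies perfectly", {
  set.seed(52)
  values <- matrix(100, 20, 10)
  labels <- rep(c("LEFT", "RIGHT"), each = 10)
  values[labels == "RIGHT", c(1, 6)] <- 130      # two clean features
  values <- values + matrix(rnorm(200, sd = 0.01), 20)
  fm <- toy_feature_matrix(values, labels)
  r <- monte_carlo_cv(fm, n_repeats = 5, n_select_channels = 2,
                      n_select_bands = 1, seed = 3)
  expect_equal(r$accuracy, 1)
  expect_lt(r$significance, 0.01)
})

test_that("permuted labels stay inside the binomial 99% band around chance", {
  set.seed(53)
  values <- matrix(100 + rnorm(20 * 95), 20, 95)
  labels <- sample(rep(c("LEFT", "RIGHT"), each = 10))   # labels carry no signal
  fm <- toy_feature_matrix(values, labels)
  r <- monte_carlo_cv(fm, n_repeats = 10, seed = 17)
  n_total <- 10 * r$n_test
  half_width <- stats::qnorm(0.995) * sqrt(0.25 / n_total)
  expect_gte(r$accuracy, 0.5 - half_width - 1e-9)
  expect_lte(r$accuracy, 0.5 + half_width + 1e-9)
})

test_that("feature selection sees only the training split", {
  set.seed(54)
  values <- matrix(100 + rnorm(20 * 10), 20, 10)
  labels <- rep(c("LEFT", "RIGHT"), each = 10)
  fm <- toy_feature_matrix(values, labels)
  r1 <- monte_carlo_cv(fm, n_repeats = 2, n_select_channels = 2,
                       n_select_bands = 2, seed = 21)
  # replace the test epochs of repeat 1 with fresh noise: the selected ids
  # of that repeat must not move
  split <- eegcam:::with_seed(eegcam:::derive_seed(21, 1), {
    left <- which(labels == "LEFT"); right <- which(labels == "RIGHT")
    tr <- c(sample(left, 7), sample(right, 7))
    sort(tr)
  })
  test_rows <- setdiff(1:20, split)
  values2 <- values
  values2[test_rows, ] <- 100 + rnorm(length(test_rows) * 10)
  r2 <- monte_carlo_cv(toy_feature_matrix(values2, labels), n_repeats = 2,
                       n_select_channels = 2, n_select_bands = 2, seed = 21)
  expect_identical(r1$selected_ids[[1]], r2$selected_ids[[1]])
})

test_that("time-domain baseline trains exactly two pruned prototypes", {
  cfg <- small_config()
  s <- bandpass(generate_session(cfg, "S03", seed = 2))
  r <- suppressMessages(time_domain_baseline(s, per_class_duration = 20,
                                             seed = 5))
  expect_equal(r$n_train, 2)
  expect_gte(r$n_test, 10)       # held-out epochs only
  expect_lte(r$n_test, 20)
  expect_lte(r$n_effective, 19)
  r2 <- suppressMessages(time_domain_baseline(s, per_class_duration = 20,
                                              seed = 5))
  expect_identical(r$accuracy, r2$accuracy)
})

test_that("band-wise classification reports the table structure and ranks delta first", {
  cfg <- small_config()
  epochs <- unlist(lapply(c("S01", "S02"), function(id)   # both in G1
    suppressMessages(extract_epochs(bandpass(generate_session(cfg, id, 8)),
                                    c(0, 5)))), recursive = FALSE)
  fm <- build_feature_matrix(epochs)
  rd <- bandwise_classification(fm, "delta", train_frac = 0.5, seed = 4)
  expect_equal(rd$band, "delta")
  expect_lte(rd$n_effective, 19)
  expect_equal(rd$n_test, 20)
  rh <- bandwise_classification(fm, "high_beta", train_frac = 0.5, seed = 4)
  # G1's planted signatures live in delta only
  expect_gte(rd$accuracy, rh$accuracy)
  expect_error(bandwise_classification(fm, "gamma"), "unknown band")
})

test_that("group patterns form six labeled complementary pairs over six features", {
  cfg <- small_config()
  sessions <- simulate_study(cfg, seed = 6)
  fms <- suppressMessages(lapply(sessions, function(s)
    build_feature_matrix(extract_epochs(bandpass(s), c(0, cfg$epoch_s)))))
  # cross-group duplicates can legitimately occur on sparse signatures;
  # the warning is tested separately below
  gp <- suppressWarnings(group_patterns(fms, cfg$group_assignment,
                                        n_features = 6))
  expect_equal(dim(gp), c(6, 6))
  expect_true(all(gp %in% c(-1, 1)))
  expect_setequal(rownames(gp),
                  c("G1.LEFT", "G1.RIGHT", "G2.LEFT", "G2.RIGHT",
                    "G3.LEFT", "G3.RIGHT"))
  for (g in c("G1", "G2", "G3"))
    expect_equal(gp[paste0(g, ".LEFT"), ], -gp[paste0(g, ".RIGHT"), ])

  # duplicated cells raise the degenerate-stable-point warning
  fms_dup <- fms
  const <- fms[[1]]
  const$values[] <- rep(100 + seq_len(ncol(const$values)),
                        each = nrow(const$values))
  # identical feature values in every subject -> ties everywhere -> +1 rows
  fms_dup <- lapply(fms_dup, function(f) const)
  names(fms_dup) <- names(fms)
  expect_warning(group_patterns(fms_dup, cfg$group_assignment, n_features = 6),
                 "duplicate stable points")
})

test_that("the high-SNR recovery study reaches >= 90% per-subject accuracy", {
  cfg <- small_config(n_subjects = 2,
                      group_assignment = c(S01 = "G1", S02 = "G1"),
                      band_signatures = recovery_signatures())
  accs <- vapply(c("S01", "S02"), function(id) {
    s <- generate_session(cfg, id, seed = 12)
    suppressMessages(subject_pipeline(s, seed = 30))$accuracy
  }, 1)
  expect_gte(mean(accs), 0.9)
})

test_that("the benchmark study reproduces the pipeline ordering", {
  res <- suppressMessages(evaluate_study(generator_config(), seed = 42))
  best_band <- max(vapply(res$bandwise, `[[`, 1, "accuracy"))
  # one-sided sampling allowance: one binomial SE at the ~100-probe test
  # sizes of the pooled experiments
  eps <- 0.05
  expect_gte(res$mean_subject_accuracy, res$selected$accuracy - eps)
  expect_gte(res$selected$accuracy, best_band - eps)
  expect_gte(best_band, res$time_domain$accuracy - eps)
  # and the top of the progression strictly beats its bottom
  expect_gt(res$mean_subject_accuracy, res$time_domain$accuracy)
})
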