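test_that("t ranking matches the brute-force Welch formula", {
  set.seed(31)
  values <- matrix(100 + rnorm(20 * 5), 20, 5)
  labels <- rep(c("LEFT", "RIGHT"), each = 10)
  fm <- toy_feature_matrix(values, labels)
  ranked <- rank_features(fm)
  for (j in seq_len(5)) {
    id <- fm$feature_info$id[j]
    t_hand <- abs(welch_t_oracle(values[1:10, j], values[11:20, j]))
    expect_equal(ranked$t_abs[ranked$id == id], t_hand, tolerance = 1e-10)
  }
  expect_equal(ranked$rank, seq_len(5))
  expect_true(all(diff(ranked$t_abs) <= 0))
  expect_true(all(ranked$p_value >= 0 & ranked$p_value <= 1))

  # a feature identical in every epoch ranks last with t = 0
  values[, 3] <- 42
  ranked2 <- rank_features(toy_feature_matrix(values, labels))
  expect_equal(ranked2$t_abs[ranked2$id == fm$feature_info$id[3]], 0)
  expect_equal(ranked2$rank[ranked2$id == fm$feature_info$id[3]], 5)

  expect_error(rank_features(toy_feature_matrix(values, rep("LEFT", 20))),
               "both classes")
})

test_that("ranking is invariant to positive affine rescaling of a feature", {
  set.seed(32)
  values <- matrix(100 + rnorm(16 * 4), 16, 4)
  labels <- rep(c("LEFT", "RIGHT"), 8)
  r1 <- rank_features(toy_feature_matrix(values, labels))
  values2 <- values
  values2[, 2] <- 3.7 * values2[, 2] + 11
  r2 <- rank_features(toy_feature_matrix(values2, labels))
  id <- r1$id[2]
  expect_equal(r1$t_abs[r1$id == id], r2$t_abs[r2$id == id],
               tolerance = 1e-10)
})

test_that("a planted 3-SD shift is recovered at top rank in >= 95/100 runs", {
  hits <- 0
  for (sim in 1:100) {
    set.seed(300 + sim)
    values <- matrix(100 + rnorm(20 * 95), 20, 95)
    labels <- rep(c("LEFT", "RIGHT"), each = 10)
    values[labels == "RIGHT", 40] <- values[labels == "RIGHT", 40] + 3
    fm <- toy_feature_matrix(values, labels)
    ranked <- rank_features(fm)
    if (ranked$id[1] == fm$feature_info$id[40]) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("two-stage selection returns the channel x band cross product", {
  set.seed(33)
  values <- matrix(100 + rnorm(20 * 95), 20, 95)
  labels <- rep(c("LEFT", "RIGHT"), each = 10)
  fm <- toy_feature_matrix(values, labels)
  ranked <- rank_features(fm)

  sel <- two_stage_select(ranked, 7, 2)
  expect_length(sel, 14)
  expect_true(all(sel %in% ranked$id))
  info <- parse_feature_id(sel)
  expect_length(unique(info$channel), 7)
  expect_length(unique(info$band), 2)

  expect_setequal(two_stage_select(ranked, 19, 5), ranked$id)
  expect_error(two_stage_select(ranked, 25, 2), "exceed")

  # planting signal only on T5-delta and T5-alpha makes T5 the top channel
  v2 <- values
  t5d <- which(fm$feature_info$id == feature_id("T5", "delta"))
  t5a <- which(fm$feature_info$id == feature_id("T5", "alpha"))
  v2[labels == "RIGHT", c(t5d, t5a)] <- v2[labels == "RIGHT", c(t5d, t5a)] + 5
  sel2 <- two_stage_select(rank_features(toy_feature_matrix(v2, labels)), 1, 2)
  expect_true(all(parse_feature_id(sel2)$channel == "T5"))
})

test_that("binarization produces bipolar patterns with the sign(0) -> +1 rule", {
  values <- rbind(c(5, 1, 3), c(1, 3, 3), c(3, 2, 3), c(3, 4, 3)) + 100
  labels <- c("LEFT", "LEFT", "RIGHT", "RIGHT")
  fm <- toy_feature_matrix(values, labels)
  bin <- binarize(fm)
  expect_true(all(bin$patterns %in% c(-1, 1)))
  # feature 1: mean 3 -> values 5,1,3,3 give +1,-1,+1,+1 (zero -> +1)
  expect_equal(unname(bin$patterns[, 1]), c(1, -1, 1, 1))
  # feature 3 is constant: centred to 0 everywhere -> +1 by the tie rule
  expect_equal(unname(bin$patterns[, 3]), rep(1, 4))
  # prototypes: class means binarized with the same centring
  expect_equal(unname(bin$prototypes["LEFT", ]), c(1, -1, 1))
  expect_equal(unname(bin$prototypes["RIGHT", ]), c(1, 1, 1))

  expect_error(binarize(fm, character(0)), "empty")
})

test_that("balanced classes give complementary prototypes except at ties", {
  set.seed(34)
  values <- matrix(100 + rnorm(12 * 6), 12, 6)
  labels <- rep(c("LEFT", "RIGHT"), 6)
  bin <- binarize(toy_feature_matrix(values, labels))
  expect_equal(unname(bin$prototypes["LEFT", ]),
               -unname(bin$prototypes["RIGHT", ]))
})

test_that("pruning keeps exactly the discriminative positions", {
  L <- c(1, -1, 1)
  R <- c(1, 1, -1)
  keep <- prune_constant(rbind(L, R))
  expect_equal(unname(keep), c(2, 3))

  expect_equal(unname(prune_constant(rbind(L, -L))), 1:3)
  expect_error(prune_constant(rbind(L, L)), "no discriminative")

  # idempotence: pruning the pruned prototypes keeps everything
  pruned <- rbind(L, R)[, keep, drop = FALSE]
  expect_equal(unname(prune_constant(pruned)), seq_along(keep))
})
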