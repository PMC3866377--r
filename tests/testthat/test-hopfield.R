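test_that("Hebbian training matches the definitional sum and its invariants", {
  p <- c(1, -1, 1, -1)
  net <- hopfield(p)
  expect_equal(unname(coef(net)), hebbian_oracle(matrix(p, 1)))
  off <- coef(net)[upper.tri(coef(net))]
  expect_true(all(off %in% c(-1, 1)))
  expect_true(all(diag(coef(net)) == 0))

  set.seed(41)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    P <- matrix(sample(c(-1, 1), sample(1:4, 1) * n, TRUE), ncol = n)
    net <- hopfield(P)
    W <- coef(net)
    expect_equal(unname(W), hebbian_oracle(P))
    expect_identical(W, t(W))
    expect_true(all(diag(W) == 0))
  }

  expect_error(hopfield(matrix(c(1, 0, -1, 1), 2)), "bipolar")
  expect_error(hopfield(matrix(1, 2, 3), labels = "A"), "one label")
})

test_that("state updates follow the sign-threshold rule", {
  p <- c(1, 1, -1, -1, 1)
  net <- hopfield(p)
  # the stored pattern is a fixed point under both schedules
  expect_equal(update_state(net, p, "sync"), p)
  expect_equal(update_state(net, p, "async", seed = 1), p)

  # local field exactly 0 -> neuron goes to +1
  z <- hopfield(rbind(c(1, 1), c(1, -1)))   # zero weight matrix
  expect_equal(update_state(z, c(-1, -1), "sync"), c(1, 1))

  # synchronous result equals the entrywise matrix-product oracle
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    P <- matrix(sample(c(-1, 1), 2 * n, TRUE), ncol = n)
    th <- rnorm(n)
    net <- hopfield(P, thresholds = th)
    s <- sample(c(-1, 1), n, TRUE)
    expect_equal(update_state(net, s, "sync"),
                 sync_oracle(coef(net), th, s))
  }

  expect_error(update_state(net, c(1, -1)), "length")
})

test_that("energy has the quadratic closed form and its symmetries", {
  p <- rep(1, 6)
  net <- hopfield(p)
  expect_equal(energy(net, p), -15)   # -(n^2 - n)/2 for a self-consistent state

  # flipping any single bit of the stored pattern strictly increases E
  for (i in 1:6) {
    q <- p
    q[i] <- -q[i]
    expect_gt(energy(net, q), energy(net, p))
  }

  # with zero thresholds, E(x) = E(-x) for every state
  set.seed(43)
  net2 <- hopfield(matrix(sample(c(-1, 1), 3 * 7, TRUE), ncol = 7))
  for (rep in 1:10) {
    s <- sample(c(-1, 1), 7, TRUE)
    expect_equal(energy(net2, s), energy(net2, -s))
  }
})

test_that("asynchronous single-neuron updates never increase the energy", {
  set.seed(44)
  for (rep in 1:1000) {
    n <- sample(3:10, 1)
    P <- matrix(sample(c(-1, 1), sample(1:5, 1) * n, TRUE), ncol = n)
    net <- hopfield(P, thresholds = rnorm(n))
    s <- sample(c(-1, 1), n, TRUE)
    e0 <- energy(net, s)
    i <- sample(n, 1)
    s2 <- s
    s2[i] <- if (sum(coef(net)[i, ] * s) - net$thresholds[i] >= 0) 1 else -1
    expect_lte(energy(net, s2), e0 + 1e-12)
  }
})

test_that("recall reaches fixed points; stored pattern and negation are stable", {
  p <- c(1, -1, -1, 1, 1, -1, 1)
  net <- hopfield(p)
  r <- recall(net, p, seed = 2)
  expect_true(r$converged)
  expect_equal(r$n_iterations, 1)
  expect_equal(r$final_state, p)
  expect_true(all(diff(r$energy_trace) <= 1e-12))
  # the negation is stored implicitly
  expect_equal(recall(net, -p, seed = 2)$final_state, -p)
})

test_that("async fixed points equal the exhaustive enumeration", {
  set.seed(45)
  for (n in c(4, 8, 12)) {
    P <- matrix(sample(c(-1, 1), 3 * n, TRUE), ncol = n)
    net <- hopfield(P)
    fp <- fixed_points_oracle(coef(net), net$thresholds, n)
    # every enumerated fixed point is invariant under recall
    for (k in seq_len(nrow(fp))) {
      r <- recall(net, fp[k, ], seed = k)
      expect_equal(r$final_state, fp[k, ])
      expect_equal(r$n_iterations, 1)
    }
    # every recall lands on an enumerated fixed point
    states <- all_states(min(n, 8))
    idx <- if (n > 8) sample(nrow(states), 40) else seq_len(nrow(states))
    for (k in idx) {
      probe <- if (n > 8)
        c(states[k, ], sample(c(-1, 1), n - 8, TRUE)) else states[k, ]
      out <- recall(net, probe, seed = k)$final_state
      expect_true(any(apply(fp, 1, function(f) all(f == out))))
    }
  }
})

test_that("a synchronous two-cycle is reported as non-converged", {
  net <- hopfield(c(1, -1))           # W = [[0,-1],[-1,0]]
  r <- recall(net, c(1, 1), schedule = "sync", max_iter = 40)
  expect_false(r$converged)
  expect_equal(r$n_iterations, 40)
  # the same probe converges under the asynchronous schedule
  expect_true(recall(net, c(1, 1), schedule = "async", seed = 1)$converged)
})

test_that("classification agrees with the enumerated recall + nearest-Hamming oracle", {
  P <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1))   # orthogonal pair
  net <- hopfield(P, labels = c("A", "B"))
  states <- all_states(4)
  for (k in seq_len(nrow(states))) {
    probe <- states[k, ]
    out <- sync_recall_oracle(coef(net), net$thresholds, probe)
    d <- apply(P, 1, hamming, b = out)
    oracle <- if (length(unique(c("A", "B")[d == min(d)])) == 1)
      c("A", "B")[which.min(d)] else NA_character_
    expect_identical(classify(net, probe, schedule = "sync"), oracle)
  }

  # probe equal to a stored fixed point returns its own label
  expect_identical(classify(net, P[1, ], seed = 3), "A")
  # a final state equidistant from both stored patterns is indeterminate
  expect_true(is.na(classify(hopfield(rbind(c(1, 1), c(-1, -1)),
                                      c("A", "B")),
                             c(1, -1), schedule = "sync")))
  expect_error(classify(hopfield(c(1, -1)), c(1, -1)), "no labeled")
})

test_that("distortion flips exactly round(fraction * n) distinct bits", {
  p <- rep(1, 6)
  expect_identical(distort(p, 0, seed = 1), p)
  expect_equal(distort(p, 1, seed = 1), -p)
  expect_equal(hamming(distort(p, 0.15, seed = 1), p), 1)  # round(0.9) = 1
  p20 <- rep(1, 20)
  for (s in 1:10)
    expect_equal(hamming(distort(p20, 0.3, seed = s), p20), 6)
  expect_error(distort(p, 1.5), "fraction")
})

test_that("distortion experiments score perfect recall and degrade with distortion", {
  P <- rbind(c(1, 1, 1, -1, -1, -1), c(1, -1, 1, -1, 1, -1))
  net <- hopfield(P, labels = c("L", "R"))
  r0 <- distortion_experiment(net, fraction = 0, n_trials = 5, seed = 1)
  expect_equal(r0$bit_accuracy, 1)
  expect_equal(r0$mean_error, 0)
  expect_equal(r0$accuracy, 1)

  # monotone on average: heavier distortion never helps (100 seeds)
  mean_perf <- function(f) {
    mean(vapply(1:100, function(s)
      distortion_experiment(net, f, n_trials = 2, seed = s)$bit_accuracy, 1))
  }
  m <- vapply(c(0, 0.15, 0.3, 0.5), mean_perf, 1)
  expect_true(all(diff(m) <= 0.02))   # one-sided sampling allowance
})

test_that("hopfield methods print, summarize, simulate and serialize", {
  P <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  net <- hopfield(P, labels = c("A", "B"))
  expect_output(print(net), "2 stored")
  sm <- summary(net)
  expect_equal(sm$n_patterns, 2)
  expect_true(all(sm$fixed))
  expect_output(print(sm), "fixed points")

  sim <- simulate(net, nsim = 3, seed = 5, fraction = 0.25)
  expect_equal(nrow(sim), 6)
  expect_true(all(sim$bits_flipped == 1))
  expect_identical(simulate(net, nsim = 3, seed = 5, fraction = 0.25), sim)

  pred <- predict(net, P, seed = 1)
  expect_identical(pred, c("A", "B"))
})
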