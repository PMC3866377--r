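# The Hopfield content-addressable memory: Hebbian fitting, sign-threshold
# dynamics, energy, recall, classification and distortion experiments.

#' Fit a Hopfield network by the Hebbian outer-product rule
#'
#' Stores a set of bipolar (+/-1) patterns in a fully connected recurrent
#' network: `w_ij = sum_p x_i^(p) x_j^(p)` for `i != j`, `w_ii = 0`, so the
#' weight matrix is symmetric with zero diagonal.  Neuron thresholds are
#' zero by default.  Weights are kept as integers (sums of +/-1 products).
#'
#' @param patterns Matrix with one +/-1 pattern per row (a single pattern
#'   may be given as a vector).
#' @param labels Optional character labels, one per pattern.
#' @param thresholds Optional numeric threshold vector (default all zero).
#' @return An object of class `hopfield` with components `weights`,
#'   `thresholds`, `patterns`, `labels`, `n`.
#' @export
#' @examples
#' net <- hopfield(rbind(c(1, -1, 1, -1), c(1, 1, -1, -1)), c("A", "B"))
#' net
#' predict(net, c(1, -1, 1, 1), seed = 1)
hopfield <- function(patterns, labels = NULL, thresholds = NULL) {
  if (is.vector(patterns)) patterns <- matrix(patterns, nrow = 1)
  patterns <- as.matrix(patterns)
  if (!nrow(patterns)) stop("need at least one pattern", call. = FALSE)
  if (!all(patterns %in% c(-1, 1)))
    stop("patterns must be bipolar (+1/-1)", call. = FALSE)
  if (!is.null(labels) && length(labels) != nrow(patterns))
    stop("one label per pattern required", call. = FALSE)
  n <- ncol(patterns)
  W <- t(patterns) %*% patterns
  diag(W) <- 0
  storage.mode(W) <- "integer"
  thresholds <- thresholds %||% numeric(n)
  if (length(thresholds) != n)
    stop("thresholds must have length n", call. = FALSE)
  structure(
    list(weights = W, thresholds = thresholds, patterns = patterns,
         labels = labels, n = n),
    class = "hopfield"
  )
}

#' @export
print.hopfield <- function(x, ...) {
  cat(sprintf("Hopfield network: %d neurons, %d stored pattern(s) (load %.2f)\n",
              x$n, nrow(x$patterns), nrow(x$patterns) / x$n))
  if (!is.null(x$labels))
    cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.hopfield <- function(object, ...) {
  p <- nrow(object$patterns)
  fixed <- vapply(seq_len(p), function(i) {
    s <- object$patterns[i, ]
    all(update_state(object, s, schedule = "sync") == s)
  }, logical(1))
  structure(
    list(n = object$n, n_patterns = p, load = p / object$n,
         capacity = 0.138 * object$n, fixed = fixed, labels = object$labels,
         weight_range = range(object$weights)),
    class = "summary.hopfield"
  )
}

#' @export
print.summary.hopfield <- function(x, ...) {
  cat(sprintf("Hopfield network: %d neurons, %d pattern(s), load %.2f (capacity ~%.1f)\n",
              x$n, x$n_patterns, x$load, x$capacity))
  cat(sprintf("  stored patterns that are fixed points: %d/%d\n",
              sum(x$fixed), x$n_patterns))
  cat(sprintf("  weight range: [%d, %d]\n", x$weight_range[1],
              x$weight_range[2]))
  invisible(x)
}

#' @export
coef.hopfield <- function(object, ...) object$weights

check_state <- function(net, state) {
  if (length(state) != net$n)
    stop("state length ", length(state), " != network size ", net$n,
         call. = FALSE)
  if (!all(state %in% c(-1, 1)))
    stop("state must be bipolar (+1/-1)", call. = FALSE)
  as.numeric(state)
}

#' One update of the network state
#'
#' Each updated neuron `i` takes `sign(sum_j w_ij x_j - T_i)` with
#' `sign(0) = +1`.  `"sync"` updates every neuron simultaneously from the
#' current state; `"async"` performs one full sweep in seeded random order,
#' each neuron seeing the freshest state.
#'
#' @param net A [hopfield()] network.
#' @param state +/-1 state vector of length `n`.
#' @param schedule `"async"` (default) or `"sync"`.
#' @param seed Optional seed for the asynchronous update order.
#' @return The updated +/-1 state vector.
#' @export
update_state <- function(net, state, schedule = c("async", "sync"),
                         seed = NULL) {
  schedule <- match.arg(schedule)
  state <- check_state(net, state)
  if (schedule == "sync") {
    sign_bipolar(as.vector(net$weights %*% state) - net$thresholds)
  } else {
    with_seed(seed, {
      for (i in sample.int(net$n)) {
        state[i] <- sign_bipolar(sum(net$weights[i, ] * state) -
                                   net$thresholds[i])
      }
      state
    })
  }
}

#' Energy of a network state
#'
#' `E = -1/2 sum_{i != j} w_ij x_i x_j + sum_i T_i x_i`.  Asynchronous
#' single-neuron updates never increase `E`, which is why recall descends
#' to a stored (or spurious) fixed point.
#'
#' @inheritParams update_state
#' @return Scalar energy.
#' @export
energy <- function(net, state) {
  state <- check_state(net, state)
  -0.5 * sum(state * (net$weights %*% state)) + sum(net$thresholds * state)
}

#' Iterated recall from a probe pattern
#'
#' Runs update sweeps until a full sweep changes no neuron or `max_iter`
#' sweeps have been performed, recording the energy after each sweep.
#'
#' @inheritParams update_state
#' @param probe +/-1 probe vector.
#' @param max_iter Maximum number of full sweeps (default 40).
#' @return An object of class `hopfield_recall`: list with `final_state`,
#'   `converged`, `n_iterations` and `energy_trace`.
#' @export
recall <- function(net, probe, max_iter = 40, schedule = c("async", "sync"),
                   seed = NULL) {
  schedule <- match.arg(schedule)
  state <- check_state(net, probe)
  trace <- energy(net, state)
  converged <- FALSE
  it <- 0L
  with_seed(seed, {
    while (it < max_iter) {
      it <- it + 1L
      new_state <- update_state(net, state, schedule = schedule)
      trace <- c(trace, energy(net, new_state))
      if (all(new_state == state)) { converged <- TRUE; break }
      state <- new_state
    }
  })
  structure(list(final_state = state, converged = converged,
                 n_iterations = it, energy_trace = trace),
            class = "hopfield_recall")
}

#' @export
print.hopfield_recall <- function(x, ...) {
  cat(sprintf("Hopfield recall: %s after %d sweep(s), final energy %.1f\n",
              if (x$converged) "converged" else "not converged",
              x$n_iterations, tail(x$energy_trace, 1)))
  invisible(x)
}

#' Classify a probe by nearest stored pattern
#'
#' Recalls from the probe and returns the label of the stored pattern at
#' minimum Hamming distance from the final state; an exact tie between
#' patterns with different labels is indeterminate (`NA`).
#'
#' @inheritParams recall
#' @return Character label, or `NA_character_` when indeterminate.
#' @export
classify <- function(net, probe, max_iter = 40, schedule = c("async", "sync"),
                     seed = NULL) {
  if (is.null(net$labels)) stop("network has no labeled patterns", call. = FALSE)
  r <- recall(net, probe, max_iter = max_iter, schedule = schedule, seed = seed)
  d <- colSums(t(net$patterns) != r$final_state)
  winners <- unique(net$labels[d == min(d)])
  if (length(winners) == 1L) winners else NA_character_
}

#' @describeIn hopfield `predict` method: classify one probe (vector) or a
#'   matrix of probes (one per row); `type = "state"` returns recalled
#'   states instead of labels.
#' @param object,newdata,... A fitted network, probe pattern(s), and
#'   arguments passed on to [recall()] (`max_iter`, `schedule`, `seed`).
#' @param type `"class"` or `"state"`.
#' @export
predict.hopfield <- function(object, newdata, type = c("class", "state"),
                             ...) {
  type <- match.arg(type)
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (type == "class")
    vapply(seq_len(nrow(newdata)),
           function(i) classify(object, newdata[i, ], ...), "")
  else
    t(vapply(seq_len(nrow(newdata)),
             function(i) recall(object, newdata[i, ], ...)$final_state,
             numeric(object$n)))
}

#' Randomly flip a fixed fraction of a bipolar pattern
#'
#' Flips exactly `round(fraction * n)` distinct positions chosen uniformly
#' (IEEE round-half-to-even, so 15% of 6 bits flips 1 bit).
#'
#' @param pattern +/-1 vector.
#' @param fraction Fraction of bits to flip, in `[0, 1]`.
#' @param seed Optional seed.
#' @return The distorted pattern.
#' @export
distort <- function(pattern, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  n <- length(pattern)
  k <- round(fraction * n)
  if (k == 0) return(pattern)
  with_seed(seed, {
    idx <- sample.int(n, k)
    pattern[idx] <- -pattern[idx]
    pattern
  })
}

#' Distortion-recall experiment
#'
#' Per trial, every stored pattern is distorted by `fraction` random bit
#' flips and recalled (at most `max_iter` sweeps).  Reports both readings
#' of "performance": pattern-level accuracy (probes whose recalled state is
#' uniquely nearest its own source pattern) and bit-level performance (mean
#' fraction of final-state bits matching the source); mean error is one
#' minus bit-level performance.
#'
#' @param net A [hopfield()] network with stored patterns.
#' @param fraction Distortion fraction per probe.
#' @param n_trials Number of trials (default 20).
#' @param max_iter Recall sweep cap (default 40).
#' @param seed Optional seed.
#' @return A [performance_report()] with `accuracy` (pattern-level),
#'   `bit_accuracy`, `mean_error` and per-trial bit accuracies.
#' @export
distortion_experiment <- function(net, fraction = 0.15, n_trials = 20,
                                  max_iter = 40, seed = NULL) {
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  p <- nrow(net$patterns)
  with_seed(seed, {
    per_trial <- numeric(n_trials)
    pattern_hits <- 0L
    bit_hits <- 0
    bits_total <- 0
    for (tr in seq_len(n_trials)) {
      trial_bits <- 0
      for (i in seq_len(p)) {
        src <- net$patterns[i, ]
        probe <- distort(src, fraction)
        out <- recall(net, probe, max_iter = max_iter)$final_state
        match_bits <- sum(out == src)
        trial_bits <- trial_bits + match_bits
        bit_hits <- bit_hits + match_bits
        bits_total <- bits_total + net$n
        d <- colSums(t(net$patterns) != out)
        if (d[i] == min(d) && sum(d == min(d)) == 1L)
          pattern_hits <- pattern_hits + 1L
      }
      per_trial[tr] <- trial_bits / (p * net$n)
    }
    bit_acc <- bit_hits / bits_total
    sig <- binom.test(bit_hits, bits_total, 0.5,
                      alternative = "greater")$p.value
    performance_report(
      accuracy = pattern_hits / (n_trials * p),
      bit_accuracy = bit_acc,
      per_repeat = per_trial,
      n_train = p, n_test = n_trials * p,
      seed = seed, significance = sig,
      notes = sprintf("distortion fraction %.2f (%d bit flip(s) of %d), %d trials",
                      fraction, round(fraction * net$n), net$n, n_trials))
  })
}

#' @describeIn hopfield `simulate` method: `nsim` seeded distortion-recall
#'   trials of every stored pattern; returns a data frame with one row per
#'   (trial, pattern) giving flipped and matching bit counts.
#' @param nsim,seed Number of trials and seed (see [stats::simulate]).
#' @param fraction Distortion fraction (default 0.15).
#' @export
simulate.hopfield <- function(object, nsim = 1, seed = NULL,
                              fraction = 0.15, ...) {
  p <- nrow(object$patterns)
  with_seed(seed, {
    rows <- vector("list", nsim * p)
    k <- 0L
    for (tr in seq_len(nsim)) for (i in seq_len(p)) {
      src <- object$patterns[i, ]
      probe <- distort(src, fraction)
      out <- recall(object, probe)$final_state
      k <- k + 1L
      rows[[k]] <- data.frame(
        trial = tr, pattern = i,
        label = if (is.null(object$labels)) NA_character_ else object$labels[i],
        bits_flipped = sum(probe != src), bits_matching = sum(out == src),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' @describeIn hopfield `plot` method: image of the weight matrix, or the
#'   energy trace of a recall from `probe`.
#' @param x A `hopfield` object.
#' @param which `"weights"` or `"energy"`.
#' @param probe Probe pattern for `which = "energy"`.
#' @export
plot.hopfield <- function(x, which = c("weights", "energy"), probe = NULL,
                          ...) {
  which <- match.arg(which)
  if (which == "weights") {
    image(seq_len(x$n), seq_len(x$n), t(x$weights[x$n:1, , drop = FALSE]),
          xlab = "neuron j", ylab = "neuron i", main = "Hebbian weights",
          axes = FALSE, ...)
    axis(1, at = seq_len(x$n))
    axis(2, at = seq_len(x$n), labels = rev(seq_len(x$n)))
  } else {
    if (is.null(probe)) stop("energy plot needs a probe", call. = FALSE)
    r <- recall(x, probe, ...)
    plot(seq_along(r$energy_trace) - 1, r$energy_trace, type = "b",
         xlab = "sweep", ylab = "energy", main = "Energy descent")
  }
  invisible(x)
}
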