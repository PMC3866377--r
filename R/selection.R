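# Scalar feature ranking, two-stage channel/band selection, bipolar
# binarization and effective-feature pruning.

#' Rank features by absolute two-sample t statistic
#'
#' Computes, per feature, the Welch (unequal-variance) two-sample t
#' statistic between LEFT and RIGHT epochs and ranks features by |t|
#' descending.  p-values are reported descriptively; no multiple-testing
#' correction is applied because the statistic is used for ranking, not
#' testing.  Ties (including all-constant features with t = 0) keep their
#' original column order.
#'
#' @param fm A [feature_matrix()] containing both classes with at least two
#'   epochs each.
#' @return Data frame sorted by `t_abs` descending with columns `id`,
#'   `channel`, `band`, `t_abs`, `p_value`, `rank`.
#' @export
rank_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  left <- fm$labels == "LEFT"
  right <- fm$labels == "RIGHT"
  if (sum(left) < 2 || sum(right) < 2)
    stop("both classes need at least 2 epochs", call. = FALSE)
  k <- ncol(fm$values)
  t_abs <- numeric(k)
  p_value <- numeric(k)
  for (j in seq_len(k)) {
    x <- fm$values[left, j]
    y <- fm$values[right, j]
    if (var(x) == 0 && var(y) == 0) {   # degenerate: no spread at all
      sep <- mean(x) != mean(y)         # constant but perfectly separating
      t_abs[j] <- if (sep) Inf else 0
      p_value[j] <- if (sep) 0 else 1
    } else {
      tt <- t.test(x, y)
      t_abs[j] <- abs(unname(tt$statistic))
      p_value[j] <- tt$p.value
    }
  }
  out <- data.frame(fm$feature_info, t_abs = t_abs, p_value = p_value,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$t_abs), ]       # stable: ties keep column order
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Two-stage channel/band feature selection
#'
#' Channels are ranked by their |t| aggregated over bands, bands by their
#' |t| aggregated over channels; the selection is the cross product of the
#' top `n_channels` channels and top `n_bands` bands (so always exactly
#' `n_channels * n_bands` ids).  Aggregation is the mean of |t| by default;
#' `"max"` is available.
#'
#' @param ranked Output of [rank_features()].
#' @param n_channels,n_bands How many channels and bands to keep.
#' @param aggregate `"mean"` or `"max"`.
#' @return Character vector of selected feature ids, ordered by channel
#'   rank then band rank.
#' @export
two_stage_select <- function(ranked, n_channels = 7, n_bands = 2,
                             aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (!nrow(ranked)) stop("empty ranking", call. = FALSE)
  agg <- switch(aggregate, mean = mean, max = max)
  ch_score <- tapply(ranked$t_abs, ranked$channel, agg)
  bd_score <- tapply(ranked$t_abs, ranked$band, agg)
  if (n_channels > length(ch_score) || n_bands > length(bd_score))
    stop("selection sizes exceed available channels/bands", call. = FALSE)
  # stable order: first appearance in the feature table breaks ties
  ch_names <- unique(ranked$channel[order(ranked$rank)])
  ch_names <- ch_names[order(-ch_score[ch_names])]
  bd_names <- unique(ranked$band[order(ranked$rank)])
  bd_names <- bd_names[order(-bd_score[bd_names])]
  top_ch <- ch_names[seq_len(n_channels)]
  top_bd <- bd_names[seq_len(n_bands)]
  ids <- character(0)
  for (ch in top_ch) for (bd in top_bd) {
    hit <- ranked$id[ranked$channel == ch & ranked$band == bd]
    ids <- c(ids, hit)
  }
  ids
}

#' Bipolar pattern set from selected features
#'
#' Centres each selected feature by its cross-epoch mean and maps positive
#' values to `+1` and negative to `-1` (exact zero maps to `+1`; one global
#' tie rule, shared with the network's sign function).  Class prototypes
#' are the class-mean feature values binarized with the same centring.
#'
#' @param fm A [feature_matrix()].
#' @param selected Character vector of feature ids to use.
#' @param center Optional centring vector (training means) to reuse, e.g.
#'   when binarizing held-out epochs; defaults to the cross-epoch means of
#'   `fm` itself.
#' @return List with `patterns` (epochs x features +/-1 matrix),
#'   `prototypes` (2 x features +/-1 matrix, rows `LEFT`/`RIGHT` when both
#'   classes are present), `center` (the centring vector) and `labels`.
#' @export
binarize <- function(fm, selected = NULL, center = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  selected <- selected %||% fm$feature_info$id
  if (!length(selected)) stop("empty selection", call. = FALSE)
  sub <- subset_features(fm, selected)
  center <- center %||% colMeans(sub$values)
  centred <- sweep(sub$values, 2, center)
  patterns <- sign_bipolar(centred)
  classes <- intersect(c("LEFT", "RIGHT"), unique(sub$labels))
  prototypes <- NULL
  if (length(classes)) {
    prototypes <- t(vapply(classes, function(cls) {
      sign_bipolar(colMeans(sub$values[sub$labels == cls, , drop = FALSE]) -
                     center)
    }, numeric(ncol(sub$values))))
    rownames(prototypes) <- classes
  }
  list(patterns = patterns, prototypes = prototypes, center = center,
       labels = sub$labels, feature_ids = selected)
}

# sign with sign(0) -> +1; the package-wide tie rule.
sign_bipolar <- function(x) {
  s <- ifelse(x >= 0, 1, -1)
  if (is.matrix(x)) dimnames(s) <- dimnames(x)
  s
}

#' Prune features constant across class prototypes
#'
#' Keeps only the "effective" positions where the two class prototypes
#' disagree; positions with the same value in both states carry no
#' discriminative information for a two-state network.
#'
#' @param prototypes A 2 x features matrix of +/-1 prototypes.
#' @return Integer vector of retained positions (named with feature ids
#'   when the matrix has column names).  Errors when the prototypes are
#'   identical everywhere.
#' @export
prune_constant <- function(prototypes) {
  stopifnot(is.matrix(prototypes), nrow(prototypes) == 2)
  keep <- which(prototypes[1, ] != prototypes[2, ])
  if (!length(keep))
    stop("no discriminative features: class prototypes are identical",
         call. = FALSE)
  keep
}
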