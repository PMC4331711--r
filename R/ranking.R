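entropy_counts <- function(n) {
  n <- n[n > 0]
  if (length(n) <= 1L) return(0)
  p <- n / sum(n)
  -sum(p * log2(p))
}

#' Gain ratio of the best binary split of a continuous feature
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted values. For each threshold the information gain is
#' `H(class) - w_L H(class | left) - w_R H(class | right)` and the split
#' information is the entropy of the two branch sizes; the gain ratio is
#' their quotient. All entropies are in bits (any fixed base gives the
#' same ranking). Ties between thresholds are broken toward the smallest
#' threshold. A constant feature scores 0 with its single value returned
#' as the threshold.
#'
#' @param values numeric vector (one feature across samples).
#' @param labels two-class factor aligned with `values` (see
#'   [label_vector()]).
#' @return list with `gain_ratio` and `best_threshold`.
#' @examples
#' gain_ratio(c(1, 2, 9, 10), factor(c("n", "n", "p", "p")))
#' @export
gain_ratio <- function(values, labels) {
  if (length(values) != length(labels))
    stop("values and labels differ in length")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("gain ratio needs two classes present")
  if (nlevels(labels) > 2L) stop("gain ratio is defined here for two classes")
  o <- order(values)
  v <- values[o]
  y <- labels[o] == levels(labels)[1]
  n <- length(v)
  cut_after <- which(v[-n] != v[-1])          # split between i and i+1
  if (length(cut_after) == 0L)
    return(list(gain_ratio = 0, best_threshold = v[1]))
  H <- entropy_counts(tabulate(labels, 2L))
  c1 <- cumsum(y)                              # class-1 count left of cut
  nl <- cut_after
  nr <- n - nl
  l1 <- c1[cut_after]
  l2 <- nl - l1
  r1 <- sum(y) - l1
  r2 <- nr - r1
  h2 <- function(a, b) {                       # vectorized 2-class entropy
    tot <- a + b
    pa <- ifelse(a > 0, a / tot, 1)
    pb <- ifelse(b > 0, b / tot, 1)
    -(ifelse(a > 0, a / tot * log2(pa), 0) +
        ifelse(b > 0, b / tot * log2(pb), 0))
  }
  ig <- H - (nl / n) * h2(l1, l2) - (nr / n) * h2(r1, r2)
  si <- h2(nl, nr)
  gr <- ifelse(si > 0, ig / si, 0)
  best <- which.max(gr)                        # first max = smallest threshold
  thr <- (v[cut_after[best]] + v[cut_after[best] + 1L]) / 2
  list(gain_ratio = max(0, gr[best]), best_threshold = thr)
}

#' Two-sided two-sample t-test p-value
#'
#' Classical pooled-variance Student's t-test by default; set
#' `welch = TRUE` for the unequal-variance form. Degenerate inputs with
#' zero pooled variance return p = 1 when the group means are equal and
#' p = 0 otherwise.
#'
#' @inheritParams gain_ratio
#' @param welch use the Welch approximation instead of pooled variance.
#' @return two-sided p-value.
#' @export
t_test_p <- function(values, labels, welch = FALSE) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("t-test needs exactly two classes")
  g1 <- values[labels == levels(labels)[1]]
  g2 <- values[labels == levels(labels)[2]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each class needs at least two samples")
  if (stats::var(g1) == 0 && stats::var(g2) == 0)
    return(if (mean(g1) == mean(g2)) 1 else 0)
  stats::t.test(g1, g2, var.equal = !welch)$p.value
}

#' Rank features by gain ratio
#'
#' Scores every feature with [gain_ratio()] and [t_test_p()], keeps the
#' features whose gain ratio strictly exceeds `gr_cutoff`, sorts them by
#' gain ratio descending (ties broken by feature id, lexicographically)
#' and assigns ranks 1..n.
#'
#' @param mat an [expression_matrix()].
#' @param labels a [label_vector()] covering `mat`'s samples.
#' @param gr_cutoff retain features with gain ratio > this value
#'   (default 0.5).
#' @param welch passed to [t_test_p()].
#' @return data.frame with columns `feature_id`, `rank`, `gain_ratio`,
#'   `best_threshold`, `p_value`.
#' @export
rank_features <- function(mat, labels, gr_cutoff = 0.5, welch = FALSE) {
  labels <- align_labels(mat, labels)
  scores <- lapply(rownames(mat), function(f) {
    g <- gain_ratio(mat[f, ], labels)
    data.frame(feature_id = f, gain_ratio = g$gain_ratio,
               best_threshold = g$best_threshold,
               p_value = t_test_p(mat[f, ], labels, welch = welch))
  })
  df <- do.call(rbind, scores)
  df <- df[df$gain_ratio > gr_cutoff, , drop = FALSE]
  df <- df[order(-df$gain_ratio, df$feature_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("feature_id", "rank", "gain_ratio", "best_threshold", "p_value")]
}
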