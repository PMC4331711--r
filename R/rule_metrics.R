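#' Max-Min inter-class distance of a rule
#'
#' Samples are projected onto the rule's feature subspace (raw
#' expression values) and the minimum Euclidean distance over all
#' cross-class sample pairs is returned. Larger values mean a wider
#' separation between the two classes and hence a more reliable rule.
#'
#' @param rule a [new_rule()].
#' @param mat an [expression_matrix()] containing the rule's features.
#' @param labels a [label_vector()] covering `mat`'s samples.
#' @return non-negative real.
#' @examples
#' m <- expression_matrix(matrix(c(0, 0, 3, 4), 2, 2),
#'                        c("f1", "f2"), c("s1", "s2"))
#' y <- label_vector(c("s1", "s2", "s3", "s4"), c("p", "n", "p", "n"))
#' r <- new_rule(data.frame(feature = c("f1", "f2"), low = 0, high = 1),
#'               "p", 1, 0, 1)
#' # maxmin_distance(r, m, y[1:2]) would need >=2 samples per class
#' @export
maxmin_distance <- function(rule, mat, labels) {
  labels <- align_labels(mat, labels)
  f <- rule$conditions$feature
  X <- t(mat[f, , drop = FALSE])
  a <- X[labels == levels(labels)[1], , drop = FALSE]
  b <- X[labels == levels(labels)[2], , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both classes must be non-empty")
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Stratified k-fold cross-validated AUC of a rule
#'
#' Samples are split into `folds` stratified folds (per-class shuffling
#' driven by `seed`). For each fold a depth-<=2 gain-ratio tree is
#' trained on the rule's features using the remaining samples; held-out
#' samples are scored by the probability of the rule's target class in
#' the leaf they fall into, and the fold's ROC AUC is computed. Folds
#' whose held-out part contains a single class have no defined AUC and
#' are excluded with a warning; if no fold is usable the function falls
#' back to the AUC pooled over all held-out predictions.
#'
#' @inheritParams maxmin_distance
#' @param folds number of folds (default 10).
#' @param seed integer driving the fold assignment.
#' @param max_depth tree depth limit (default 2).
#' @return mean AUC over usable folds.
#' @export
cv_auc <- function(rule, mat, labels, folds = 10L, seed = 1L, max_depth = 2L) {
  labels <- align_labels(mat, labels)
  f <- rule$conditions$feature
  sub <- mat[f, , drop = FALSE]
  n <- ncol(sub)
  if (folds < 2L) stop("folds must be >= 2")
  fold_id <- integer(n)
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      fold_id[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(folds), length(idx))
    }
  })
  pos <- rule$target_class
  neg <- setdiff(levels(labels), pos)
  aucs <- numeric(0)
  pooled_scores <- numeric(0)
  pooled_labels <- character(0)
  skipped <- 0L
  for (k in seq_len(folds)) {
    test <- which(fold_id == k)
    train <- which(fold_id != k)
    if (length(test) == 0L) next
    tree <- build_tree(
      expression_matrix(sub[, train, drop = FALSE]),
      labels[train], max_depth = max_depth)
    scores <- vapply(test, function(i)
      tree_predict_prob(tree, stats::setNames(sub[, i], rownames(sub)), pos), 0)
    pooled_scores <- c(pooled_scores, scores)
    pooled_labels <- c(pooled_labels, as.character(labels[test]))
    if (length(unique(labels[test])) < 2L) {
      skipped <- skipped + 1L
      next
    }
    aucs <- c(aucs, roc_auc(labels[test] == pos, scores))
  }
  if (skipped > 0L)
    warning(skipped, " fold(s) had a single class held out; excluded from the mean AUC")
  if (length(aucs) == 0L) {
    warning("no fold had both classes held out; returning pooled AUC")
    return(roc_auc(pooled_labels == pos, pooled_scores))
  }
  mean(aucs)
}

# AUC via pROC; is_pos logical, scores = P(positive)
roc_auc <- function(is_pos, scores) {
  r <- pROC::roc(response = factor(is_pos, levels = c(FALSE, TRUE)),
                 predictor = scores, levels = c("FALSE", "TRUE"),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Pearson correlation with degenerate-input guarding
#'
#' Plain sample Pearson correlation; inputs must be equal-length numeric
#' vectors of length >= 3. A constant vector has no defined correlation
#' and yields `NA` with a warning (never silently 0).
#'
#' @param x,y numeric vectors.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

# run code with a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
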