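#' In-memory containers for the rule-mining pipeline
#'
#' `expression_matrix()` wraps a numeric features x samples matrix,
#' `label_vector()` a two-class sample annotation, `target_map()` a
#' miRNA -> target-gene lookup, and `seq_record()` a single UTR/CDS
#' sequence. Every downstream function consumes these validated types
#' only, so malformed input is rejected at construction time rather
#' than deep inside the pipeline.
#'
#' @param values numeric matrix, rows = features, cols = samples.
#' @param feature_ids,sample_ids character vectors of unique ids; taken
#'   from `dimnames(values)` when omitted.
#' @return `expression_matrix()` returns a numeric matrix of class
#'   `"ExpressionMatrix"` with feature ids as rownames and sample ids as
#'   colnames.
#' @examples
#' m <- expression_matrix(matrix(1:4, 2, 2), c("m1", "m2"), c("s1", "s2"))
#' y <- label_vector(c("s1", "s2", "s3", "s4"), c("a", "a", "b", "b"))
#' @export
expression_matrix <- function(values, feature_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("expression matrix needs feature and sample ids")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(feature_ids) || ncol(values) != length(sample_ids))
    stop("dimensions do not match id lengths")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite (no NA/NaN/Inf)")
  dimnames(values) <- list(feature_ids, sample_ids)
  class(values) <- c("ExpressionMatrix", class(values))
  values
}

#' @rdname expression_matrix
#' @param labels character/factor of per-sample class labels; exactly two
#'   distinct classes, each with at least two samples. Class order is
#'   first-seen order.
#' @return `label_vector()` returns a named factor (names = sample ids,
#'   two levels in first-seen order).
#' @export
label_vector <- function(sample_ids, labels) {
  sample_ids <- as.character(sample_ids)
  labels <- as.character(labels)
  if (length(sample_ids) != length(labels))
    stop("sample_ids and labels differ in length")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in labels")
  classes <- unique(labels)
  if (length(classes) != 2)
    stop("need exactly two distinct classes, got ", length(classes), ": ",
         paste(classes, collapse = ", "))
  if (any(table(labels) < 2))
    stop("each class needs at least two samples")
  y <- factor(labels, levels = classes)
  names(y) <- sample_ids
  y
}

#' @rdname expression_matrix
#' @param mapping named list, miRNA id -> character vector of target gene
#'   ids. Duplicated targets are collapsed to a set; empty sets rejected.
#' @export
target_map <- function(mapping) {
  if (!is.list(mapping) || is.null(names(mapping)) || any(names(mapping) == ""))
    stop("target map must be a named list of character vectors")
  mapping <- lapply(mapping, function(g) unique(as.character(g)))
  if (any(lengths(mapping) == 0L)) stop("target sets must be non-empty")
  class(mapping) <- "TargetMap"
  mapping
}

#' @rdname expression_matrix
#' @param id sequence identifier.
#' @param region one of `"5UTR"`, `"3UTR"`, `"CDS"`.
#' @param sequence RNA string over A/C/G/U; DNA `T` is normalized to `U`.
#' @export
seq_record <- function(id, sequence, region = "3UTR") {
  region <- match.arg(region, c("5UTR", "3UTR", "CDS"))
  sequence <- chartr("acgut", "ACGUT", as.character(sequence))
  sequence <- chartr("T", "U", sequence)
  if (nchar(sequence) < 1L) stop("empty sequence for ", id)
  if (grepl("[^ACGU]", sequence))
    stop("sequence ", id, " contains non-RNA characters")
  structure(list(id = as.character(id), region = region, sequence = sequence),
            class = "SeqRecord")
}

#' Construct an interval rule
#'
#' A rule is a conjunction of closed interval conditions
#' `low_i <= x_i <= high_i` over distinct features, predicting one class.
#' A 100%-frequency rule covers every sample of its target class and no
#' sample of the other class.
#'
#' @param conditions data.frame with columns `feature`, `low`, `high`.
#' @param target_class class name the rule predicts.
#' @param n_covered_target,n_covered_other training samples of the target
#'   / other class inside the region.
#' @param class_size total number of target-class training samples
#'   (frequency denominator).
#' @param round mining round the rule came from (greedy miner), or `NA`.
#' @return object of class `"Rule"`.
#' @export
new_rule <- function(conditions, target_class, n_covered_target,
                     n_covered_other, class_size, round = NA_integer_) {
  conditions <- as.data.frame(conditions)[, c("feature", "low", "high")]
  conditions$feature <- as.character(conditions$feature)
  if (anyDuplicated(conditions$feature))
    stop("rule conditions must use distinct features")
  if (any(conditions$low > conditions$high))
    stop("interval with low > high")
  structure(list(
    conditions = conditions,
    target_class = as.character(target_class),
    frequency = n_covered_target / class_size,
    n_covered_target = as.integer(n_covered_target),
    n_covered_other = as.integer(n_covered_other),
    class_size = as.integer(class_size),
    round = as.integer(round)
  ), class = "Rule")
}

#' @export
print.Rule <- function(x, ...) {
  conds <- sprintf("%.4g <= %s <= %.4g",
                   x$conditions$low, x$conditions$feature, x$conditions$high)
  cat(paste(conds, collapse = "  AND  "), "\n  -> ", x$target_class,
      sprintf(" (frequency %.3f, other-class covered %d)\n",
              x$frequency, x$n_covered_other), sep = "")
  invisible(x)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples\n", nrow(x), ncol(x)))
  y <- x
  class(y) <- "matrix"
  print(utils::head(y[, seq_len(min(6L, ncol(y))), drop = FALSE]), ...)
  invisible(x)
}

#' Does a rule cover a sample?
#'
#' @param rule a [new_rule()] object.
#' @param sample named numeric vector holding at least the rule's features.
#' @return logical: `TRUE` iff every condition holds, with inclusive bounds.
#' @examples
#' r <- new_rule(data.frame(feature = "m1", low = 8.94, high = 43.53),
#'               "pos", 24, 0, 24)
#' rule_covers(r, c(m1 = 8.94))  # boundary is inside
#' @export
rule_covers <- function(rule, sample) {
  f <- rule$conditions$feature
  if (!all(f %in% names(sample)))
    stop("sample is missing features: ",
         paste(setdiff(f, names(sample)), collapse = ", "))
  x <- as.numeric(sample[f])
  all(rule$conditions$low <= x & x <= rule$conditions$high)
}

# samples (columns of mat) covered by rule; returns logical vector
covered_samples <- function(rule, mat) {
  f <- rule$conditions$feature
  if (!all(f %in% rownames(mat)))
    stop("matrix is missing rule features: ",
         paste(setdiff(f, rownames(mat)), collapse = ", "))
  sub <- mat[f, , drop = FALSE]
  ok <- rep(TRUE, ncol(mat))
  for (i in seq_along(f))
    ok <- ok & rule$conditions$low[i] <= sub[i, ] & sub[i, ] <= rule$conditions$high[i]
  unname(ok)
}

#' Verify the 100%-frequency property of a rule on labelled data
#'
#' @inheritParams rule_covers
#' @param mat an [expression_matrix()].
#' @param labels a [label_vector()] aligned with `mat`'s samples.
#' @return logical: covers every target-class sample and no other-class one.
#' @export
is_full_frequency <- function(rule, mat, labels) {
  cov <- covered_samples(rule, mat)
  tgt <- labels[colnames(mat)] == rule$target_class
  all(cov[tgt]) && !any(cov[!tgt])
}

align_labels <- function(mat, labels) {
  if (!all(colnames(mat) %in% names(labels)))
    stop("samples without labels: ",
         paste(setdiff(colnames(mat), names(labels)), collapse = ", "))
  labels[colnames(mat)]
}
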