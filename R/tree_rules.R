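#' Build a gain-ratio decision tree
#'
#' Recursive binary splitting in the C4.5 style: at each node the
#' feature/threshold pair with the highest gain ratio (computed on the
#' node's samples) is chosen, with the left branch holding samples with
#' value <= threshold. Growth stops when a node is class-pure, no split
#' has positive information gain, or `max_depth` is reached. No pruning
#' and no missing-value handling (inputs are validated upstream).
#'
#' @param mat an [expression_matrix()] (features x samples).
#' @param labels a [label_vector()] covering `mat`'s samples.
#' @param max_depth maximum number of tests on any root-to-leaf path
#'   (default 2, matching the 2-feature rule focus).
#' @return object of class `"DecisionTree"`: nested list of
#'   `node(feature, threshold, left, right)` and
#'   `leaf(counts, class)` elements, plus `root_feature`.
#' @export
build_tree <- function(mat, labels, max_depth = 2L) {
  labels <- align_labels(mat, labels)
  lev <- levels(labels)
  feats <- sort(rownames(mat))

  make_leaf <- function(idx) {
    counts <- table(factor(labels[idx], levels = lev))
    list(type = "leaf", counts = as.integer(counts),
         classes = lev, class = lev[which.max(counts)])
  }
  grow <- function(idx, depth) {
    counts <- table(factor(labels[idx], levels = lev))
    if (min(counts) == 0L || depth >= max_depth) return(make_leaf(idx))
    best <- NULL
    for (f in feats) {                       # sorted: lexicographic tie-break
      g <- gain_ratio(mat[f, idx], labels[idx])
      if (g$gain_ratio > 1e-12 &&
          (is.null(best) || g$gain_ratio > best$gain_ratio + 1e-12))
        best <- list(feature = f, threshold = g$best_threshold,
                     gain_ratio = g$gain_ratio)
    }
    if (is.null(best)) return(make_leaf(idx))
    left <- idx[mat[best$feature, idx] <= best$threshold]
    right <- setdiff(idx, left)
    if (length(left) == 0L || length(right) == 0L) return(make_leaf(idx))
    list(type = "node", feature = best$feature, threshold = best$threshold,
         left = grow(left, depth + 1L), right = grow(right, depth + 1L))
  }
  root <- if (nlevels(droplevels(labels)) < 2L)
    make_leaf(seq_along(labels)) else grow(seq_along(labels), 0L)
  structure(list(root = root,
                 root_feature = if (root$type == "node") root$feature else NA_character_,
                 classes = lev),
            class = "DecisionTree")
}

tree_predict_prob <- function(tree, sample, target_class) {
  node <- tree$root
  while (node$type == "node")
    node <- if (sample[node$feature] <= node$threshold) node$left else node$right
  k <- match(target_class, node$classes)
  n <- sum(node$counts)
  if (n == 0L) 0.5 else node$counts[k] / n
}

tree_features <- function(node) {
  if (node$type == "leaf") return(character())
  unique(c(node$feature, tree_features(node$left), tree_features(node$right)))
}

#' Build a committee of decision trees by iterative root removal
#'
#' The first tree is grown on the full matrix; each subsequent tree is
#' grown after removing the previous tree's root feature, until fewer
#' than two features remain or a tree fails to split.
#'
#' @inheritParams build_tree
#' @return list of `"DecisionTree"` objects; each carries the feature
#'   set it was trained on as attribute `"features"`.
#' @export
committee <- function(mat, labels, max_depth = 2L) {
  trees <- list()
  remaining <- mat
  while (nrow(remaining) >= 2L) {
    tr <- build_tree(remaining, labels, max_depth = max_depth)
    attr(tr, "features") <- rownames(remaining)
    if (is.na(tr$root_feature)) break
    trees[[length(trees) + 1L]] <- tr
    remaining <- remaining[setdiff(rownames(remaining), tr$root_feature), ,
                           drop = FALSE]
  }
  trees
}

# all root-to-leaf paths; each a list of (feature, threshold, side)
tree_paths <- function(node, prefix = list()) {
  if (node$type == "leaf") return(list(list(tests = prefix, leaf = node)))
  c(tree_paths(node$left,
               c(prefix, list(list(feature = node$feature,
                                   threshold = node$threshold, side = "le")))),
    tree_paths(node$right,
               c(prefix, list(list(feature = node$feature,
                                   threshold = node$threshold, side = "gt")))))
}

# class whose samples are ALL inside region and other class absent, or NA
pure_class_in_region <- function(inside, labels) {
  for (cl in levels(labels)) {
    tgt <- labels == cl
    if (all(inside[tgt]) && !any(inside[!tgt])) return(cl)
  }
  NA_character_
}

box_rule_for_class <- function(feats, cl, mat, labels) {
  tgt <- labels == cl
  sub <- mat[feats, , drop = FALSE]
  conds <- data.frame(feature = feats,
                      low = apply(sub[, tgt, drop = FALSE], 1, min),
                      high = apply(sub[, tgt, drop = FALSE], 1, max))
  r <- new_rule(conds, cl, sum(tgt), 0L, sum(tgt))
  cov <- covered_samples(r, mat)
  r$n_covered_other <- as.integer(sum(cov[!tgt]))
  r
}

#' Extract 2-feature 100%-frequency interval rules from a tree committee
#'
#' Every root-to-leaf path whose axis-aligned region contains all
#' samples of one class and none of the other yields a candidate rule.
#' Interval bounds are then tightened to the observed minimum/maximum of
#' the target class on each path feature, producing closed two-sided
#' intervals (the printed form of such rules reports data extremes, not
#' tree thresholds). Paths testing two distinct features map directly to
#' 2-feature rules; a path whose single feature already separates the
#' classes is completed to the 2-feature form by pairing it with the
#' highest-gain-ratio other feature available to that tree (tightening
#' keeps the region pure, so the completed rule is still 100%-frequency).
#' Rules are mined for both classes; duplicates (same feature set and
#' class) are collapsed.
#'
#' @param trees committee from [committee()].
#' @param mat the matrix the committee was built on.
#' @param labels a [label_vector()].
#' @return list of verified [new_rule()] objects (possibly empty).
#' @export
extract_rules <- function(trees, mat, labels) {
  labels <- align_labels(mat, labels)
  rules <- list()
  seen <- character()
  add_rule <- function(r) {
    key <- paste(c(sort(r$conditions$feature), r$target_class), collapse = "|")
    if (key %in% seen) return(invisible())
    if (!is_full_frequency(r, mat, labels))  # cannot happen; guards regressions
      stop("internal error: extracted rule fails the 100%-frequency check")
    seen <<- c(seen, key)
    rules[[length(rules) + 1L]] <<- r
  }
  for (tr in trees) {
    tr_feats <- attr(tr, "features")
    for (p in tree_paths(tr$root)) {
      if (length(p$tests) == 0L) next
      feats <- unique(vapply(p$tests, `[[`, "", "feature"))
      if (length(feats) > 2L) next
      inside <- rep(TRUE, ncol(mat))
      for (tst in p$tests) {
        v <- mat[tst$feature, ]
        inside <- inside & if (tst$side == "le") v <= tst$threshold else v > tst$threshold
      }
      cl <- pure_class_in_region(inside, labels)
      if (is.na(cl)) next
      if (length(feats) == 1L) {
        others <- setdiff(tr_feats, feats)
        if (length(others) == 0L) next
        gr <- vapply(sort(others), function(f)
          gain_ratio(mat[f, ], labels)$gain_ratio, 0)
        feats <- c(feats, names(gr)[which.max(gr)])
      }
      add_rule(box_rule_for_class(feats, cl, mat, labels))
    }
  }
  rules
}
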