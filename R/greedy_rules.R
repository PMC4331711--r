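#' Expression range of a class over the active samples
#'
#' The closed interval `[min, max]` of one feature over the class-`cl`
#' samples among `active`.
#'
#' @param values numeric vector (one feature across samples).
#' @param labels two-class factor aligned with `values`.
#' @param cl class name.
#' @param active logical vector of currently active samples.
#' @return list with `low` and `high`.
#' @export
class_range <- function(values, labels, cl, active = rep(TRUE, length(values))) {
  sel <- active & labels == cl
  if (!any(sel)) stop("no active samples of class ", cl)
  list(low = min(values[sel]), high = max(values[sel]))
}

#' Compactness of an interval
#'
#' `p = N_c / N`, where `N` counts the active samples whose value lies
#' inside the closed interval and `N_c` those of class `cl`.
#'
#' @inheritParams class_range
#' @param bounds list with `low`, `high` (e.g. from [class_range()]).
#' @return compactness in (0, 1].
#' @export
compactness <- function(values, labels, cl, bounds,
                        active = rep(TRUE, length(values))) {
  inside <- active & bounds$low <= values & values <= bounds$high
  if (!any(inside)) stop("no active samples inside the interval")
  sum(inside & labels == cl) / sum(inside)
}

#' Greedy compactness search for one 100%-frequency rule
#'
#' Starting from all samples active, each iteration computes for every
#' unused feature the class-`cl` expression range over the active
#' samples and its compactness, accepts the highest-compactness interval
#' (ties broken by feature id), and restricts the active samples to that
#' interval. The loop ends when p reaches 1 (a rule is returned) or when
#' no candidate strictly increases p (no rule for this class). Because
#' every accepted interval spans the full class-`cl` range, all class
#' samples survive every restriction, so any returned rule covers the
#' whole class: its frequency is 1 and it covers zero other-class
#' samples.
#'
#' @param mat an [expression_matrix()].
#' @param labels a [label_vector()] covering `mat`'s samples.
#' @param cl target class name.
#' @param exclude feature ids not to be considered (used by the
#'   multi-round driver).
#' @return a [new_rule()] or `NULL`.
#' @export
mine_one_rule <- function(mat, labels, cl, exclude = character()) {
  labels <- align_labels(mat, labels)
  if (!cl %in% levels(labels)) stop("unknown class: ", cl)
  feats <- sort(setdiff(rownames(mat), exclude))
  if (length(feats) == 0L) return(NULL)
  active <- rep(TRUE, ncol(mat))
  tgt <- labels == cl
  p_cur <- sum(tgt) / length(tgt)
  accepted <- list()
  repeat {
    best <- NULL
    for (f in feats) {
      b <- class_range(mat[f, ], labels, cl, active)
      p <- compactness(mat[f, ], labels, cl, b, active)
      if (is.null(best) || p > best$p + 1e-12)
        best <- list(feature = f, low = b$low, high = b$high, p = p)
    }
    if (is.null(best) || best$p <= p_cur + 1e-12) return(NULL)
    accepted[[length(accepted) + 1L]] <-
      data.frame(feature = best$feature, low = best$low, high = best$high)
    active <- active & best$low <= mat[best$feature, ] &
      mat[best$feature, ] <= best$high
    p_cur <- best$p
    feats <- setdiff(feats, best$feature)
    if (p_cur >= 1) {
      conds <- do.call(rbind, accepted)
      return(new_rule(conds, cl, sum(tgt), 0L, sum(tgt)))
    }
    if (length(feats) == 0L) return(NULL)
  }
}

#' Multi-round mining of 100%-frequency rules for every class
#'
#' In each round one rule is sought per class with [mine_one_rule()];
#' features used by any previously accepted rule are excluded from later
#' rounds. Mining stops after the first round in which no class yields a
#' rule. Rules are tagged with their round number.
#'
#' @inheritParams mine_one_rule
#' @return named list (one element per class) of lists of rules.
#' @export
mine_all_rules <- function(mat, labels) {
  labels <- align_labels(mat, labels)
  classes <- levels(labels)
  out <- stats::setNames(vector("list", length(classes)), classes)
  used <- character()
  round <- 0L
  repeat {
    round <- round + 1L
    found_any <- FALSE
    new_used <- character()
    for (cl in classes) {
      r <- mine_one_rule(mat, labels, cl, exclude = used)
      if (!is.null(r)) {
        r$round <- round
        out[[cl]] <- c(out[[cl]], list(r))
        new_used <- c(new_used, r$conditions$feature)
        found_any <- TRUE
      }
    }
    used <- union(used, new_used)
    if (!found_any || length(setdiff(rownames(mat), used)) == 0L) break
  }
  out
}
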