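# Independent oracles used across test files. These re-derive expected
# results by direct enumeration, never by calling the code paths they check.

# entropy in bits from class counts
oracle_entropy <- function(n) {
  n <- n[n > 0]
  if (length(n) <= 1) return(0)
  p <- n / sum(n)
  -sum(p * log2(p))
}

# brute-force best gain ratio over all midpoint thresholds
oracle_gain_ratio <- function(values, labels) {
  labels <- as.character(labels)
  uv <- sort(unique(values))
  if (length(uv) < 2) return(list(gain_ratio = 0, best_threshold = uv[1]))
  thr <- (head(uv, -1) + tail(uv, -1)) / 2
  H <- oracle_entropy(table(labels))
  n <- length(values)
  best <- -Inf; best_thr <- NA
  for (t in thr) {
    l <- labels[values <= t]; r <- labels[values > t]
    ig <- H - length(l) / n * oracle_entropy(table(l)) -
      length(r) / n * oracle_entropy(table(r))
    si <- oracle_entropy(c(length(l), length(r)))
    gr <- ig / si
    if (gr > best + 1e-12) { best <- gr; best_thr <- t }
  }
  list(gain_ratio = max(0, best), best_threshold = best_thr)
}

# is the class-extreme box over `feats` pure for class cl?
oracle_box_is_pure <- function(mat, labels, feats, cl) {
  tgt <- labels == cl
  sub <- mat[feats, , drop = FALSE]
  lo <- apply(sub[, tgt, drop = FALSE], 1, min)
  hi <- apply(sub[, tgt, drop = FALSE], 1, max)
  inside <- rep(TRUE, ncol(mat))
  for (i in seq_along(feats))
    inside <- inside & lo[i] <= sub[i, ] & sub[i, ] <= hi[i]
  !any(inside & !tgt)
}

# all pure class-extreme boxes over 1 or 2 features, per class
oracle_pure_boxes <- function(mat, labels, max_k = 2) {
  feats <- rownames(mat)
  out <- list()
  for (cl in levels(labels)) {
    keys <- character()
    for (f in feats)
      if (oracle_box_is_pure(mat, labels, f, cl)) keys <- c(keys, f)
    if (max_k >= 2 && length(feats) >= 2) {
      cmb <- combn(feats, 2)
      for (j in seq_len(ncol(cmb)))
        if (oracle_box_is_pure(mat, labels, cmb[, j], cl))
          keys <- c(keys, paste(sort(cmb[, j]), collapse = "|"))
    }
    out[[cl]] <- keys
  }
  out
}

# random two-class matrix; optionally with a planted separating pair
# (each planted feature only partially separates on its own)
random_case <- function(seed, planted = FALSE) {
  set.seed(seed)
  n_f <- sample(4:12, 1)
  n_pos <- sample(5:20, 1)
  n_neg <- sample(5:20, 1)
  n <- n_pos + n_neg
  labels <- label_vector(sprintf("s%02d", 1:n),
                         rep(c("pos", "neg"), c(n_pos, n_neg)))
  m <- matrix(rnorm(n_f * n), n_f, n,
              dimnames = list(sprintf("f%02d", 1:n_f), names(labels)))
  if (planted) {
    # joint separation: pos class lives in a tight box on f01/f02, each
    # negative sample escapes the box on at least one of the two axes
    m["f01", labels == "pos"] <- runif(n_pos, 0, 1)
    m["f02", labels == "pos"] <- runif(n_pos, 0, 1)
    esc <- sample(1:2, n_neg, replace = TRUE)
    m["f01", labels == "neg"] <- ifelse(esc == 1, runif(n_neg, 2, 3),
                                        runif(n_neg, 0, 1))
    m["f02", labels == "neg"] <- ifelse(esc == 2, runif(n_neg, 2, 3),
                                        runif(n_neg, 0, 1))
  }
  list(mat = expression_matrix(m), labels = labels)
}

# minimal labelled 2-feature fixture with a perfectly separable layout
separable_fixture <- function(n_pos = 10, n_neg = 6, gap = 10, sd = 0.1,
                              seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  labels <- label_vector(sprintf("s%02d", 1:n),
                         rep(c("pos", "neg"), c(n_pos, n_neg)))
  m <- rbind(
    f1 = rnorm(n, ifelse(labels == "pos", gap, 0), sd),
    f2 = rnorm(n, ifelse(labels == "pos", 0, gap), sd),
    noise = rnorm(n))
  colnames(m) <- names(labels)
  list(mat = expression_matrix(m), labels = labels)
}
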