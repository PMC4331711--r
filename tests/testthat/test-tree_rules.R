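test_that("rule coverage uses closed intervals", {
  r <- new_rule(data.frame(feature = c("m1", "m2"),
                           low = c(8.94, 95.54), high = c(43.53, 1057.51)),
                "HCV+", 24, 0, 24)
  expect_true(rule_covers(r, c(m1 = 10, m2 = 100)))
  expect_true(rule_covers(r, c(m1 = 8.94, m2 = 95.54)))   # boundary inside
  expect_false(rule_covers(r, c(m1 = 8.93, m2 = 100)))
  expect_error(rule_covers(r, c(m1 = 10)), "missing")
})

test_that("trees split greedily and respect the depth cap", {
  fx <- separable_fixture(seed = 2)
  tr <- build_tree(fx$mat, fx$labels)
  expect_identical(tr$root$type, "node")
  expect_identical(tr$root$left$type, "leaf")
  expect_identical(tr$root$right$type, "leaf")
  counts <- rbind(tr$root$left$counts, tr$root$right$counts)
  expect_true(all(apply(counts, 1, min) == 0))   # both leaves pure

  # XOR-like layout: neither feature separates alone, the pair does
  m <- expression_matrix(rbind(
    fa = c(0, 0, 5, 5, 0, 0, 0, 5, 5, 5),
    fb = c(0, 1, 5, 6, 2, 5, 6, 0, 1, 2)),
    c("fa", "fb"), sprintf("s%02d", 1:10))
  y <- label_vector(colnames(m), rep(c("p", "n"), each = 5))
  tr2 <- build_tree(m, y)
  leaves <- function(nd) if (nd$type == "leaf") list(nd) else
    c(leaves(nd$left), leaves(nd$right))
  expect_true(all(vapply(leaves(tr2$root), function(l) min(l$counts) == 0,
                         TRUE)))
  expect_length(unique(c(tr2$root$feature, tr2$root$left$feature,
                         tr2$root$right$feature)), 2L)

  # pure-noise data must build without error, impure leaves allowed
  set.seed(10)
  mn <- expression_matrix(matrix(rnorm(40), 4, 10,
                                 dimnames = list(paste0("f", 1:4),
                                                 colnames(m))))
  expect_s3_class(build_tree(mn, y), "DecisionTree")
})

test_that("committee removes roots iteratively with distinct roots", {
  fx <- separable_fixture(seed = 3)
  set.seed(3)
  extra <- matrix(rnorm(2 * ncol(fx$mat)), 2,
                  dimnames = list(c("z1", "z2"), colnames(fx$mat)))
  mat <- expression_matrix(rbind(unclass(fx$mat), extra))  # 5 features
  trees <- committee(mat, fx$labels)
  expect_lte(length(trees), 4L)
  roots <- vapply(trees, `[[`, "", "root_feature")
  expect_false(anyDuplicated(roots) > 0)

  two <- expression_matrix(unclass(fx$mat)[c("f1", "f2"), ])
  expect_length(committee(two, fx$labels), 1L)
})

test_that("removing a non-root feature does not change the first tree", {
  fx <- separable_fixture(seed = 4)
  t1 <- build_tree(fx$mat, fx$labels)
  expect_false(t1$root_feature == "noise")
  reduced <- expression_matrix(
    unclass(fx$mat)[setdiff(rownames(fx$mat), "noise"), , drop = FALSE])
  t1b <- build_tree(reduced, fx$labels)
  expect_equal(t1$root, t1b$root)
})

test_that("extracted rules are 100%-frequency with class-extreme bounds", {
  fx <- separable_fixture(seed = 5)
  trees <- committee(fx$mat, fx$labels)
  rules <- extract_rules(trees, fx$mat, fx$labels)
  expect_gte(length(rules), 1L)
  for (r in rules) {
    expect_equal(r$frequency, 1.0)
    expect_identical(r$n_covered_other, 0L)
    expect_true(is_full_frequency(r, fx$mat, fx$labels))
    tgt <- fx$labels == r$target_class
    for (i in seq_len(nrow(r$conditions))) {
      v <- fx$mat[r$conditions$feature[i], tgt]
      expect_equal(r$conditions$low[i], min(v))
      expect_equal(r$conditions$high[i], max(v))
    }
  }
})

test_that("replanted published bounds are recovered as interval ends", {
  # target-class values spanning exactly 8.94..43.53 on one miRNA and
  # 95.54..1057.51 on the other; other class far outside
  set.seed(8)
  pos_m1 <- c(8.94, runif(10, 9, 43), 43.53)
  pos_m2 <- c(95.54, runif(10, 100, 1000), 1057.51)
  neg_m1 <- runif(6, 60, 80)
  neg_m2 <- runif(6, 1200, 1500)
  m <- expression_matrix(rbind(`miR-557` = c(pos_m1, neg_m1),
                               `miR-214` = c(pos_m2, neg_m2)),
                         c("miR-557", "miR-214"), sprintf("s%02d", 1:18))
  y <- label_vector(colnames(m), rep(c("HCV+", "HCV-"), c(12, 6)))
  rules <- extract_rules(committee(m, y), m, y)
  pos_rules <- Filter(function(r) r$target_class == "HCV+", rules)
  expect_gte(length(pos_rules), 1L)
  r <- pos_rules[[1]]
  co <- r$conditions[order(r$conditions$feature), ]
  expect_equal(co$low[co$feature == "miR-557"], 8.94)
  expect_equal(co$high[co$feature == "miR-557"], 43.53)
  expect_equal(co$low[co$feature == "miR-214"], 95.54)
  expect_equal(co$high[co$feature == "miR-214"], 1057.51)
})

test_that("pure-noise matrices yield (usually) no rules", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    m <- expression_matrix(matrix(rnorm(8 * 36), 8, 36,
                                  dimnames = list(paste0("f", 1:8),
                                                  sprintf("s%02d", 1:36))))
    y <- label_vector(colnames(m), rep(c("p", "n"), c(24, 12)))
    hits <- hits + (length(extract_rules(committee(m, y), m, y)) > 0L)
  }
  expect_lte(hits, 1L)
})

test_that("extracted rules are a subset of the exhaustive box search", {
  for (s in 1:30) {
    case <- random_case(s, planted = s %% 2 == 0)
    trees <- committee(case$mat, case$labels)
    rules <- extract_rules(trees, case$mat, case$labels)
    oracle <- oracle_pure_boxes(case$mat, case$labels)
    for (r in rules) {
      key <- paste(sort(r$conditions$feature), collapse = "|")
      expect_true(key %in% oracle[[r$target_class]],
                  info = sprintf("seed %d rule %s", s, key))
      expect_true(is_full_frequency(r, case$mat, case$labels))
    }
  }
})
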