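mirna_rule_fix <- function(feats = c("m1", "m2"), cl = "pos") {
  new_rule(data.frame(feature = feats, low = -Inf, high = Inf), cl, 4, 0, 4)
}

mrna_rule_fix <- function(feats, cl = "pos", round = 1L) {
  new_rule(data.frame(feature = feats, low = -Inf, high = Inf),
           cl, 4, 0, 4, round = round)
}

test_that("filter_targets keeps the union of present targets", {
  map <- target_map(list(m1 = c("g1", "g2"), m2 = c("g2", "g3")))
  mat <- expression_matrix(matrix(rnorm(12), 3, 4),
                           c("g2", "g3", "g9"), paste0("s", 1:4))
  got <- filter_targets(mirna_rule_fix(), map, mat)
  expect_setequal(rownames(got), c("g2", "g3"))
  expect_identical(colnames(got), colnames(mat))
  # idempotent
  expect_identical(unclass(filter_targets(mirna_rule_fix(), map, got)),
                   unclass(got))
  expect_error(filter_targets(mirna_rule_fix(c("m1", "mX")), map, mat),
               "absent from the target map")

  # 97 predicted, 78 present
  genes <- sprintf("G%03d", 1:97)
  map2 <- target_map(list(m1 = genes))
  mat2 <- expression_matrix(matrix(0, 78, 4), genes[1:78], paste0("s", 1:4))
  expect_equal(nrow(filter_targets(mirna_rule_fix("m1"), map2, mat2)), 78L)
})

test_that("top mRNA rules are selected per class with documented ordering", {
  plus <- lapply(1:3, function(i)
    mrna_rule_fix(paste0("p", i), "pos", round = i))
  minus <- lapply(1:5, function(i)
    mrna_rule_fix(paste0("n", i), "neg", round = i))
  sel <- select_top_rules(list(pos = plus, neg = minus), 2L)
  expect_length(sel, 4L)
  expect_equal(vapply(sel, `[[`, 0L, "round"), c(1L, 2L, 1L, 2L))

  sel2 <- select_top_rules(list(pos = plus[1], neg = minus), 2L)
  expect_length(sel2, 3L)   # one class may contribute a single rule

  # tie in round and size -> lexicographic on feature ids
  tied <- list(mrna_rule_fix("zz", "pos", 1L), mrna_rule_fix("aa", "pos", 1L))
  sel3 <- select_top_rules(list(pos = tied), 1L)
  expect_identical(sel3[[1]]$conditions$feature, "aa")
})

test_that("modules join rules through the target map with correlations", {
  set.seed(41)
  n <- 10
  sids <- sprintf("s%02d", 1:n)
  mirna <- expression_matrix(matrix(rnorm(2 * n), 2, n),
                             c("m1", "m2"), sids)
  genes <- paste0("g", 1:4)
  mrna_vals <- rbind(-unclass(mirna)["m1", ] + rnorm(n, 0, 0.01),
                     unclass(mirna)["m1", ],
                     unclass(mirna)["m2", ],
                     rnorm(n))
  mrna <- expression_matrix(mrna_vals, genes, sids)
  map <- target_map(list(m1 = c("g1", "g2", "g3", "g4"),
                         m2 = c("g1", "g2", "g3", "g4")))
  mod <- build_module(mirna_rule_fix(), list(mrna_rule_fix(genes)),
                      map, mirna, mrna)
  expect_equal(nrow(mod$edges), 8L)   # 2 miRNAs x 4 mRNAs, full targeting
  expect_lt(mod$edges$pearson_r[mod$edges$mirna == "m1" &
                                  mod$edges$mrna == "g1"], -0.9)

  # an mRNA in a rule but not a target of either miRNA gets no edge
  map2 <- target_map(list(m1 = c("g1", "g2"), m2 = c("g3")))
  mod2 <- build_module(mirna_rule_fix(), list(mrna_rule_fix(genes)),
                       map2, mirna, mrna)
  expect_equal(nrow(mod2$edges), 3L)
  expect_false("g4" %in% mod2$edges$mrna)
  expect_true("g4" %in% unlist(lapply(mod2$mrna_rules,
                                      function(r) r$conditions$feature)))

  # unpaired samples are dropped and counted
  mrna_sub <- expression_matrix(mrna_vals[, 1:8], genes, sids[1:8])
  mod3 <- build_module(mirna_rule_fix(), list(mrna_rule_fix(genes)),
                       map, mirna, mrna_sub)
  expect_equal(mod3$n_paired, 8L)
  expect_equal(mod3$n_unpaired, 2L)
})

test_that("merged networks deduplicate edges and stay bipartite", {
  set.seed(42)
  n <- 12
  sids <- sprintf("s%02d", 1:n)
  mirna <- expression_matrix(matrix(rnorm(3 * n), 3, n),
                             c("m1", "m2", "m3"), sids)
  mrna <- expression_matrix(matrix(rnorm(2 * n), 2, n),
                            c("g1", "g2"), sids)
  map <- target_map(list(m1 = c("g1", "g2"), m2 = "g1", m3 = "g1"))
  modA <- build_module(mirna_rule_fix(c("m1", "m2")),
                       list(mrna_rule_fix(c("g1", "g2"))), map, mirna, mrna)
  modB <- build_module(mirna_rule_fix(c("m1", "m3")),
                       list(mrna_rule_fix("g1")), map, mirna, mrna)
  net <- merge_network(list(A = modA, B = modB))
  key <- paste(net$edges$mirna, net$edges$mrna)
  expect_false(anyDuplicated(key) > 0)
  shared <- net$edges$modules[net$edges$mirna == "m1" &
                                net$edges$mrna == "g1"]
  expect_identical(shared, "A,B")
  expect_length(intersect(net$mirna_nodes, net$mrna_nodes), 0L)
  expect_true(all(net$edges$mirna %in% c("m1", "m2", "m3")))
  expect_true(all(net$edges$mrna %in% c("g1", "g2")))

  # many-to-many core: g1 has 3 regulators, g2 only 1
  core3 <- many_to_many(net, 3L)
  expect_setequal(core3$mrna_nodes, "g1")
  core4 <- many_to_many(net, 4L)
  expect_length(core4$mrna_nodes, 0L)
})

test_that("planted coupling signs are recovered on module edges", {
  d <- simulate_dataset(synthetic_spec(seed = 13))
  res <- run_pipeline(d$mirna, d$mrna, d$labels, d$targets,
                      config = pipeline_config(seed = 13))
  expect_gte(length(res$modules), 1L)
  edges <- res$network$edges
  truth <- d$truth$couplings
  merged <- merge(edges, truth, by.x = c("mirna", "mrna"),
                  by.y = c("mirna", "gene"))
  expect_gte(nrow(merged), 1L)
  expect_true(all(sign(merged$pearson_r) == merged$sign))
})
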