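#' Restrict an mRNA matrix to the predicted targets of a miRNA rule
#'
#' Keeps every sample but only those mRNA features that are predicted
#' targets of at least one miRNA in the rule. Idempotent.
#'
#' @param mirna_rule a [new_rule()] over miRNA features.
#' @param map a [target_map()].
#' @param mrna_mat an [expression_matrix()] of mRNA profiles.
#' @return the restricted [expression_matrix()].
#' @export
filter_targets <- function(mirna_rule, map, mrna_mat) {
  mirnas <- mirna_rule$conditions$feature
  missing <- setdiff(mirnas, names(map))
  if (length(missing) > 0L)
    stop("miRNA(s) absent from the target map: ",
         paste(missing, collapse = ", "))
  targets <- unique(unlist(map[mirnas], use.names = FALSE))
  present <- intersect(rownames(mrna_mat), targets)
  if (length(present) == 0L)
    stop("no predicted target of rule {",
         paste(mirnas, collapse = ", "), "} is present in the mRNA matrix")
  expression_matrix(mrna_mat[present, , drop = FALSE])
}

rule_sort_key <- function(rules) {
  order(vapply(rules, function(r) if (is.na(r$round)) 1L else r$round, 0L),
        vapply(rules, function(r) nrow(r$conditions), 0L),
        vapply(rules, function(r)
          paste(sort(r$conditions$feature), collapse = "|"), ""))
}

#' Select the top mRNA rules per class
#'
#' Takes up to `limit_per_class` rules per class, ordered by mining
#' round (ascending), then number of conditions (ascending: more
#' parsimonious first), then lexicographically on the sorted feature
#' ids. Short lists are allowed: a class contributes however many rules
#' it has, up to the limit.
#'
#' @param rules_by_class named list of per-class rule lists, as returned
#'   by [mine_all_rules()].
#' @param limit_per_class maximum rules per class (default 2, i.e. up to
#'   four rules for two classes).
#' @return flat list of selected rules.
#' @export
select_top_rules <- function(rules_by_class, limit_per_class = 2L) {
  out <- list()
  for (cl in names(rules_by_class)) {
    rl <- rules_by_class[[cl]]
    if (length(rl) == 0L) next
    rl <- rl[rule_sort_key(rl)]
    out <- c(out, rl[seq_len(min(limit_per_class, length(rl)))])
  }
  out
}

#' Build one miRNA-mRNA regulatory module
#'
#' A bipartite structure: the miRNAs of one discriminatory rule on one
#' side, the mRNAs of its selected mRNA rules on the other. An edge
#' (miRNA, mRNA) is drawn when the mRNA is a predicted target of the
#' miRNA; the edge carries the Pearson correlation of the two expression
#' profiles over the paired samples (samples present in both matrices;
#' unpaired samples are excluded and counted in `n_unpaired`). An mRNA
#' appearing in a rule but targeted by none of the module's miRNAs stays
#' in the rule listing but gets no edge.
#'
#' @param mirna_rule a [new_rule()] over miRNAs.
#' @param mrna_rules selected mRNA rules (see [select_top_rules()]).
#' @param map a [target_map()].
#' @param mirna_mat,mrna_mat paired [expression_matrix()] objects.
#' @return object of class `"RegulatoryModule"` with fields
#'   `mirna_rule`, `mrna_rules`, `edges` (data.frame `mirna`, `mrna`,
#'   `pearson_r`), `n_paired`, `n_unpaired`.
#' @export
build_module <- function(mirna_rule, mrna_rules, map, mirna_mat, mrna_mat) {
  paired <- intersect(colnames(mirna_mat), colnames(mrna_mat))
  n_unpaired <- length(union(colnames(mirna_mat), colnames(mrna_mat))) -
    length(paired)
  if (length(paired) < 3L)
    stop("need at least 3 paired samples for correlation")
  mirnas <- mirna_rule$conditions$feature
  genes <- unique(unlist(lapply(mrna_rules, function(r) r$conditions$feature)))
  edges <- list()
  for (m in mirnas) {
    tg <- intersect(genes, map[[m]])
    for (g in tg) {
      r <- suppressWarnings(
        pearson_cor(mirna_mat[m, paired], mrna_mat[g, paired]))
      edges[[length(edges) + 1L]] <-
        data.frame(mirna = m, mrna = g, pearson_r = r)
    }
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(mirna = character(), mrna = character(),
               pearson_r = numeric())
  structure(list(mirna_rule = mirna_rule, mrna_rules = mrna_rules,
                 edges = edges, n_paired = length(paired),
                 n_unpaired = n_unpaired),
            class = "RegulatoryModule")
}

#' Merge regulatory modules into one interaction network
#'
#' Edges shared by several modules appear once, with all source module
#' ids attached. The miRNA pairs that co-occur in a rule are kept as
#' `corule` edges (rendered as miRNA-miRNA links in SIF export). Edges
#' are classified as `inverse`, `positive` or `uncorrelated` by the sign
#' of Pearson r against `sign_threshold`.
#'
#' @param modules list of `"RegulatoryModule"` objects.
#' @param sign_threshold |r| at or above which an edge gets a sign label
#'   (default 0.1).
#' @return object of class `"InteractionNetwork"` with `mirna_nodes`,
#'   `mrna_nodes`, `edges` (data.frame `mirna`, `mrna`, `pearson_r`,
#'   `regulation`, `modules`), `corule`.
#' @export
merge_network <- function(modules, sign_threshold = 0.1) {
  if (length(modules) == 0L) stop("need at least one module")
  ids <- names(modules)
  if (is.null(ids)) ids <- sprintf("M%d", seq_along(modules))
  all_edges <- do.call(rbind, lapply(seq_along(modules), function(i) {
    e <- modules[[i]]$edges
    if (nrow(e) == 0L) return(NULL)
    e$module <- ids[i]
    e
  }))
  if (is.null(all_edges))
    all_edges <- data.frame(mirna = character(), mrna = character(),
                            pearson_r = numeric(), module = character())
  key <- paste(all_edges$mirna, all_edges$mrna, sep = "\r")
  first <- !duplicated(key)
  edges <- all_edges[first, c("mirna", "mrna", "pearson_r")]
  edges$modules <- vapply(key[first], function(k)
    paste(sort(unique(all_edges$module[key == k])), collapse = ","), "")
  edges$regulation <- ifelse(
    is.na(edges$pearson_r) | abs(edges$pearson_r) < sign_threshold,
    "uncorrelated",
    ifelse(edges$pearson_r < 0, "inverse", "positive"))
  rownames(edges) <- NULL
  co <- do.call(rbind, lapply(modules, function(m) {
    f <- sort(m$mirna_rule$conditions$feature)
    if (length(f) < 2L) return(NULL)
    pairs <- utils::combn(f, 2)
    data.frame(mirna1 = pairs[1, ], mirna2 = pairs[2, ])
  }))
  if (!is.null(co)) co <- unique(co)
  structure(list(
    mirna_nodes = unique(edges$mirna),
    mrna_nodes = unique(edges$mrna),
    edges = edges,
    corule = co
  ), class = "InteractionNetwork")
}

#' Many-to-many core of an interaction network
#'
#' Keeps the mRNAs regulated by at least `min_regulators` distinct
#' miRNAs, together with their incident edges.
#'
#' @param network an `"InteractionNetwork"` from [merge_network()].
#' @param min_regulators minimum number of distinct miRNA partners
#'   (default 3).
#' @return an `"InteractionNetwork"` restricted to the core.
#' @export
many_to_many <- function(network, min_regulators = 3L) {
  deg <- tapply(network$edges$mirna, network$edges$mrna,
                function(m) length(unique(m)))
  keep <- names(deg)[deg >= min_regulators]
  edges <- network$edges[network$edges$mrna %in% keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(mirna_nodes = unique(edges$mirna),
                 mrna_nodes = unique(edges$mrna),
                 edges = edges, corule = network$corule),
            class = "InteractionNetwork")
}
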