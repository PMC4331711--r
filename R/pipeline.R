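#' Pipeline configuration
#'
#' Bundles every tunable setting of the full analysis with the
#' defaults used throughout the package: gain-ratio cutoff 0.5 for
#' feature ranking, 2-feature interval rules, 10-fold cross-validated
#' AUC, up to two mRNA rules per class (four per module), many-to-many
#' cores at three regulators, a one-mismatch seed-scan budget, and an
#' |r| >= 0.1 threshold for calling an edge inverse/positive. One global
#' seed fans out to per-stage seeds by fixed offsets, so adding a stage
#' never perturbs earlier stages' randomness.
#'
#' @param gr_cutoff gain-ratio cutoff for [rank_features()].
#' @param max_k maximum conditions per miRNA rule (tree depth limit).
#' @param folds folds for [cv_auc()].
#' @param top_rules_per_class mRNA rules kept per class per module.
#' @param min_regulators threshold for [many_to_many()].
#' @param max_mismatch seed-scan mismatch budget.
#' @param sign_threshold |r| at or above which an edge is sign-labelled.
#' @param welch use Welch's t-test in ranking.
#' @param allow_wobble accept G-U pairs in the seed scan.
#' @param seed global RNG seed.
#' @return object of class `"PipelineConfig"` (a validated list).
#' @export
pipeline_config <- function(gr_cutoff = 0.5, max_k = 2L, folds = 10L,
                            top_rules_per_class = 2L, min_regulators = 3L,
                            max_mismatch = 1L, sign_threshold = 0.1,
                            welch = FALSE, allow_wobble = FALSE, seed = 1L) {
  stopifnot(max_k >= 1L, folds >= 2L, top_rules_per_class >= 1L,
            min_regulators >= 1L, max_mismatch >= 0L)
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full rule-connection analysis
#'
#' Chains all stages on in-memory inputs: (1) gain-ratio ranking of the
#' miRNAs with t-test p-values, (2) committee-tree discovery of
#' 100%-frequency 2-miRNA interval rules on the top-ranked features,
#' (3) per-rule scoring by Max-Min distance and cross-validated AUC,
#' (4) for each miRNA rule, restriction of the mRNA matrix to the
#' rule's predicted targets and greedy multi-round mining of
#' 100%-frequency mRNA rules, (5) module construction (top mRNA rules,
#' bipartite Pearson-signed edges) and network merging, and optionally
#' (6) a seed-complementarity scan of supplied sequences against
#' supplied seeds. Rules whose miRNAs all lack target predictions are
#' skipped and counted in the manifest.
#'
#' @param mirna,mrna [expression_matrix()] objects over a shared (or
#'   overlapping) sample set.
#' @param labels a [label_vector()] covering the miRNA samples.
#' @param targets a [target_map()].
#' @param sequences optional list of [seq_record()]s for the seed scan.
#' @param seeds optional named character vector, miRNA id -> seed
#'   string.
#' @param config a [pipeline_config()].
#' @return list with `ranked`, `trees`, `mirna_rules` (named R1..Rn,
#'   ordered by class then Max-Min distance), `scores`, `mrna_rules`,
#'   `modules`, `network`, `many_to_many`, `seed_matches`, `manifest`.
#' @export
run_pipeline <- function(mirna, mrna, labels, targets,
                         sequences = NULL, seeds = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"))
  manifest <- list(config = unclass(config), seed = config$seed)

  ranked <- rank_features(mirna, labels, gr_cutoff = config$gr_cutoff,
                          welch = config$welch)
  manifest$n_features_ranked <- nrow(ranked)
  if (nrow(ranked) < 2L)
    stop("stage ranking: fewer than two miRNAs pass the gain-ratio cutoff ",
         config$gr_cutoff)
  top <- expression_matrix(mirna[ranked$feature_id, , drop = FALSE])

  trees <- committee(top, labels, max_depth = config$max_k)
  rules <- extract_rules(trees, top, labels)
  manifest$n_trees <- length(trees)
  manifest$n_mirna_rules <- length(rules)
  if (length(rules) == 0L) {
    manifest$note <- "no 100%-frequency miRNA rule found"
    return(list(ranked = ranked, trees = trees, mirna_rules = list(),
                scores = NULL, mrna_rules = list(), modules = list(),
                network = NULL, many_to_many = NULL, seed_matches = NULL,
                manifest = manifest))
  }

  dist <- vapply(rules, maxmin_distance, 0, mat = top, labels = labels)
  cls <- vapply(rules, `[[`, "", "target_class")
  ord <- order(match(cls, levels(align_labels(top, labels))), -dist)
  rules <- rules[ord]
  names(rules) <- sprintf("R%d", seq_along(rules))
  scores <- data.frame(
    rule_id = names(rules),
    target_class = cls[ord],
    maxmin_distance = dist[ord],
    mean_auc = vapply(seq_along(rules), function(i)
      suppressWarnings(cv_auc(rules[[i]], top, labels,
                              folds = config$folds,
                              seed = config$seed + 1000L + i)), 0))

  mrna_rules <- list()
  modules <- list()
  skipped <- character()
  for (rid in names(rules)) {
    r <- rules[[rid]]
    if (!any(r$conditions$feature %in% names(targets))) {
      skipped <- c(skipped, rid)
      next
    }
    known <- r$conditions$feature[r$conditions$feature %in% names(targets)]
    sub_rule <- r
    sub_rule$conditions <- r$conditions[r$conditions$feature %in% known, ,
                                        drop = FALSE]
    selected_mat <- tryCatch(filter_targets(sub_rule, targets, mrna),
                             error = function(e) NULL)
    if (is.null(selected_mat)) {
      skipped <- c(skipped, rid)
      next
    }
    by_class <- mine_all_rules(selected_mat, labels)
    top_rules <- select_top_rules(by_class, config$top_rules_per_class)
    mrna_rules[[rid]] <- by_class
    if (length(top_rules) == 0L) next
    modules[[rid]] <- build_module(r, top_rules, targets, mirna, mrna)
  }
  manifest$n_modules <- length(modules)
  manifest$skipped_rules <- skipped
  manifest$n_mrna_rules <- vapply(mrna_rules, function(bc)
    sum(lengths(bc)), 0)

  network <- if (length(modules) > 0L)
    merge_network(modules, sign_threshold = config$sign_threshold) else NULL
  core <- if (!is.null(network))
    many_to_many(network, config$min_regulators) else NULL
  if (!is.null(network)) manifest$n_edges <- nrow(network$edges)

  seed_matches <- NULL
  if (!is.null(sequences) && !is.null(seeds)) {
    hits <- list()
    for (m in names(seeds))
      for (sq in sequences) {
        h <- scan_seed(seeds[[m]], sq, max_mismatch = config$max_mismatch,
                       allow_wobble = config$allow_wobble, mirna_id = m)
        if (nrow(h) > 0L) hits[[length(hits) + 1L]] <- h
      }
    seed_matches <- if (length(hits) > 0L) do.call(rbind, hits) else
      data.frame()
    manifest$n_seed_matches <- nrow(seed_matches)
  }

  list(ranked = ranked, trees = trees, mirna_rules = rules, scores = scores,
       mrna_rules = mrna_rules, modules = modules, network = network,
       many_to_many = core, seed_matches = seed_matches, manifest = manifest)
}

#' Write the pipeline's artifacts to a directory
#'
#' Serializes the ranked table, miRNA/mRNA rules, per-module edges, the
#' merged network (SIF + edge list) and the manifest as plain-text
#' files.
#'
#' @param result value of [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  utils::write.table(result$ranked, p("ranked.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(result$mirna_rules) > 0L)
    write_rules(result$mirna_rules, p("mirna_rules.json"))
  if (!is.null(result$scores))
    utils::write.table(result$scores, p("rule_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (rid in names(result$mrna_rules)) {
    flat <- unlist(result$mrna_rules[[rid]], recursive = FALSE)
    if (length(flat) > 0L)
      write_rules(flat, p(sprintf("mrna_rules_%s.json", rid)))
  }
  if (!is.null(result$network)) {
    write_network(result$network, p("network.sif"), "sif")
    write_network(result$network, p("network_edges.tsv"), "edgelist")
  }
  if (!is.null(result$seed_matches) && nrow(result$seed_matches) > 0L)
    utils::write.table(result$seed_matches, p("seed_matches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
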