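#' Read an expression matrix from TSV/CSV
#'
#' First row holds sample ids, first column feature ids, body numeric.
#' The delimiter is auto-detected from the file extension (`.csv` ->
#' comma, otherwise tab) and can be forced with `dialect`. Values are
#' used as supplied; no log-transform or rescaling is applied.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- switch(dialect,
                auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t",
                tsv = "\t", csv = ",")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("empty or header-only expression file: ", path)
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (nrow(df) != length(lines) - 1L)
    stop("parsed row count does not match input line count")
  feature_ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at feature '%s', sample '%s'",
                 feature_ids[bad[1, 1]], colnames(body)[bad[1, 2]]))
  expression_matrix(vals, feature_ids, colnames(body))
}

#' Write an expression matrix
#'
#' @param mat an [expression_matrix()].
#' @inheritParams read_expression
#' @export
write_expression <- function(mat, path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- switch(dialect,
                auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t",
                tsv = "\t", csv = ",")
  body <- matrix(formatC(mat, digits = 17, format = "g"), nrow = nrow(mat))
  lines <- c(paste(c("id", colnames(mat)), collapse = sep),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(rownames(mat)[i], body[i, ]), collapse = sep), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read per-sample class labels
#'
#' Two-column CSV/TSV `sample_id, label` (no header required; a header
#' line `sample_id` is skipped if present). Exactly two distinct classes
#' are required; class order is first-seen order.
#'
#' @param path file path.
#' @return a [label_vector()].
#' @export
read_labels <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          colClasses = "character", comment.char = "")
  if (tolower(df[1, 1]) %in% c("sample_id", "sample", "id"))
    df <- df[-1, , drop = FALSE]
  if (ncol(df) != 2L) stop("label file must have exactly two columns")
  label_vector(df[[1]], df[[2]])
}

#' @rdname read_labels
#' @param labels a [label_vector()].
#' @export
write_labels <- function(labels, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(data.frame(names(labels), as.character(labels)),
                     path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a miRNA -> target-gene map
#'
#' Two-column TSV `miRNA_id, gene_id` (TargetScan-style export).
#' Duplicate rows collapse to set membership.
#'
#' @param path file path.
#' @return a [target_map()].
#' @export
read_target_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "")
  if (nrow(df) == 0L) stop("empty target map: ", path)
  if (ncol(df) < 2L) stop("target map must have two tab-separated columns")
  target_map(split(df[[2]], df[[1]]))
}

#' @rdname read_target_map
#' @param map a [target_map()].
#' @export
write_target_map <- function(map, path) {
  df <- data.frame(mirna = rep(names(map), lengths(map)),
                   gene = unlist(map, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read UTR/CDS sequences from FASTA
#'
#' Headers follow the convention `>id|region` with region one of
#' 5UTR/3UTR/CDS; when the region tag is absent the record defaults to
#' 3UTR (the canonical miRNA binding region). DNA `T` is normalized to
#' RNA `U`.
#'
#' @param path FASTA file.
#' @return list of [seq_record()] objects.
#' @export
read_fasta_regions <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    parts <- strsplit(headers[i], "|", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    id <- strsplit(parts[1], "\\s+")[[1]][1]
    if (is.na(id) || !nzchar(id)) stop("malformed FASTA header: ", headers[i])
    region <- if (length(parts) >= 2L) parts[2] else "3UTR"
    if (!region %in% c("5UTR", "3UTR", "CDS"))
      stop("unknown region tag '", region, "' in header: ", headers[i])
    seq_record(id, as.character(set[[i]]), region)
  })
}

#' @rdname read_fasta_regions
#' @param records list of [seq_record()] objects.
#' @export
write_fasta_regions <- function(records, path) {
  txt <- unlist(lapply(records, function(r)
    c(paste0(">", r$id, "|", r$region), r$sequence)))
  writeLines(txt, path)
  invisible(path)
}

rule_to_list <- function(rule) {
  list(class = rule$target_class,
       conditions = lapply(seq_len(nrow(rule$conditions)), function(i)
         list(feature = rule$conditions$feature[i],
              low = rule$conditions$low[i],
              high = rule$conditions$high[i])),
       frequency = rule$frequency,
       n_covered_class = rule$n_covered_target,
       n_covered_other = rule$n_covered_other,
       class_size = rule$class_size,
       round = if (is.na(rule$round)) NULL else rule$round)
}

list_to_rule <- function(x) {
  conds <- do.call(rbind, lapply(x$conditions, function(co)
    data.frame(feature = co$feature, low = co$low, high = co$high)))
  rd <- x$round
  if (is.null(rd) || length(rd) == 0L) rd <- NA_integer_
  new_rule(conds, x$class, x$n_covered_class, x$n_covered_other,
           x$class_size, rd)
}

#' Serialize rules as structured JSON text
#'
#' Lossless round-trip: `read_rules(write_rules(rules, path))` recovers
#' the same rule objects.
#'
#' @param rules list of [new_rule()] objects.
#' @param path output file.
#' @export
write_rules <- function(rules, path) {
  jsonlite::write_json(lapply(rules, rule_to_list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  x <- jsonlite::read_json(path)
  lapply(x, list_to_rule)
}

#' Write a bipartite interaction network
#'
#' `sif` writes `miRNA<TAB>regulates<TAB>mRNA` rows (plus
#' `miRNA<TAB>corule<TAB>miRNA` rows for miRNAs sharing a rule, when the
#' network carries them); `edgelist` writes three columns
#' `miRNA, mRNA, pearson_r`.
#'
#' @param network an interaction network from [merge_network()].
#' @param path output file.
#' @param format `"sif"` or `"edgelist"`.
#' @export
write_network <- function(network, path, format = c("sif", "edgelist")) {
  format <- match.arg(format)
  e <- network$edges
  if (format == "sif") {
    rows <- sprintf("%s\tregulates\t%s", e$mirna, e$mrna)
    co <- network$corule
    if (!is.null(co) && nrow(co) > 0L)
      rows <- c(rows, sprintf("%s\tcorule\t%s", co$mirna1, co$mirna2))
    writeLines(rows, path)
  } else {
    utils::write.table(
      data.frame(e$mirna, e$mrna, signif(e$pearson_r, 6)),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
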