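#' Published dinucleotide transition table of the GFRA2 5' UTR
#'
#' The GFRA2 transcript's 5' UTR (length 675 nt; 151 A, 182 G, 161 U,
#' 181 C) is the worked reference case for the first-order Markov
#' background model: its published adjacent-base count table, bundled
#' here as plain text, lets the transition probabilities and seed-site
#' significance be recomputed without the sequence itself.
#' `gfra2_transition_counts()` returns the 4x4 count matrix (A/G/U/C
#' order), `gfra2_transition_probs()` the accompanying 3-decimal
#' row-stochastic probabilities, and `gfra2_transition_matrix()` a
#' ready-made `"TransitionMatrix"` built from the counts, with the base
#' composition taken from the count row sums.
#'
#' @return a 4x4 numeric matrix, or a `"TransitionMatrix"`.
#' @examples
#' tm <- gfra2_transition_matrix()
#' tm$length            # 675
#' mm_probability("AAAAAAA", tm)
#' @export
gfra2_transition_counts <- function() {
  f <- system.file("extdata", "gfra2_5utr_transition_counts.tsv",
                   package = "mirulenet", mustWork = TRUE)
  as.matrix(utils::read.table(f, header = TRUE, row.names = 1, sep = "\t"))
}

#' @rdname gfra2_transition_counts
#' @export
gfra2_transition_probs <- function() {
  f <- system.file("extdata", "gfra2_5utr_transition_probs.tsv",
                   package = "mirulenet", mustWork = TRUE)
  as.matrix(utils::read.table(f, header = TRUE, row.names = 1, sep = "\t"))
}

#' @rdname gfra2_transition_counts
#' @export
gfra2_transition_matrix <- function() {
  counts <- gfra2_transition_counts()
  transition_matrix_from_counts(counts, rowSums(counts))
}
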