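RNA_BASES <- c("A", "G", "U", "C")   # fixed row/column order of all outputs

#' First-order Markov transition matrix of a sequence
#'
#' Counts every adjacent base pair of the sequence, row-normalizes the
#' counts into transition probabilities, and records the base
#' composition and length. Row b of the count matrix sums to the number
#' of occurrences of b, minus one if b is the terminal base (the last
#' base starts no pair). Bases absent from the sequence leave a
#' zero-count row: its probability row is left at zero and listed in
#' the `zero_rows` field.
#'
#' @param x a [seq_record()] or an RNA string.
#' @return object of class `"TransitionMatrix"` with fields `counts`,
#'   `probs` (both 4x4, A/G/U/C order), `composition`, `length`,
#'   `zero_rows`.
#' @examples
#' tm <- build_transition_matrix("ACGUACGU")
#' tm$probs
#' @export
build_transition_matrix <- function(x) {
  s <- if (inherits(x, "SeqRecord")) x$sequence else
    seq_record("seq", x)$sequence
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2L) stop("need a sequence of length >= 2")
  from <- factor(ch[-length(ch)], levels = RNA_BASES)
  to <- factor(ch[-1], levels = RNA_BASES)
  counts <- table(from, to)
  counts <- matrix(as.integer(counts), 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  composition <- table(factor(ch, levels = RNA_BASES))
  composition <- stats::setNames(as.integer(composition), RNA_BASES)
  structure(list(counts = counts, probs = probs,
                 composition = composition, length = length(ch),
                 zero_rows = RNA_BASES[rs == 0]),
            class = "TransitionMatrix")
}

#' Assemble a transition matrix from externally supplied counts
#'
#' For analyses that start from a published dinucleotide count table
#' rather than from the sequence itself.
#'
#' @param counts 4x4 integer matrix, rows = preceding base, A/G/U/C order.
#' @param composition named integer vector of base counts (A/G/U/C).
#' @param length sequence length L; defaults to `sum(composition)`.
#' @return a `"TransitionMatrix"`.
#' @export
transition_matrix_from_counts <- function(counts, composition,
                                          length = sum(composition)) {
  counts <- as.matrix(counts)
  dimnames(counts) <- list(RNA_BASES, RNA_BASES)
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  if (!is.null(names(composition))) composition <- composition[RNA_BASES]
  structure(list(counts = counts, probs = probs,
                 composition = stats::setNames(as.integer(composition),
                                               RNA_BASES),
                 length = as.integer(length),
                 zero_rows = RNA_BASES[rs == 0]),
            class = "TransitionMatrix")
}

#' @export
print.TransitionMatrix <- function(x, ...) {
  cat(sprintf("First-order Markov model of a length-%d sequence\n", x$length))
  m <- matrix(sprintf("%d (%.3f)", x$counts, x$probs), 4, 4,
              dimnames = dimnames(x$counts))
  print(m, quote = FALSE)
  cat("composition:", paste(sprintf("%s=%d", names(x$composition),
                                    x$composition), collapse = " "), "\n")
  invisible(x)
}

#' Markov probability of a k-mer
#'
#' `p = composition[c1]/L * prod(probs[c_i, c_{i+1}])`: the chance that
#' a window of the background chain spells the k-mer, with the initial
#' distribution taken from the global base composition. Summed over all
#' 4^k k-mers of a fixed k this is 1 whenever every reachable row of the
#' transition matrix is stochastic. A zero-probability transition gives
#' p = 0.
#'
#' @param kmer RNA string.
#' @param tm a `"TransitionMatrix"`.
#' @return probability in (0, 1], or 0 for an unreachable k-mer.
#' @export
mm_probability <- function(kmer, tm) {
  kmer <- chartr("T", "U", toupper(kmer))
  ch <- strsplit(kmer, "")[[1]]
  if (length(ch) < 1L) stop("empty k-mer")
  if (!all(ch %in% RNA_BASES)) stop("k-mer contains non-RNA characters")
  p <- tm$composition[ch[1]] / tm$length
  for (i in seq_len(length(ch) - 1L))
    p <- p * tm$probs[ch[i], ch[i + 1L]]
  unname(p)
}

#' Reverse complement of an RNA string
#'
#' @param x RNA string (A/C/G/U; T accepted and treated as U).
#' @return the reverse complement as an RNA string.
#' @export
reverse_complement_rna <- function(x) {
  x <- chartr("T", "U", toupper(x))
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

#' Scan a sequence for seed-complementary sites
#'
#' Slides a window of seed length over the sense strand and reports
#' every window equal to the reverse complement of the seed at up to
#' `max_mismatch` positions. Only Watson-Crick pairs (A-U, G-C) count as
#' matches unless `allow_wobble = TRUE`, which additionally accepts G-U
#' pairs. Each match is annotated with the first-order Markov
#' probability of the observed genomic window under the sequence's own
#' background model (`p_exact`) and with
#' `p_window = 1 - (1 - p_exact)^(L - k + 1)`, the probability that at
#' least one window of the sequence spells that site. Coordinates are
#' 1-based and inclusive.
#'
#' @param seed miRNA seed (positions 2-8 of the mature miRNA, typically
#'   7 nt; lengths 6-8 accepted), 5'->3'.
#' @param seq a [seq_record()].
#' @param max_mismatch mismatch budget (default 1).
#' @param allow_wobble accept G-U wobble pairs as matches.
#' @param mirna_id id recorded in the output (defaults to the seed).
#' @return data.frame with columns `mirna_id`, `sequence_id`, `region`,
#'   `start`, `end`, `mismatches`, `site`, `p_exact`, `p_window`.
#' @examples
#' s <- seq_record("g1", "GGUUUUUUUGG", "5UTR")
#' scan_seed("AAAAAAA", s)   # one perfect site at 3..9
#' @export
scan_seed <- function(seed, seq, max_mismatch = 1L, allow_wobble = FALSE,
                      mirna_id = seed) {
  seed <- chartr("T", "U", toupper(seed))
  if (grepl("[^ACGU]", seed)) stop("seed contains non-RNA characters")
  k <- nchar(seed)
  if (k < 6L || k > 8L) stop("seed length must be 6-8 nt")
  s <- seq$sequence
  L <- nchar(s)
  if (L < k) stop("sequence shorter than the seed")
  pat <- strsplit(reverse_complement_rna(seed), "")[[1]]
  ch <- strsplit(s, "")[[1]]
  n_win <- L - k + 1L
  mism <- integer(n_win)
  for (i in seq_len(k)) {
    t_base <- ch[seq_len(n_win) + i - 1L]
    ok <- t_base == pat[i]
    if (allow_wobble)   # seed G pairs target U; seed U pairs target G
      ok <- ok | (pat[i] == "C" & t_base == "U") | (pat[i] == "A" & t_base == "G")
    mism <- mism + !ok
  }
  hit <- which(mism <= max_mismatch)
  if (length(hit) == 0L)
    return(data.frame(mirna_id = character(), sequence_id = character(),
                      region = character(), start = integer(), end = integer(),
                      mismatches = integer(), site = character(),
                      p_exact = numeric(), p_window = numeric()))
  tm <- build_transition_matrix(seq)
  sites <- substring(s, hit, hit + k - 1L)
  p_exact <- vapply(sites, function(w) mm_probability(w, tm), 0, USE.NAMES = FALSE)
  data.frame(
    mirna_id = mirna_id, sequence_id = seq$id, region = seq$region,
    start = hit, end = hit + k - 1L, mismatches = mism[hit], site = sites,
    p_exact = p_exact,
    p_window = 1 - (1 - p_exact)^(L - k + 1L))
}

#' Export a transition matrix as a count/probability table
#'
#' Writes a TSV shaped like the standard presentation of dinucleotide
#' transition tables: one row per preceding base, cells
#' `count (3-decimal probability)`, plus row sums and a terminal
#' column-sum row.
#'
#' @param tm a `"TransitionMatrix"`.
#' @param path output file.
#' @export
write_transition_matrix <- function(tm, path) {
  body <- vapply(seq_len(4), function(i)
    paste(sprintf("%d (%.3f)", tm$counts[i, ], tm$probs[i, ]), collapse = "\t"),
    "")
  rows <- c(paste(c("", RNA_BASES, "Sum"), collapse = "\t"),
            sprintf("%s\t%s\t%d (1.000)", RNA_BASES, body, rowSums(tm$counts)),
            paste(c("Sum", sprintf("%d", colSums(tm$counts)),
                    sprintf("%d", sum(tm$counts))), collapse = "\t"))
  writeLines(rows, path)
  invisible(path)
}
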