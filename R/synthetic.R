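#' Specification for the synthetic paired-expression generator
#'
#' Describes a two-class study with planted, recoverable structure:
#' `n_signal_mirna` miRNAs whose class-conditional means differ by
#' `class_gap` (within-class spread `noise_sd`), a block of background
#' miRNAs with no class signal, one planted target mRNA block per signal
#' miRNA (linear coupling `sign * slope * miRNA + noise`), background
#' mRNAs, a target map linking each signal miRNA to its planted targets
#' plus decoys, and UTR/CDS sequences carrying seed-complementary sites
#' at recorded positions. The seed fully determines the output. The
#' defaults mirror a 24 vs 12 two-class design with four strongly
#' separated signal miRNAs (gap-to-noise ratio 100) carrying three
#' targets each with couplings of magnitude 0.9.
#'
#' @param n_pos,n_neg samples per class.
#' @param n_signal_mirna,n_noise_mirna signal / background miRNA counts.
#' @param targets_per_mirna planted targets per signal miRNA.
#' @param decoys_per_mirna background genes added to each miRNA's
#'   predicted-target set (predicted but not coupled).
#' @param n_noise_mrna background mRNA count.
#' @param coupling_signs vector of +1/-1 recycled over planted targets;
#'   default alternates, so both inverse and positive regulation are
#'   planted.
#' @param slope coupling magnitude.
#' @param noise_sd Gaussian noise s.d. for miRNA within-class spread and
#'   mRNA residuals.
#' @param class_gap separation of the class-conditional miRNA means.
#' @param seed_length seed length in nt (default 7).
#' @param utr_length length of each generated sequence.
#' @param site_mismatches mismatches planted into each seed site (0/1).
#' @param seed RNG seed; same spec + seed gives bit-identical output.
#' @return object of class `"SyntheticSpec"`.
#' @export
synthetic_spec <- function(n_pos = 24L, n_neg = 12L,
                           n_signal_mirna = 4L, n_noise_mirna = 20L,
                           targets_per_mirna = 3L, decoys_per_mirna = 2L,
                           n_noise_mrna = 40L,
                           coupling_signs = c(1, -1),
                           slope = 0.9, noise_sd = 0.1, class_gap = 10,
                           seed_length = 7L, utr_length = 120L,
                           site_mismatches = 1L, seed = 1L) {
  if (n_pos < 2L || n_neg < 2L) stop("need at least two samples per class")
  if (n_signal_mirna < 1L && n_noise_mirna < 1L) stop("no miRNA features")
  if (class_gap < 0 || noise_sd < 0) stop("class_gap and noise_sd must be >= 0")
  structure(as.list(environment()), class = "SyntheticSpec")
}

random_rna <- function(n) paste(sample(RNA_BASES, n, replace = TRUE),
                                collapse = "")

complement_base <- function(b) c(A = "U", U = "A", G = "C", C = "G")[b]

plant_site <- function(utr_length, seed_str, mismatches) {
  k <- nchar(seed_str)
  site <- strsplit(reverse_complement_rna(seed_str), "")[[1]]
  if (mismatches > 0L) {
    pos <- sample.int(k, mismatches)
    for (p in pos)
      site[p] <- sample(setdiff(RNA_BASES, site[p]), 1L)
  }
  start <- sample.int(utr_length - k + 1L, 1L)
  bg <- strsplit(random_rna(utr_length), "")[[1]]
  bg[start:(start + k - 1L)] <- site
  list(sequence = paste(bg, collapse = ""), start = start, end = start + k - 1L)
}

#' Generate a synthetic paired miRNA/mRNA study
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `mirna`, `mrna` ([expression_matrix()]s),
#'   `labels` ([label_vector()]), `targets` ([target_map()]),
#'   `sequences` (list of [seq_record()]s) and `truth`, a list recording
#'   the planted structure: `signal_mirnas`, `couplings` (data.frame
#'   `mirna`, `gene`, `sign`, `slope`), `seeds` (named vector of seed
#'   strings), `sites` (data.frame `gene`, `start`, `end`,
#'   `mismatches`).
#' @examples
#' d <- simulate_dataset(synthetic_spec(seed = 7))
#' dim(d$mirna); table(d$labels)
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_seed(spec$seed, {
    n <- spec$n_pos + spec$n_neg
    sample_ids <- sprintf("s%02d", seq_len(n))
    labels <- label_vector(sample_ids,
                           rep(c("pos", "neg"), c(spec$n_pos, spec$n_neg)))
    is_pos <- labels == "pos"

    sig_ids <- if (spec$n_signal_mirna > 0L)
      sprintf("miR-s%02d", seq_len(spec$n_signal_mirna)) else character()
    noi_ids <- if (spec$n_noise_mirna > 0L)
      sprintf("miR-n%02d", seq_len(spec$n_noise_mirna)) else character()
    mirna <- matrix(0, length(sig_ids) + length(noi_ids), n,
                    dimnames = list(c(sig_ids, noi_ids), sample_ids))
    for (i in seq_along(sig_ids)) {
      base <- stats::runif(1, 50, 100)
      up_in_pos <- i %% 2L == 1L       # alternate the shifted class
      mu <- ifelse(xor(is_pos, !up_in_pos), base + spec$class_gap, base)
      mirna[sig_ids[i], ] <- stats::rnorm(n, mu, spec$noise_sd)
    }
    for (j in seq_along(noi_ids))
      mirna[noi_ids[j], ] <- stats::rnorm(n, stats::runif(1, 50, 100), 1)

    couplings <- NULL
    tgt_ids <- character()
    mrna_rows <- list()
    sgn <- rep_len(spec$coupling_signs,
                   spec$n_signal_mirna * spec$targets_per_mirna)
    idx <- 0L
    for (i in seq_along(sig_ids)) {
      for (t in seq_len(spec$targets_per_mirna)) {
        idx <- idx + 1L
        g <- sprintf("TGT-%02d-%d", i, t)
        tgt_ids <- c(tgt_ids, g)
        x <- mirna[sig_ids[i], ]
        mrna_rows[[g]] <- sgn[idx] * spec$slope * x +
          stats::rnorm(n, 0, spec$noise_sd)
        couplings <- rbind(couplings,
                           data.frame(mirna = sig_ids[i], gene = g,
                                      sign = sgn[idx], slope = spec$slope))
      }
    }
    bg_ids <- if (spec$n_noise_mrna > 0L)
      sprintf("BG-%03d", seq_len(spec$n_noise_mrna)) else character()
    for (g in bg_ids) mrna_rows[[g]] <- stats::rnorm(n, 0, 1)
    mrna <- do.call(rbind, mrna_rows)
    mrna <- expression_matrix(mrna, names(mrna_rows), sample_ids)

    mapping <- list()
    for (i in seq_along(sig_ids)) {
      planted <- couplings$gene[couplings$mirna == sig_ids[i]]
      decoys <- if (spec$decoys_per_mirna > 0L && length(bg_ids) > 0L)
        sample(bg_ids, min(spec$decoys_per_mirna, length(bg_ids))) else character()
      mapping[[sig_ids[i]]] <- c(planted, decoys)
    }

    seeds <- stats::setNames(
      vapply(seq_along(sig_ids), function(i) random_rna(spec$seed_length), ""),
      sig_ids)
    sequences <- list()
    sites <- NULL
    for (i in seq_along(sig_ids)) {
      for (g in couplings$gene[couplings$mirna == sig_ids[i]]) {
        region <- if (couplings$sign[couplings$gene == g][1] > 0) "5UTR" else "3UTR"
        pl <- plant_site(spec$utr_length, seeds[[sig_ids[i]]],
                         spec$site_mismatches)
        sequences[[g]] <- seq_record(g, pl$sequence, region)
        sites <- rbind(sites, data.frame(gene = g, start = pl$start,
                                         end = pl$end,
                                         mismatches = spec$site_mismatches))
      }
    }

    list(mirna = expression_matrix(mirna, rownames(mirna), sample_ids),
         mrna = mrna,
         labels = labels,
         targets = if (length(mapping) > 0L) target_map(mapping) else NULL,
         sequences = unname(sequences),
         truth = list(signal_mirnas = sig_ids, couplings = couplings,
                      seeds = seeds, sites = sites))
  })
}
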