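test_that("transition counts follow the adjacent-pair definition", {
  tm <- build_transition_matrix("AAAA")
  expect_equal(tm$counts["A", "A"], 3L)
  expect_equal(tm$probs["A", "A"], 1.0)
  expect_equal(unname(tm$composition["A"]), 4L)

  tm2 <- build_transition_matrix("ACGU")
  expect_equal(tm2$counts["A", "C"], 1L)
  expect_equal(tm2$counts["C", "G"], 1L)
  expect_equal(tm2$counts["G", "U"], 1L)
  expect_equal(sum(tm2$counts), 3L)

  expect_error(build_transition_matrix("A"), "length >= 2")
  # DNA input is normalized
  expect_equal(build_transition_matrix("ACGT")$counts["G", "U"], 1L)
})

test_that("row sums equal composition minus the terminal-base correction", {
  set.seed(51)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "U"), 675, replace = TRUE),
               collapse = "")
    tm <- build_transition_matrix(s)
    last <- substr(s, 675, 675)
    want <- tm$composition
    want[last] <- want[last] - 1L
    expect_equal(rowSums(tm$counts)[names(want)], as.numeric(want),
                 ignore_attr = TRUE)
    expect_equal(sum(tm$counts), 674L)
    # determinism on a character-level copy
    expect_identical(tm, build_transition_matrix(paste(strsplit(s, "")[[1]],
                                                       collapse = "")))
  }
})

test_that("k-mer probabilities follow the chain closed form", {
  unif <- transition_matrix_from_counts(matrix(25L, 4, 4),
                                        c(A = 100, G = 100, U = 100, C = 100),
                                        length = 400)
  expect_equal(mm_probability("AAAAAAA", unif), 0.25^7)
  expect_equal(mm_probability("ACGUACG", unif), 0.25^7)

  # published GFRA2 5' UTR table: first-base share times six A->A steps
  tm <- gfra2_transition_matrix()
  expect_equal(mm_probability("AAAAAAA", tm), (151 / 675) * (33 / 151)^6)
  expect_equal(mm_probability("AAAAAAA", tm), 2.43722e-05, tolerance = 1e-5)
})

test_that("k-mer probabilities sum to one for random chains", {
  set.seed(52)
  for (rep in 1:3) {
    s <- paste(sample(c("A", "C", "G", "U"), 300, replace = TRUE),
               collapse = "")
    tm <- build_transition_matrix(s)
    for (k in c(1, 2, 3)) {
      kmers <- do.call(paste0, expand.grid(rep(list(c("A", "G", "U", "C")), k)))
      total <- sum(vapply(kmers, function(x) mm_probability(x, tm), 0))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
})

test_that("seed scanning finds reverse-complement sites within budget", {
  s <- seq_record("t1", "GGUUUUUUUGG", "5UTR")
  hits <- scan_seed("AAAAAAA", s, max_mismatch = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 9L)
  expect_equal(hits$mismatches, 0L)
  expect_identical(hits$site, "UUUUUUU")

  # planted single-mismatch site: absent at budget 0, present at 1
  s2 <- seq_record("t2", "GGUUUAUUUGGGGGGG")
  expect_equal(nrow(scan_seed("AAAAAAA", s2, max_mismatch = 0)), 0L)
  h1 <- scan_seed("AAAAAAA", s2, max_mismatch = 1)
  expect_gte(nrow(h1), 1L)
  expect_true(all(h1$mismatches <= 1))

  expect_error(scan_seed("AAXAAAA", s), "non-RNA")
  expect_error(scan_seed("AAAA", s), "length")
})

test_that("scan matches brute-force window enumeration", {
  set.seed(53)
  seed7 <- paste(sample(c("A", "C", "G", "U"), 7, replace = TRUE),
                 collapse = "")
  bg <- sample(c("A", "C", "G", "U"), 60, replace = TRUE)
  rc <- strsplit(reverse_complement_rna(seed7), "")[[1]]
  bg[20:26] <- rc
  sq <- seq_record("r1", paste(bg, collapse = ""))
  for (mm_budget in 0:2) {
    hits <- scan_seed(seed7, sq, max_mismatch = mm_budget)
    # brute force over all windows
    want <- integer()
    for (i in 1:(60 - 6)) {
      w <- bg[i:(i + 6)]
      if (sum(w != rc) <= mm_budget) want <- c(want, i)
    }
    expect_identical(hits$start, want)
    # coordinates recover the site sequence
    for (j in seq_len(nrow(hits)))
      expect_identical(hits$site[j],
                       substr(sq$sequence, hits$start[j], hits$end[j]))
  }
  # mismatch budget m results contain budget m-1 results
  h0 <- scan_seed(seed7, sq, max_mismatch = 0)
  h1 <- scan_seed(seed7, sq, max_mismatch = 1)
  expect_true(all(h0$start %in% h1$start))
})

test_that("window probability aggregates the per-site probability", {
  s <- seq_record("t1", "GGUUUUUUUGGACGUACGUAC")
  hits <- scan_seed("AAAAAAA", s)
  L <- nchar(s$sequence)
  expect_equal(hits$p_window, 1 - (1 - hits$p_exact)^(L - 7 + 1))
  expect_true(all(hits$p_exact > 0 & hits$p_exact <= 1))
})

test_that("wobble pairing widens matches only when enabled", {
  # seed GGGGGGG pairs CCCCCCC; with wobble, U also pairs each G
  s <- seq_record("x", "AACCCUCCCAA")
  strict <- scan_seed("GGGGGGG", s, max_mismatch = 0)
  expect_equal(nrow(strict), 0L)
  wob <- scan_seed("GGGGGGG", s, max_mismatch = 0, allow_wobble = TRUE)
  expect_equal(nrow(wob), 1L)
  expect_equal(wob$start, 3L)
})

test_that("the bundled count table exports in the printed shape", {
  tm <- gfra2_transition_matrix()
  expect_equal(tm$length, 675L)
  expect_equal(unname(tm$composition),
               c(151L, 182L, 161L, 181L))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_transition_matrix(tm, p)
  lines <- readLines(p)
  expect_length(lines, 6L)
  expect_match(lines[2], "^A\t33 \\(0\\.219\\)")
})
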