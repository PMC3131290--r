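# Degenerate 8-mer scanning, over-representation testing, and matching
# against the published forkhead consensus patterns.

test_that("pattern parsing accepts IUPAC and bracket notation", {
  expect_equal(parse_motif("A[A/T]GT")[[2]], c("A", "T"))
  expect_equal(parse_motif("AWGT"), parse_motif("A[A/T]GT"))
  expect_error(parse_motif("AATTTGT?"), "IUPAC")
  expect_error(parse_motif("A[AT"), "unclosed")
  expect_error(scan_motif("AATTTGT", "ACGT"), "length 8")
})

test_that("motif scanning counts stranded matches once per start", {
  expect_equal(unname(scan_motif("A[A/T]GTAAAT", "AAGTAAATCC")), 1L)
  expect_equal(unname(scan_motif("A[A/T]GTAAAT", "GGATTTACTT")), 1L) # revcomp
  expect_equal(unname(scan_motif("ACGTACGT", c("AAAAAAAAAA", "CCCCCCCCCC"))),
               c(0L, 0L))
  # palindromic pattern matching both strands at one start counts once
  expect_equal(unname(scan_motif("ACGTACGT", "TACGTACGTA")), 1L)
})

test_that("scanning agrees with a regex oracle on random cases", {
  withr::with_seed(55, {
    for (i in 1:500) {
      sets <- lapply(1:8, function(j) {
        k <- sample(1:2, 1, prob = c(0.7, 0.3))
        sort(sample(c("A", "C", "G", "T"), k))
      })
      pat <- paste(vapply(sets, function(s)
        if (length(s) == 1) s else paste0("[", s[1], "/", s[2], "]"),
        character(1)), collapse = "")
      sq <- paste(sample(c("A", "C", "G", "T"), sample(20:60, 1),
                         replace = TRUE), collapse = "")
      expect_identical(unname(scan_motif(pat, sq)), naive_scan(pat, sq))
    }
  })
})

test_that("hypergeometric presence p-values match the brute-force tail", {
  withr::with_seed(9, {
    for (i in 1:50) {
      N <- sample(10:50, 1)
      n <- sample(2:(N - 2), 1)
      K <- sample(0:N, 1)
      x <- sample(0:min(K, n), 1)
      expect_equal(nullchip:::presence_pvalue(x, K, n, N),
                   naive_hyper_tail(x, K, n, N), tolerance = 1e-12)
    }
  })
})

test_that("a planted degenerate motif is recovered at rank one", {
  cfg <- small_cfg(prevalence_target = 0.7, prevalence_background = 0.2,
                   seq_length = 1000, seed = 6)
  seqs <- gen_promoter_sequences(cfg, sprintf("T%03d", 1:200),
                                 sprintf("B%03d", 1:200))
  tab <- enumerate_and_test(seqs$targets, seqs$background)
  expect_gt(nrow(tab), 0)
  top_variants <- nullchip:::pattern_variants(parse_motif(tab$pattern[1]))
  planted <- nullchip:::pattern_variants(parse_motif(cfg$motif))
  expect_true(all(planted %in% top_variants))
  expect_lt(tab$p[1], 1e-6)
  expect_lte(tab$promoter_count[1], 200)
  expect_true(all(tab$p_min <= tab$p_max))
})

test_that("the scan is calibrated when targets and background are exchangeable", {
  fracs <- vapply(1:5, function(s) {
    cfg <- small_cfg(prevalence_target = 0, prevalence_background = 0,
                     seq_length = 300, seed = 100 + s)
    seqs <- gen_promoter_sequences(cfg, sprintf("T%02d", 1:40),
                                   sprintf("B%02d", 1:40))
    tab <- enumerate_and_test(seqs$targets, seqs$background)
    attr(tab, "n_words_significant") / attr(tab, "n_words_tested")
  }, numeric(1))
  expect_lte(mean(fracs), 0.07)
})

test_that("enumerate_and_test validates its inputs", {
  expect_error(enumerate_and_test(character(0), rep("ACGTACGTAA", 20)),
               "no target")
  expect_error(enumerate_and_test(rep("ACGTACGTAA", 5),
                                  rep("ACGTACGTAA", 5)), ">= 10")
})

test_that("consensus matching distinguishes complete, partial and none", {
  # 8-mer containing the 7-base consensus verbatim
  expect_equal(attr(match_known("AATTTGTA"), "overall"), "complete")
  m <- match_known("AATTTGTA")
  expect_equal(m$match[m$consensus == "AATTTGT"], "complete")

  # strand symmetry: the reverse complement of a consensus matches it
  expect_equal(attr(match_known("AYAAATA"), "overall"), "complete")

  # GC-rich random word matches nothing
  expect_equal(attr(match_known("GGCCGGCC"), "overall"), "none")
  gg <- match_known("GGCCGGCC")
  expect_true(all(gg$match == "none"))
})
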