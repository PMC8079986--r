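# window extraction, ZOOPS EM, pattern matching, spacer statistics,
# RBS discovery, anti-SD complementarity

test_that("extract_windows follows the strand-aware upstream convention", {
  seqn <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  # forward anchor at 100, window 10: bases [90, 100)
  w <- extract_windows(100L, "+", seqn, 10L)
  expect_equal(w$sequence, substring(seqn, 91, 100))
  expect_false(w$truncated)
  # reverse anchor at 100, window 10: reverse complement of [101, 111)
  w <- extract_windows(100L, "-", seqn, 10L)
  expect_equal(w$sequence, revcomp(substring(seqn, 102, 111)))
  # truncation at the chromosome edge
  w <- extract_windows(4L, "+", seqn, 10L)
  expect_true(w$truncated)
  expect_equal(nchar(w$sequence), 4L)
})

test_that("extracted windows relocate to the expected genomic offset", {
  set.seed(41)
  for (i in 1:10) {
    seqn <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                  collapse = "")
    p <- sample(60:400, 1)
    s <- sample(c("+", "-"), 1)
    w <- extract_windows(p, s, seqn, 25L)
    located <- if (s == "+") substring(seqn, p - 25 + 1, p)
               else revcomp(substring(seqn, p + 2, p + 26))
    expect_identical(w$sequence, located)
  }
})

test_that("EM recovers a planted -10 element with correct placements", {
  w <- simulate_motif_windows(200, "TATAAT", window = 70,
                              spacer_range = c(7, 7), mutation_rate = 0.05,
                              gc = 0.72, seed = 42)
  m <- em_find_motif(w$sequences, 6L, c(4L, 9L),
                     motif_search_config(em_restarts = 8L, seed = 1L))
  expect_equal(m$consensus, "TATAAT")
  expect_gte(mean(!is.na(m$placements) & m$placements == w$offsets), 0.95)
  # log-likelihood trace is non-decreasing at every step
  expect_true(all(diff(m$ll_trace) >= -1e-8 * (abs(m$ll_trace[-1]) + 1)))
})

test_that("EM on identical sequences degenerates to unit columns", {
  seqs <- rep("GGCCGGCCTATAATCCGGCCG", 20)
  m <- em_find_motif(seqs, 6L, c(4L, 9L),
                     motif_search_config(em_restarts = 2L, seed = 3L))
  expect_true(all(apply(m$pfm, 2, max) > 0.99))
  expect_false(grepl("n", m$consensus))
})

test_that("EM is deterministic given config seed and input", {
  w <- simulate_motif_windows(60, "TATAAT", seed = 9)
  cfg <- motif_search_config(em_restarts = 4L, seed = 11L)
  a <- em_find_motif(w$sequences, 6L, c(4L, 9L), cfg)
  b <- em_find_motif(w$sequences, 6L, c(4L, 9L), cfg)
  expect_identical(a, b)
})

test_that("EM validates its preconditions", {
  expect_error(em_find_motif(rep("ACGTACGTACGTACGT", 5), 6L, c(4L, 9L)),
               "at least 10")
  seqs <- c(rep(strrep("ACGT", 10), 11), "ACGT")
  expect_error(em_find_motif(seqs, 6L, c(4L, 9L)), "shorter than")
})

test_that("match_pattern_fraction implements consensus-with-spacer matching", {
  # TACGGT at spacer 6 matches TAnnnT
  s1 <- paste0(strrep("G", 58), "TACGGT", strrep("C", 6))
  expect_equal(match_pattern_fraction(s1, "TAnnnT", c(4, 9))$fraction, 1)
  s2 <- paste0(strrep("G", 58), "AACGGT", strrep("C", 6))
  expect_equal(match_pattern_fraction(s2, "TAnnnT", c(4, 9))$fraction, 0)
  expect_error(match_pattern_fraction(s1, "", c(4, 9)), "empty")
  # all-n pattern matches whenever the spacer range is feasible
  set.seed(43)
  seqs <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = ""),
    character(1))
  expect_equal(match_pattern_fraction(seqs, "nnnnnn", c(4, 9))$fraction, 1)
})

test_that("match_pattern_fraction agrees with a regex oracle on random input", {
  set.seed(44)
  seqs <- vapply(1:500, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE,
                 prob = c(0.2, 0.3, 0.3, 0.2)), collapse = ""),
    character(1))
  res <- match_pattern_fraction(seqs, "TAnnnT", c(4, 9))
  oracle <- vapply(seqs, function(s) {
    any(vapply(4:9, function(d) {
      o <- nchar(s) - d - 6
      o >= 0 && grepl("^TA...T$", substring(s, o + 1, o + 6))
    }, logical(1)))
  }, logical(1))
  expect_equal(res$hits, unname(oracle))
})

test_that("spacer_stats summarises placements", {
  model <- structure(list(spacers = c(5, 7)), class = "MotifModel")
  s <- spacer_stats(model)
  expect_equal(s$mean, 6)
  s1 <- spacer_stats(structure(list(spacers = 9), class = "MotifModel"))
  expect_equal(s1$mean, 9)
  expect_equal(s1$range, c(9, 9))
  s0 <- spacer_stats(structure(list(spacers = NA_real_),
                               class = "MotifModel"))
  expect_true(s0$no_placements)
  # 1,000 synthetic placements against the direct average
  set.seed(45)
  sp <- sample(4:9, 1000, replace = TRUE)
  s2 <- spacer_stats(structure(list(spacers = sp), class = "MotifModel"))
  expect_equal(s2$mean, mean(sp))
})

test_that("find_rbs recovers a planted Shine-Dalgarno motif genome-wide", {
  sim <- simulate_genome(sim_config(seed = 8, background_rate = 0,
                                    leaderless_fraction = 0,
                                    attenuator_peptides = character(0),
                                    n_genes = 60L, suboperon_prob = 0))
  ct <- classify_tss(detect_tss(sim$profile), sim$annotation)
  r <- find_rbs(sim$annotation, ct,
                motif_search_config(em_restarts = 8L, seed = 2L))
  expect_false(r$insufficient_data)
  expect_equal(r$model$consensus, "AGGAGG")
  # only genes whose drawn UTR admits a full-range element carry one
  expect_gte(r$placement_fraction, 0.8)
  expect_true(abs(r$spacer$mean - 6.5) < 1)
})

test_that("RBS spacer mean is recovered within 0.2 nt on planted windows", {
  w <- simulate_motif_windows(400, "AGGAGG", window = 20,
                              spacer_range = c(5, 8), mutation_rate = 0.05,
                              gc = 0.72, seed = 3)
  m <- em_find_motif(w$sequences, 6L, c(4L, 9L),
                     motif_search_config(em_restarts = 8L, seed = 5L))
  expect_equal(m$consensus, "AGGAGG")
  expect_lt(abs(spacer_stats(m)$mean - mean(w$spacers)), 0.2)
  expect_gte(mean(!is.na(m$placements) & m$placements == w$offsets), 0.9)
})

test_that("find_rbs reports insufficient data when no CDS qualifies", {
  ann <- make_toy_annotation()
  tss <- classify_tss(data.frame(position = 100L, strand = "+",
                                 read_start_count = 20,
                                 percent_increase = 2000), ann)
  r <- find_rbs(ann, tss)   # the single TSS is leaderless (utr 0)
  expect_true(r$insufficient_data)
})

test_that("longest_complement finds the anti-SD match", {
  # RBS core against the written-5'-to-3' 16S rRNA tail
  expect_equal(longest_complement("GGAGG", "ACCUCCUUU"), 5L)
  expect_equal(longest_complement("", "ACGT"), 0L)
  expect_equal(longest_complement("ACGT", ""), 0L)
  for (s in c("ACGTACGT", "GGGGCCCC", "ATATATAT")) {
    expect_equal(longest_complement(s, revcomp(s)), nchar(s))
  }
  # brute-force oracle over all substring pairs
  set.seed(46)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
               collapse = "")
    best <- 0L
    for (la in 1:12) for (sa in 1:(12 - la + 1)) {
      sub <- substring(a, sa, sa + la - 1)
      if (grepl(revcomp(sub), b, fixed = TRUE)) best <- max(best, la)
    }
    expect_equal(longest_complement(a, b), best)
  }
})

test_that("promoter motif discovery splits leaderless and leadered TSS", {
  sim <- simulate_genome(sim_config(seed = 14, background_rate = 0,
                                    leaderless_fraction = 0.5))
  ct <- classify_tss(detect_tss(sim$profile), sim$annotation)
  res <- find_promoter_motifs(sim$annotation, ct,
                              motif_search_config(em_restarts = 8L, seed = 4L))
  for (group in c("leaderless", "leadered")) {
    g <- res[[group]]
    expect_equal(g$minus10$consensus, "TATAAT")
    # exact TAnnnT match keeps ~0.9^3 of windows under 10% mutation;
    # the leaderless group is small, so allow wide sampling slack
    expect_gte(g$tannnt, 0.5)
    expect_false(g$minus10_spacer$no_placements)
    expect_true(g$minus10_spacer$mean >= 4 && g$minus10_spacer$mean <= 9)
  }
  # the -35 element is anchored on the -10 placement
  m35 <- res$leadered$minus35
  if (inherits(m35, "MotifModel")) {
    sp35 <- spacer_stats(m35)
    expect_true(sp35$mean >= 15 && sp35$mean <= 19)
  }
})
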