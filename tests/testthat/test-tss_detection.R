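# TSS calling thresholds, stack collapsing, classification, UTR statistics

test_that("detect_tss enforces the read-start floor and percent increase", {
  len <- 200L
  # 9 starts over zero background: fails the count floor
  p <- make_stack_profile(len, fwd_stacks = 50L, heights = 9L)
  expect_equal(nrow(detect_tss(p)), 0L)
  # 10 starts over zero background: increase 1000% exactly, called
  p <- make_stack_profile(len, fwd_stacks = 50L, heights = 10L)
  out <- detect_tss(p)
  expect_equal(out$position, 50L)
  expect_equal(out$read_start_count, 10)
  # 50 starts over upstream neighbour 4: increase 1150% >= 1000%
  fwd <- numeric(len); fwd[50] <- 4; fwd[51] <- 50
  out <- detect_tss(strand_profile(fwd, numeric(len)))
  expect_equal(out$position, 50L)
  expect_equal(out$percent_increase, 1150)
  # 40 over 4 would be 900%: rejected in standard, kept in low-coverage
  fwd[51] <- 40
  p <- strand_profile(fwd, numeric(len))
  expect_equal(nrow(detect_tss(p, mode = "standard")), 0L)
  expect_equal(detect_tss(p, mode = "low_coverage")$position, 50L)
})

test_that("detect_tss treats chromosome edges as zero-count neighbours", {
  p <- make_stack_profile(100L, fwd_stacks = 0L, heights = 12L)
  expect_equal(detect_tss(p)$position, 0L)
  p <- make_stack_profile(100L, rev_stacks = 99L, heights = 12L)
  out <- detect_tss(p)
  expect_equal(out$position, 99L)
  expect_equal(out$strand, "-")
})

test_that("detect_tss on an all-zero profile returns an empty table", {
  p <- strand_profile(numeric(300), numeric(300))
  out <- detect_tss(p)
  expect_equal(nrow(out), 0L)
})

test_that("planted stacks are recovered exactly and match the brute-force oracle", {
  cfg <- detection_config()
  p <- make_stack_profile(1000L, fwd_stacks = c(100L, 400L),
                          rev_stacks = 700L, heights = c(15L, 50L))
  out <- detect_tss(p, cfg)
  expect_equal(out$position, c(100L, 400L, 700L))
  oracle <- oracle_detect(p, cfg$min_read_starts, cfg$percent_increase)
  expect_equal(out[c("position", "strand")],
               oracle, ignore_attr = TRUE)
})

test_that("adjacent stacks within +/-2 nt collapse to the strongest position", {
  len <- 300L
  fwd <- numeric(len)
  fwd[101] <- 30; fwd[103] <- 45          # 2 nt apart: keep the stronger
  p <- strand_profile(fwd, numeric(len))
  expect_equal(detect_tss(p)$position, 102L)
  # tie resolves to the most upstream (smaller coordinate on +)
  fwd[103] <- 30
  p <- strand_profile(fwd, numeric(len))
  expect_equal(detect_tss(p)$position, 100L)
  # on the reverse strand upstream means the larger coordinate
  rev <- numeric(len)
  rev[201] <- 30; rev[203] <- 30
  p <- strand_profile(numeric(len), rev)
  expect_equal(detect_tss(p)$position, 202L)
  # without collapsing both sides survive (oracle mode)
  expect_equal(nrow(detect_tss(p, collapse = FALSE)), 2L)
})

test_that("classification follows the genomic-context precedence rules", {
  ann <- make_toy_annotation()
  cfg <- detection_config()
  # 60 nt upstream of f1 (start 100): primary, utr 60, leadered
  tss <- data.frame(position = 40L, strand = "+", read_start_count = 20,
                    percent_increase = 2000)
  ct <- classify_tss(tss, ann, cfg)
  expect_equal(ct$tss_class, "primary")
  expect_equal(ct$assigned_feature_id, "f1")
  expect_equal(ct$utr_length, 60L)
  expect_false(ct$leaderless)
  # at the TLS exactly: utr 0, leaderless
  ct <- classify_tss(transform(tss, position = 100L), ann, cfg)
  expect_equal(ct$utr_length, 0L)
  expect_true(ct$leaderless)
  # utr 3 leaderless, utr 4 leadered
  expect_true(classify_tss(transform(tss, position = 97L), ann, cfg)$leaderless)
  expect_false(classify_tss(transform(tss, position = 96L), ann, cfg)$leaderless)
  # reverse strand: TLS of r1 is end-1 = 1199; 30 nt upstream = 1229
  ct <- classify_tss(data.frame(position = 1229L, strand = "-",
                                read_start_count = 15,
                                percent_increase = 1500), ann, cfg)
  expect_equal(ct$tss_class, "primary")
  expect_equal(ct$assigned_feature_id, "r1")
  expect_equal(ct$utr_length, 30L)
})

test_that("the 500 nt TSS-to-TLS window is a hard boundary", {
  # gene far from any other feature on a long genome
  seqn <- paste(rep("ACGT", 1000), collapse = "")
  ann <- genome_annotation("c", seqn, data.frame(
    feature_id = "g", kind = "CDS", start = 3000L, end = 3600L,
    strand = "+", product = ""))
  tss_at <- function(p) data.frame(position = p, strand = "+",
                                   read_start_count = 12,
                                   percent_increase = 1200)
  expect_equal(classify_tss(tss_at(2500L), ann)$tss_class, "primary")  # 500
  expect_equal(classify_tss(tss_at(2499L), ann)$tss_class, "intergenic") # 501
})

test_that("antisense and intragenic contexts are recognised", {
  ann <- make_toy_annotation()
  # forward TSS inside reverse CDS r1 [900,1200): antisense
  ct <- classify_tss(data.frame(position = 1000L, strand = "+",
                                read_start_count = 12,
                                percent_increase = 1200), ann)
  expect_equal(ct$tss_class, "antisense")
  # reverse TSS inside f1 body, no downstream reverse TLS within 500:
  # r1 TLS (1199) is 199 nt downstream of position 1000 on '-'... use 150
  ct <- classify_tss(data.frame(position = 150L, strand = "+",
                                read_start_count = 12,
                                percent_increase = 1200), ann)
  # position 150 is inside f1 on the same strand but 350 nt from f2's TLS
  # (500): rule 1 wins, assigned to f2
  expect_equal(ct$tss_class, "primary")
  expect_equal(ct$assigned_feature_id, "f2")
  # an antisense call via the UTR of an opposite-strand primary TSS
  tss2 <- data.frame(position = c(40L, 60L), strand = c("+", "-"),
                     read_start_count = c(20, 12),
                     percent_increase = c(2000, 1200))
  ct2 <- classify_tss(tss2, ann)
  expect_equal(ct2$tss_class[ct2$strand == "-"], "antisense")
})

test_that("one primary per gene; ties break towards the TLS", {
  ann <- make_toy_annotation()
  tss <- data.frame(position = c(40L, 70L, 90L), strand = "+",
                    read_start_count = c(30, 50, 30),
                    percent_increase = 2000)
  ct <- classify_tss(tss, ann)
  expect_equal(ct$tss_class, c("secondary", "primary", "secondary"))
  # tie on count: the TSS closest to the TLS wins
  tss$read_start_count <- c(30, 30, 30)
  ct <- classify_tss(tss, ann)
  expect_equal(ct$tss_class, c("secondary", "secondary", "primary"))
  # exactly one primary per assigned feature, for random TSS sets
  set.seed(31)
  for (i in 1:10) {
    tssr <- data.frame(position = sample(0:1499, 30),
                       strand = sample(c("+", "-"), 30, replace = TRUE),
                       read_start_count = sample(10:99, 30, replace = TRUE),
                       percent_increase = 2000)
    ctr <- classify_tss(tssr, ann)
    per_feat <- table(ctr$assigned_feature_id[ctr$tss_class == "primary"])
    assigned_feats <- unique(stats::na.omit(
      ctr$assigned_feature_id[ctr$tss_class %in% c("primary", "secondary")]))
    expect_true(all(per_feat == 1L))
    expect_setequal(names(per_feat), assigned_feats)
  }
})

test_that("classification is permutation-invariant", {
  ann <- make_toy_annotation()
  set.seed(32)
  tss <- data.frame(position = sample(0:1499, 40),
                    strand = sample(c("+", "-"), 40, replace = TRUE),
                    read_start_count = sample(10:99, 40, replace = TRUE),
                    percent_increase = 2000)
  a <- classify_tss(tss, ann)
  perm <- sample(nrow(tss))
  b <- classify_tss(tss[perm, ], ann)
  b <- b[order(match(b$position, a$position)), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("classify_tss rejects positions outside the genome", {
  ann <- make_toy_annotation()
  expect_error(classify_tss(data.frame(position = 5000L, strand = "+",
                                       read_start_count = 12,
                                       percent_increase = 1200), ann),
               "outside genome")
})

test_that("utr_histogram bins as specified", {
  tss <- data.frame(tss_class = "primary",
                    utr_length = c(0L, 2L, 7L, 12L))
  h <- utr_histogram(tss)
  expect_equal(h$leaderless, 2L)
  expect_equal(unname(h$bins["6-10"]), 1L)
  expect_equal(unname(h$bins["11-15"]), 1L)
  expect_equal(h$total, 4L)
  # empty input
  h0 <- utr_histogram(data.frame(tss_class = character(0),
                                 utr_length = integer(0)))
  expect_equal(h0$leaderless, 0L)
  expect_true(all(h0$bins == 0L))
  # 1,000 synthetic lengths against an independent tally
  set.seed(33)
  u <- sample(0:600, 1000, replace = TRUE)
  tss <- data.frame(tss_class = "primary", utr_length = u)
  h <- utr_histogram(tss)
  expect_equal(h$leaderless, sum(u <= 3))
  expect_equal(h$overflow, sum(u > 500))
  for (k in c(1, 7, 42, 100)) {
    lo <- (k - 1) * 5 + 1; hi <- k * 5
    expect_equal(unname(h$bins[sprintf("%d-%d", lo, hi)]),
                 sum(u > 3 & u >= lo & u <= hi))
  }
  expect_equal(h$leaderless + sum(h$bins) + h$overflow, h$total)
  expect_error(utr_histogram(data.frame(tss_class = "primary",
                                        utr_length = -1L)), "negative")
})

test_that("tss_summary partitions the classified list", {
  tss <- data.frame(tss_class = c(rep("primary", 3), "antisense"))
  s <- tss_summary(tss)
  expect_equal(s$primary, 3L)
  expect_equal(s$antisense, 1L)
  expect_equal(s$secondary + s$intragenic + s$intergenic, 0L)
  expect_equal(s$total, 4L)
  s0 <- tss_summary(data.frame(tss_class = character(0)))
  expect_equal(s0$total, 0L)
})
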