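# bridging reads, operon chaining, sub-operons, summaries

two_genes <- function(gap = 30L, strand = "+") {
  list(a = list(start = 100L, end = 400L, strand = strand),
       b = list(start = 400L + gap, end = 700L + gap, strand = strand))
}

reads_spanning <- function(n, junction_left, junction_right, strand = "+",
                           len = 75L) {
  starts <- seq(junction_right - len + 1L, junction_left,
                length.out = n)
  data.frame(start = as.integer(round(starts)),
             end = as.integer(round(starts)) + len, strand = strand)
}

test_that("count_bridging_reads counts reads spanning the whole gap", {
  g <- two_genes(gap = 30L)
  reads <- reads_spanning(7, g$a$end - 1L, g$b$start)
  expect_equal(count_bridging_reads(g$a, g$b, reads), 7L)
  # reads ending inside the gap never bridge
  inside <- data.frame(start = c(380L, 405L), end = c(420L, 425L),
                       strand = "+")
  expect_equal(count_bridging_reads(g$a, g$b, inside), 0L)
  # opposite-strand reads do not count
  wrong <- transform(reads, strand = "-")
  expect_equal(count_bridging_reads(g$a, g$b, wrong), 0L)
})

test_that("overlapping genes count every read covering the junction base", {
  a <- list(start = 100L, end = 400L, strand = "+")
  b <- list(start = 390L, end = 700L, strand = "+")   # 10 nt overlap
  reads <- data.frame(start = c(380L, 389L, 391L), end = c(395L, 401L, 430L),
                      strand = "+")
  # junction base is b$start = 390; reads 1 and 2 cover it, read 3 does not
  expect_equal(count_bridging_reads(a, b, reads), 2L)
})

test_that("count_bridging_reads agrees with an interval-overlap oracle", {
  set.seed(51)
  for (trial in 1:100) {
    gap <- sample(0:40, 1)
    g <- two_genes(gap = gap)
    reads <- data.frame(start = sample(250:550, 60, replace = TRUE),
                        strand = sample(c("+", "-"), 60, replace = TRUE))
    reads$end <- reads$start + sample(30:90, 60, replace = TRUE)
    got <- count_bridging_reads(g$a, g$b, reads)
    left <- g$a$end - 1L; right <- g$b$start
    oracle <- sum(vapply(seq_len(nrow(reads)), function(i) {
      r <- reads[i, ]
      covers <- function(p) r$start <= p && p < r$end
      r$strand == "+" && covers(left) && covers(right)
    }, logical(1)))
    expect_equal(got, oracle)
  }
})

test_that("operon linking flips exactly at the five-read threshold", {
  ann <- genome_annotation("c", strrep("ACGT", 1000), data.frame(
    feature_id = c("A", "B", "C"), kind = "CDS",
    start = c(0L, 500L, 1000L), end = c(450L, 950L, 1450L),
    strand = "+", product = ""))
  bridging <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                         count = c(7L, 5L))
  om <- infer_operons(ann, bridging)
  expect_equal(length(om$operons), 1L)
  expect_equal(om$operons[[1]]$gene_ids, c("A", "B", "C"))
  expect_equal(om$monocistronic, character(0))

  bridging$count <- c(7L, 4L)
  om <- infer_operons(ann, bridging)
  expect_equal(om$operons[[1]]$gene_ids, c("A", "B"))
  expect_equal(om$monocistronic, "C")

  bridging$count <- c(0L, 0L)
  om <- infer_operons(ann, bridging)
  expect_equal(length(om$operons), 0L)
  expect_setequal(om$monocistronic, c("A", "B", "C"))
})

test_that("an internal TSS spawns a suffix sub-operon and validates operons", {
  ann <- genome_annotation("c", strrep("ACGT", 1000), data.frame(
    feature_id = c("A", "B", "C"), kind = "CDS",
    start = c(0L, 500L, 1000L), end = c(450L, 950L, 1450L),
    strand = "+", product = ""))
  bridging <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                         count = c(9L, 9L))
  tss <- data.frame(position = c(0L, 495L), strand = "+",
                    read_start_count = c(40, 20), percent_increase = 2000,
                    tss_class = c("primary", "primary"),
                    assigned_feature_id = c("A", "B"),
                    utr_length = c(0L, 5L), leaderless = c(TRUE, FALSE))
  om <- infer_operons(ann, bridging, tss)
  expect_true(om$operons[[1]]$validated)
  expect_equal(length(om$operons[[1]]$sub_operons), 1L)
  expect_equal(om$operons[[1]]$sub_operons[[1]]$gene_ids, c("B", "C"))
  expect_equal(om$operons[[1]]$sub_operons[[1]]$start_gene_index, 2L)
  # without a TSS at gene A the operon is predicted, not validated
  om2 <- infer_operons(ann, bridging, tss[2, ])
  expect_false(om2$operons[[1]]$validated)
})

test_that("reverse-strand operons report genes in transcription order", {
  ann <- genome_annotation("c", strrep("ACGT", 1000), data.frame(
    feature_id = c("A", "B"), kind = "CDS",
    start = c(0L, 500L), end = c(450L, 950L),
    strand = "-", product = ""))
  bridging <- data.frame(gene_a = "A", gene_b = "B", count = 8L)
  om <- infer_operons(ann, bridging)
  expect_equal(om$operons[[1]]$gene_ids, c("B", "A"))
})

test_that("an interleaved opposite-strand gene breaks the chain", {
  ann <- genome_annotation("c", strrep("ACGT", 1000), data.frame(
    feature_id = c("A", "X", "B"), kind = "CDS",
    start = c(0L, 500L, 1000L), end = c(450L, 950L, 1450L),
    strand = c("+", "-", "+"), product = ""))
  bridging <- data.frame(gene_a = "A", gene_b = "B", count = 50L)
  om <- infer_operons(ann, bridging)
  expect_equal(length(om$operons), 0L)
  expect_setequal(om$monocistronic, c("A", "X", "B"))
})

test_that("operon membership partitions the gene set; threshold is monotone", {
  sim <- simulate_genome(sim_config(seed = 16, background_rate = 0,
                                    suboperon_prob = 1))
  ct <- classify_tss(detect_tss(sim$profile), sim$annotation)
  bridging <- bridging_counts(sim$annotation, sim$reads)
  om <- infer_operons(sim$annotation, bridging, ct)
  in_ops <- unlist(lapply(om$operons, `[[`, "gene_ids"))
  all_genes <- sim$annotation$features$feature_id
  expect_equal(sort(c(in_ops, om$monocistronic)), sort(all_genes))
  expect_equal(anyDuplicated(c(in_ops, om$monocistronic)), 0L)
  # raising the threshold only unlinks junctions
  linked_at <- function(minreads) {
    cfg <- detection_config(bridging_reads_min = minreads)
    o <- infer_operons(sim$annotation, bridging, ct, cfg)
    unlist(lapply(o$operons, function(x)
      paste(utils::head(x$gene_ids, -1), x$gene_ids[-1])))
  }
  l5 <- linked_at(5L); l8 <- linked_at(8L); l12 <- linked_at(12L)
  expect_true(all(l8 %in% l5))
  expect_true(all(l12 %in% l8))
})

test_that("operon_summary counts are consistent", {
  ann <- genome_annotation("c", strrep("ACGT", 1000), data.frame(
    feature_id = c("A", "B", "C", "D", "E"), kind = "CDS",
    start = c(0L, 300L, 600L, 900L, 1200L),
    end = c(252L, 552L, 852L, 1152L, 1452L),
    strand = "+", product = ""))
  bridging <- data.frame(gene_a = c("A", "B", "C", "D"),
                         gene_b = c("B", "C", "D", "E"),
                         count = c(9L, 9L, 0L, 0L))
  om <- infer_operons(ann, bridging)
  s <- operon_summary(om)
  expect_equal(s$operons, 1L)
  expect_equal(s$genes_in_operons, 3L)
  expect_equal(s$monocistronic, 2L)
  expect_equal(s$largest, 3L)
  s0 <- operon_summary(list(operons = list(), monocistronic = character(0)))
  expect_equal(s0$operons, 0L)
  expect_equal(s0$largest, 0L)
})
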