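# Synthetic genomes with planted ground truth. The generator emulates a
# high-GC (~72%) bacterial chromosome: promoters with a TAnnnT -10 box and
# a -35 element at realistic spacers, Shine-Dalgarno motifs, a configurable
# leaderless fraction, operons with bridging reads across junctions,
# attenuator leaders (small ORFs + terminator hairpins), overdispersed
# 5'-read stacks at each TSS and Poisson background noise.

#' Default attenuator leader peptides planted by the simulator
#'
#' The classic attenuator leader peptides of high-GC actinomycetes
#' (leucine-, tryptophan-, alanine-, isoleucine/valine-, methionine- and
#' threonine-responsive small ORFs upstream of amino-acid biosynthesis and
#' tRNA-ligase genes).
#' @format named character vector of eight peptides.
#' @export
LEADER_PEPTIDES_DEFAULT <- c(
  alaL  = "MNVIGRNIFATARATSSPVAAA",
  ilvL  = "MRTRILVLGKRVG",
  thrL  = "MKRVRPFLETTPGFVPAR",
  trpL2 = "MMTRTCTQLWRAA",
  leuL2 = "MRAVRLLLSEPR",
  leuL1 = "MRFGLLLLSCRGEGL",
  trpL1 = "MFAHSTRNWWWTAHPAAH",
  metL  = "MSTTSDRTPATEATTTPGARCMCRRMCAF")

#' Simulation configuration
#'
#' Defaults state the world the pipeline is built for: a 100 kb high-GC
#' chromosome with ~80 genes, ten operons, a 17% leaderless fraction,
#' TATAAT/TTGACA promoter elements, an AGGAGG RBS, negative-binomial
#' 5'-read stacks (mean 50) and 0.02 background starts per base.
#'
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @param genome_length chromosome length (nt).
#' @param gc_content target GC fraction.
#' @param n_genes total CDS count (operon genes + attenuator targets +
#'   monocistronic remainder).
#' @param operon_spec integer vector of operon sizes (each >= 2).
#' @param suboperon_prob probability that an operon gets one internal TSS
#'   (a sub-operon).
#' @param leaderless_fraction Bernoulli probability that a transcription
#'   unit's primary TSS is leaderless (UTR 0).
#' @param utr_range,utr_mu,utr_size leadered UTR lengths are
#'   `utr_range[1] + NB(mu, size)` truncated to `utr_range` — a
#'   geometric-like law whose modal bin falls in the 26-40 nt range.
#' @param minus10_consensus,minus10_mutation -10 element and per-position
#'   mutation rate.
#' @param minus10_spacer_probs named probabilities of -10-to-TSS spacers
#'   (distances 4..9; mean ~6.3).
#' @param minus35_consensus,minus35_spacer_range -35 element and its
#'   distance range to the -10 box.
#' @param rbs_consensus,rbs_spacer_range RBS element and RBS-to-TLS
#'   distance range.
#' @param tss_signal_mean mean 5'-read-stack height at a planted TSS; the
#'   stack is `min_read_starts + NB` so every planted TSS carries at least
#'   a detectable signal (lower-truncated negative binomial).
#' @param tss_nb_size NB size parameter (overdispersion) of stack heights.
#' @param background_rate Poisson background 5'-read starts per base per
#'   strand (0 gives the noiseless closed-loop regime).
#' @param bridge_base,bridge_extra_mean reads bridging each operon
#'   junction: `bridge_base + Poisson(bridge_extra_mean)`.
#' @param read_length whole-transcriptome read length (nt).
#' @param gene_codon_range CDS lengths in codons (uniform draw).
#' @param junction_gap intergenic gap inside operons (nt).
#' @param expression_range per-unit coverage depth range (uniform draw).
#' @param attenuator_peptides named character vector of leader peptides to
#'   plant (default: the eight classic ones); set to `character(0)` for
#'   none.
#' @param min_read_starts detection floor mirrored by the stack truncation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       gc_content = 0.72,
                       n_genes = 80L,
                       operon_spec = c(3L, 2L, 4L, 2L, 3L, 2L, 2L, 3L, 2L, 4L),
                       suboperon_prob = 0.5,
                       leaderless_fraction = 0.17,
                       utr_range = c(4L, 300L), utr_mu = 50, utr_size = 3,
                       minus10_consensus = "TATAAT",
                       minus10_mutation = 0.1,
                       minus10_spacer_probs = c(`4` = 0.06, `5` = 0.22,
                                                `6` = 0.30, `7` = 0.24,
                                                `8` = 0.11, `9` = 0.07),
                       minus35_consensus = "TTGACA",
                       minus35_spacer_range = c(15L, 19L),
                       rbs_consensus = "AGGAGG",
                       rbs_spacer_range = c(5L, 8L),
                       tss_signal_mean = 50,
                       tss_nb_size = 2,
                       background_rate = 0.02,
                       bridge_base = 5L, bridge_extra_mean = 5,
                       read_length = 75L,
                       gene_codon_range = c(100L, 250L),
                       junction_gap = 30L,
                       expression_range = c(5L, 200L),
                       attenuator_peptides = LEADER_PEPTIDES_DEFAULT,
                       min_read_starts = 10L) {
  cfg <- as.list(environment())
  stopifnot(cfg$gc_content > 0, cfg$gc_content < 1,
            cfg$leaderless_fraction >= 0, cfg$leaderless_fraction <= 1,
            all(cfg$operon_spec >= 2L),
            cfg$n_genes >= sum(cfg$operon_spec) + length(cfg$attenuator_peptides),
            abs(sum(cfg$minus10_spacer_probs) - 1) < 1e-6,
            cfg$tss_signal_mean > cfg$min_read_starts,
            cfg$background_rate >= 0)
  structure(cfg, class = "sim_config")
}

# sample() treats a length-1 vector as 1:n; draw_int() is the safe
# single-value draw used for every configurable range.
draw_int <- function(x) x[sample.int(length(x), 1L)]

# Random DNA at a target GC content.
random_dna_vec <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# One random sense codon (no stop), GC-biased.
random_codons <- function(n, gc) {
  out <- character(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- vapply(need, function(i)
      paste(random_dna_vec(3L, gc), collapse = ""), character(1))
    ok <- !(cand %in% STOP_CODONS)
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

# Synonymous re-encoding of a peptide (uniform over each residue's codons).
CODONS_BY_AA <- split(names(Biostrings::GENETIC_CODE),
                      unname(Biostrings::GENETIC_CODE))

#' Re-encode a peptide with random synonymous codons
#' @param peptide amino-acid string.
#' @param stop append a random stop codon.
#' @return DNA string coding for the peptide.
#' @export
reencode_peptide <- function(peptide, stop = TRUE) {
  aa <- strsplit(toupper(peptide), "")[[1L]]
  codons <- vapply(aa, function(a) {
    pool <- CODONS_BY_AA[[a]]
    if (is.null(pool)) stop("no codon for residue ", a)
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  paste(c(codons, if (stop) sample(STOP_CODONS, 1L)), collapse = "")
}

# Mutate a consensus at a per-position rate (random different base).
mutate_motif <- function(consensus, rate) {
  ch <- strsplit(consensus, "")[[1L]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  paste(ch, collapse = "")
}

draw_utr <- function(cfg) {
  u <- cfg$utr_range[1L] + stats::rnbinom(1L, size = cfg$utr_size,
                                          mu = cfg$utr_mu)
  min(u, cfg$utr_range[2L])
}

#' Generate a synthetic genome with planted ground truth
#'
#' Lays transcription units (operons, attenuator-regulated genes,
#' monocistronic genes) along a random high-GC chromosome, plants promoter
#' and RBS elements, 5'-read stacks, gene-body coverage and
#' junction-bridging reads, and records everything planted as ground
#' truth.
#'
#' @param config a [sim_config()].
#' @return list `annotation` (`GenomeAnnotation`), `profile`
#'   (`StrandProfile`), `reads` (whole-transcriptome read intervals),
#'   `truth` (planted TSS / operons / attenuators / expression),
#'   `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  L <- cfg$genome_length
  genome <- random_dna_vec(L, cfg$gc_content)
  n_att <- length(cfg$attenuator_peptides)
  n_oper_genes <- sum(cfg$operon_spec)
  n_mono <- cfg$n_genes - n_oper_genes - n_att

  # unit plan: one row per transcription unit, shuffled along the genome
  units <- c(lapply(seq_along(cfg$operon_spec),
                    function(i) list(type = "operon", size = cfg$operon_spec[i])),
             lapply(seq_len(n_att), function(i)
               list(type = "attenuator",
                    peptide = unname(cfg$attenuator_peptides[i]),
                    name = names(cfg$attenuator_peptides)[i])),
             lapply(seq_len(n_mono), function(i) list(type = "mono")))
  units <- units[sample.int(length(units))]

  features <- list(); truth_tss <- list(); operons <- list()
  sub_operons <- list(); mono_ids <- character(0)
  attenuators <- list(); expression <- list()
  reads <- list()
  rs_fwd <- numeric(L); rs_rev <- numeric(L)
  cov_fwd <- numeric(L); cov_rev <- numeric(L)
  gene_no <- 0L
  cursor <- 100L
  inter_block <- 60L
  promoter_pad <- 50L

  plant <- function(pos0, motif_seq, strand) {
    # write motif (given 5'->3' on `strand`) at genomic 0-based start pos0
    ch <- strsplit(if (strand == "-") revcomp(motif_seq) else motif_seq,
                   "")[[1L]]
    if (pos0 < 0L || pos0 + length(ch) > L)
      stop("infeasible packing: too many genes for genome_length ", L)
    genome[(pos0 + 1L):(pos0 + length(ch))] <<- ch
  }

  plant_promoter <- function(tss, strand) {
    d10 <- as.integer(sample(names(cfg$minus10_spacer_probs), 1L,
                             prob = cfg$minus10_spacer_probs))
    m10 <- mutate_motif(cfg$minus10_consensus, cfg$minus10_mutation)
    w10 <- nchar(m10)
    d35 <- draw_int(cfg$minus35_spacer_range[1L]:cfg$minus35_spacer_range[2L])
    m35 <- mutate_motif(cfg$minus35_consensus, cfg$minus10_mutation)
    w35 <- nchar(m35)
    if (strand == "+") {
      s10 <- tss - d10 - w10
      plant(s10, m10, "+")
      plant(s10 - d35 - w35, m35, "+")
    } else {
      s10 <- tss + d10 + 1L
      plant(s10, m10, "-")
      plant(s10 + w10 + d35, m35, "-")
    }
  }

  stack_height <- function() {
    cfg$min_read_starts +
      stats::rnbinom(1L, size = cfg$tss_nb_size,
                     mu = cfg$tss_signal_mean - cfg$min_read_starts)
  }

  add_tss <- function(pos, strand, feature_id, utr, group) {
    h <- stack_height()
    if (strand == "+") rs_fwd[pos + 1L] <<- rs_fwd[pos + 1L] + h
    else rs_rev[pos + 1L] <<- rs_rev[pos + 1L] + h
    truth_tss[[length(truth_tss) + 1L]] <<- data.frame(
      position = pos, strand = strand, tss_class = "primary",
      assigned_feature_id = feature_id, utr_length = utr,
      leaderless = utr <= 3L, count = h, group = group,
      stringsAsFactors = FALSE)
  }

  plant_rbs <- function(tls, strand, utr) {
    if (utr < nchar(cfg$rbs_consensus) + cfg$rbs_spacer_range[1L]) return()
    r_max <- min(cfg$rbs_spacer_range[2L], utr - nchar(cfg$rbs_consensus))
    r <- draw_int(cfg$rbs_spacer_range[1L]:r_max)
    w <- nchar(cfg$rbs_consensus)
    if (strand == "+") plant(tls - r - w, cfg$rbs_consensus, "+")
    else plant(tls + r + 1L, cfg$rbs_consensus, "-")
  }

  new_gene <- function(start, n_codons, strand, product = "hypothetical protein") {
    gene_no <<- gene_no + 1L
    id <- sprintf("gene_%04d", gene_no)
    body <- c(sample(c("ATG", "GTG", "TTG"), 1L,
                     prob = c(0.554, 0.408, 0.038)),
              random_codons(n_codons - 2L, cfg$gc_content),
              sample(STOP_CODONS, 1L))
    dna <- paste(body, collapse = "")
    end <- start + nchar(dna)
    plant(start, dna, strand)
    features[[length(features) + 1L]] <<- data.frame(
      feature_id = id, kind = "CDS", start = start, end = end,
      strand = strand, product = product, stringsAsFactors = FALSE)
    list(id = id, start = start, end = end, strand = strand)
  }

  add_coverage <- function(a, b, strand, depth) {
    if (a < 0L || b > L)
      stop("infeasible packing: too many genes for genome_length ", L)
    idx <- (a + 1L):b
    if (strand == "+") cov_fwd[idx] <<- cov_fwd[idx] + depth
    else cov_rev[idx] <<- cov_rev[idx] + depth
  }

  add_bridge_reads <- function(left_gene_end, right_gene_start, strand) {
    n <- cfg$bridge_base + stats::rpois(1L, cfg$bridge_extra_mean)
    lo <- right_gene_start + 1L - cfg$read_length
    hi <- left_gene_end - 1L
    starts <- sample(lo:hi, n, replace = TRUE)
    reads[[length(reads) + 1L]] <<- data.frame(
      start = starts, end = starts + cfg$read_length, strand = strand,
      stringsAsFactors = FALSE)
  }

  for (u in units) {
    strand <- sample(c("+", "-"), 1L)
    leaderless <- stats::runif(1L) < cfg$leaderless_fraction
    utr <- if (leaderless) 0L else draw_utr(cfg)
    depth <- draw_int(cfg$expression_range[1L]:cfg$expression_range[2L])

    if (u$type == "attenuator") {
      orf_dna <- reencode_peptide(u$peptide)
      orf_len <- nchar(orf_dna)
      stem <- paste(random_dna_vec(8L, 0.8), collapse = "")
      hairpin <- paste0(stem, paste(random_dna_vec(4L, 0.5), collapse = ""),
                        revcomp(stem))
      leader_tail <- paste0(paste(random_dna_vec(10L, cfg$gc_content),
                                  collapse = ""),
                            hairpin, strrep("T", 8L),
                            paste(random_dna_vec(25L, cfg$gc_content),
                                  collapse = ""))
      leader_dna <- paste0(orf_dna, leader_tail)
      utr_att <- nchar(leader_dna)
      n_codons <- draw_int(cfg$gene_codon_range[1L]:cfg$gene_codon_range[2L])
      gene_len <- 3L * n_codons
      block <- promoter_pad + utr_att + gene_len + 10L
      if (strand == "+") {
        g_start <- cursor + promoter_pad + utr_att
        gene <- new_gene(g_start, n_codons,
                         "+", paste0(u$name, "-regulated amino-acid pathway gene"))
        plant(cursor + promoter_pad, leader_dna, "+")
        tss <- cursor + promoter_pad
      } else {
        g_start <- cursor + 10L
        gene <- new_gene(g_start, n_codons,
                         "-", paste0(u$name, "-regulated amino-acid pathway gene"))
        plant(gene$end, leader_dna, "-")
        tss <- gene$end + utr_att - 1L
      }
      plant_promoter(tss, strand)
      add_tss(tss, strand, gene$id, utr_att, "attenuator")
      add_coverage(min(tss, gene$start), max(tss + 1L, gene$end), strand, depth)
      mono_ids <- c(mono_ids, gene$id)
      attenuators[[length(attenuators) + 1L]] <- data.frame(
        target = gene$id, peptide = u$peptide, name = u$name,
        stringsAsFactors = FALSE)
      expression[[length(expression) + 1L]] <- data.frame(
        feature_id = gene$id, level = depth, stringsAsFactors = FALSE)
      cursor <- cursor + block + inter_block
      next
    }

    size <- if (u$type == "operon") u$size else 1L
    n_codons <- sample(cfg$gene_codon_range[1L]:cfg$gene_codon_range[2L],
                       size, replace = TRUE)
    gene_lens <- 3L * n_codons
    span <- sum(gene_lens) + (size - 1L) * cfg$junction_gap
    left_pad <- if (strand == "+") promoter_pad + utr else 10L
    right_pad <- if (strand == "+") 10L else promoter_pad + utr
    genes <- vector("list", size)
    g_cursor <- cursor + left_pad
    for (k in seq_len(size)) {
      genes[[k]] <- new_gene(g_cursor, n_codons[k], strand)
      g_cursor <- genes[[k]]$end + cfg$junction_gap
    }
    tx_order <- if (strand == "-") rev(seq_len(size)) else seq_len(size)
    first <- genes[[tx_order[1L]]]
    tls <- feature_tls(first$start, first$end, strand)
    tss <- if (strand == "+") tls - utr else tls + utr
    plant_promoter(tss, strand)
    if (!leaderless) plant_rbs(tls, strand, utr)
    add_tss(tss, strand, first$id, utr, "unit")
    unit_a <- min(tss, genes[[1L]]$start)
    unit_b <- max(tss + 1L, genes[[size]]$end)
    add_coverage(unit_a, unit_b, strand, depth)
    for (g in genes)
      expression[[length(expression) + 1L]] <- data.frame(
        feature_id = g$id, level = depth, stringsAsFactors = FALSE)

    if (u$type == "operon") {
      for (k in seq_len(size - 1L))
        add_bridge_reads(genes[[k]]$end, genes[[k + 1L]]$start, strand)
      op_genes <- vapply(genes[tx_order], function(g) g$id, character(1))
      operons[[length(operons) + 1L]] <- op_genes
      if (stats::runif(1L) < cfg$suboperon_prob && size >= 2L) {
        k <- (2L:size)[sample.int(size - 1L, 1L)]
        internal <- genes[[tx_order[k]]]
        i_tls <- feature_tls(internal$start, internal$end, strand)
        utr_sub <- draw_int(4L:12L)
        tss_sub <- if (strand == "+") i_tls - utr_sub else i_tls + utr_sub
        plant_promoter(tss_sub, strand)
        plant_rbs(i_tls, strand, utr_sub)
        add_tss(tss_sub, strand, internal$id, utr_sub, "sub_operon")
        sub_operons[[length(sub_operons) + 1L]] <- list(
          operon_index = length(operons), start_gene_index = k,
          gene_ids = op_genes[k:size])
      }
    } else {
      mono_ids <- c(mono_ids, genes[[1L]]$id)
    }
    cursor <- cursor + left_pad + span + right_pad + inter_block
  }

  if (cursor > L - 100L)
    stop("infeasible packing: ", cursor, " nt needed but genome_length is ", L)

  # background 5' read starts
  if (cfg$background_rate > 0) {
    rs_fwd <- rs_fwd + stats::rpois(L, cfg$background_rate)
    rs_rev <- rs_rev + stats::rpois(L, cfg$background_rate)
  }

  feature_tab <- do.call(rbind, features)
  ann <- genome_annotation("synthetic_chr", paste(genome, collapse = ""),
                           feature_tab)
  reads_tab <- if (length(reads)) do.call(rbind, reads) else
    data.frame(start = integer(0), end = integer(0), strand = character(0))
  total <- sum(rs_fwd) + sum(rs_rev) + nrow(reads_tab) +
    round((sum(cov_fwd) + sum(cov_rev)) / cfg$read_length)
  profile <- strand_profile(rs_fwd, rs_rev, cov_fwd, cov_rev, total)
  truth <- list(
    tss = { t <- do.call(rbind, truth_tss); rownames(t) <- NULL
            t[order(t$position), , drop = FALSE] },
    operons = operons, sub_operons = sub_operons,
    monocistronic = sort(mono_ids),
    attenuators = if (length(attenuators)) do.call(rbind, attenuators) else
      data.frame(target = character(0), peptide = character(0),
                 name = character(0)),
    expression = do.call(rbind, expression))
  list(annotation = ann, profile = profile, reads = reads_tab,
       truth = truth, config = cfg)
}

#' Generate anchored motif windows with a planted element
#'
#' Stand-alone generator for motif-recovery experiments: fixed-length
#' windows of GC-biased background with a (mutated) consensus planted at a
#' drawn anchor distance.
#'
#' @param n number of windows.
#' @param consensus planted element.
#' @param window window length (nt).
#' @param spacer_range planted element-to-anchor distances (uniform draw).
#' @param mutation_rate per-position mutation rate of the element.
#' @param gc background GC content.
#' @param seed RNG seed.
#' @param plant_fraction fraction of windows that receive the element.
#' @return list `sequences`, `offsets` (0-based planted offsets, NA where
#'   unplanted), `spacers` (planted anchor distances).
#' @export
simulate_motif_windows <- function(n, consensus = "TATAAT", window = 70L,
                                   spacer_range = c(4L, 9L),
                                   mutation_rate = 0.1, gc = 0.72,
                                   seed = 1L, plant_fraction = 1) {
  set.seed(seed)
  w <- nchar(consensus)
  seqs <- vapply(seq_len(n), function(i)
    paste(random_dna_vec(window, gc), collapse = ""), character(1))
  offsets <- rep(NA_integer_, n)
  spacers <- rep(NA_integer_, n)
  planted <- stats::runif(n) < plant_fraction
  for (i in which(planted)) {
    d <- draw_int(spacer_range[1L]:spacer_range[2L])
    o <- window - d - w
    m <- mutate_motif(consensus, mutation_rate)
    substr(seqs[i], o + 1L, o + w) <- m
    offsets[i] <- o
    spacers[i] <- d
  }
  list(sequences = seqs, offsets = offsets, spacers = spacers)
}
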