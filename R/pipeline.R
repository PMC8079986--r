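# End-to-end orchestration: TSS detection -> classification -> TLS
# correction -> UTR/motif analysis -> operons -> attenuators -> rpkm,
# with a structured report mirroring the classic reannotation summaries.

#' Run the full reannotation pipeline
#'
#' Stage order: TSS detection, genomic-context classification,
#' translation-start correction, 5'-UTR statistics, promoter and RBS motif
#' discovery, operon inference, attenuator scan, per-gene transcription
#' strength. Deterministic given the config (EM seeds derive from it).
#'
#' @param ann a `GenomeAnnotation`.
#' @param profile a `StrandProfile` (5'-end and whole-transcriptome
#'   tracks).
#' @param reads optional whole-transcriptome read-interval data.frame for
#'   operon bridging; alternatively pass precomputed `bridging`.
#' @param bridging optional `gene_a, gene_b, count` table.
#' @param config a [pipeline_config()].
#' @return a `ReannotationReport`: list with `tss`, `tss_summary`,
#'   `utr_histogram`, `leaderless_fraction`, `tls_proposals`,
#'   `start_codons` (before/after), `corrected_annotation`, `motifs`,
#'   `rbs`, `operon_map`, `operon_summary`, `attenuators`, `rpkm`,
#'   `config`, and a per-stage `log`.
#' @export
run_pipeline <- function(ann, profile, reads = NULL, bridging = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(ann, "GenomeAnnotation"),
            inherits(profile, "StrandProfile"))
  if (genome_length(ann) != profile_length(profile))
    stop("annotation and profile disagree on genome length")
  if (config$strandedness == "antisense") {
    profile[c("read_starts_fwd", "read_starts_rev")] <-
      profile[c("read_starts_rev", "read_starts_fwd")]
    profile[c("coverage_fwd", "coverage_rev")] <-
      profile[c("coverage_rev", "coverage_fwd")]
  }
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- list(stage = stage, ...)
  }

  tss <- detect_tss(profile, config$detection, mode = config$tss_mode)
  note("detect_tss", n_out = nrow(tss))

  tss <- classify_tss(tss, ann, config$detection)
  note("classify_tss", n_in = nrow(tss),
       classes = as.list(tss_summary(tss)))

  usage_before <- start_codon_usage(ann)
  proposals <- propose_tls_corrections(ann, tss, profile, config$detection)
  corrected <- apply_tls_corrections(ann, proposals)
  usage_after <- start_codon_usage(corrected)
  note("tls_correction", n_proposals = nrow(proposals))

  hist <- utr_histogram(tss, leaderless_max = config$detection$leaderless_max_utr)
  n_prim <- sum(tss$tss_class == "primary")
  leaderless_fraction <- if (n_prim)
    sum(isTRUE_vec(tss$leaderless) & tss$tss_class == "primary") / n_prim
  else NA_real_
  note("utr_analysis", n_utr = hist$total,
       leaderless = hist$leaderless)

  motifs <- if (n_prim >= 10L)
    find_promoter_motifs(corrected, tss, config$motifs)
  else list(insufficient_data = TRUE, n = n_prim)
  rbs <- find_rbs(corrected, tss, config$motifs)
  note("motifs", n_primary = n_prim)

  if (is.null(bridging)) {
    bridging <- if (!is.null(reads)) bridging_counts(corrected, reads)
    else data.frame(gene_a = character(0), gene_b = character(0),
                    strand = character(0), count = integer(0))
  }
  operon_map <- infer_operons(corrected, bridging, tss, config$detection)
  op_sum <- operon_summary(operon_map)
  note("operons", n_operons = op_sum$operons,
       n_monocistronic = op_sum$monocistronic)

  atten <- scan_attenuators(corrected, tss, config$attenuators,
                            config$detection)
  note("attenuators", n_hits = nrow(atten))

  expr <- rpkm_table(corrected, profile, config$rpkm_counting)
  note("rpkm", n_features = nrow(expr))

  structure(list(tss = tss, tss_summary = tss_summary(tss),
                 utr_histogram = hist,
                 leaderless_fraction = leaderless_fraction,
                 tls_proposals = proposals,
                 start_codons = list(before = usage_before,
                                     after = usage_after),
                 corrected_annotation = corrected,
                 motifs = motifs, rbs = rbs,
                 operon_map = operon_map, operon_summary = op_sum,
                 attenuators = atten, rpkm = expr,
                 config = config, log = log),
            class = "ReannotationReport")
}

#' @export
print.ReannotationReport <- function(x, ...) {
  s <- x$tss_summary
  cat("ReannotationReport\n")
  cat(sprintf("  TSS: %d (primary %d, secondary %d, antisense %d, intragenic %d, intergenic %d)\n",
              s$total, s$primary, s$secondary, s$antisense, s$intragenic,
              s$intergenic))
  cat(sprintf("  leaderless fraction: %s\n",
              ifelse(is.na(x$leaderless_fraction), "n/a",
                     sprintf("%.1f%%", 100 * x$leaderless_fraction))))
  cat(sprintf("  TLS corrections proposed: %d\n", nrow(x$tls_proposals)))
  o <- x$operon_summary
  cat(sprintf("  operons: %d (%d validated, %d sub-operons), %d genes in operons, %d monocistronic\n",
              o$operons, o$validated, o$sub_operons, o$genes_in_operons,
              o$monocistronic))
  cat(sprintf("  attenuator leader-peptide hits: %d\n", nrow(x$attenuators)))
  if (!isTRUE(x$rbs$insufficient_data))
    cat(sprintf("  RBS: consensus %s, placed in %.1f%% of %d sequences\n",
                x$rbs$model$consensus, 100 * x$rbs$placement_fraction,
                x$rbs$n_sequences))
  invisible(x)
}

#' Serialise a report to JSON
#'
#' Writes the scalar/summary sections (not the full per-base objects);
#' rerunning the pipeline with identical inputs reproduces the file
#' byte-identically.
#'
#' @param report a `ReannotationReport`.
#' @param path output JSON file.
#' @export
write_report_json <- function(report, path) {
  consensus_or_na <- function(m)
    if (inherits(m, "MotifModel")) m$consensus else NA_character_
  motif_sec <- function(g) {
    if (is.null(g) || isTRUE(g$insufficient_data))
      return(list(insufficient_data = TRUE))
    list(minus10_consensus = consensus_or_na(g$minus10),
         minus10_spacer_mean = if (!isTRUE(g$minus10_spacer$no_placements))
           g$minus10_spacer$mean else NA_real_,
         tannnt_fraction = g$tannnt,
         minus35_consensus = consensus_or_na(g$minus35),
         n = g$n)
  }
  out <- list(
    tss_summary = report$tss_summary,
    leaderless_fraction = report$leaderless_fraction,
    utr_histogram = list(leaderless = report$utr_histogram$leaderless,
                         bins = as.list(report$utr_histogram$bins),
                         overflow = report$utr_histogram$overflow),
    n_tls_proposals = nrow(report$tls_proposals),
    start_codons = report$start_codons,
    motifs = list(leaderless = motif_sec(report$motifs$leaderless),
                  leadered = motif_sec(report$motifs$leadered)),
    rbs = if (isTRUE(report$rbs$insufficient_data))
      list(insufficient_data = TRUE)
    else list(consensus = report$rbs$model$consensus,
              placement_fraction = report$rbs$placement_fraction,
              spacer_mean = report$rbs$spacer$mean),
    operon_summary = report$operon_summary,
    n_attenuator_hits = nrow(report$attenuators),
    log = report$log)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
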