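# Tunable thresholds of every stage, with the field's established defaults.
# All distances are in nucleotides, all counts in reads.

#' TSS / operon / TLS-correction detection thresholds
#'
#' @param min_read_starts minimum 5'-read-start count at a candidate TSS.
#' @param percent_increase required percent increase of read starts from the
#'   strand-aware upstream neighbour (-1) to the candidate position (+1),
#'   standard mode. 1000 means the increase must be at least tenfold.
#' @param low_coverage_percent_increase same threshold in low-coverage mode.
#' @param max_tss_tls_distance maximal distance from a putative TSS to the
#'   next downstream translation start for gene assignment.
#' @param leaderless_max_utr maximal 5'-UTR length (nt) still called
#'   leaderless.
#' @param bridging_reads_min minimum whole-transcriptome reads spanning an
#'   intergenic junction to join two genes into an operon.
#' @param tls_scan_fraction fraction of each CDS (from its 5' end) scanned
#'   for start-codon corrections.
#' @param old_tls_coverage_max maximal whole-transcriptome coverage allowed
#'   at the original TLS for a correction to be proposed ("no reads at the
#'   old start", hardened to a count).
#' @param collapse_window half-width (nt) of the window in which adjacent
#'   read stacks are collapsed to the strongest position.
#' @return a `detection_config` list.
#' @export
detection_config <- function(min_read_starts = 10L,
                             percent_increase = 1000,
                             low_coverage_percent_increase = 100,
                             max_tss_tls_distance = 500L,
                             leaderless_max_utr = 3L,
                             bridging_reads_min = 5L,
                             tls_scan_fraction = 0.25,
                             old_tls_coverage_max = 0L,
                             collapse_window = 2L) {
  cfg <- list(min_read_starts = as.integer(min_read_starts),
              percent_increase = percent_increase,
              low_coverage_percent_increase = low_coverage_percent_increase,
              max_tss_tls_distance = as.integer(max_tss_tls_distance),
              leaderless_max_utr = as.integer(leaderless_max_utr),
              bridging_reads_min = as.integer(bridging_reads_min),
              tls_scan_fraction = tls_scan_fraction,
              old_tls_coverage_max = as.integer(old_tls_coverage_max),
              collapse_window = as.integer(collapse_window))
  with(cfg, {
    stopifnot(min_read_starts > 0, percent_increase > 0,
              low_coverage_percent_increase > 0,
              max_tss_tls_distance > 0, leaderless_max_utr >= 0,
              leaderless_max_utr < max_tss_tls_distance,
              bridging_reads_min > 0,
              tls_scan_fraction > 0, tls_scan_fraction <= 1,
              old_tls_coverage_max >= 0, collapse_window >= 0)
  })
  structure(cfg, class = "detection_config")
}

#' Motif-search configuration
#'
#' @param promoter_window nt upstream of the TSS searched for promoter
#'   elements (70 by default; 80 is a common alternative).
#' @param minus10_spacer allowed distance range (nt) between the -10
#'   hexamer 3' end and the TSS.
#' @param minus35_spacer allowed distance range between the -35 hexamer and
#'   the -10 element (anchored on the -10 placement, not the TSS).
#' @param rbs_window nt upstream of the TLS searched for the RBS.
#' @param rbs_spacer allowed RBS-to-TLS distance range.
#' @param rbs_utr_range 5'-UTR length range of CDS admitted to the RBS
#'   search.
#' @param width motif width (hexamers throughout).
#' @param em_restarts number of random EM initialisations; best
#'   log-likelihood wins.
#' @param max_iter EM iteration cap.
#' @param pseudocount added to each PFM cell.
#' @param seed RNG seed for EM initialisation (results are invariant under
#'   input order because the seed derives from the config, not the data).
#' @return a `motif_search_config` list.
#' @export
motif_search_config <- function(promoter_window = 70L,
                                minus10_spacer = c(4L, 9L),
                                minus35_spacer = c(15L, 19L),
                                rbs_window = 20L,
                                rbs_spacer = c(4L, 9L),
                                rbs_utr_range = c(10L, 150L),
                                width = 6L,
                                em_restarts = 4L,
                                max_iter = 200L,
                                pseudocount = 0.01,
                                seed = 1L) {
  cfg <- list(promoter_window = as.integer(promoter_window),
              minus10_spacer = as.integer(minus10_spacer),
              minus35_spacer = as.integer(minus35_spacer),
              rbs_window = as.integer(rbs_window),
              rbs_spacer = as.integer(rbs_spacer),
              rbs_utr_range = as.integer(rbs_utr_range),
              width = as.integer(width),
              em_restarts = as.integer(em_restarts),
              max_iter = as.integer(max_iter),
              pseudocount = pseudocount,
              seed = as.integer(seed))
  stopifnot(cfg$width > 0,
            diff(cfg$minus10_spacer) >= 0, diff(cfg$minus35_spacer) >= 0,
            diff(cfg$rbs_spacer) >= 0, diff(cfg$rbs_utr_range) >= 0,
            cfg$promoter_window >= cfg$width + max(cfg$minus10_spacer),
            cfg$rbs_window >= cfg$width + max(cfg$rbs_spacer),
            cfg$em_restarts >= 1, cfg$max_iter >= 1, cfg$pseudocount > 0)
  structure(cfg, class = "motif_search_config")
}

#' Attenuator-scan configuration
#'
#' @param min_len_aa,max_len_aa admissible leader-peptide length range.
#' @param min_enrichment required fold enrichment of the top residue over
#'   the background frequency (uniform 1/20 by default).
#' @param min_residue_count required count of the enriched residue.
#' @param min_stem minimal perfect stem length (bp) of a terminator hairpin.
#' @param loop_range admissible hairpin loop length range (nt).
#' @param u_window nt downstream of the stem inspected for the U-stretch.
#' @param min_u minimal number of T/U in `u_window` for a canonical
#'   Rho-independent terminator.
#' @param terminator_window nt downstream of a leader ORF searched for a
#'   terminator.
#' @param leader_window fallback leader length (nt upstream of the TLS)
#'   when no TSS is assigned to the target gene.
#' @param background named numeric vector of residue background frequencies
#'   (default uniform over the 20 amino acids).
#' @return an `attenuator_config` list.
#' @export
attenuator_config <- function(min_len_aa = 8L, max_len_aa = 35L,
                              min_enrichment = 3.0, min_residue_count = 2L,
                              min_stem = 6L, loop_range = c(3L, 9L),
                              u_window = 10L, min_u = 3L,
                              terminator_window = 80L,
                              leader_window = 250L,
                              background = NULL) {
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  cfg <- list(min_len_aa = as.integer(min_len_aa),
              max_len_aa = as.integer(max_len_aa),
              min_enrichment = min_enrichment,
              min_residue_count = as.integer(min_residue_count),
              min_stem = as.integer(min_stem),
              loop_range = as.integer(loop_range),
              u_window = as.integer(u_window), min_u = as.integer(min_u),
              terminator_window = as.integer(terminator_window),
              leader_window = as.integer(leader_window),
              background = background)
  stopifnot(cfg$min_len_aa >= 1, cfg$max_len_aa >= cfg$min_len_aa,
            cfg$min_enrichment > 0, cfg$min_stem >= 2,
            diff(cfg$loop_range) >= 0, all(cfg$loop_range >= 1),
            cfg$u_window >= 1, cfg$min_u >= 0,
            all(abs(sum(cfg$background) - 1) < 1e-6))
  structure(cfg, class = "attenuator_config")
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Full pipeline configuration
#'
#' Bundles the per-stage configurations plus pipeline-level switches.
#'
#' @param detection a [detection_config()].
#' @param motifs a [motif_search_config()].
#' @param attenuators an [attenuator_config()].
#' @param tss_mode `"standard"` or `"low_coverage"`.
#' @param strandedness `"sense"` (default) or `"antisense"` library
#'   chemistry; `"antisense"` swaps the strand tracks on input.
#' @param rpkm_counting `"read_starts"` (default) or `"coverage"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(detection = detection_config(),
                            motifs = motif_search_config(),
                            attenuators = attenuator_config(),
                            tss_mode = c("standard", "low_coverage"),
                            strandedness = c("sense", "antisense"),
                            rpkm_counting = c("read_starts", "coverage")) {
  structure(list(detection = detection, motifs = motifs,
                 attenuators = attenuators,
                 tss_mode = match.arg(tss_mode),
                 strandedness = match.arg(strandedness),
                 rpkm_counting = match.arg(rpkm_counting)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Top-level keys `detection`, `motifs`, `attenuators` mirror the
#' corresponding constructor arguments; unknown keys are rejected.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  }
  known <- c("detection", "motifs", "attenuators", "tss_mode",
             "strandedness", "rpkm_counting")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  pipeline_config(
    detection = do.call(detection_config, as.list(raw$detection %||% list())),
    motifs = do.call(motif_search_config, as.list(raw$motifs %||% list())),
    attenuators = do.call(attenuator_config, as.list(raw$attenuators %||% list())),
    tss_mode = raw$tss_mode %||% "standard",
    strandedness = raw$strandedness %||% "sense",
    rpkm_counting = raw$rpkm_counting %||% "read_starts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
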