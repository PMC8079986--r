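# Translation-start correction from intragenic TSS, and start-codon usage.
# High-GC genomes are depleted of AT-rich stop codons, so gene callers tend
# to over-extend ORFs at the 5' end; an intragenic TSS downstream of a
# silent predicted start is the transcriptomic signature of such an error.

START_CODONS <- c("ATG", "GTG", "TTG")

#' Propose corrected translation start sites
#'
#' For each CDS carrying a same-strand intragenic TSS within the first
#' `tls_scan_fraction` of its length, the CDS reading frame is scanned
#' downstream of that TSS (still within the same bound) for the first
#' ATG/GTG/TTG. A proposal is emitted iff such a codon exists, the
#' whole-transcriptome coverage at the original TLS base is at most
#' `old_tls_coverage_max`, and no primary/secondary TSS is assigned to the
#' CDS. At most one proposal per CDS.
#'
#' @param ann a `GenomeAnnotation`.
#' @param tss classified TSS table ([classify_tss()]).
#' @param profile `StrandProfile` providing the whole-transcriptome
#'   coverage track.
#' @param config a [detection_config()].
#' @return data.frame `feature_id, old_tls, new_tls, new_start_codon,
#'   supporting_tss, old_tls_coverage` (0-based TLS coordinates).
#' @export
propose_tls_corrections <- function(ann, tss, profile,
                                    config = detection_config()) {
  ft <- ann$features[ann$features$kind == "CDS", , drop = FALSE]
  assigned_ids <- unique(tss$assigned_feature_id[
    tss$tss_class %in% c("primary", "secondary")])
  intragenic <- tss[tss$tss_class == "intragenic", , drop = FALSE]
  props <- list()
  for (i in seq_len(nrow(ft))) {
    f <- ft[i, ]
    cds_len <- f$end - f$start
    if (cds_len < 9L) { warning("CDS shorter than 3 codons skipped: ",
                                f$feature_id); next }
    if (f$feature_id %in% assigned_ids) next   # gene already has its own TSS
    bound <- floor(config$tls_scan_fraction * cds_len)
    tls <- feature_tls(f$start, f$end, f$strand)
    cand <- intragenic[intragenic$strand == f$strand &
                       intragenic$position >= f$start &
                       intragenic$position < f$end, , drop = FALSE]
    if (!nrow(cand)) next
    off <- tss_tls_distance(tls, cand$position, f$strand)  # TSS offset into CDS
    cand <- cand[off > 0L & off < bound, , drop = FALSE]
    off <- off[off > 0L & off < bound]
    if (!nrow(cand)) next
    # most upstream qualifying intragenic TSS supports the proposal
    j <- which.min(off)
    tss_off <- off[j]
    # coverage at the original TLS base, strand-matched
    cov <- profile_track(profile, "coverage", f$strand)[tls + 1L]
    if (cov > config$old_tls_coverage_max) next
    # first in-frame start codon strictly downstream of the TSS, within bound
    new_off <- NA_integer_
    for (o in seq.int(from = 3L * ceiling((tss_off + 1L) / 3L), by = 3L,
                      length.out = max(0L, floor((bound - 1L) / 3L) + 1L))) {
      if (o >= bound) break
      codon <- cds_codon_at(ann$sequence, f, o)
      if (codon %in% START_CODONS) { new_off <- o; break }
    }
    if (is.na(new_off)) next
    new_tls <- if (f$strand == "-") tls - new_off else tls + new_off
    props[[f$feature_id]] <- data.frame(
      feature_id = f$feature_id, old_tls = tls, new_tls = new_tls,
      new_start_codon = cds_codon_at(ann$sequence, f, new_off),
      supporting_tss = cand$position[j], old_tls_coverage = cov,
      stringsAsFactors = FALSE)
  }
  if (!length(props))
    return(data.frame(feature_id = character(0), old_tls = integer(0),
                      new_tls = integer(0), new_start_codon = character(0),
                      supporting_tss = integer(0),
                      old_tls_coverage = numeric(0)))
  out <- do.call(rbind, props)
  rownames(out) <- NULL
  out[order(out$old_tls), , drop = FALSE]
}

# Codon at 0-based in-frame offset `off` from the 5' end of a CDS, read in
# transcription direction.
cds_codon_at <- function(sequence, feature, off) {
  if (feature$strand == "-") {
    revcomp(seq_sub(sequence, feature$end - off - 3L, feature$end - off))
  } else {
    seq_sub(sequence, feature$start + off, feature$start + off + 3L)
  }
}

#' Apply translation-start corrections
#'
#' Moves each proposed CDS start (strand-aware) to `new_tls`. The CDS
#' shrinks; stop codon and reading frame are preserved, which is checked.
#'
#' @param ann a `GenomeAnnotation`.
#' @param proposals output of [propose_tls_corrections()].
#' @return the corrected `GenomeAnnotation`.
#' @export
apply_tls_corrections <- function(ann, proposals) {
  if (!nrow(proposals)) return(ann)
  ft <- ann$features
  for (i in seq_len(nrow(proposals))) {
    p <- proposals[i, ]
    j <- match(p$feature_id, ft$feature_id)
    if (is.na(j)) stop("proposal references unknown feature: ", p$feature_id)
    f <- ft[j, ]
    old_tls <- feature_tls(f$start, f$end, f$strand)
    shift <- tss_tls_distance(old_tls, p$new_tls, f$strand) * -1L
    shift <- abs(shift)
    if (shift %% 3L != 0L || shift <= 0L || shift >= (f$end - f$start))
      stop("proposal violates reading frame for ", p$feature_id)
    if (f$strand == "-") ft$end[j] <- f$end - shift
    else ft$start[j] <- f$start + shift
  }
  ann$features <- as_feature_table(ft)
  validate_annotation(ann)
}

#' Start-codon usage of annotated CDS
#'
#' @param ann a `GenomeAnnotation`.
#' @return list with `fractions` (ATG/GTG/TTG over CDS with a recognised
#'   start codon), `other_fraction` (over all CDS), and `n_cds`.
#' @export
start_codon_usage <- function(ann) {
  ft <- ann$features[ann$features$kind == "CDS", , drop = FALSE]
  if (!nrow(ft))
    return(list(fractions = stats::setNames(numeric(3), START_CODONS),
                other_fraction = 0, n_cds = 0L))
  codons <- vapply(seq_len(nrow(ft)),
                   function(i) cds_codon_at(ann$sequence, ft[i, ], 0L),
                   character(1))
  recognised <- codons %in% START_CODONS
  frac <- if (any(recognised)) {
    t <- table(factor(codons[recognised], levels = START_CODONS))
    as.numeric(t) / sum(t)
  } else numeric(3)
  list(fractions = stats::setNames(frac, START_CODONS),
       other_fraction = mean(!recognised), n_cds = nrow(ft))
}
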