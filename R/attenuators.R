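# Attenuator leader-peptide detection: small ORFs in 5' leaders, residue
# enrichment, and a Rho-independent terminator heuristic (perfect inverted
# repeat + trailing U-stretch). Attenuation couples ribosome progression
# over a short leader ORF enriched in codons of the downstream pathway's
# amino acid to the formation of terminator vs anti-terminator hairpins.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find small ORFs in a leader sequence
#'
#' Enumerates every ATG/GTG/TTG start on the forward strand of the given
#' leader (5'->3'), extends in frame to the first stop, and keeps ORFs
#' whose peptide length is within the configured bounds and whose stop lies
#' inside the leader. GTG/TTG starts translate as M. ORFs spanning an `N`
#' are skipped with a warning.
#'
#' @param leader_sequence 5' leader, 5'->3' on the target's strand.
#' @param config an [attenuator_config()].
#' @return data.frame `start`, `end` (0-based half-open within the leader,
#'   stop codon included), `peptide`, `length_aa`, 5'-most first.
#' @export
find_leader_orfs <- function(leader_sequence, config = attenuator_config()) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      peptide = character(0), length_aa = integer(0),
                      stringsAsFactors = FALSE)
  seq <- toupper(leader_sequence)
  L <- nchar(seq)
  if (L < (config$min_len_aa + 1L) * 3L) return(empty)
  ch <- strsplit(seq, "")[[1L]]
  starts <- which(vapply(seq_len(L - 2L), function(i)
    substr(seq, i, i + 2L) %in% START_CODONS, logical(1)))
  rows <- list()
  for (s in starts) {
    # in-frame scan for the first stop
    stop_at <- NA_integer_
    has_n <- FALSE
    for (i in seq.int(s, L - 2L, by = 3L)) {
      codon <- substr(seq, i, i + 2L)
      if (grepl("N", codon, fixed = TRUE)) { has_n <- TRUE; break }
      if (codon %in% STOP_CODONS) { stop_at <- i; break }
    }
    if (has_n) { warning("ORF containing N skipped at offset ", s - 1L); next }
    if (is.na(stop_at)) next                  # no stop inside the leader
    len_aa <- (stop_at - s) %/% 3L
    if (len_aa < config$min_len_aa || len_aa > config$max_len_aa) next
    pep <- translate_cds(substr(seq, s, stop_at - 1L))
    if (is.na(pep) || grepl("\\*", pep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = s - 1L, end = stop_at + 2L, peptide = pep, length_aa = len_aa,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Residue composition and enrichment of a peptide
#'
#' Enrichment is observed frequency over a background frequency (uniform
#' 1/20 by default). The enriched residue is the arg-max enrichment among
#' residues occurring at least `min_count` times (ties: alphabetical).
#'
#' @param peptide amino-acid string over the 20-letter alphabet.
#' @param background named residue background frequencies.
#' @param min_count minimal count for the enriched-residue call.
#' @return list `residue_counts` (named, sums to `length_aa`), `length_aa`,
#'   `enrichment` (named fold-enrichments), `enriched_residue` (NA when no
#'   residue reaches `min_count`) and `max_enrichment`.
#' @export
residue_composition <- function(peptide,
                                background = stats::setNames(rep(1 / 20, 20),
                                                             AA_ALPHABET),
                                min_count = 2L) {
  aa <- strsplit(toupper(peptide), "")[[1L]]
  if (!all(aa %in% AA_ALPHABET))
    stop("invalid residue letter(s): ",
         paste(unique(setdiff(aa, AA_ALPHABET)), collapse = ", "))
  counts <- table(factor(aa, levels = AA_ALPHABET))
  counts <- stats::setNames(as.integer(counts), AA_ALPHABET)
  n <- length(aa)
  enr <- (counts / n) / background[AA_ALPHABET]
  eligible <- which(counts >= min_count)
  enriched <- if (length(eligible)) {
    cand <- eligible[enr[eligible] == max(enr[eligible])]
    AA_ALPHABET[cand[1L]]    # alphabet is sorted, so ties break alphabetically
  } else NA_character_
  list(residue_counts = counts, length_aa = n,
       enrichment = stats::setNames(as.numeric(enr), AA_ALPHABET),
       enriched_residue = enriched,
       max_enrichment = if (length(eligible)) max(enr[eligible]) else NA_real_)
}

#' Rho-independent terminator heuristic
#'
#' Enumerates all hairpin candidates with a perfect reverse-complement stem
#' of at least `min_stem` bp and a loop in `loop_range` nt. A canonical hit
#' additionally requires at least `min_u` T/U within `u_window` nt after
#' the stem's 3' arm. The best hit has the longest stem (ties: most
#' upstream). If only U-less hairpins exist, the best is returned flagged
#' `canonical = FALSE`.
#'
#' @param dna_window character DNA window downstream of a leader ORF.
#' @param config an [attenuator_config()].
#' @return `NULL` if no hairpin at all, else a list `position` (0-based
#'   stem start), `stem_length`, `loop_length`, `u_stretch_length`,
#'   `canonical`.
#' @export
find_terminator <- function(dna_window, config = attenuator_config()) {
  seq <- toupper(dna_window)
  L <- nchar(seq)
  if (L < 2L * config$min_stem + config$loop_range[1L]) return(NULL)
  ch <- strsplit(seq, "")[[1L]]
  comp <- chartr("ACGTN", "TGCAN", ch)
  pick <- function(hit, cur) {
    if (is.null(cur)) return(hit)
    if (hit$stem_length > cur$stem_length) return(hit)
    if (hit$stem_length == cur$stem_length && hit$position < cur$position)
      return(hit)
    cur
  }
  best_canon <- NULL; best_any <- NULL
  for (i in seq_len(L)) {                         # 1-based stem-1 start
    for (loop in config$loop_range[1L]:config$loop_range[2L]) {
      # windows are short (<= ~120 nt); exhaustive stem-length scan is fine
      max_stem <- (L - i + 1L - loop) %/% 2L
      if (max_stem < config$min_stem) next
      for (stem in config$min_stem:max_stem) {
        s1 <- i; e1 <- i + stem - 1L
        s2 <- e1 + loop + 1L; e2 <- s2 + stem - 1L
        if (e2 > L) next
        ok <- all(ch[s1:e1] != "N") &&
          all(ch[s1:e1] == rev(comp[s2:e2]))
        if (!ok) next
        u_end <- min(L, e2 + config$u_window)
        u_len <- if (u_end > e2) sum(ch[(e2 + 1L):u_end] == "T") else 0L
        hit <- list(position = i - 1L, stem_length = stem,
                    loop_length = loop, u_stretch_length = u_len,
                    canonical = u_len >= config$min_u)
        if (hit$canonical) best_canon <- pick(hit, best_canon)
        best_any <- pick(hit, best_any)
      }
    }
  }
  if (!is.null(best_canon)) best_canon else best_any
}

#' Scan gene leaders for attenuator leader peptides
#'
#' The leader of a target gene is `[TSS, TLS)` when a primary/secondary
#' TSS is assigned, else a fixed `leader_window` upstream of the TLS.
#' Each small ORF found there is scored by residue enrichment; a hit
#' requires enrichment >= `min_enrichment` with at least
#' `min_residue_count` copies of the enriched residue. A terminator is
#' searched between the ORF stop and the target TLS. `leaderless_start`
#' marks ORFs whose start coincides (within the leaderless UTR bound) with
#' a called TSS.
#'
#' @param ann `GenomeAnnotation`.
#' @param tss classified TSS table.
#' @param config an [attenuator_config()].
#' @param detection a [detection_config()] (for the leaderless bound).
#' @param target_filter optional regular expression on the `product` field
#'   (e.g. amino-acid biosynthesis / tRNA-ligase keywords); default all CDS.
#' @return data.frame of hits: `upstream_of`, `orf_start`, `orf_end`
#'   (genomic, 0-based), `peptide`, `length_aa`, `enriched_residue`,
#'   `enriched_count`, `enrichment`, `leaderless_start`, and terminator
#'   columns (`terminator`, `stem_length`, `loop_length`,
#'   `u_stretch_length`, `terminator_canonical`).
#' @export
scan_attenuators <- function(ann, tss, config = attenuator_config(),
                             detection = detection_config(),
                             target_filter = NULL) {
  ft <- ann$features[ann$features$kind == "CDS", , drop = FALSE]
  if (!is.null(target_filter))
    ft <- ft[grepl(target_filter, ft$product, ignore.case = TRUE), ,
             drop = FALSE]
  len <- genome_length(ann)
  assigned <- tss[tss$tss_class %in% c("primary", "secondary"), ,
                  drop = FALSE]
  tss_pos <- split(assigned$position, assigned$strand)
  rows <- list()
  for (i in seq_len(nrow(ft))) {
    f <- ft[i, ]
    tls <- feature_tls(f$start, f$end, f$strand)
    own <- assigned[!is.na(assigned$assigned_feature_id) &
                    assigned$assigned_feature_id == f$feature_id, ,
                    drop = FALSE]
    leader_len <- if (nrow(own)) max(own$utr_length) else config$leader_window
    if (leader_len < (config$min_len_aa + 1L) * 3L) next
    if (f$strand == "+") {
      a <- max(0L, tls - leader_len); b <- tls
      leader <- seq_sub(ann$sequence, a, b)
    } else {
      a <- tls + 1L; b <- min(len, tls + 1L + leader_len)
      leader <- revcomp(seq_sub(ann$sequence, a, b))
    }
    orfs <- find_leader_orfs(leader, config)
    Lh <- nchar(leader)
    for (k in seq_len(nrow(orfs))) {
      o <- orfs[k, ]
      comp <- residue_composition(o$peptide, config$background,
                                  config$min_residue_count)
      if (is.na(comp$enriched_residue) ||
          comp$max_enrichment < config$min_enrichment) next
      # terminator between ORF stop and the target TLS
      term_seq <- substring(leader, o$end + 1L,
                            min(Lh, o$end + config$terminator_window))
      term <- find_terminator(term_seq, config)
      # genomic ORF coordinates
      if (f$strand == "+") {
        g_start <- tls - Lh + o$start; g_end <- tls - Lh + o$end
      } else {
        g_start <- tls + Lh - o$end + 1L; g_end <- tls + Lh - o$start + 1L
      }
      orf_start_genomic <- if (f$strand == "+") g_start else g_end - 1L
      near_tss <- any(abs(tss_pos[[f$strand]] %||% integer(0) -
                          orf_start_genomic) <= detection$leaderless_max_utr)
      rows[[length(rows) + 1L]] <- data.frame(
        upstream_of = f$feature_id, orf_start = g_start, orf_end = g_end,
        peptide = o$peptide, length_aa = o$length_aa,
        enriched_residue = comp$enriched_residue,
        enriched_count = comp$residue_counts[comp$enriched_residue],
        enrichment = comp$max_enrichment,
        leaderless_start = near_tss,
        terminator = !is.null(term),
        stem_length = if (is.null(term)) NA_integer_ else term$stem_length,
        loop_length = if (is.null(term)) NA_integer_ else term$loop_length,
        u_stretch_length = if (is.null(term)) NA_integer_
                           else term$u_stretch_length,
        terminator_canonical = if (is.null(term)) FALSE else term$canonical,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(upstream_of = character(0), orf_start = integer(0),
               orf_end = integer(0), peptide = character(0),
               length_aa = integer(0), enriched_residue = character(0),
               enriched_count = integer(0), enrichment = numeric(0),
               leaderless_start = logical(0), terminator = logical(0),
               stem_length = integer(0), loop_length = integer(0),
               u_stretch_length = integer(0),
               terminator_canonical = logical(0))
  rownames(out) <- NULL
  out
}

#' Export attenuator hits as GFF3 `leader_peptide` features
#' @param hits output of [scan_attenuators()].
#' @param ann the `GenomeAnnotation` scanned.
#' @param path output file.
#' @export
write_attenuators_gff3 <- function(hits, ann, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(hits)) {
    ft <- ann$features
    strands <- ft$strand[match(hits$upstream_of, ft$feature_id)]
    writeLines(sprintf(
      "%s\tprimarytx\tleader_peptide\t%d\t%d\t.\t%s\t0\tID=leader_%04d;upstream_of=%s;peptide=%s;enriched=%s",
      ann$sequence_id, hits$orf_start + 1L, hits$orf_end, strands,
      seq_len(nrow(hits)), hits$upstream_of, hits$peptide,
      hits$enriched_residue), con)
  }
  invisible(path)
}
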