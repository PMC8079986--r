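# TSS calling from the 5'-end read-start track, genomic-context
# classification, and 5'-UTR statistics.

TSS_CLASSES <- c("primary", "secondary", "antisense", "intragenic",
                 "intergenic")

#' Detect transcription start site candidates
#'
#' A position is a candidate iff its 5'-read-start count reaches
#' `min_read_starts` AND the percent increase from the strand-aware
#' upstream neighbour reaches the mode's threshold:
#' `100 * (starts[i] - starts[i-1]) / max(starts[i-1], 1)`. A missing
#' neighbour at the chromosome edge counts as 0. Adjacent stacks within
#' `collapse_window` nt collapse to the strongest position (tie: most
#' upstream).
#'
#' @param profile a `StrandProfile`.
#' @param config a [detection_config()].
#' @param mode `"standard"` (1000% increase) or `"low_coverage"` (100%).
#' @param collapse collapse adjacent stacks (default TRUE; the exhaustive
#'   per-position oracle uses FALSE).
#' @return data.frame `position` (0-based), `strand`, `read_start_count`,
#'   `percent_increase`, sorted by position then strand.
#' @export
detect_tss <- function(profile, config = detection_config(),
                       mode = c("standard", "low_coverage"),
                       collapse = TRUE) {
  mode <- match.arg(mode)
  threshold <- if (mode == "standard") config$percent_increase
               else config$low_coverage_percent_increase
  out <- list()
  for (strand in c("+", "-")) {
    rs <- profile_track(profile, "read_starts", strand)
    n <- length(rs)
    if (n == 0L) next
    upstream <- if (strand == "+") c(0, rs[-n]) else c(rs[-1L], 0)
    inc <- 100 * (rs - upstream) / pmax(upstream, 1)
    hit <- which(rs >= config$min_read_starts & inc >= threshold)
    if (!length(hit)) next
    df <- data.frame(position = hit - 1L, strand = strand,
                     read_start_count = rs[hit], percent_increase = inc[hit],
                     stringsAsFactors = FALSE)
    if (collapse && config$collapse_window > 0L)
      df <- collapse_stacks(df, strand, config$collapse_window)
    out[[strand]] <- df
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(position = integer(0), strand = character(0),
               read_start_count = numeric(0), percent_increase = numeric(0))
  res <- res[order(res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Cluster candidate positions whose pairwise gap is <= window and keep the
# strongest one per cluster; ties resolve to the most upstream position
# (smallest coordinate on +, largest on -).
collapse_stacks <- function(df, strand, window) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(df$position), , drop = FALSE]
  cluster <- cumsum(c(1L, diff(df$position) > window))
  keep <- vapply(split(seq_len(nrow(df)), cluster), function(idx) {
    cnt <- df$read_start_count[idx]
    best <- idx[cnt == max(cnt)]
    if (strand == "+") best[1L] else best[length(best)]
  }, integer(1))
  df[sort(keep), , drop = FALSE]
}

#' Classify TSS by genomic context
#'
#' Two-pass precedence per TSS:
#' 1. If a same-strand feature's TLS lies 0..`max_tss_tls_distance` nt
#'    downstream, the TSS is assigned to the nearest such feature. Per
#'    feature, the assigned TSS with the highest read-start count is
#'    `primary` (tie: closest to the TLS); the rest are `secondary`.
#' 2. Otherwise: `antisense` if inside an opposite-strand feature or
#'    inside the 5'-UTR established by an opposite-strand primary TSS;
#'    `intragenic` if inside a same-strand feature body; else
#'    `intergenic`.
#'
#' `utr_length` is set for primary/secondary TSS only; `leaderless` is
#' `utr_length <= leaderless_max_utr`.
#'
#' @param tss data.frame from [detect_tss()].
#' @param ann a `GenomeAnnotation`.
#' @param config a [detection_config()].
#' @return the TSS table with `tss_class`, `assigned_feature_id`,
#'   `utr_length`, `leaderless` columns added.
#' @export
classify_tss <- function(tss, ann, config = detection_config()) {
  len <- genome_length(ann)
  if (nrow(tss) && (any(tss$position < 0L) || any(tss$position >= len)))
    stop("TSS position outside genome")
  ft <- ann$features
  n <- nrow(tss)
  cls <- rep(NA_character_, n)
  feat <- rep(NA_character_, n)
  utr <- rep(NA_integer_, n)

  # pass 1: gene-associated TSS (nearest same-strand downstream TLS)
  for (i in seq_len(n)) {
    p <- tss$position[i]; s <- tss$strand[i]
    same <- ft[ft$strand == s, , drop = FALSE]
    if (!nrow(same)) next
    tls <- feature_tls(same$start, same$end, same$strand)
    d <- tss_tls_distance(p, tls, s)
    ok <- which(d >= 0L & d <= config$max_tss_tls_distance)
    if (!length(ok)) next
    j <- ok[which.min(d[ok])]
    feat[i] <- same$feature_id[j]
    utr[i] <- d[j]
  }
  assigned <- !is.na(feat)
  for (fid in unique(feat[assigned])) {
    idx <- which(feat == fid & assigned)
    cnt <- tss$read_start_count[idx]
    best <- idx[cnt == max(cnt)]
    if (length(best) > 1L) best <- best[which.min(utr[best])]
    cls[idx] <- "secondary"
    cls[best[1L]] <- "primary"
  }

  # UTR intervals established by pass-1 primary TSS, for antisense calls
  prim <- which(cls == "primary" & utr > 0L)
  utr_iv <- if (length(prim)) {
    data.frame(
      start = ifelse(tss$strand[prim] == "+", tss$position[prim],
                     tss$position[prim] - utr[prim] + 1L),
      end = ifelse(tss$strand[prim] == "+", tss$position[prim] + utr[prim],
                   tss$position[prim] + 1L),   # half-open
      strand = tss$strand[prim], stringsAsFactors = FALSE)
  } else data.frame(start = integer(0), end = integer(0),
                    strand = character(0))

  # pass 2: the rest
  for (i in which(is.na(cls))) {
    p <- tss$position[i]; s <- tss$strand[i]
    opp <- ft$strand != s & ft$start <= p & p < ft$end
    opp_utr <- utr_iv$strand != s & utr_iv$start <= p & p < utr_iv$end
    if (any(opp) || any(opp_utr)) { cls[i] <- "antisense"; next }
    same <- ft$strand == s & ft$start <= p & p < ft$end
    cls[i] <- if (any(same)) "intragenic" else "intergenic"
    if (any(same)) feat[i] <- ft$feature_id[which(same)[1L]]
  }

  tss$tss_class <- cls
  tss$assigned_feature_id <- feat
  tss$utr_length <- ifelse(cls %in% c("primary", "secondary"), utr,
                           NA_integer_)
  tss$leaderless <- ifelse(is.na(tss$utr_length), NA,
                           tss$utr_length <= config$leaderless_max_utr)
  tss
}

#' 5'-UTR length histogram
#'
#' Leaderless transcripts (UTR 0..`leaderless_max`) form their own bin;
#' the remaining lengths are binned in `bin_width`-nt intervals
#' `[k*bw+1, (k+1)*bw]`, with lengths above `max_length` pooled into an
#' overflow bin. Counts sum to the number of primary + secondary TSS.
#'
#' @param tss classified TSS table.
#' @param bin_width histogram bin width (nt).
#' @param max_length overflow threshold (nt).
#' @param leaderless_max upper UTR bound of the leaderless category.
#' @return list with `leaderless` count, `bins` (named counts),
#'   `overflow` count and `total`.
#' @export
utr_histogram <- function(tss, bin_width = 5L, max_length = 500L,
                          leaderless_max = 3L) {
  u <- tss$utr_length[tss$tss_class %in% c("primary", "secondary")]
  u <- u[!is.na(u)]
  if (any(u < 0L)) stop("negative utr_length: internal consistency error")
  n_bins <- ceiling(max_length / bin_width)
  lo <- (seq_len(n_bins) - 1L) * bin_width + 1L
  hi <- pmin(seq_len(n_bins) * bin_width, max_length)
  bins <- stats::setNames(integer(n_bins), sprintf("%d-%d", lo, hi))
  leaderless <- sum(u <= leaderless_max)
  mid <- u[u > leaderless_max & u <= max_length]
  if (length(mid)) {
    k <- ceiling(mid / bin_width)
    t <- table(factor(k, levels = seq_len(n_bins)))
    bins <- bins + as.integer(t)
    names(bins) <- sprintf("%d-%d", lo, hi)
  }
  overflow <- sum(u > max_length)
  list(leaderless = leaderless, bins = bins, overflow = overflow,
       total = length(u))
}

#' Per-class TSS counts
#'
#' @param tss classified TSS table.
#' @return named list of per-class counts plus `total`.
#' @export
tss_summary <- function(tss) {
  cls <- factor(tss$tss_class, levels = TSS_CLASSES)
  counts <- as.list(table(cls))
  counts$total <- nrow(tss)
  counts
}

#' Write a classified TSS table as TSV (1-based positions)
#' @param tss classified TSS table.
#' @param path output file.
#' @export
write_tss_tsv <- function(tss, path) {
  out <- tss
  out$position <- out$position + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
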