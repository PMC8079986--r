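# StrandProfile: strand-specific per-base 5'-read-start and
# whole-transcriptome coverage tracks for one replicon.

#' Construct a strand profile
#'
#' @param read_starts_fwd,read_starts_rev integer vectors of 5'-read-start
#'   counts per base (forward / reverse strand).
#' @param coverage_fwd,coverage_rev whole-transcriptome coverage per base.
#' @param total_mapped_reads library size used for rpkm normalisation.
#' @return a `StrandProfile`.
#' @export
strand_profile <- function(read_starts_fwd, read_starts_rev,
                           coverage_fwd = NULL, coverage_rev = NULL,
                           total_mapped_reads = NULL) {
  n <- length(read_starts_fwd)
  if (is.null(coverage_fwd)) coverage_fwd <- integer(n)
  if (is.null(coverage_rev)) coverage_rev <- integer(n)
  vecs <- list(read_starts_fwd = as.numeric(read_starts_fwd),
               read_starts_rev = as.numeric(read_starts_rev),
               coverage_fwd = as.numeric(coverage_fwd),
               coverage_rev = as.numeric(coverage_rev))
  lens <- lengths(vecs)
  if (length(unique(lens)) != 1L)
    stop("profile vectors differ in length: ", paste(lens, collapse = ", "))
  if (any(vapply(vecs, function(v) any(v < 0), logical(1))))
    stop("negative counts in profile")
  if (is.null(total_mapped_reads))
    total_mapped_reads <- sum(vecs$read_starts_fwd) + sum(vecs$read_starts_rev)
  peak <- max(0, vecs$read_starts_fwd, vecs$read_starts_rev)
  if (total_mapped_reads < peak)
    stop("total_mapped_reads smaller than the largest read-start stack")
  structure(c(vecs, list(total_mapped_reads = total_mapped_reads)),
            class = "StrandProfile")
}

#' @export
print.StrandProfile <- function(x, ...) {
  cat(sprintf(
    "StrandProfile: %s nt, %s 5' read starts (+: %s, -: %s), %s mapped reads\n",
    format(length(x$read_starts_fwd), big.mark = ","),
    format(sum(x$read_starts_fwd) + sum(x$read_starts_rev), big.mark = ","),
    format(sum(x$read_starts_fwd), big.mark = ","),
    format(sum(x$read_starts_rev), big.mark = ","),
    format(x$total_mapped_reads, big.mark = ",")))
  invisible(x)
}

profile_length <- function(profile) length(profile$read_starts_fwd)

# Strand accessors; `track` is "read_starts" or "coverage".
profile_track <- function(profile, track, strand) {
  profile[[paste0(track, if (strand == "-") "_rev" else "_fwd")]]
}

#' Combine replicate profiles by element-wise summation
#'
#' Pools sequencing experiments to raise coverage in weakly transcribed
#' regions. Associative and commutative; `total_mapped_reads` adds up.
#'
#' @param profiles list of `StrandProfile`s over the same genome.
#' @return the pooled `StrandProfile`.
#' @export
combine_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "StrandProfile")))
  lens <- vapply(profiles, profile_length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("profiles have different genome lengths: ",
         paste(unique(lens), collapse = ", "))
  acc <- profiles[[1L]]
  for (p in profiles[-1L]) {
    for (nm in c("read_starts_fwd", "read_starts_rev",
                 "coverage_fwd", "coverage_rev"))
      acc[[nm]] <- acc[[nm]] + p[[nm]]
    acc$total_mapped_reads <- acc$total_mapped_reads + p$total_mapped_reads
  }
  acc
}

# bedGraph I/O ---------------------------------------------------------------

#' Read one strand's track from a 4-column bedGraph
#'
#' bedGraph intervals are 0-based half-open; absent positions are 0 and
#' overlapping intervals sum.
#'
#' @param path bedGraph file (`chrom start end value`); `track`/comment
#'   lines are skipped.
#' @param length genome length of the dense output vector.
#' @return numeric vector of per-base values.
#' @export
read_profile_bedgraph <- function(path, length) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  out <- numeric(length)
  if (!length(lines)) return(out)
  tab <- utils::read.table(text = lines, sep = "",
                           col.names = c("chrom", "start", "end", "value"),
                           colClasses = c("character", "integer", "integer",
                                          "numeric"))
  if (any(tab$start < 0L) || any(tab$end > length) || any(tab$start >= tab$end))
    stop("bedGraph interval outside [0, ", length, ") in ", path)
  for (i in seq_len(nrow(tab)))
    out[(tab$start[i] + 1L):tab$end[i]] <-
      out[(tab$start[i] + 1L):tab$end[i]] + tab$value[i]
  out
}

#' Write one strand's track as bedGraph
#'
#' Runs of equal non-zero values are merged; output is sorted by start.
#'
#' @param values per-base numeric vector.
#' @param chrom chromosome name.
#' @param path output file.
#' @export
write_profile_bedgraph <- function(values, chrom, path) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  tab <- data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
                    value = r$values[keep])
  writeLines(sprintf("%s\t%d\t%d\t%s", tab$chrom, tab$start, tab$end,
                     format(tab$value, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

# Transcription strength -----------------------------------------------------

#' Transcription strength of one feature (rpkm)
#'
#' `rpkm = assigned_reads * 1e9 / (total_mapped_reads * length_nt)`.
#' Assigned reads are strand-matched 5' read starts inside the feature
#' interval (default), or the mean coverage-derived read equivalent when
#' `counting = "coverage"`.
#'
#' @param feature one row of a feature table (list or single-row
#'   data.frame with `start`, `end`, `strand`).
#' @param profile a `StrandProfile` with `total_mapped_reads > 0`.
#' @param counting `"read_starts"` or `"coverage"`.
#' @return a single rpkm value.
#' @export
rpkm <- function(feature, profile, counting = c("read_starts", "coverage")) {
  counting <- match.arg(counting)
  start <- as.integer(feature$start); end <- as.integer(feature$end)
  len <- end - start
  if (len <= 0L) stop("zero-length feature")
  if (profile$total_mapped_reads <= 0) stop("total_mapped_reads must be > 0")
  if (start < 0L || end > profile_length(profile))
    stop("feature outside genome")
  track <- if (counting == "read_starts") "read_starts" else "coverage"
  v <- profile_track(profile, track, feature$strand)
  reads <- sum(v[(start + 1L):end])
  if (counting == "coverage") reads <- reads / len
  reads * 1e9 / (profile$total_mapped_reads * len)
}

#' Per-gene rpkm table
#'
#' @param ann a `GenomeAnnotation`.
#' @param profile a `StrandProfile`.
#' @param counting see [rpkm()].
#' @param kinds feature kinds to include.
#' @return data.frame with `feature_id, start, end, strand, reads, rpkm`.
#' @export
rpkm_table <- function(ann, profile, counting = c("read_starts", "coverage"),
                       kinds = "CDS") {
  counting <- match.arg(counting)
  ft <- ann$features[ann$features$kind %in% kinds, , drop = FALSE]
  reads <- numeric(nrow(ft)); val <- numeric(nrow(ft))
  for (i in seq_len(nrow(ft))) {
    f <- ft[i, ]
    v <- profile_track(profile,
                       if (counting == "read_starts") "read_starts" else "coverage",
                       f$strand)
    reads[i] <- sum(v[(f$start + 1L):f$end])
    val[i] <- rpkm(f, profile, counting)
  }
  data.frame(feature_id = ft$feature_id, start = ft$start, end = ft$end,
             strand = ft$strand, reads = reads, rpkm = val,
             stringsAsFactors = FALSE)
}
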