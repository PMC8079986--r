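#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based half-open everywhere.
# GFF3 (1-based inclusive) and other external formats are converted at I/O
# only.  "Upstream" on the reverse strand means LARGER genomic coordinate;
# the strand-aware helpers below own that arithmetic so no stage re-derives
# it.

#' Reverse complement of character DNA sequences
#'
#' Vectorised over short character sequences; `U` is treated as `T`, any
#' letter outside `ACGTN` maps to `N`.
#'
#' @param x character vector of DNA (or RNA) sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- vapply(strsplit(chartr("uU", "tT", x), "", fixed = TRUE),
                function(ch) paste(rev(ch), collapse = ""), character(1))
  out <- chartr("acgtnACGTN", "TGCANTGCAN", out)
  gsub("[^ACGTN]", "N", out)
}

# Extract [start, end) of a sequence, 0-based half-open.
seq_sub <- function(sequence, start, end) {
  substring(sequence, start + 1L, end)
}

# Strand-aware extraction: reverse-strand extraction equals the reverse
# complement of the forward extraction on the same interval.
seq_sub_strand <- function(sequence, start, end, strand) {
  s <- seq_sub(sequence, start, end)
  ifelse(strand == "-", revcomp(s), s)
}

#' @keywords internal
normalize_dna <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    warning(sum(vapply(gregexpr("[^ACGTN]", x[bad]),
                       function(m) sum(m > 0L), integer(1))),
            " non-ACGTN letter(s) mapped to N")
    x <- gsub("[^ACGTN]", "N", x)
  }
  x
}

# Translate an in-frame DNA string with the standard bacterial code.
# Alternative starts (GTG/TTG) translate as M when `initiator = TRUE`.
# Returns NA if the sequence contains N inside a codon.
translate_cds <- function(dna, initiator = TRUE) {
  n <- nchar(dna)
  if (n %% 3L != 0L || n == 0L) stop("sequence length not a codon multiple")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  if (any(grepl("N", codons, fixed = TRUE))) return(NA_character_)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) return(NA_character_)
  if (initiator && codons[1L] %in% c("ATG", "GTG", "TTG")) aa[1L] <- "M"
  paste(aa, collapse = "")
}

# Distance helpers -----------------------------------------------------------

# Strand-aware distance from a TSS to a TLS (>= 0 when the TLS lies
# downstream of the TSS in transcription direction).  0 means the transcript
# starts at the start codon (leaderless).
tss_tls_distance <- function(tss_pos, tls_pos, strand) {
  d <- tls_pos - tss_pos
  strand <- rep_len(strand, length(d))
  ifelse(strand == "-", -d, d)
}

# First base of the start codon of a feature, strand-aware.
feature_tls <- function(start, end, strand) {
  ifelse(strand == "-", end - 1L, start)
}
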