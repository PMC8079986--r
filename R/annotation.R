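# GenomeAnnotation: the container every stage acts on.  A single replicon
# (bacterial chromosome), its sequence, and an ordered feature table.

FEATURE_KINDS <- c("CDS", "rRNA", "tRNA", "ncRNA", "leader_peptide")

#' Construct a genome annotation
#'
#' Bundles a replicon sequence with a typed feature table. Internally all
#' coordinates are 0-based half-open; `start < end` always, and "upstream"
#' on the reverse strand means larger coordinate.
#'
#' @param sequence_id single replicon identifier.
#' @param sequence DNA string over `A/C/G/T/N` (uppercased on input).
#' @param features `data.frame` with columns `feature_id`, `kind` (one of
#'   `CDS`, `rRNA`, `tRNA`, `ncRNA`, `leader_peptide`), `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`) and `product`.
#' @return an object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(sequence_id, sequence, features = empty_features()) {
  sequence <- normalize_dna(sequence)
  obj <- structure(list(sequence_id = as.character(sequence_id),
                        sequence = sequence,
                        features = as_feature_table(features)),
                  class = "GenomeAnnotation")
  validate_annotation(obj)
}

#' @export
empty_features <- function() {
  data.frame(feature_id = character(0), kind = character(0),
             start = integer(0), end = integer(0),
             strand = character(0), product = character(0),
             stringsAsFactors = FALSE)
}

as_feature_table <- function(features) {
  needed <- c("feature_id", "kind", "start", "end", "strand", "product")
  if (!("product" %in% names(features))) features$product <- ""
  missing <- setdiff(needed, names(features))
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  features <- features[needed]
  features$feature_id <- as.character(features$feature_id)
  features$kind <- as.character(features$kind)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.character(features$strand)
  features$product <- as.character(features$product)
  features <- features[order(features$start, features$strand), , drop = FALSE]
  rownames(features) <- NULL
  features
}

validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  len <- nchar(ann$sequence)
  if (len == 0L) stop("empty genome sequence")
  ft <- ann$features
  if (nrow(ft)) {
    if (anyDuplicated(ft$feature_id))
      stop("duplicate feature_id: ",
           ft$feature_id[anyDuplicated(ft$feature_id)])
    if (!all(ft$kind %in% FEATURE_KINDS))
      stop("unknown feature kind: ",
           paste(unique(setdiff(ft$kind, FEATURE_KINDS)), collapse = ", "))
    if (any(ft$start < 0L) || any(ft$start >= ft$end))
      stop("invalid feature interval (need 0 <= start < end)")
    if (any(ft$end > len))
      stop("feature interval beyond sequence length for: ",
           paste(ft$feature_id[ft$end > len], collapse = ", "))
    if (!all(ft$strand %in% c("+", "-")))
      stop("feature strand must be '+' or '-'")
    bad_frame <- ft$kind == "CDS" & (ft$end - ft$start) %% 3L != 0L
    if (any(bad_frame))
      warning("CDS length not divisible by 3 (flagged, not rejected): ",
              paste(ft$feature_id[bad_frame], collapse = ", "))
  }
  ann
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", x$sequence_id,
      sprintf("(%s nt, %d features)\n", format(nchar(x$sequence), big.mark = ","),
              nrow(x$features)))
  if (nrow(x$features)) print(table(x$features$kind))
  invisible(x)
}

#' Genome length of an annotation
#' @param ann a `GenomeAnnotation`.
#' @return integer sequence length.
#' @export
genome_length <- function(ann) nchar(ann$sequence)

# FASTA ----------------------------------------------------------------------

#' Read a genome sequence from FASTA
#'
#' Sequences are uppercased; letters outside `A/C/G/T/N` are mapped to `N`
#' with a warning. For a multi-record file the first record is used as the
#' replicon unless `record` names another id.
#'
#' @param path FASTA file.
#' @param record optional record id to select.
#' @return a `GenomeAnnotation` with an empty feature table.
#' @export
read_fasta <- function(path, record = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate FASTA record ids in ", path)
  i <- if (is.null(record)) 1L else match(record, ids)
  if (is.na(i)) stop("record not found in FASTA: ", record)
  genome_annotation(ids[i], as.character(seqs[[i]]))
}

#' Write a genome sequence to FASTA
#' @param ann a `GenomeAnnotation`.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(ann, path, width = 70L) {
  dna <- Biostrings::DNAStringSet(ann$sequence)
  names(dna) <- ann$sequence_id
  Biostrings::writeXStringSet(dna, path, width = width)
  invisible(path)
}

# GFF3 -----------------------------------------------------------------------

# GFF3 'type' <-> internal 'kind'; unknown types fall through as ncRNA.
GFF_TYPE_MAP <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                  ncRNA = "ncRNA", leader_peptide = "leader_peptide")

#' Read genome features from GFF3
#'
#' Parses CDS/rRNA/tRNA/ncRNA/leader_peptide features and converts the
#' 1-based inclusive GFF3 coordinates to the internal 0-based half-open
#' convention. Feature ids come from the `ID=` attribute (or
#' `locus_tag=`), products from `product=`.
#'
#' @param path GFF3 file.
#' @param ann optional `GenomeAnnotation` carrying the sequence; features
#'   are attached to it (and validated against its length).
#' @param sequence_length used for validation when `ann` is absent.
#' @return feature `data.frame` (if `ann` is `NULL`) or the annotation with
#'   features attached.
#' @export
read_gff3 <- function(path, ann = NULL, sequence_length = NULL) {
  gff <- ape::read.gff(path, GFF3 = TRUE)
  gff <- gff[gff$type %in% names(GFF_TYPE_MAP), , drop = FALSE]
  if (nrow(gff)) {
    bad <- which(gff$start > gff$end)
    if (length(bad))
      stop("GFF3 start > end for feature on line(s): ",
           paste(bad, collapse = ", "))
    if (!all(as.character(gff$strand) %in% c("+", "-")))
      stop("unknown strand symbol in GFF3 (need '+' or '-'): ",
           paste(setdiff(unique(as.character(gff$strand)), c("+", "-")),
                 collapse = ", "))
  }
  attr_field <- function(attrs, key) {
    vapply(regmatches(attrs, gregexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attrs)),
           function(v) if (length(v)) sub(paste0(".*", key, "="), "", v[1])
                       else NA_character_,
           character(1))
  }
  ids <- attr_field(gff$attributes, "ID")
  lt <- attr_field(gff$attributes, "locus_tag")
  ids[is.na(ids)] <- lt[is.na(ids)]
  ids[is.na(ids)] <- sprintf("feature_%04d", which(is.na(ids)))
  prod <- attr_field(gff$attributes, "product")
  prod[is.na(prod)] <- ""
  features <- data.frame(
    feature_id = ids,
    kind = unname(GFF_TYPE_MAP[as.character(gff$type)]),
    start = as.integer(gff$start) - 1L,   # to 0-based half-open
    end = as.integer(gff$end),
    strand = as.character(gff$strand),
    product = prod,
    stringsAsFactors = FALSE)
  if (!is.null(ann)) {
    ann$features <- as_feature_table(features)
    return(validate_annotation(ann))
  }
  if (!is.null(sequence_length) && nrow(features) &&
      any(features$end > sequence_length))
    stop("feature interval beyond sequence length")
  as_feature_table(features)
}

#' Write genome features to GFF3
#'
#' Converts internal 0-based half-open coordinates back to 1-based
#' inclusive. Output order is deterministic (start, then strand).
#'
#' @param ann a `GenomeAnnotation`.
#' @param path output file.
#' @param source value of the GFF3 source column.
#' @export
write_gff3 <- function(ann, path, source = "primarytx") {
  ft <- ann$features
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", ann$sequence_id,
                     genome_length(ann)), con)
  if (nrow(ft)) {
    attrs <- sprintf("ID=%s", ft$feature_id)
    has_prod <- !is.na(ft$product) & nzchar(ft$product)
    attrs[has_prod] <- paste0(attrs[has_prod], ";product=", ft$product[has_prod])
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                       ann$sequence_id, source, ft$kind,
                       ft$start + 1L, ft$end, ft$strand,
                       ifelse(ft$kind == "CDS", "0", "."), attrs), con)
  }
  invisible(path)
}
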