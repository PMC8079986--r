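# Operon inference from whole-transcriptome reads that bridge intergenic
# junctions, sub-operon splitting at internal TSS, and the monocistronic
# remainder.

#' Count reads bridging one intergenic junction
#'
#' A read bridges the junction between two genomically adjacent same-strand
#' genes iff its interval covers both the last base of the upstream gene
#' and the first base of the downstream gene (the entire gap). When the
#' genes overlap the gap is empty and every read covering the junction
#' base (the downstream gene's first base) counts.
#'
#' @param gene_a,gene_b single feature rows (lists/one-row data.frames with
#'   `start`, `end`, `strand`), `gene_a` genomically left of `gene_b`.
#' @param reads data.frame of read intervals: `start`, `end` (0-based
#'   half-open), `strand`.
#' @return integer bridging-read count.
#' @export
count_bridging_reads <- function(gene_a, gene_b, reads) {
  if (gene_a$strand != gene_b$strand)
    stop("bridging is defined for same-strand gene pairs")
  if (gene_a$start > gene_b$start) { tmp <- gene_a; gene_a <- gene_b; gene_b <- tmp }
  left <- gene_a$end - 1L          # last base of upstream gene
  right <- gene_b$start            # first base of downstream gene
  if (right < gene_a$end) { left <- right }   # overlapping genes: junction base
  same <- reads$strand == gene_a$strand
  sum(same & reads$start <= left & reads$end > right)
}

#' Bridging-read counts for all same-strand adjacent gene pairs
#'
#' Adjacency is consecutive position in genomic order over the given
#' feature kinds; an interleaved opposite-strand gene breaks the chain.
#'
#' @param ann `GenomeAnnotation`.
#' @param reads read-interval data.frame (see [count_bridging_reads()]).
#' @param kinds feature kinds considered (default CDS).
#' @return data.frame `gene_a, gene_b, strand, count`.
#' @export
bridging_counts <- function(ann, reads, kinds = "CDS") {
  ft <- ann$features[ann$features$kind %in% kinds, , drop = FALSE]
  ft <- ft[order(ft$start), , drop = FALSE]
  if (nrow(ft) < 2L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      strand = character(0), count = integer(0)))
  i <- seq_len(nrow(ft) - 1L)
  same <- ft$strand[i] == ft$strand[i + 1L]
  out <- data.frame(gene_a = ft$feature_id[i][same],
                    gene_b = ft$feature_id[i + 1L][same],
                    strand = ft$strand[i][same],
                    count = 0L, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    a <- ft[match(out$gene_a[k], ft$feature_id), ]
    b <- ft[match(out$gene_b[k], ft$feature_id), ]
    out$count[k] <- count_bridging_reads(a, b, reads)
  }
  out
}

#' Infer primary operons, sub-operons and monocistronic genes
#'
#' Adjacent same-strand genes are linked when their bridging count reaches
#' `bridging_reads_min`; maximal linked chains of >= 2 genes are primary
#' operons (gene order follows transcription direction). An operon is
#' `validated` iff its first gene carries an assigned primary/secondary
#' TSS. Every internal gene (index >= 2) with an assigned TSS spawns a
#' sub-operon consisting of that gene and all following genes. Unlinked
#' genes are monocistronic.
#'
#' @param ann `GenomeAnnotation`.
#' @param bridging data.frame `gene_a, gene_b, count` (from
#'   [bridging_counts()] or an external table).
#' @param tss classified TSS table (may be empty).
#' @param config a [detection_config()].
#' @param kinds feature kinds considered.
#' @return list `operons` (list of `Operon`s: `gene_ids`, `strand`,
#'   `validated`, `sub_operons`) and `monocistronic` (character vector).
#' @export
infer_operons <- function(ann, bridging, tss = NULL,
                          config = detection_config(), kinds = "CDS") {
  ft <- ann$features[ann$features$kind %in% kinds, , drop = FALSE]
  ft <- ft[order(ft$start), , drop = FALSE]
  assigned <- if (!is.null(tss) && nrow(tss))
    unique(tss$assigned_feature_id[tss$tss_class %in% c("primary", "secondary")])
  else character(0)
  linked <- bridging[bridging$count >= config$bridging_reads_min, ,
                     drop = FALSE]
  # chain genes along genomic order
  n <- nrow(ft)
  link_next <- logical(max(n - 1L, 0L))
  if (n >= 2L) {
    i <- seq_len(n - 1L)
    key <- paste(ft$feature_id[i], ft$feature_id[i + 1L])
    link_next <- key %in% paste(linked$gene_a, linked$gene_b) &
      ft$strand[i] == ft$strand[i + 1L]
  }
  comp <- cumsum(c(1L, !link_next))
  operons <- list()
  mono <- character(0)
  for (idx in split(seq_len(n), comp)) {
    if (length(idx) < 2L) { mono <- c(mono, ft$feature_id[idx]); next }
    strand <- ft$strand[idx[1L]]
    genes <- ft$feature_id[idx]
    if (strand == "-") genes <- rev(genes)   # transcription order
    sub <- list()
    for (k in seq_along(genes)[-1L]) {
      if (genes[k] %in% assigned)
        sub[[length(sub) + 1L]] <- list(start_gene_index = k,
                                        gene_ids = genes[k:length(genes)])
    }
    operons[[length(operons) + 1L]] <- structure(
      list(gene_ids = genes, strand = strand,
           validated = genes[1L] %in% assigned, sub_operons = sub),
      class = "Operon")
  }
  list(operons = operons, monocistronic = mono)
}

#' Summarise an operon map
#'
#' @param operon_map output of [infer_operons()].
#' @return list of counts: primary operons, validated operons, sub-operons,
#'   genes in operons, monocistronic genes, largest operon size.
#' @export
operon_summary <- function(operon_map) {
  ops <- operon_map$operons
  sizes <- vapply(ops, function(o) length(o$gene_ids), integer(1))
  list(operons = length(ops),
       validated = sum(vapply(ops, function(o) o$validated, logical(1))),
       sub_operons = sum(vapply(ops, function(o) length(o$sub_operons),
                                integer(1))),
       genes_in_operons = sum(sizes),
       monocistronic = length(operon_map$monocistronic),
       largest = if (length(sizes)) max(sizes) else 0L)
}

#' Export an operon map as TSV
#' @param operon_map output of [infer_operons()].
#' @param path output file.
#' @export
write_operons_tsv <- function(operon_map, path) {
  ops <- operon_map$operons
  rows <- lapply(seq_along(ops), function(i) {
    o <- ops[[i]]
    data.frame(operon_id = sprintf("operon_%04d", i),
               strand = o$strand, n_genes = length(o$gene_ids),
               validated = o$validated,
               genes = paste(o$gene_ids, collapse = ","),
               sub_operons = paste(vapply(o$sub_operons, function(s)
                 paste(s$gene_ids, collapse = "|"), character(1)),
                 collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(operon_id = character(0), strand = character(0),
               n_genes = integer(0), validated = logical(0),
               genes = character(0), sub_operons = character(0))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export operons as GFF3 `operon` features
#' @param operon_map output of [infer_operons()].
#' @param ann the `GenomeAnnotation` the operons refer to.
#' @param path output file.
#' @export
write_operons_gff3 <- function(operon_map, ann, path) {
  ft <- ann$features
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(operon_map$operons)) {
    o <- operon_map$operons[[i]]
    rows <- ft[match(o$gene_ids, ft$feature_id), ]
    writeLines(sprintf(
      "%s\tprimarytx\toperon\t%d\t%d\t.\t%s\t.\tID=operon_%04d;genes=%s;validated=%s",
      ann$sequence_id, min(rows$start) + 1L, max(rows$end), o$strand, i,
      paste(o$gene_ids, collapse = ","), tolower(o$validated)), con)
  }
  invisible(path)
}
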