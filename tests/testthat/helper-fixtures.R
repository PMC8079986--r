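# Shared fixture builders. Everything is generated in code; no stored data.

# A small annotation: two forward CDS, one reverse CDS, one reverse tRNA.
#   f1: CDS + [100, 400)   f2: CDS + [500, 800)
#   r1: CDS - [900, 1200)  t1: tRNA - [1300, 1375)
make_toy_annotation <- function(len = 1500L, seed = 101L) {
  set.seed(seed)
  seqn <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                       prob = c(0.14, 0.36, 0.36, 0.14)), collapse = "")
  features <- data.frame(
    feature_id = c("f1", "f2", "r1", "t1"),
    kind = c("CDS", "CDS", "CDS", "tRNA"),
    start = c(100L, 500L, 900L, 1300L),
    end = c(400L, 800L, 1200L, 1375L),
    strand = c("+", "+", "-", "-"),
    product = c("", "", "", ""))
  genome_annotation("toy", seqn, features)
}

# A profile with read-start stacks at the given positions (0-based).
make_stack_profile <- function(len, fwd_stacks = integer(0),
                               rev_stacks = integer(0),
                               heights = 50L) {
  fwd <- numeric(len); rev <- numeric(len)
  if (length(fwd_stacks))
    fwd[fwd_stacks + 1L] <- rep_len(heights, length(fwd_stacks))
  if (length(rev_stacks))
    rev[rev_stacks + 1L] <- rep_len(heights, length(rev_stacks))
  strand_profile(fwd, rev)
}

# Independent brute-force TSS oracle: per-position double loop with the
# threshold arithmetic written out longhand.
oracle_detect <- function(profile, min_starts, pct) {
  hits <- list()
  for (strand in c("+", "-")) {
    rs <- if (strand == "+") profile$read_starts_fwd else profile$read_starts_rev
    for (i in seq_along(rs)) {
      up <- if (strand == "+") {
        if (i == 1L) 0 else rs[i - 1L]
      } else {
        if (i == length(rs)) 0 else rs[i + 1L]
      }
      inc <- 100 * (rs[i] - up) / max(up, 1)
      if (rs[i] >= min_starts && inc >= pct)
        hits[[length(hits) + 1L]] <- data.frame(position = i - 1L,
                                                strand = strand)
    }
  }
  if (!length(hits)) return(data.frame(position = integer(0),
                                       strand = character(0)))
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), , drop = FALSE]
}

# Brute-force stem-loop oracle: enumerate every (start, stem, loop) triple.
oracle_terminator <- function(window, min_stem = 6L, loop_range = c(3L, 9L),
                              u_window = 10L, min_u = 3L) {
  ch <- strsplit(toupper(window), "")[[1L]]
  comp <- chartr("ACGTN", "TGCAN", ch)
  L <- length(ch)
  hits <- list()
  for (i in seq_len(L)) {
    for (stem in min_stem:max(min_stem, L)) {
      for (loop in loop_range[1L]:loop_range[2L]) {
        e2 <- i + 2L * stem + loop - 1L
        if (e2 > L) next
        s1 <- i; e1 <- i + stem - 1L; s2 <- e1 + loop + 1L
        if (any(ch[s1:e1] == "N")) next
        if (!all(ch[s1:e1] == rev(comp[s2:e2]))) next
        u_end <- min(L, e2 + u_window)
        u_len <- if (u_end > e2) sum(ch[(e2 + 1L):u_end] == "T") else 0L
        hits[[length(hits) + 1L]] <-
          data.frame(position = i - 1L, stem_length = stem,
                     loop_length = loop, u_stretch_length = u_len)
      }
    }
  }
  if (!length(hits)) return(NULL)
  tab <- do.call(rbind, hits)
  canon <- tab[tab$u_stretch_length >= min_u, , drop = FALSE]
  pool <- if (nrow(canon)) canon else tab
  pool <- pool[order(-pool$stem_length, pool$position), , drop = FALSE]
  list(best = pool[1L, ], canonical = nrow(canon) > 0L)
}

# Brute-force forward-strand ORF oracle over every (start, frame) pair.
oracle_orfs <- function(seqn, min_aa = 8L, max_aa = 35L) {
  seqn <- toupper(seqn)
  L <- nchar(seqn)
  starts <- c("ATG", "GTG", "TTG"); stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (s in seq_len(max(L - 2L, 0L))) {
    if (!substr(seqn, s, s + 2L) %in% starts) next
    i <- s
    repeat {
      if (i + 2L > L) break
      codon <- substr(seqn, i, i + 2L)
      if (grepl("N", codon)) break
      if (codon %in% stops) {
        len_aa <- (i - s) %/% 3L
        if (len_aa >= min_aa && len_aa <= max_aa)
          rows[[length(rows) + 1L]] <- data.frame(start = s - 1L,
                                                  end = i + 2L,
                                                  length_aa = len_aa)
        break
      }
      i <- i + 3L
    }
  }
  if (!length(rows)) return(data.frame(start = integer(0), end = integer(0),
                                       length_aa = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}
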