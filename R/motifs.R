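# Promoter (-10/-35) and ribosome-binding-site motif discovery.
#
# The search is a fixed-width ZOOPS (zero-or-one occurrence per sequence)
# EM over placement offsets, restricted so that the distance between the
# motif's 3' end and the anchor (TSS for promoters, TLS for the RBS) lies
# in a configured spacer range. Background is a 0-order model estimated
# from the input; several seeded random restarts are run and the best
# log-likelihood wins.

DNA_BASES <- c("A", "C", "G", "T")

#' Extract anchor-upstream sequence windows
#'
#' Each window is the `window` nt immediately upstream of the anchor,
#' reported 5'->3' on the anchor's strand (reverse-strand anchors yield
#' reverse-complemented windows). The last base of a window is adjacent to
#' the anchor. Windows truncated at a chromosome edge are flagged.
#'
#' @param positions anchor coordinates (0-based; e.g. TSS or TLS).
#' @param strands `"+"`/`"-"` per anchor.
#' @param ann `GenomeAnnotation` (or a plain sequence string).
#' @param window window length in nt.
#' @return data.frame `position, strand, sequence, truncated`.
#' @export
extract_windows <- function(positions, strands, ann, window) {
  sequence <- if (inherits(ann, "GenomeAnnotation")) ann$sequence else ann
  len <- nchar(sequence)
  stopifnot(length(positions) == length(strands),
            all(positions >= 0L), all(positions < len))
  n <- length(positions)
  seqs <- character(n); trunc <- logical(n)
  for (i in seq_len(n)) {
    p <- positions[i]
    if (strands[i] == "+") {
      a <- max(0L, p - window); b <- p
      trunc[i] <- (p - window) < 0L
      seqs[i] <- seq_sub(sequence, a, b)
    } else {
      a <- p + 1L; b <- min(len, p + 1L + window)
      trunc[i] <- (p + 1L + window) > len
      seqs[i] <- revcomp(seq_sub(sequence, a, b))
    }
  }
  data.frame(position = positions, strand = strands, sequence = seqs,
             truncated = trunc, stringsAsFactors = FALSE)
}

# Map sequences to integer codes 1..4 (A,C,G,T); 0 for N/other.
encode_dna <- function(seqs) {
  lapply(strsplit(seqs, "", fixed = TRUE), function(ch) {
    m <- match(ch, DNA_BASES)
    m[is.na(m)] <- 0L
    m
  })
}

# Allowed 0-based placement offsets of a width-w motif in a sequence of
# length L such that the 3'-end-to-anchor distance d = L - off - w lies in
# spacer_range. Offsets whose window contains N are dropped.
allowed_offsets <- function(code, width, spacer_range) {
  L <- length(code)
  d <- spacer_range[1L]:spacer_range[2L]
  off <- L - d - width
  off <- off[off >= 0L]
  off[vapply(off, function(o) all(code[(o + 1L):(o + width)] > 0L),
             logical(1))]
}

#' ZOOPS EM motif search
#'
#' @param sequences character vector of equal-orientation windows (each
#'   ending adjacent to its anchor).
#' @param width motif width.
#' @param spacer_range integer `c(min, max)` distance between the motif 3'
#'   end and the anchor.
#' @param config a [motif_search_config()] supplying `em_restarts`,
#'   `max_iter`, `pseudocount` and `seed`.
#' @return a `MotifModel`: `width`, `pfm` (4 x width, columns sum to 1),
#'   `consensus` (letters with column frequency >= 0.5, else `n`),
#'   `placements` (0-based best offsets, `NA` when the best posterior is
#'   below 0.5), `spacers` (anchor distances of placed sequences),
#'   `spacer_distribution`, `gamma` (motif prevalence), `background`,
#'   `loglik` and the per-iteration `ll_trace`.
#' @export
em_find_motif <- function(sequences, width = 6L,
                          spacer_range = c(4L, 9L),
                          config = motif_search_config()) {
  if (length(sequences) < 10L)
    stop("need at least 10 sequences, got ", length(sequences))
  need <- width + max(spacer_range)
  short <- which(nchar(sequences) < need)
  if (length(short))
    stop("sequence(s) shorter than width + max spacer (", need, " nt): ",
         paste(utils::head(short, 10L), collapse = ", "))
  codes <- encode_dna(toupper(sequences))
  offs <- lapply(codes, allowed_offsets, width = width,
                 spacer_range = spacer_range)
  usable <- lengths(offs) > 0L
  if (!any(usable)) stop("no N-free placement window in any sequence")

  # flat (sequence, offset) design: rows index candidate placements
  seq_idx <- rep(seq_along(codes)[usable], lengths(offs)[usable])
  off_flat <- unlist(offs[usable])
  pos_mat <- matrix(0L, nrow = length(seq_idx), ncol = width)
  for (k in seq_len(width))
    pos_mat[, k] <- vapply(seq_along(seq_idx), function(r)
      codes[[seq_idx[r]]][off_flat[r] + k], integer(1))
  n_seq <- length(codes)
  rows_of_seq <- split(seq_along(seq_idx), seq_idx)

  all_bases <- unlist(codes)
  all_bases <- all_bases[all_bases > 0L]
  background <- as.numeric(table(factor(all_bases, levels = 1:4)))
  background <- (background + 1) / sum(background + 1)

  log_bg_row <- rowSums(matrix(log(background)[pos_mat], ncol = width))

  run_em <- function(init_theta = NULL) {
    theta <- if (is.null(init_theta)) {
      matrix(stats::runif(4L * width, 0.5, 1.5), nrow = 4L)
    } else init_theta
    theta <- sweep(theta, 2L, colSums(theta), "/")
    gamma <- 0.5
    ll_trace <- numeric(0)
    z_rows <- NULL
    for (iter in seq_len(config$max_iter)) {
      log_theta <- log(theta)
      log_motif_row <- rowSums(matrix(log_theta[cbind(
        as.vector(pos_mat), rep(seq_len(width), each = nrow(pos_mat)))],
        ncol = width))
      # per-row joint weight of "motif at this offset"
      ll <- 0
      z_rows <- numeric(length(seq_idx))
      nk <- lengths(rows_of_seq)
      for (si in seq_along(rows_of_seq)) {
        rows <- rows_of_seq[[si]]
        lw <- log(gamma / nk[si]) + log_motif_row[rows] - log_bg_row[rows]
        m <- max(lw, 0)   # include the null (log weight log(1-gamma) rel.)
        w_motif <- exp(lw - m)
        w_null <- exp(log(1 - gamma) - m)
        tot <- w_null + sum(w_motif)
        z_rows[rows] <- w_motif / tot
        ll <- ll + m + log(tot)
      }
      # the objective EM ascends is the pseudocount-penalised (MAP)
      # log-likelihood; the raw LL alone may dip by O(pseudocount)
      ll_pen <- ll + config$pseudocount * sum(log(theta))
      ll_trace <- c(ll_trace, ll_pen)
      if (iter > 1L) {
        prev <- ll_trace[iter - 1L]
        if (ll_pen < prev - 1e-8 * (abs(prev) + 1))
          stop("EM objective decreased")   # invariant, never expected
        if (ll_pen - prev < 1e-8 * (abs(prev) + 1)) break
      }
      # M-step
      counts <- matrix(config$pseudocount, nrow = 4L, ncol = width)
      for (k in seq_len(width)) {
        t <- tapply(z_rows, factor(pos_mat[, k], levels = 1:4), sum)
        t[is.na(t)] <- 0
        counts[, k] <- counts[, k] + as.numeric(t)
      }
      theta <- sweep(counts, 2L, colSums(counts), "/")
      gamma <- min(max(sum(z_rows) / sum(usable), 1e-6), 1 - 1e-6)
    }
    list(theta = theta, gamma = gamma, ll = ll_trace[length(ll_trace)],
         ll_raw = ll, ll_trace = ll_trace, z_rows = z_rows)
  }

  best <- NULL
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  # Restarts alternate between random position-frequency initialisations
  # and substring seeding (a candidate placement window drawn from the
  # data, its letters up-weighted), which starts EM in the basin of
  # actually occurring words.
  for (r in seq_len(config$em_restarts)) {
    init <- NULL
    if (r %% 2L == 0L) {
      row <- sample.int(nrow(pos_mat), 1L)
      init <- matrix(0.15, nrow = 4L, ncol = width)
      init[cbind(pos_mat[row, ], seq_len(width))] <- 0.55
    }
    fit <- run_em(init)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }

  # final responsibilities -> placements, PFM
  placements <- rep(NA_integer_, n_seq)
  placement_prob <- rep(NA_real_, n_seq)
  for (si in seq_along(rows_of_seq)) {
    rows <- rows_of_seq[[si]]
    z <- best$z_rows[rows]
    j <- which.max(z)
    i_seq <- as.integer(names(rows_of_seq)[si])
    placement_prob[i_seq] <- z[j]
    if (z[j] >= 0.5) placements[i_seq] <- off_flat[rows[j]]
  }
  counts <- matrix(config$pseudocount, nrow = 4L, ncol = width)
  for (k in seq_len(width)) {
    t <- tapply(best$z_rows, factor(pos_mat[, k], levels = 1:4), sum)
    t[is.na(t)] <- 0
    counts[, k] <- counts[, k] + as.numeric(t)
  }
  pfm <- sweep(counts, 2L, colSums(counts), "/")
  rownames(pfm) <- DNA_BASES
  consensus <- paste(vapply(seq_len(width), function(k) {
    j <- which.max(pfm[, k])
    if (pfm[j, k] >= 0.5) DNA_BASES[j] else "n"
  }, character(1)), collapse = "")
  spacers <- nchar(sequences) - placements - width
  structure(list(width = width, pfm = pfm, consensus = consensus,
                 placements = placements, placement_prob = placement_prob,
                 spacers = spacers,
                 spacer_distribution = table(spacers[!is.na(spacers)]),
                 gamma = best$gamma,
                 background = stats::setNames(background, DNA_BASES),
                 loglik = best$ll, ll_trace = best$ll_trace,
                 n_sequences = n_seq),
            class = "MotifModel")
}

#' @export
print.MotifModel <- function(x, ...) {
  cat(sprintf("MotifModel: width %d, consensus %s, %d/%d placed (gamma %.2f)\n",
              x$width, x$consensus, sum(!is.na(x$placements)),
              x$n_sequences, x$gamma))
  print(round(x$pfm, 3))
  invisible(x)
}

#' Fraction of sequences matching a fixed consensus pattern
#'
#' A sequence is a hit iff a window matching `pattern` (over `ACGTn`, `n`
#' matching any base) sits at an anchor distance within `spacer_range`.
#'
#' @param sequences anchor-upstream windows (as in [em_find_motif()]).
#' @param pattern consensus string, e.g. `"TAnnnT"`.
#' @param spacer_range allowed anchor distances of the pattern's 3' end.
#' @return list `fraction`, `hits` (logical), `offsets` (0-based offset of
#'   the most anchor-proximal match, `NA` if none).
#' @export
match_pattern_fraction <- function(sequences, pattern,
                                   spacer_range = c(4L, 9L)) {
  if (!nzchar(pattern)) stop("empty pattern")
  pat <- strsplit(toupper(pattern), "")[[1L]]
  if (!all(pat %in% c(DNA_BASES, "N"))) stop("pattern must be over ACGTn")
  w <- length(pat)
  fixed <- pat != "N"
  hits <- logical(length(sequences))
  offsets <- rep(NA_integer_, length(sequences))
  for (i in seq_along(sequences)) {
    ch <- strsplit(toupper(sequences[i]), "")[[1L]]
    L <- length(ch)
    for (d in spacer_range[1L]:spacer_range[2L]) {
      o <- L - d - w
      if (o < 0L) next
      if (all(ch[(o + 1L):(o + w)][fixed] == pat[fixed])) {
        hits[i] <- TRUE
        offsets[i] <- o
        break   # most anchor-proximal match (smallest spacer)
      }
    }
  }
  list(fraction = mean(hits), hits = hits, offsets = offsets)
}

#' Spacer statistics of a motif model
#'
#' @param model a `MotifModel`.
#' @return list `mean`, `range`, `histogram` over placed sequences, or a
#'   `no_placements = TRUE` marker when nothing was placed.
#' @export
spacer_stats <- function(model) {
  sp <- model$spacers[!is.na(model$spacers)]
  if (!length(sp)) return(list(no_placements = TRUE))
  list(no_placements = FALSE, mean = mean(sp), range = range(sp),
       histogram = table(sp), n = length(sp))
}

#' Ribosome-binding-site discovery
#'
#' Selects CDS that carry a primary TSS with a 5'-UTR in `rbs_utr_range`,
#' extracts `rbs_window` nt upstream of each TLS, and runs the ZOOPS EM
#' with `rbs_spacer` anchor distances.
#'
#' @param ann `GenomeAnnotation`.
#' @param tss classified TSS table.
#' @param config a [motif_search_config()].
#' @return list `model` (`MotifModel`), `placement_fraction`,
#'   `spacer` ([spacer_stats()]), `n_sequences`; or
#'   `insufficient_data = TRUE` when fewer than 10 CDS qualify.
#' @export
find_rbs <- function(ann, tss, config = motif_search_config()) {
  prim <- tss[tss$tss_class == "primary" & !is.na(tss$utr_length) &
              tss$utr_length >= config$rbs_utr_range[1L] &
              tss$utr_length <= config$rbs_utr_range[2L], , drop = FALSE]
  ft <- ann$features
  keep <- ft$feature_id %in% prim$assigned_feature_id & ft$kind == "CDS"
  cds <- ft[keep, , drop = FALSE]
  if (nrow(cds) < 10L)
    return(list(insufficient_data = TRUE, n_sequences = nrow(cds)))
  tls <- feature_tls(cds$start, cds$end, cds$strand)
  win <- extract_windows(tls, cds$strand, ann, config$rbs_window)
  model <- em_find_motif(win$sequence, width = config$width,
                         spacer_range = config$rbs_spacer, config = config)
  list(insufficient_data = FALSE, model = model,
       placement_fraction = mean(!is.na(model$placements)),
       spacer = spacer_stats(model), n_sequences = nrow(cds),
       feature_ids = cds$feature_id)
}

#' Longest contiguous reverse-complement match between two sequences
#'
#' Maximal `L` such that some length-`L` substring of `seq_a` is the
#' reverse complement of a substring of `seq_b` (both given 5'->3'; `U`
#' treated as `T`). Used to quantify anti-Shine-Dalgarno complementarity
#' between an RBS consensus and the 16S rRNA 3' tail.
#'
#' @param seq_a,seq_b DNA/RNA strings.
#' @return integer match length (0 for empty input).
#' @export
longest_complement <- function(seq_a, seq_b) {
  a <- toupper(chartr("uU", "tT", seq_a))
  b <- if (nchar(seq_b)) revcomp(seq_b) else ""
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) return(0L)
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  best <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    for (j in seq_len(nb)) {
      if (av[i] == bv[j]) cur[j] <- (if (j > 1L) prev[j - 1L] else 0L) + 1L
    }
    best <- max(best, cur)
    prev <- cur
  }
  as.integer(best)
}

#' Promoter motif discovery around primary TSS
#'
#' Runs the -10 search on `promoter_window`-nt windows upstream of each
#' primary TSS, then the -35 search on the window parts upstream of each
#' -10 placement (anchored on the -10 element), separately for leaderless
#' and leadered TSS. Also reports the exact `TAnnnT` match fraction.
#'
#' @param ann `GenomeAnnotation`.
#' @param tss classified TSS table.
#' @param config a [motif_search_config()].
#' @return nested list with `leaderless` and `leadered` components, each
#'   holding `minus10` (`MotifModel` or insufficient-data marker),
#'   `minus35`, `tannnt` (match fraction) and `n`.
#' @export
find_promoter_motifs <- function(ann, tss, config = motif_search_config()) {
  prim <- tss[tss$tss_class == "primary", , drop = FALSE]
  out <- list()
  for (group in c("leaderless", "leadered")) {
    sel <- if (group == "leaderless") isTRUE_vec(prim$leaderless)
           else !isTRUE_vec(prim$leaderless)
    sub <- prim[sel, , drop = FALSE]
    res <- list(n = nrow(sub))
    if (nrow(sub) < 10L) {
      res$insufficient_data <- TRUE
      out[[group]] <- res
      next
    }
    win <- extract_windows(sub$position, sub$strand, ann,
                           config$promoter_window)
    win <- win[!win$truncated, , drop = FALSE]
    m10 <- em_find_motif(win$sequence, width = config$width,
                         spacer_range = config$minus10_spacer,
                         config = config)
    res$minus10 <- m10
    res$minus10_spacer <- spacer_stats(m10)
    res$tannnt <- match_pattern_fraction(win$sequence, "TAnnnT",
                                         config$minus10_spacer)$fraction
    # -35: anchored on the -10 placement
    placed <- which(!is.na(m10$placements))
    sub35 <- substring(win$sequence[placed], 1L, m10$placements[placed])
    need <- config$width + max(config$minus35_spacer)
    sub35 <- sub35[nchar(sub35) >= need]
    if (length(sub35) >= 10L) {
      m35 <- em_find_motif(sub35, width = config$width,
                           spacer_range = config$minus35_spacer,
                           config = config)
      res$minus35 <- m35
      res$minus35_spacer <- spacer_stats(m35)
    } else {
      res$minus35 <- list(insufficient_data = TRUE, n = length(sub35))
    }
    out[[group]] <- res
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Export a position frequency matrix as TSV
#' @param model a `MotifModel`.
#' @param path output file (`position`, `A`, `C`, `G`, `T` columns).
#' @export
write_pfm_tsv <- function(model, path) {
  tab <- data.frame(position = seq_len(model$width), t(model$pfm))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
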