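# Precision/recall scoring of pipeline output against planted ground
# truth. Runs on the outputs of the same simulation; position matching is
# exact by default with an optional +/- tolerance.

#' Score pipeline output against planted ground truth
#'
#' @param tss classified TSS table from the pipeline (or `NULL` to skip).
#' @param operon_map output of [infer_operons()] (or `NULL`).
#' @param attenuator_hits output of [scan_attenuators()] (or `NULL`).
#' @param truth the `truth` component of [simulate_genome()].
#' @param tolerance maximal |position difference| (nt) for a TSS match.
#' @return list with `tss` (precision, recall, n matched, class confusion
#'   matrix, utr agreement), `operons` (exact-match rate, sub-operon
#'   recovery, monocistronic agreement), `attenuators` (peptide recovery
#'   rate).
#' @export
evaluate_against_truth <- function(truth, tss = NULL, operon_map = NULL,
                                   attenuator_hits = NULL, tolerance = 0L) {
  out <- list()
  if (!is.null(tss)) {
    tt <- truth$tss
    matched_pred <- logical(nrow(tss))
    match_of_truth <- rep(NA_integer_, nrow(tt))
    for (i in seq_len(nrow(tt))) {
      cand <- which(!matched_pred & tss$strand == tt$strand[i] &
                    abs(tss$position - tt$position[i]) <= tolerance)
      if (length(cand)) {
        j <- cand[which.min(abs(tss$position[cand] - tt$position[i]))]
        matched_pred[j] <- TRUE
        match_of_truth[i] <- j
      }
    }
    hit <- !is.na(match_of_truth)
    confusion <- if (any(hit) && "tss_class" %in% names(tss))
      table(truth = tt$tss_class[hit],
            predicted = tss$tss_class[match_of_truth[hit]])
    else NULL
    utr_ok <- if (any(hit) && "utr_length" %in% names(tss)) {
      pu <- tss$utr_length[match_of_truth[hit]]
      mean(!is.na(pu) & pu == tt$utr_length[hit])
    } else NA_real_
    out$tss <- list(
      precision = if (nrow(tss)) mean(matched_pred) else NA_real_,
      recall = if (nrow(tt)) mean(hit) else NA_real_,
      n_truth = nrow(tt), n_predicted = nrow(tss), n_matched = sum(hit),
      class_confusion = confusion, utr_agreement = utr_ok)
  }
  if (!is.null(operon_map)) {
    pred_ops <- lapply(operon_map$operons, function(o)
      paste(o$gene_ids, collapse = ","))
    truth_ops <- vapply(truth$operons, paste, character(1), collapse = ",")
    op_rate <- if (length(truth_ops)) mean(truth_ops %in% unlist(pred_ops))
               else NA_real_
    pred_subs <- unlist(lapply(operon_map$operons, function(o)
      vapply(o$sub_operons, function(s) paste(s$gene_ids, collapse = ","),
             character(1))))
    truth_subs <- vapply(truth$sub_operons, function(s)
      paste(s$gene_ids, collapse = ","), character(1))
    sub_rate <- if (length(truth_subs)) mean(truth_subs %in% pred_subs)
                else NA_real_
    mono_ok <- setequal(operon_map$monocistronic, truth$monocistronic)
    out$operons <- list(exact_match_rate = op_rate,
                        sub_operon_recovery = sub_rate,
                        monocistronic_agreement = mono_ok,
                        n_truth = length(truth_ops),
                        n_predicted = length(pred_ops))
  }
  if (!is.null(attenuator_hits)) {
    ta <- truth$attenuators
    found <- vapply(seq_len(nrow(ta)), function(i)
      any(attenuator_hits$upstream_of == ta$target[i] &
          attenuator_hits$peptide == ta$peptide[i]), logical(1))
    out$attenuators <- list(
      recovery_rate = if (nrow(ta)) mean(found) else NA_real_,
      n_truth = nrow(ta), recovered = ta$name[found])
  }
  out
}
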