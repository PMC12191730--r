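CHAIN_REGIONS <- as.vector(outer(c("H", "L"), REGION_ORDER, paste, sep = ":"))

#' Per-position masked-prediction accuracy by region
#'
#' For every residue position of every record, exactly that one position is
#' replaced by `<mask>`, the model predicts it (one forward pass per
#' position; positions of one sequence are batched), and the argmax over
#' residue tokens is compared to the true residue. Accuracies are aggregated
#' per chain-qualified region (14 labels) per sequence, with records split
#' into `"unmutated"` and `"mutated"` cohorts: a pair counts as mutated if
#' either chain carries V-gene mutations.
#'
#' @param params Model parameters.
#' @param records List of `abmlm_pair` records.
#' @param vocab Vocabulary.
#' @param n_per_cohort Cap on records per cohort (`NULL` = use all).
#' @param max_len Encoded length.
#' @param chunk Forward batch size for the position sweep.
#' @return Data frame (class `abmlm_accuracy`): `pair_id`, `cohort`, `chain`,
#'   `region`, `correct`, `total`, `accuracy`.
#' @export
per_position_accuracy <- function(params, records, vocab,
                                  n_per_cohort = NULL, max_len = 320L,
                                  chunk = 64L) {
  config <- attr(params, "config")
  mutated <- vapply(records, function(r) {
    isTRUE(r$heavy$v_mutation_count > 0L) || isTRUE(r$light$v_mutation_count > 0L)
  }, TRUE)
  take <- function(idx) {
    if (!is.null(n_per_cohort)) idx <- idx[seq_len(min(length(idx), n_per_cohort))]
    idx
  }
  use <- c(take(which(!mutated)), take(which(mutated)))
  rows <- list()
  for (i in use) {
    rec <- records[[i]]
    enc <- tryCatch(
      encode_pair(rec$heavy, rec$light, vocab, max_len = max_len,
                  pair_id = rec$pair_id),
      error = function(e) NULL
    )
    if (is.null(enc)) next  # skipped and logged by omission from the table
    n_real <- sum(enc$attention)
    tokens <- enc$token_ids[seq_len(n_real)]
    region <- enc$region_mask[seq_len(n_real)]
    res_pos <- which(!region %in% c("SPECIAL", "PAD"))
    correct_at <- logical(length(res_pos))
    for (c0 in seq(1L, length(res_pos), by = chunk)) {
      pos <- res_pos[c0:min(c0 + chunk - 1L, length(res_pos))]
      B <- length(pos)
      toks <- matrix(rep(tokens, each = B), B, n_real)
      toks[cbind(seq_len(B), pos)] <- vocab$mask_id
      logits <- cpp_logits_at(unclass(params), unclass(config), toks,
                              rep(n_real, B), pos)
      # argmax restricted to residue tokens; predicting a special is never correct
      pred <- vocab$residue_ids[max.col(logits[, vocab$residue_ids, drop = FALSE],
                                        ties.method = "first")]
      correct_at[c0:(c0 + B - 1L)] <- pred == tokens[pos]
    }
    tab <- tapply(correct_at, region[res_pos], function(x) c(sum(x), length(x)))
    for (rg in names(tab)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = rec$pair_id,
        cohort = if (mutated[i]) "mutated" else "unmutated",
        chain = substr(rg, 1L, 1L),
        region = rg,
        correct = tab[[rg]][1L],
        total = tab[[rg]][2L]
      )
    }
  }
  out <- do.call(rbind, rows)
  out$accuracy <- out$correct / out$total
  class(out) <- c("abmlm_accuracy", "data.frame")
  out
}

#' Paired per-region comparison of two models
#'
#' Two-sided paired t test on per-sequence region accuracies of two accuracy
#' tables computed on the same records, with Bonferroni correction for the 14
#' chain-qualified region hypotheses: adjusted p = min(1, 14 x raw p).
#' Regions with fewer than 2 paired observations, or with all paired
#' differences zero, are reported as untestable (`NA` statistics) with a
#' note.
#'
#' @param table_a,table_b `abmlm_accuracy` tables over the same `pair_id`s.
#' @param n_regions Hypothesis count for the Bonferroni factor (default 14).
#' @return Data frame: `region`, `n`, `t`, `df`, `p_raw`, `p_adj`, `note`.
#' @export
compare_models <- function(table_a, table_b, n_regions = 14L) {
  merged <- merge(table_a[, c("pair_id", "region", "accuracy")],
                  table_b[, c("pair_id", "region", "accuracy")],
                  by = c("pair_id", "region"), suffixes = c("_a", "_b"))
  regions <- sort(unique(merged$region))
  rows <- lapply(regions, function(rg) {
    d <- merged[merged$region == rg, ]
    out <- data.frame(region = rg, n = nrow(d), t = NA_real_, df = NA_real_,
                      p_raw = NA_real_, p_adj = NA_real_, note = "")
    if (nrow(d) < 2L) {
      out$note <- "untestable: fewer than 2 paired observations"
      return(out)
    }
    diffs <- d$accuracy_a - d$accuracy_b
    if (all(diffs == 0)) {
      out$note <- "no difference"
      return(out)
    }
    if (stats::sd(diffs) == 0) {
      out$note <- "untestable: constant nonzero differences"
      return(out)
    }
    tt <- stats::t.test(d$accuracy_a, d$accuracy_b, paired = TRUE)
    out$t <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p_raw <- tt$p.value
    out$p_adj <- min(1, n_regions * tt$p.value)
    out
  })
  do.call(rbind, rows)
}
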