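#' AttCAT impact scores for one classified sequence
#'
#' Gradient-based attribution of a frozen-base classifier decision. For layer
#' l and token i the component is the inner product of the layer's input
#' hidden state with the gradient of the target-class logit with respect to
#' it; components are weighted by the mean attention received by token i in
#' that layer (averaged over heads and query positions) and summed over
#' layers. Positive raw impact pushes toward the target class; the `scores`
#' field is negated so that negative values indicate impact toward the target
#' class, the orientation used for display. Pad positions are excluded by
#' construction (inputs are trimmed to their real length).
#'
#' @param params Frozen base model parameters.
#' @param head A head from [train_head()] (fields `W`, `b`), or any list with
#'   an H x 2 weight matrix `W` and length-2 bias `b`.
#' @param encoded An `abmlm_encoded` pair from [encode_pair()].
#' @param target Target class column (1 or 2) of the head.
#' @param pooling `"mean"` or `"cls"`, matching how the head was trained.
#' @param feature_center,feature_scale Optional feature standardization used
#'   at head-training time (taken from `abmlm_heads` objects automatically
#'   when you pass `heads$heads[[f]]` plus the parent's scaling).
#' @return An object of class `abmlm_attribution`: `scores` (display sign:
#'   negative = toward target), `impact_raw`, `components` (layers x tokens),
#'   `attn_received`, `logit`, `tokens`, `region_mask`, `normalized`
#'   (`"raw"`), plus `grad_h0`/`h0` for gradient verification.
#' @export
attcat_scores <- function(params, head, encoded, target = 2L,
                          pooling = c("mean", "cls"),
                          feature_center = NULL, feature_scale = NULL) {
  pooling <- match.arg(pooling)
  config <- attr(params, "config")
  n_real <- sum(encoded$attention)
  tokens <- encoded$token_ids[seq_len(n_real)]
  region <- encoded$region_mask[seq_len(n_real)]
  resmask <- as.numeric(!region %in% c("SPECIAL", "PAD"))
  W <- head$W
  b <- head$b
  if (!is.null(feature_center)) {
    # fold the feature standardization into the affine head
    W <- W / feature_scale
    b <- b - as.numeric(feature_center %*% (head$W / feature_scale))
  }
  res <- cpp_attcat(unclass(params), unclass(config), tokens, W, b,
                    target - 1L, if (pooling == "cls") 0L else 1L, resmask)
  att <- res$attn_received
  stopifnot(all(att >= 0))
  structure(list(scores = -res$impact, impact_raw = res$impact,
                 components = res$components, attn_received = att,
                 logit = res$logit, tokens = tokens, region_mask = region,
                 normalized = "raw", target = target,
                 grad_h0 = res$grad_h0, h0 = res$h0),
            class = "abmlm_attribution")
}

#' Standard-scale attribution scores
#'
#' Centers and scales the per-token scores to mean 0 and (population) sd 1
#' over the sequence, the normalization used to compare attributions across
#' models. A flag prevents accidental double application; constant scores
#' yield all zeros with a warning.
#'
#' @param result An `abmlm_attribution`.
#' @return The result with `scores` standardized and `normalized =
#'   "standard"`.
#' @export
standardize <- function(result) {
  stopifnot(inherits(result, "abmlm_attribution"))
  if (result$normalized == "standard") {
    stop("attribution scores are already standard-scaled", call. = FALSE)
  }
  x <- result$scores
  if (length(x) < 2L) stop("need at least 2 tokens to standardize", call. = FALSE)
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) {
    warning("constant attribution scores: standardized output is all zeros")
    result$scores <- rep(0, length(x))
  } else {
    result$scores <- (x - mean(x)) / s
  }
  result$normalized <- "standard"
  result
}

#' Region enrichment of attribution magnitude
#'
#' Mean absolute impact per chain-qualified region, with summary ratios:
#' CDR vs FR and heavy vs light chain. Ratios with a zero denominator are
#' reported as the capped sentinel `Inf` replaced by `1e6`.
#'
#' @param result An `abmlm_attribution`.
#' @return List with `per_region` (data frame `region`, `mean_abs_impact`,
#'   `n`), `cdr_vs_fr`, `heavy_vs_light`.
#' @export
region_enrichment <- function(result) {
  stopifnot(inherits(result, "abmlm_attribution"))
  region <- result$region_mask
  imp <- abs(result$impact_raw)
  res <- !region %in% c("SPECIAL", "PAD")
  per <- stats::aggregate(imp[res], list(region = region[res]),
                          function(x) c(mean(x), length(x)))
  per_region <- data.frame(region = per$region,
                           mean_abs_impact = per$x[, 1L], n = per$x[, 2L])
  ratio <- function(num, den) {
    if (den == 0) {
      if (num == 0) 1 else 1e6
    } else num / den
  }
  is_cdr <- grepl("CDR", region) & res
  is_fr <- grepl("FR", region) & res
  is_h <- startsWith(region, "H:") & res
  is_l <- startsWith(region, "L:") & res
  list(per_region = per_region,
       cdr_vs_fr = ratio(mean(imp[is_cdr]), mean(imp[is_fr])),
       heavy_vs_light = ratio(mean(imp[is_h]), mean(imp[is_l])))
}

#' Select an explanation cohort spread over prediction confidence
#'
#' Averages each record's predicted probability over the supplied classifier
#' columns, ranks records in ascending order, and picks `k` records evenly
#' spaced across the rank range. Ties in mean probability are broken by
#' `pair_id`, so the output is deterministic.
#'
#' @param prob_table Data frame with `pair_id` and one or more probability
#'   columns.
#' @param k Number of records to select (default 50). If more than available,
#'   all records are returned with a warning.
#' @return Data frame `pair_id`, `mean_prob`, in ascending mean-probability
#'   order.
#' @export
select_explanation_cohort <- function(prob_table, k = 50L) {
  prob_cols <- setdiff(names(prob_table), "pair_id")
  mean_prob <- rowMeans(as.matrix(prob_table[, prob_cols, drop = FALSE]))
  out <- data.frame(pair_id = prob_table$pair_id, mean_prob = mean_prob)
  out <- out[order(out$mean_prob, out$pair_id), , drop = FALSE]
  n <- nrow(out)
  if (k >= n) {
    if (k > n) warning(sprintf("requested %d records but only %d available", k, n))
    rownames(out) <- NULL
    return(out)
  }
  idx <- unique(round(seq(1L, n, length.out = k)))
  out <- out[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
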