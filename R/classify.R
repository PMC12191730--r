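derangement <- function(n) {
  if (n < 2L) stop("derangement needs at least 2 elements", call. = FALSE)
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Build a native-vs-shuffled pairing dataset
#'
#' Within each donor, a random fraction of pairs (default 50%) keep their
#' native light chain; the rest have their light chains permuted by a
#' derangement, so no pair keeps its own light chain by the permutation.
#' Shuffled pairs whose resulting heavy+light sequence combination is
#' identical to any native pair (light-chain redundancy) are removed and
#' counted. The final set is re-balanced exactly by dropping excess native
#' pairs at random. Donors whose shuffle sample contains a single pair return
#' it to the native set (logged). Consumes the caller's RNG stream.
#'
#' @param records List of `abmlm_pair` records with donor labels.
#' @param shuffle_fraction Fraction of each donor's pairs to shuffle.
#' @return List of class `abmlm_clf_dataset`: `records` (with
#'   `pairing_label`), `labels` (factor native/shuffled), `task = "pairing"`,
#'   and `log` (`n_collisions`, `n_single_donor`, `n_trimmed`).
#' @export
make_shuffled_pairs <- function(records, shuffle_fraction = 0.5) {
  if (length(records) == 0L) {
    return(structure(list(records = list(), labels = factor(character(0)),
                          task = "pairing",
                          log = list(n_collisions = 0L, n_single_donor = 0L,
                                     n_trimmed = 0L)),
                     class = "abmlm_clf_dataset"))
  }
  donors <- vapply(records, function(r) r$donor_id, "")
  native_keys <- vapply(records, function(r) {
    paste0(r$heavy$sequence, "|", r$light$sequence)
  }, "")
  native <- list()
  shuffled <- list()
  n_single <- 0L
  n_coll <- 0L
  for (d in unique(donors)) {
    idx <- which(donors == d)
    n_shuf <- round(length(idx) * shuffle_fraction)
    shuf_idx <- if (n_shuf > 0L) sample(idx, n_shuf) else integer(0)
    if (length(shuf_idx) == 1L) {
      n_single <- n_single + 1L
      shuf_idx <- integer(0)
    }
    nat_idx <- setdiff(idx, shuf_idx)
    for (i in nat_idx) native[[length(native) + 1L]] <- records[[i]]
    if (length(shuf_idx) >= 2L) {
      perm <- derangement(length(shuf_idx))
      for (k in seq_along(shuf_idx)) {
        rec <- records[[shuf_idx[k]]]
        rec$light <- records[[shuf_idx[perm[k]]]]$light
        rec$pairing_label <- "shuffled"
        rec$pair_id <- paste0(rec$pair_id, "S")
        key <- paste0(rec$heavy$sequence, "|", rec$light$sequence)
        if (key %in% native_keys) {
          n_coll <- n_coll + 1L  # light-chain redundancy recreated a native pair
        } else {
          shuffled[[length(shuffled) + 1L]] <- rec
        }
      }
    }
  }
  n_trim <- max(0L, length(native) - length(shuffled))
  if (n_trim > 0L) {
    keep <- sample.int(length(native), length(shuffled))
    native <- native[sort(keep)]
  } else if (length(shuffled) > length(native)) {
    keep <- sample.int(length(shuffled), length(native))
    shuffled <- shuffled[sort(keep)]
  }
  out <- c(native, shuffled)
  labels <- factor(vapply(out, function(r) r$pairing_label, ""),
                   levels = c("native", "shuffled"))
  structure(list(records = out, labels = labels, task = "pairing",
                 log = list(n_collisions = n_coll, n_single_donor = n_single,
                            n_trimmed = n_trim)),
            class = "abmlm_clf_dataset")
}

#' Stratified k-fold assignment
#'
#' Deterministic for a fixed seed; every fold's label ratio is within one
#' record of the global ratio. With `donors` given, whole donors are assigned
#' to folds instead (held-out-donor evaluation); stratification is then only
#' as exact as the donor composition allows.
#'
#' @param labels Factor or vector of class labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param donors Optional donor label per record; when supplied, records of
#'   one donor never split across folds.
#' @return Integer vector of fold assignments (1..k), same length as
#'   `labels`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 0L, donors = NULL) {
  labels <- as.factor(labels)
  if (any(table(labels) < k)) {
    stop("each class needs at least k records for stratified k-fold",
         call. = FALSE)
  }
  folds <- integer(length(labels))
  if (!is.null(donors)) {
    ids <- unique(donors)
    if (length(ids) < k) {
      stop("need at least k donors for donor-held-out folds", call. = FALSE)
    }
    with_seed(seed, {
      donor_fold <- stats::setNames(((seq_along(ids) - 1L) %% k) + 1L,
                                    sample(ids))
      folds <- unname(donor_fold[donors])
    })
    return(folds)
  }
  with_seed(seed, {
    start <- 0L
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      # rotate the dealing start between classes so remainder records spread
      # over different folds and total fold sizes differ by at most one
      folds[idx] <- ((seq_along(idx) - 1L + start) %% k) + 1L
      start <- (start + length(idx)) %% k
    }
  })
  folds
}

#' Binary classification metrics
#'
#' Accuracy, F1 and MCC at the 0.5 threshold plus threshold-free AUC (via
#' pROC) and AUPR (average precision). If only one class is present, AUC and
#' AUPR are undefined and reported as `NA`.
#'
#' @param scores Predicted probabilities of the positive class.
#' @param labels Binary truth (0/1, logical, or 2-level factor whose second
#'   level is positive).
#' @return One-row data frame: `accuracy`, `auc`, `aupr`, `f1`, `mcc`.
#' @export
compute_metrics <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  acc <- (tp + tn) / length(labels)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  if (length(unique(labels)) < 2L) {
    auc <- NA_real_
    aupr <- NA_real_
  } else {
    auc <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    aupr <- average_precision(scores, labels)
  }
  data.frame(accuracy = acc, auc = auc, aupr = aupr, f1 = f1, mcc = mcc)
}

# Average precision: sum over positives, in descending-score order, of
# precision at each positive (step integration of the PR curve).
average_precision <- function(scores, labels) {
  ord <- order(-scores)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1L]) / sum(lab)
}

softmax2 <- function(z) {
  m <- pmax(z[, 1L], z[, 2L])
  e1 <- exp(z[, 1L] - m)
  e2 <- exp(z[, 2L] - m)
  e2 / (e1 + e2)
}

# Train one affine head (H -> 2 logits) on fixed features with AdamW-style
# updates, cross-entropy loss, linear warmup then linear decay.
fit_head <- function(X, y, epochs = 50L, batch_size = 64L, peak_lr = 0.01,
                     warmup_ratio = 0.1, weight_decay = 1e-4) {
  n <- nrow(X)
  H <- ncol(X)
  W <- matrix(0, H, 2L)
  b <- c(0, 0)
  mW <- W; vW <- W; mb <- b; vb <- b
  t <- 0L
  total <- epochs * ceiling(n / batch_size)
  warm <- max(1L, round(warmup_ratio * total))
  curve <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (i0 in seq(1L, n, by = batch_size)) {
      idx <- ord[i0:min(i0 + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      z <- Xb %*% W
      z[, 1L] <- z[, 1L] + b[1L]
      z[, 2L] <- z[, 2L] + b[2L]
      p2 <- softmax2(z)
      yb <- y[idx]
      ep_loss <- ep_loss + mean(-log(pmax(ifelse(yb == 1L, p2, 1 - p2), 1e-12)))
      nb <- nb + 1L
      dz2 <- (p2 - yb) / length(idx)
      dz <- cbind(-dz2, dz2)
      gW <- crossprod(Xb, dz)
      gb <- colSums(dz)
      t <- t + 1L
      lr <- if (t <= warm) peak_lr * t / warm else {
        peak_lr * max(0, (total - t) / (total - warm))
      }
      mW <- 0.9 * mW + 0.1 * gW; vW <- 0.98 * vW + 0.02 * gW^2
      mb <- 0.9 * mb + 0.1 * gb; vb <- 0.98 * vb + 0.02 * gb^2
      W <- W - lr * ((mW / (1 - 0.9^t)) / (sqrt(vW / (1 - 0.98^t)) + 1e-8) +
                       weight_decay * W)
      b <- b - lr * (mb / (1 - 0.9^t)) / (sqrt(vb / (1 - 0.98^t)) + 1e-8)
    }
    curve[ep] <- ep_loss / nb
  }
  list(W = W, b = b, curve = curve)
}

#' Train frozen-base classifier heads with cross-validation
#'
#' Pools sequence embeddings from a frozen base model and trains one affine
#' head (a single feedforward layer to 2 logits) per fold; each head is
#' evaluated only on its held-out fold, so no prediction ever comes from a
#' head that saw that sequence in training. The base weights are verified
#' bit-identical before and after by checksum.
#'
#' @param params Frozen base model parameters.
#' @param dataset Encoded dataset from [encode_dataset()].
#' @param labels Binary labels (2-level factor; second level = positive
#'   class).
#' @param folds Fold assignment from [stratified_kfold()].
#' @param pooling `"cls"` or `"mean"` pooled representation.
#' @param epochs,batch_size,peak_lr,warmup_ratio Head training
#'   hyperparameters (defaults are the tiny-scale configuration).
#' @param seed Integer seed.
#' @return List of class `abmlm_heads`: `heads` (per fold), `metrics` (per
#'   fold), `summary` (mean and SE over folds), `scores` (out-of-fold
#'   positive-class probability per record), `curves`, `pooling`.
#' @export
train_head <- function(params, dataset, labels, folds,
                       pooling = c("mean", "cls"), epochs = 50L,
                       batch_size = 64L, peak_lr = 0.01, warmup_ratio = 0.1,
                       seed = 0L) {
  pooling <- match.arg(pooling)
  before <- params_checksum(params)
  X <- pooled_features(params, dataset, pooling = pooling)
  mu <- colMeans(X)
  sdv <- pmax(apply(X, 2L, stats::sd), 1e-8)
  X <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  k <- max(folds)
  heads <- vector("list", k)
  curves <- vector("list", k)
  metrics <- vector("list", k)
  scores <- rep(NA_real_, length(y))
  with_seed(seed, {
    for (f in seq_len(k)) {
      tr <- which(folds != f)
      te <- which(folds == f)
      stopifnot(length(intersect(tr, te)) == 0L)  # no train/eval leakage
      h <- fit_head(X[tr, , drop = FALSE], y[tr], epochs = epochs,
                    batch_size = batch_size, peak_lr = peak_lr,
                    warmup_ratio = warmup_ratio)
      z <- X[te, , drop = FALSE] %*% h$W
      z[, 1L] <- z[, 1L] + h$b[1L]
      z[, 2L] <- z[, 2L] + h$b[2L]
      scores[te] <- softmax2(z)
      heads[[f]] <- h
      curves[[f]] <- h$curve
      metrics[[f]] <- cbind(fold = f, compute_metrics(scores[te], y[te]))
    }
  })
  after <- params_checksum(params)
  if (!identical(before, after)) {
    stop("base model weights changed during head training", call. = FALSE)
  }
  metrics <- do.call(rbind, metrics)
  vals <- metrics[, c("accuracy", "auc", "aupr", "f1", "mcc")]
  summary <- data.frame(metric = names(vals),
                        mean = colMeans(as.matrix(vals)),
                        se = apply(as.matrix(vals), 2L, stats::sd) / sqrt(k),
                        row.names = NULL)
  structure(list(heads = heads, metrics = metrics, summary = summary,
                 scores = scores, curves = curves, pooling = pooling,
                 feature_center = mu, feature_scale = sdv),
            class = "abmlm_heads")
}

#' Mutation-count grids of pairing predictions
#'
#' Tabulates pairs by (heavy, light) V-mutation count, separately for true
#' native and true shuffled pairs, with the per-cell mean predicted
#' probability of the shuffled class.
#'
#' @param scores Predicted shuffled-class probabilities.
#' @param records The records the scores belong to (same order).
#' @return Long-format data frame: `truth`, `m_h`, `m_l`, `count`,
#'   `mean_shuffled_prob`.
#' @export
mutation_grid <- function(scores, records) {
  m_h <- vapply(records, function(r) r$heavy$v_mutation_count, 0L)
  m_l <- vapply(records, function(r) r$light$v_mutation_count, 0L)
  truth <- vapply(records, function(r) r$pairing_label, "")
  df <- data.frame(truth = truth, m_h = m_h, m_l = m_l, prob = scores)
  agg <- stats::aggregate(prob ~ truth + m_h + m_l, df,
                          function(x) c(length(x), mean(x)))
  out <- data.frame(truth = agg$truth, m_h = agg$m_h, m_l = agg$m_l,
                    count = agg$prob[, 1L],
                    mean_shuffled_prob = agg$prob[, 2L])
  out[order(out$truth, out$m_h, out$m_l), ]
}

#' Accuracy split by mutation-status agreement
#'
#' Splits pairs into `"same"` (both chains mutated or both unmutated) and
#' `"different"` (exactly one chain mutated) and reports pairing-prediction
#' accuracy per group. Empty groups are absent from the result, never
#' reported as zero.
#'
#' @param scores Predicted shuffled-class probabilities.
#' @param records Records with `pairing_label` truth (same order).
#' @return Data frame: `group`, `n`, `accuracy`.
#' @export
split_by_pairing_type <- function(scores, records) {
  mut_h <- vapply(records, function(r) r$heavy$v_mutation_count > 0L, TRUE)
  mut_l <- vapply(records, function(r) r$light$v_mutation_count > 0L, TRUE)
  group <- ifelse(mut_h == mut_l, "same", "different")
  truth <- vapply(records, function(r) r$pairing_label, "") == "shuffled"
  pred <- scores >= 0.5
  out <- lapply(intersect(c("same", "different"), unique(group)), function(g) {
    i <- group == g
    data.frame(group = g, n = sum(i), accuracy = mean(pred[i] == truth[i]))
  })
  do.call(rbind, out)
}
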