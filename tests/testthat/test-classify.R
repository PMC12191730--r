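test_that("shuffled pairs within one donor form a clean balanced set", {
  set.seed(110)
  recs <- lapply(1:4, function(i) make_pair(sprintf("D%d", i), seed = 300L + i))
  clf <- make_shuffled_pairs(recs)
  expect_equal(as.vector(table(clf$labels)), c(2L, 2L))
  shuf <- clf$records[clf$labels == "shuffled"]
  native_keys <- vapply(recs, function(r) {
    paste0(r$heavy$sequence, "|", r$light$sequence)
  }, "")
  for (s in shuf) {
    expect_false(paste0(s$heavy$sequence, "|", s$light$sequence) %in% native_keys)
  }
  expect_equal(clf$log$n_collisions, 0L)
})

test_that("light-chain redundancy collisions are filtered and counted", {
  set.seed(111)
  recs <- lapply(1:6, function(i) make_pair(sprintf("C%d", i), seed = 400L + i))
  # give every record the same light chain: every shuffled pair re-creates a
  # native combination and must be filtered
  for (i in seq_along(recs)) recs[[i]]$light <- recs[[1L]]$light
  clf <- make_shuffled_pairs(recs)
  expect_gt(clf$log$n_collisions, 0L)
  expect_equal(sum(clf$labels == "shuffled"), 0L)
  # balance restored by trimming the native excess
  expect_equal(sum(clf$labels == "native"), 0L)
})

test_that("empty input and single-pair donors are handled", {
  expect_length(make_shuffled_pairs(list())$records, 0L)
  set.seed(112)
  recs <- list(make_pair("A", seed = 500L, donor_id = "d1"),
               make_pair("B", seed = 501L, donor_id = "d1"),
               make_pair("C", seed = 502L, donor_id = "d2"))
  # with shuffle_fraction 0.5, donor d2 samples one pair, which returns to the
  # native pool; some draws of d1 sample one pair too
  clf <- make_shuffled_pairs(recs, shuffle_fraction = 0.9)
  expect_true(all(vapply(clf$records, function(r) {
    r$pairing_label %in% c("native", "shuffled")
  }, TRUE)))
  expect_equal(sum(clf$labels == "native"), sum(clf$labels == "shuffled"))
})

test_that("stratified folds are balanced, deterministic and exhaustive", {
  labels <- factor(rep(c("a", "b"), each = 50L))
  f <- stratified_kfold(labels, k = 5L, seed = 1L)
  expect_equal(as.vector(table(f)), rep(20L, 5L))
  for (k in 1:5) {
    expect_equal(as.vector(table(labels[f == k])), c(10L, 10L))
  }
  expect_identical(f, stratified_kfold(labels, k = 5L, seed = 1L))
  expect_false(identical(f, stratified_kfold(labels, k = 5L, seed = 2L)))
  # 103 records, 52/51: fold sizes differ by <= 1, labels within 1 of
  # proportional (oracle: exhaustive check of fold composition)
  lab2 <- factor(c(rep("a", 52L), rep("b", 51L)))
  f2 <- stratified_kfold(lab2, k = 5L, seed = 3L)
  sizes <- table(f2)
  expect_lte(max(sizes) - min(sizes), 1L)
  for (k in 1:5) {
    tab <- table(lab2[f2 == k])
    expect_lte(abs(tab[["a"]] - 52 / 5), 1)
    expect_lte(abs(tab[["b"]] - 51 / 5), 1)
  }
  expect_error(stratified_kfold(factor(c("a", rep("b", 10L))), k = 5L),
               "at least k")
  # donor-held-out flag: a donor's records never split across folds
  donors <- rep(sprintf("don%d", 1:10), each = 10L)
  labs3 <- factor(rep(c("a", "b"), 50L))
  f3 <- stratified_kfold(labs3, k = 5L, seed = 9L, donors = donors)
  for (d in unique(donors)) {
    expect_length(unique(f3[donors == d]), 1L)
  }
  expect_setequal(unique(f3), 1:5)
})

test_that("metrics match hand values on degenerate and fixture inputs", {
  perfect <- compute_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(unlist(perfect), c(accuracy = 1, auc = 1, aupr = 1, f1 = 1, mcc = 1))
  inverted <- compute_metrics(c(0.1, 0.2, 0.9, 0.8), c(1, 1, 0, 0))
  expect_equal(inverted$mcc, -1)
  expect_equal(inverted$auc, 0)
  single <- compute_metrics(c(0.9, 0.8), c(1, 1))
  expect_true(is.na(single$auc) && is.na(single$aupr))
})

test_that("metrics on a 6-item fixture match exhaustive-threshold oracles", {
  scores <- c(0.9, 0.7, 0.6, 0.4, 0.3, 0.1)
  labels <- c(1, 0, 1, 1, 0, 0)
  m <- compute_metrics(scores, labels)
  # AUC oracle: fraction of concordant (positive, negative) pairs
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) for (q in neg) conc <- conc + (p > q) + 0.5 * (p == q)
  expect_equal(m$auc, conc / (length(pos) * length(neg)))
  # AUPR oracle: precision at each positive in descending-score order
  ord <- order(-scores)
  lab <- labels[ord]
  prec_at_pos <- (cumsum(lab) / seq_along(lab))[lab == 1]
  expect_equal(m$aupr, mean(prec_at_pos))
  # threshold-0.5 confusion counts by hand: pred = (1,1,1,0,0,0)
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$f1, 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(m$mcc, (2 * 2 - 1 * 1) / sqrt(3 * 3 * 3 * 3))
})

test_that("a frozen-base head separates motif-implanted embeddings from a base that exposes the motif", {
  v <- fix_vocab()
  base <- motif_probe_base("WGRDY", v)
  reps <- fix_repertoire()
  scfg <- sim_config(motif_implant_prob = 1, seed = 101L)
  set.seed(120)
  labeled <- implant_specificity(reps, scfg)
  labels <- factor(vapply(labeled, function(r) r$specificity_label, ""),
                   levels = c("negative", "positive"))
  ds <- encode_dataset(labeled, v)
  folds <- stratified_kfold(labels, k = 5L, seed = 4L)
  before <- params_checksum(base)
  heads <- train_head(base, ds, labels, folds, pooling = "mean", seed = 5L)
  expect_identical(params_checksum(base), before)  # frozen base
  expect_gt(heads$summary$mean[heads$summary$metric == "accuracy"], 0.9)
  # oracle: a plain logistic fit on the same pooled features separates too
  X <- pooled_features(base, ds, pooling = "mean")
  df <- data.frame(y = as.integer(labels) - 1L, X)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df[folds != 1L, ],
                                     family = "binomial"))
  pred <- suppressWarnings(stats::predict(fit, df[folds == 1L, ], type = "response"))
  oracle_acc <- mean((pred > 0.5) == df$y[folds == 1L])
  expect_gt(oracle_acc, 0.9)
})

test_that("randomly shuffled labels give chance-level held-out accuracy", {
  v <- fix_vocab()
  base <- fix_trained_base()
  ds <- fix_encoded()
  n <- length(ds$pair_ids)
  set.seed(130)
  labels <- factor(sample(rep(c("x", "y"), length.out = n)))
  folds <- stratified_kfold(labels, k = 5L, seed = 6L)
  heads <- train_head(base, ds, labels, folds, pooling = "mean", seed = 7L)
  acc <- heads$summary$mean[heads$summary$metric == "accuracy"]
  se <- sqrt(0.25 / n)
  expect_lt(abs(acc - 0.5), 5 * se)
})

test_that("per-fold scores only come from the held-out fold", {
  v <- fix_vocab()
  base <- fix_trained_base()
  ds <- fix_encoded()
  labels <- factor(rep(c("x", "y"), length.out = length(ds$pair_ids)))
  folds <- stratified_kfold(labels, k = 5L, seed = 8L)
  heads <- train_head(base, ds, labels, folds, epochs = 3L, seed = 9L)
  expect_false(anyNA(heads$scores))  # every record scored exactly once
  expect_equal(nrow(heads$metrics), 5L)
  expect_equal(nrow(heads$summary), 5L)
})

test_that("mutation grids aggregate counts and probabilities correctly", {
  recs <- list(make_pair("A", seed = 600L), make_pair("B", seed = 601L),
               make_pair("C", seed = 602L))
  recs[[1]]$heavy$v_mutation_count <- 2L
  recs[[1]]$light$v_mutation_count <- 1L
  recs[[2]]$heavy$v_mutation_count <- 2L
  recs[[2]]$light$v_mutation_count <- 1L
  recs[[3]]$heavy$v_mutation_count <- 0L
  recs[[3]]$light$v_mutation_count <- 0L
  grid <- mutation_grid(c(0.8, 0.6, 0.2), recs)
  expect_equal(sum(grid$count), 3)
  expect_true(all(grid$truth == "native"))  # all-native input, no shuffled grid
  cell <- grid[grid$m_h == 2 & grid$m_l == 1, ]
  expect_equal(cell$count, 2)
  expect_equal(cell$mean_shuffled_prob, 0.7)
})

test_that("same/different mutation-status accuracies match a manual tally", {
  mk <- function(id, mh, ml, lab) {
    r <- make_pair(id, seed = 700L + nchar(id) + mh * 10L + ml)
    r$heavy$v_mutation_count <- mh
    r$light$v_mutation_count <- ml
    r$pairing_label <- lab
    r
  }
  recs <- list(mk("A", 0L, 0L, "native"), mk("B", 3L, 2L, "native"),
               mk("C", 4L, 0L, "native"), mk("D", 0L, 5L, "shuffled"),
               mk("E", 2L, 2L, "shuffled"), mk("F", 0L, 0L, "shuffled"),
               mk("G", 6L, 0L, "shuffled"), mk("H", 1L, 1L, "native"))
  # scores: predicted shuffled prob
  scores <- c(0.1, 0.2, 0.6, 0.9, 0.4, 0.3, 0.8, 0.2)
  out <- split_by_pairing_type(scores, recs)
  # manual tally: same = A,B,E,F,H -> correct A(0.1 native), B, H; E wrong,
  # F wrong -> 3/5; different = C,D,G -> C wrong (0.6 but native), D, G -> 2/3
  expect_equal(out$accuracy[out$group == "same"], 3 / 5)
  expect_equal(out$accuracy[out$group == "different"], 2 / 3)
  all_same <- split_by_pairing_type(scores[c(1, 2)], recs[c(1, 2)])
  expect_false("different" %in% all_same$group)
})
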