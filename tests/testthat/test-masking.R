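region_mask_of <- function(rec, v = build_vocab()) build_region_mask(rec, v)

test_that("preferential probabilities follow the rescaling equation exactly", {
  v <- build_vocab()
  rec <- make_pair(seed = 10L)
  mask <- region_mask_of(rec, v)
  plan <- preferential_probs(mask)
  residue <- !mask %in% c("SPECIAL", "PAD")
  cdr3 <- mask %in% c("H:CDR3", "L:CDR3")
  p_hat <- sum(cdr3) / sum(residue)
  expect_equal(plan$p_hat_cdr3, p_hat)
  expect_true(all(plan$probs[cdr3] == 0.25))
  expect_equal(unique(plan$probs[residue & !cdr3]),
               (0.15 - 0.25 * p_hat) / (1 - p_hat))
  expect_true(all(plan$probs[!residue] == 0))
  # mean over residue positions is exactly the target average
  expect_equal(mean(plan$probs[residue]), 0.15, tolerance = 1e-12)
  expect_false(plan$clamped)
})

test_that("formula limit: zero CDR3 fraction gives the flat average rate", {
  # synthetic mask with no CDR3-labeled positions
  mask <- c("SPECIAL", rep("H:FR1", 50), "SPECIAL", "SPECIAL",
            rep("L:FR2", 40), "SPECIAL", rep("PAD", 6))
  plan <- preferential_probs(mask)
  expect_equal(unname(unique(plan$probs[grepl("FR", mask)])), 0.15)
})

test_that("worked value: p_hat 0.10 gives non-CDR3 rate 0.1388...", {
  mask <- c(rep("H:CDR3", 10), rep("H:FR1", 90))
  plan <- preferential_probs(mask)
  expect_equal(unique(plan$probs[mask == "H:FR1"]), (0.15 - 0.025) / 0.9,
               tolerance = 1e-12)
  expect_equal(unique(plan$probs[mask == "H:FR1"]), 0.138888888888889,
               tolerance = 1e-12)
})

test_that("extreme CDR3 fractions clamp non-CDR3 probability at zero", {
  mask <- c(rep("H:CDR3", 60), rep("H:FR1", 40))
  plan <- preferential_probs(mask)
  expect_true(plan$clamped)
  expect_true(all(plan$probs[mask == "H:FR1"] == 0))
  expect_true(all(plan$probs[mask == "H:CDR3"] == 0.25))
  # clamped plans exceed the target average (0.25 * 0.6 = 0.15 exactly at the
  # boundary; beyond it the mean rises)
  mask2 <- c(rep("H:CDR3", 70), rep("H:FR1", 30))
  expect_gt(mean(preferential_probs(mask2)$probs), 0.15)
})

test_that("every-residue-CDR3 input is a degenerate-input error", {
  expect_error(preferential_probs(rep("H:CDR3", 30)), "degenerate")
})

test_that("non-CDR3 probability decreases monotonically in the CDR3 fraction", {
  rates <- vapply(seq(0.02, 0.58, by = 0.04), function(ph) {
    n <- 1000L
    k <- round(ph * n)
    mask <- c(rep("H:CDR3", k), rep("H:FR1", n - k))
    unique(preferential_probs(mask)$probs[mask == "H:FR1"])
  }, 0)
  expect_true(all(diff(rates) < 0))
})

test_that("preferential with r_cdr3 = r_avg reproduces uniform bit-exactly", {
  v <- fix_vocab()
  for (rec in fix_repertoire()[1:5]) {
    mask <- region_mask_of(rec, v)
    expect_identical(preferential_probs(mask, r_cdr3 = 0.15, r_avg = 0.15)$probs,
                     uniform_probs(mask)$probs)
  }
})

test_that("uniform plan is 0.15 at residues and 0 at specials", {
  v <- build_vocab()
  mask <- region_mask_of(make_pair(seed = 12L), v)
  plan <- uniform_probs(mask)
  residue <- !mask %in% c("SPECIAL", "PAD")
  expect_true(all(plan$probs[residue] == 0.15))
  expect_true(all(plan$probs[!residue] == 0))
  expect_equal(mean(plan$probs[residue]), 0.15)
})

test_that("plan cache computes once per record, persists bit-exactly, detects staleness", {
  v <- fix_vocab()
  ds <- encode_dataset(fix_repertoire()[1:30], v)
  cache <- build_plan_cache(ds, "preferential")
  expect_equal(cache$n_computed, 30L)
  expect_equal(nrow(cache$probs), 30L)
  dir <- withr::local_tempdir()
  write_plan_cache(cache, dir)
  # round trip is bit-exact and performs zero recomputation
  back <- read_plan_cache(dir, ds, "preferential")
  expect_identical(back$probs, cache$probs)
  expect_equal(back$n_computed, 0L)
  # changed rate or strategy invalidates
  expect_error(read_plan_cache(dir, ds, "preferential", r_cdr3 = 0.35),
               class = "abmlm_stale_cache")
  expect_error(read_plan_cache(dir, ds, "uniform"),
               class = "abmlm_stale_cache")
  # changed dataset invalidates
  ds2 <- encode_dataset(fix_repertoire()[2:31], v)
  expect_error(read_plan_cache(dir, ds2, "preferential"),
               class = "abmlm_stale_cache")
})

test_that("the 0.35 CDR3-rate variant is supported", {
  v <- build_vocab()
  mask <- region_mask_of(make_pair(seed = 13L), v)
  plan <- preferential_probs(mask, r_cdr3 = 0.35)
  cdr3 <- mask %in% c("H:CDR3", "L:CDR3")
  residue <- !mask %in% c("SPECIAL", "PAD")
  expect_true(all(plan$probs[cdr3] == 0.35))
  expect_equal(mean(plan$probs[residue]), 0.15, tolerance = 1e-12)
})

test_that("collator selects nothing under an all-zero plan", {
  v <- build_vocab()
  tokens <- matrix(c(v$cls_id, 7L, 8L, 9L, v$eos_id, v$pad_id), 1L)
  set.seed(1)
  b <- collate_batch(tokens, matrix(0, 1L, 6L), v)
  expect_equal(sum(b$selection), 0L)
  expect_true(all(b$target_ids == 0L))
  expect_identical(b$input_ids, tokens)
})

test_that("collator corruption matches the 80/10/10 scheme within 3 SE", {
  v <- fix_vocab()
  ds <- encode_dataset(fix_repertoire(), v)
  cache <- build_plan_cache(ds, "uniform")
  set.seed(42)
  n_sel <- 0L; n_mask <- 0L; n_rand <- 0L; n_res <- 0L
  while (n_sel < 100000L) {
    b <- collate_batch(ds$tokens, cache$probs, v)
    n_sel <- n_sel + sum(b$selection)
    n_mask <- n_mask + b$n_masked
    n_rand <- n_rand + b$n_random
    n_res <- n_res + sum(cache$probs > 0)
  }
  # selection fraction ~ 0.15 of residue positions
  se_sel <- sqrt(0.15 * 0.85 / n_res)
  expect_lt(abs(n_sel / n_res - 0.15), 3 * se_sel)
  se_m <- sqrt(0.8 * 0.2 / n_sel)
  expect_lt(abs(n_mask / n_sel - 0.80), 3 * se_m)
  se_r <- sqrt(0.1 * 0.9 / n_sel)
  expect_lt(abs(n_rand / n_sel - 0.10), 3 * se_r)
})

test_that("collator never corrupts special positions or emits special tokens", {
  v <- fix_vocab()
  ds <- encode_dataset(fix_repertoire()[1:40], v)
  cache <- build_plan_cache(ds, "preferential")
  set.seed(7)
  specials <- c(v$pad_id, v$cls_id, v$eos_id, v$unk_id)
  for (i in 1:5) {
    b <- collate_batch(ds$tokens, cache$probs, v)
    expect_true(all(!b$selection[ds$regions %in% c("SPECIAL", "PAD")]))
    changed <- b$input_ids != ds$tokens
    expect_true(all(!b$input_ids[changed] %in% specials))
    # every selected position carries a real target; others the sentinel
    expect_true(all(b$target_ids[b$selection] > 0L))
    expect_true(all(b$target_ids[!b$selection] == 0L))
  }
})

test_that("masking is dynamic: consecutive draws select different positions", {
  v <- fix_vocab()
  ds <- encode_dataset(fix_repertoire()[1:20], v)
  cache <- build_plan_cache(ds, "preferential")
  set.seed(3)
  b1 <- collate_batch(ds$tokens, cache$probs, v)
  b2 <- collate_batch(ds$tokens, cache$probs, v)
  expect_false(identical(b1$selection, b2$selection))
})

test_that("collator rejects mismatched plan and token shapes", {
  v <- build_vocab()
  expect_error(collate_batch(matrix(7L, 2L, 10L), matrix(0.1, 2L, 8L), v),
               "mismatch")
})

test_that("per-position selection frequency converges to the plan probabilities", {
  v <- build_vocab()
  rec <- make_pair(seed = 20L)
  e <- encode_pair(rec$heavy, rec$light, v)
  plan <- preferential_probs(e$region_mask)
  tokens <- matrix(e$token_ids, 1L)
  probs <- matrix(plan$probs, 1L)
  set.seed(9)
  n_draws <- 600L
  hits <- numeric(length(plan$probs))
  for (i in seq_len(n_draws)) {
    hits <- hits + collate_batch(tokens, probs, v)$selection[1L, ]
  }
  freq <- hits / n_draws
  active <- plan$probs > 0
  se <- sqrt(plan$probs[active] * (1 - plan$probs[active]) / n_draws)
  expect_true(all(abs(freq[active] - plan$probs[active]) < 4.5 * se))
  expect_true(all(freq[!active] == 0))
  # expectation identity: sum of probs = r_avg * number of residue positions
  residue <- !e$region_mask %in% c("SPECIAL", "PAD")
  expect_equal(sum(plan$probs), 0.15 * sum(residue), tolerance = 1e-9)
})
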