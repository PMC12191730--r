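test_that("germline libraries are deterministic and locus rules hold", {
  a <- build_germline_library("heavy", 5L, 3L, 2L, seed = 7L)
  b <- build_germline_library("heavy", 5L, 3L, 2L, seed = 7L)
  expect_identical(a, b)
  expect_false(identical(a, build_germline_library("heavy", 5L, 3L, 2L, seed = 8L)))
  k <- build_germline_library("kappa", 4L, 0L, 2L, seed = 1L)
  expect_length(k$d_segments, 0L)
  expect_error(build_germline_library("kappa", 4L, 2L, 2L, seed = 1L),
               "light locus")
  expect_error(build_germline_library("heavy", 4L, 0L, 2L, seed = 1L),
               "n_d")
})

test_that("every V segment carries exactly the five annotated sub-regions", {
  lib <- build_germline_library("heavy", 50L, 20L, 6L, seed = 3L)
  expect_length(lib$v_segments, 50L)
  for (v in lib$v_segments) {
    expect_equal(nrow(v$bounds), 5L)  # oracle: count boundary records
    expect_identical(v$bounds$region, c("FR1", "CDR1", "FR2", "CDR2", "FR3"))
    expect_equal(v$bounds$end[5L], nchar(v$fr_cdr))
    expect_true(all(v$bounds$end > v$bounds$start))
  }
  # all segments over the 20-letter residue alphabet
  all_seq <- paste(vapply(lib$v_segments, function(v) v$fr_cdr, ""), collapse = "")
  expect_true(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", all_seq))
})

test_that("degenerate trimming parameters give the exact germline junction", {
  lib_h <- build_germline_library("heavy", 3L, 2L, 2L, seed = 5L)
  lib_k <- build_germline_library("kappa", 3L, 0L, 2L, seed = 6L)
  cfg <- sim_config(cdr3_insertion_mean = 0, trim_geometric_p = 1 - 1e-12,
                    seed = 1L)
  set.seed(2)
  rec <- recombine_pair(lib_h, lib_k, cfg)
  # with p -> 1 geometric trims are 0 and with zero insertion mean the CDR3 is
  # exactly V tail + D + J head, all templated
  expect_true(all(!is.na(rec$heavy$germline_full)))
  expect_true(all(!is.na(rec$light$germline_full)))
  expect_identical(strsplit(rec$heavy$sequence, "")[[1]], rec$heavy$germline_full)
})

test_that("sample mean CDR3 length matches the closed-form trim+insertion expectation", {
  n <- 3000L
  cfg <- sim_config(n_pairs = n, naive_fraction = 1, seed = 77L)
  reps <- simulate_repertoire(cfg)
  libs <- attr(reps, "libraries")
  p <- cfg$trim_geometric_p
  q <- 1 - p
  # E[min(Geom(p), m)] by direct summation
  e_trim <- function(m) sum(q^(1:m)) # = sum P(G >= k), k = 1..m
  e_keep_tail <- function(m) m - e_trim(m)
  # D segments trim from both ends sequentially; enumerate the joint pmf
  e_keep_both <- function(m) {
    g <- function(k) ifelse(k < m, p * q^k, q^m)  # pmf of min(G, m)
    tot <- 0
    for (l in 0:m) {
      rem <- m - l
      gr <- function(k) ifelse(k < rem, p * q^k, q^rem)
      for (r in 0:rem) tot <- tot + g(l) * gr(r) * (m - l - r)
    }
    tot
  }
  exp_heavy <- mean(vapply(libs$heavy$v_segments,
                           function(v) e_keep_tail(nchar(v$cdr3_tail)), 0)) +
    cfg$cdr3_insertion_mean +
    mean(vapply(libs$heavy$d_segments, function(d) e_keep_both(nchar(d$seq)), 0)) +
    mean(vapply(libs$heavy$j_segments,
                function(j) e_keep_tail(nchar(j$cdr3_head)), 0))
  obs <- vapply(reps, function(r) {
    s <- r$heavy$regions
    s$end[6L] - s$start[6L]
  }, 0)
  se <- stats::sd(obs) / sqrt(n)
  expect_lt(abs(mean(obs) - exp_heavy), 3 * se)
})

test_that("positional diversity is highest in the CDR3", {
  reps <- fix_repertoire()
  col_entropy <- function(chars) {
    p <- table(chars) / length(chars)
    -sum(p * log(p))
  }
  cdr3_cols <- sapply(1:4, function(k) {
    col_entropy(vapply(reps, function(r) {
      s <- r$heavy$regions
      substr(r$heavy$sequence, s$start[6L] + k, s$start[6L] + k)
    }, ""))
  })
  fr_cols <- sapply(1:20, function(k) {
    col_entropy(vapply(reps, function(r) substr(r$heavy$sequence, k, k), ""))
  })
  expect_gt(mean(cdr3_cols), mean(fr_cols))
})

test_that("naive cells carry zero mutations and memory loads are coupled", {
  all_naive <- simulate_repertoire(sim_config(n_pairs = 60L, naive_fraction = 1,
                                              seed = 21L))
  expect_true(all(vapply(all_naive, function(r) {
    r$heavy$n_mutations == 0L && r$light$n_mutations == 0L &&
      r$heavy$v_mutation_count == 0L
  }, TRUE)))
  memory <- simulate_repertoire(sim_config(n_pairs = 3000L, naive_fraction = 0,
                                           seed = 22L))
  m_h <- vapply(memory, function(r) r$heavy$n_mutations, 0L)
  m_l <- vapply(memory, function(r) r$light$n_mutations, 0L)
  # shared per-pair intensity makes the chain loads strongly correlated
  expect_gt(stats::cor(m_h, m_l), 0.5)
  # lights are less mutated on average (0.8x the pair intensity)
  expect_lt(mean(m_l), mean(m_h))
})

test_that("chain shuffling widens the mutation-difference distribution", {
  memory <- simulate_repertoire(sim_config(n_pairs = 1200L, naive_fraction = 0,
                                           seed = 23L))
  set.seed(24)
  clf <- make_shuffled_pairs(memory)
  diff_of <- function(recs) {
    vapply(recs, function(r) r$heavy$v_mutation_count - r$light$v_mutation_count, 0L)
  }
  native <- clf$records[clf$labels == "native"]
  shuffled <- clf$records[clf$labels == "shuffled"]
  expect_gt(stats::var(diff_of(shuffled)), stats::var(diff_of(native)))
})

test_that("mutation bookkeeping matches germline Hamming distances", {
  reps <- fix_repertoire()
  for (r in reps[1:60]) {
    for (ch in list(r$heavy, r$light)) {
      obs <- strsplit(ch$sequence, "")[[1]]
      templ <- !is.na(ch$germline_full)
      hamming <- sum(obs[templ] != ch$germline_full[templ])
      mut <- if (is.null(ch$mutated_positions)) integer(0) else ch$mutated_positions
      expect_equal(hamming, sum(templ[mut]))
      # V-span count agrees with count_v_mutations
      expect_equal(ch$v_mutation_count, count_v_mutations(ch))
      # conservation: non-CDR3 positions of unmutated chains equal germline
      if (length(mut) == 0L) {
        expect_true(all(obs[templ] == ch$germline_full[templ]))
      }
    }
  }
})

test_that("motif implantation marks positives and only positives", {
  reps <- simulate_repertoire(sim_config(n_pairs = 400L, naive_fraction = 1,
                                         seed = 31L))
  cfg0 <- sim_config(motif_implant_prob = 0, seed = 31L)
  set.seed(32)
  none <- implant_specificity(reps, cfg0)
  # prob 0: sequences untouched, classes balanced
  expect_identical(vapply(none, function(r) r$heavy$sequence, ""),
                   vapply(reps, function(r) r$heavy$sequence, ""))
  expect_equal(sum(vapply(none, function(r) r$specificity_label, "") == "positive"),
               200L)
  cfg1 <- sim_config(motif_implant_prob = 1, seed = 31L)
  set.seed(33)
  all_in <- implant_specificity(reps, cfg1)
  pos <- all_in[vapply(all_in, function(r) r$specificity_label, "") == "positive"]
  carried <- vapply(pos, function(r) {
    s <- region_span(r$heavy, "CDR3")
    grepl(cfg1$motif, substr(r$heavy$sequence, s[["start"]] + 1L, s[["end"]]),
          fixed = TRUE)
  }, TRUE)
  skipped <- attr(all_in, "n_skipped")
  expect_equal(sum(carried), length(pos) - skipped)
  # default probability enriches the motif in positives over negatives
  cfg8 <- sim_config(seed = 31L)
  set.seed(34)
  some <- implant_specificity(reps, cfg8)
  lab <- vapply(some, function(r) r$specificity_label, "")
  has_motif <- vapply(some, function(r) grepl(cfg8$motif, r$heavy$sequence,
                                              fixed = TRUE), TRUE)
  expect_gt(mean(has_motif[lab == "positive"]), mean(has_motif[lab == "negative"]))
})

test_that("identical config and seed give byte-identical repertoire files", {
  cfg <- sim_config(n_pairs = 40L, seed = 55L)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_airr_tsv(simulate_repertoire(cfg), f1)
  write_airr_tsv(simulate_repertoire(cfg), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
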