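# Shared fixtures, built once per test run and memoized.
fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- builder()
  fixture_env[[key]]
}

fix_vocab <- function() memo("vocab", build_vocab)

# Small mixed naive/memory repertoire used across modules.
fix_repertoire <- function() {
  memo("repertoire", function() {
    simulate_repertoire(sim_config(n_pairs = 120L, seed = 101L))
  })
}

fix_encoded <- function() {
  memo("encoded", function() {
    encode_dataset(fix_repertoire(), fix_vocab())
  })
}

# A tiny trained base model (a few hundred steps on the fixture repertoire);
# used by classifier and attribution tests that need informative embeddings.
fix_trained_base <- function() {
  memo("trained_base", function() {
    ds <- fix_encoded()
    cache <- build_plan_cache(ds, "preferential")
    sch <- train_schedule("tiny", total_steps = 250L, warmup_steps = 25L,
                          checkpoint_interval = 250L)
    train_mlm(ds, cache, model_config("tiny"), sch, fix_vocab(), seed = 11L)$params
  })
}

# Hand-built annotated chain with exact region boundaries.
make_chain <- function(lens = c(FR1 = 25L, CDR1 = 8L, FR2 = 17L, CDR2 = 8L,
                                FR3 = 38L, CDR3 = 12L, FR4 = 11L),
                       locus = "heavy", seed = NULL, sequence = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- sum(lens)
  if (is.null(sequence)) {
    sequence <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                               "L", "M", "N", "P", "Q", "R", "S", "T", "V",
                               "W", "Y"), n, replace = TRUE), collapse = "")
  }
  regions <- data.frame(region = names(lens),
                        start = c(0L, cumsum(lens)[-7L]),
                        end = unname(cumsum(lens)),
                        stringsAsFactors = FALSE)
  v_end <- regions$end[5L]
  annotated_chain(sequence, regions, locus,
                  germline_v = substr(sequence, 1L, v_end),
                  v_mutation_count = 0L)
}

make_pair <- function(pair_id = "T1", seed = 1L, cdr3_h = 12L, cdr3_l = 9L,
                      donor_id = "d1", cell_type = "naive") {
  set.seed(seed)
  h <- make_chain(c(FR1 = 25L, CDR1 = 8L, FR2 = 17L, CDR2 = 8L, FR3 = 38L,
                    CDR3 = cdr3_h, FR4 = 11L), "heavy")
  l <- make_chain(c(FR1 = 23L, CDR1 = 7L, FR2 = 15L, CDR2 = 7L, FR3 = 36L,
                    CDR3 = cdr3_l, FR4 = 10L), "kappa")
  paired_record(h, l, pair_id = pair_id, donor_id = donor_id,
                cell_type = cell_type)
}
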