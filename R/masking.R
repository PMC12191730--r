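#' Preferential masking probabilities
#'
#' Builds the per-position masking-probability vector that concentrates
#' training signal in the CDR3s while holding the sequence-average masking
#' rate fixed. CDR3 residue positions receive probability `r_cdr3`; every
#' other residue position receives
#' `(r_avg - r_cdr3 * p_hat) / (1 - p_hat)`, where `p_hat` is the fraction of
#' residue positions lying in either chain's CDR3, so that the mean over
#' residue positions is exactly `r_avg`. Special and pad positions always get
#' probability 0. When the CDR3 fraction is so large that the non-CDR3
#' expression goes negative (`p_hat >= r_avg / r_cdr3`), the non-CDR3
#' probability is clamped to 0 and the plan is flagged `clamped = TRUE`
#' (its average then exceeds `r_avg`).
#'
#' @param region_mask Per-position label vector from [build_region_mask()].
#' @param r_cdr3 CDR3 masking rate; default 0.25, with 0.35 as the supported
#'   high-rate variant.
#' @param r_avg Target average masking rate over residue positions
#'   (default 0.15).
#' @return An object of class `abmlm_plan`: list with `probs` (numeric vector,
#'   same length as the mask), `r_cdr3`, `r_avg`, `p_hat_cdr3`, `clamped`,
#'   `strategy = "preferential"`.
#' @export
preferential_probs <- function(region_mask, r_cdr3 = 0.25, r_avg = 0.15) {
  stopifnot(r_avg > 0, r_avg <= r_cdr3, r_cdr3 <= 1)
  residue <- !region_mask %in% c("SPECIAL", "PAD")
  cdr3 <- region_mask %in% c("H:CDR3", "L:CDR3")
  n_res <- sum(residue)
  if (n_res == 0L) stop("region mask contains no residue positions", call. = FALSE)
  p_hat <- sum(cdr3) / n_res
  if (p_hat >= 1) {
    stop("degenerate input: every residue position is CDR3", call. = FALSE)
  }
  # algebraically identical to (r_avg - r_cdr3 * p_hat) / (1 - p_hat), but
  # collapses to exactly r_avg when r_cdr3 == r_avg, making the uniform
  # strategy a bit-exact special case
  p_non <- r_avg + (r_avg - r_cdr3) * p_hat / (1 - p_hat)
  clamped <- p_hat >= r_avg / r_cdr3
  if (clamped) p_non <- max(p_non, 0)
  probs <- numeric(length(region_mask))
  probs[residue] <- p_non
  probs[cdr3] <- r_cdr3
  structure(list(probs = probs, r_cdr3 = r_cdr3, r_avg = r_avg,
                 p_hat_cdr3 = p_hat, clamped = clamped,
                 strategy = "preferential"),
            class = "abmlm_plan")
}

#' Uniform masking probabilities
#'
#' The conventional baseline: every residue position receives the same
#' masking probability (default 15%); special and pad positions get 0.
#'
#' @param region_mask Per-position label vector from [build_region_mask()].
#' @param rate Masking probability at residue positions.
#' @return An `abmlm_plan` with `strategy = "uniform"`.
#' @export
uniform_probs <- function(region_mask, rate = 0.15) {
  residue <- !region_mask %in% c("SPECIAL", "PAD")
  probs <- numeric(length(region_mask))
  probs[residue] <- rate
  structure(list(probs = probs, r_cdr3 = rate, r_avg = rate,
                 p_hat_cdr3 = sum(region_mask %in% c("H:CDR3", "L:CDR3")) /
                   max(sum(residue), 1L),
                 clamped = FALSE, strategy = "uniform"),
            class = "abmlm_plan")
}

#' Precompute and cache masking plans for a dataset
#'
#' Masking probabilities depend only on each record's region layout, so they
#' are computed in a single pass over the dataset, stored, and reused at every
#' epoch. The cache is keyed by (strategy, `r_cdr3`, `r_avg`, dataset
#' checksum); reading it back under a different configuration raises a
#' stale-cache error rather than silently reusing mismatched probabilities.
#' An instrumented counter (`n_computed`) records how many per-record
#' probability constructions have been performed.
#'
#' @param dataset An encoded dataset from [encode_dataset()].
#' @param strategy `"preferential"` or `"uniform"`.
#' @param r_cdr3,r_avg Rates forwarded to [preferential_probs()] /
#'   [uniform_probs()].
#' @return An object of class `abmlm_plan_cache`: `probs` matrix (n x
#'   max_len), `plans` metadata per record (`p_hat_cdr3`, `clamped`),
#'   `strategy`, rates, `n_clamped`, `n_computed`, `dataset_checksum`.
#' @export
build_plan_cache <- function(dataset, strategy = c("preferential", "uniform"),
                             r_cdr3 = 0.25, r_avg = 0.15) {
  strategy <- match.arg(strategy)
  n <- nrow(dataset$tokens)
  probs <- matrix(0, n, ncol(dataset$tokens))
  p_hat <- numeric(n)
  clamped <- logical(n)
  for (i in seq_len(n)) {
    plan <- if (strategy == "preferential") {
      preferential_probs(dataset$regions[i, ], r_cdr3 = r_cdr3, r_avg = r_avg)
    } else {
      uniform_probs(dataset$regions[i, ], rate = r_avg)
    }
    probs[i, ] <- plan$probs
    p_hat[i] <- plan$p_hat_cdr3
    clamped[i] <- plan$clamped
  }
  structure(list(
    probs = probs, pair_ids = dataset$pair_ids,
    p_hat_cdr3 = p_hat, clamped = clamped,
    strategy = strategy, r_cdr3 = r_cdr3, r_avg = r_avg,
    n_clamped = sum(clamped), n_computed = n,
    dataset_checksum = dataset_checksum(dataset)
  ), class = "abmlm_plan_cache")
}

dataset_checksum <- function(dataset) {
  # cheap structural fingerprint: dims + token sums + ids
  paste0(nrow(dataset$tokens), "x", ncol(dataset$tokens), ":",
         sum(as.numeric(dataset$tokens)), ":",
         sum(utf8ToInt(paste(dataset$pair_ids, collapse = ""))))
}

#' Persist / reload a plan cache
#'
#' The probability matrix is stored as a plain-text matrix file with a JSON
#' manifest (strategy, rates, dataset checksum). [read_plan_cache()] verifies
#' the manifest against the requested configuration and dataset and raises a
#' stale-cache error on any mismatch.
#'
#' @param cache An `abmlm_plan_cache`.
#' @param dir Directory to write `plan_probs.tsv` and `plan_manifest.json`.
#' @return `dir`, invisibly.
#' @export
write_plan_cache <- function(cache, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # 17 significant digits so the text round-trip is bit-exact
  txt <- matrix(formatC(cache$probs, format = "g", digits = 17),
                nrow(cache$probs))
  utils::write.table(txt, file.path(dir, "plan_probs.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  manifest <- list(strategy = cache$strategy, r_cdr3 = cache$r_cdr3,
                   r_avg = cache$r_avg, n_records = nrow(cache$probs),
                   n_clamped = cache$n_clamped,
                   dataset_checksum = cache$dataset_checksum,
                   pair_ids = cache$pair_ids,
                   p_hat_cdr3 = cache$p_hat_cdr3,
                   clamped = cache$clamped)
  jsonlite::write_json(manifest, file.path(dir, "plan_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_plan_cache
#' @param dataset The encoded dataset the cache must match.
#' @param strategy,r_cdr3,r_avg The configuration the cache must match.
#' @export
read_plan_cache <- function(dir, dataset, strategy, r_cdr3 = 0.25, r_avg = 0.15) {
  manifest <- jsonlite::read_json(file.path(dir, "plan_manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$strategy, strategy) ||
      !isTRUE(all.equal(manifest$r_cdr3, r_cdr3)) ||
      !isTRUE(all.equal(manifest$r_avg, r_avg)) ||
      !identical(manifest$dataset_checksum, dataset_checksum(dataset))) {
    stop(structure(class = c("abmlm_stale_cache", "error", "condition"),
                   list(message = "stale plan cache: configuration or dataset does not match the manifest",
                        call = NULL)))
  }
  probs <- as.matrix(utils::read.table(file.path(dir, "plan_probs.tsv"),
                                       sep = "\t"))
  dimnames(probs) <- NULL
  structure(list(probs = probs, pair_ids = manifest$pair_ids,
                 p_hat_cdr3 = manifest$p_hat_cdr3,
                 clamped = manifest$clamped,
                 strategy = manifest$strategy, r_cdr3 = manifest$r_cdr3,
                 r_avg = manifest$r_avg, n_clamped = manifest$n_clamped,
                 n_computed = 0L,
                 dataset_checksum = manifest$dataset_checksum),
            class = "abmlm_plan_cache")
}

#' Dynamic 80/10/10 corruption collator
#'
#' Draws a fresh corruption of a batch from its masking plans: each residue
#' position is selected independently with its per-position plan probability;
#' of the selected positions, 80% are replaced by `<mask>`, 10% by a random
#' residue token (one of the 21 residue tokens, never a special token), and
#' 10% are left unchanged. The original tokens at selected positions are the
#' prediction targets; every other position carries the ignored-position
#' sentinel (0). Masking is dynamic: consecutive calls on the same batch with
#' an advancing RNG stream select different positions.
#'
#' @param tokens Integer token matrix (batch x len) from [encode_dataset()].
#' @param probs Matching masking-probability matrix (rows of a plan cache).
#' @param vocab Vocabulary from [build_vocab()].
#' @return An `abmlm_batch`: `input_ids` (corrupted matrix), `target_ids`
#'   (original tokens at selected positions, 0 elsewhere), `selection`
#'   (logical matrix of predicted positions), and per-call corruption counts
#'   (`n_masked`, `n_random`, `n_kept`).
#' @export
collate_batch <- function(tokens, probs, vocab) {
  if (!all(dim(tokens) == dim(probs))) {
    stop("plan/encoding length mismatch", call. = FALSE)
  }
  sel <- matrix(stats::runif(length(tokens)) < probs, nrow(tokens))
  input <- tokens
  target <- matrix(0L, nrow(tokens), ncol(tokens))
  idx <- which(sel)
  target[idx] <- tokens[idx]
  u <- stats::runif(length(idx))
  mask_it <- idx[u < 0.8]
  rand_it <- idx[u >= 0.8 & u < 0.9]
  input[mask_it] <- vocab$mask_id
  if (length(rand_it) > 0L) {
    input[rand_it] <- sample(vocab$residue_ids, length(rand_it), replace = TRUE)
  }
  structure(list(input_ids = input, target_ids = target, selection = sel,
                 n_masked = length(mask_it), n_random = length(rand_it),
                 n_kept = length(idx) - length(mask_it) - length(rand_it)),
            class = "abmlm_batch")
}
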