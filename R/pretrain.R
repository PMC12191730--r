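region_bucket <- function(labels) {
  # chain-agnostic buckets used for the region-partitioned validation loss
  out <- rep(NA_character_, length(labels))
  bare <- sub("^[HL]:", "", labels)
  out[bare %in% c("FR1", "FR2", "FR3", "FR4")] <- "FR"
  out[bare == "CDR1"] <- "CDR1"
  out[bare == "CDR2"] <- "CDR2"
  out[bare == "CDR3"] <- "CDR3"
  out
}

#' Build fixed uniform validation masks
#'
#' Validation loss is always computed under the uniform masking strategy with
#' a fixed seed, so models trained under different strategies are scored on
#' bit-identical masked positions and the comparison is not confounded by a
#' harder validation task.
#'
#' @param dataset Encoded validation dataset from [encode_dataset()].
#' @param vocab Vocabulary.
#' @param seed Seed for the one-off corruption draw.
#' @param rate Uniform masking rate (default 0.15).
#' @return List with `input_ids`, `target_ids`, `lengths`, `regions`,
#'   trimmed to the longest real sequence in the set.
#' @export
make_validation_masks <- function(dataset, vocab, seed = 99L, rate = 0.15) {
  L <- trim_len(dataset)
  keep <- seq_len(L)
  cache <- build_plan_cache(dataset, "uniform", r_avg = rate)
  batch <- with_seed(seed, collate_batch(dataset$tokens[, keep, drop = FALSE],
                                         cache$probs[, keep, drop = FALSE],
                                         vocab))
  list(input_ids = batch$input_ids, target_ids = batch$target_ids,
       lengths = rowSums(dataset$attention),
       regions = dataset$regions[, keep, drop = FALSE])
}

#' Region-partitioned validation loss
#'
#' Cross-entropy of the model on fixed uniform validation masks, with every
#' masked position's loss assigned to its chain-agnostic region bucket
#' (FR, CDR1, CDR2, CDR3). The overall loss is the target-count-weighted mean
#' of the bucket losses. Buckets with no masked positions at small scale are
#' reported as absent (dropped), never as zero.
#'
#' @param params Model parameters (from [init_model()] or [train_mlm()]).
#' @param val_masks Fixed masks from [make_validation_masks()].
#' @param chunk Forward-pass batch size.
#' @return List with `overall`, `regions` (named numeric), `counts`.
#' @export
validate_mlm <- function(params, val_masks, chunk = 16L) {
  config <- attr(params, "config")
  n <- nrow(val_masks$input_ids)
  losses <- numeric(0)
  buckets <- character(0)
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    res <- cpp_mlm_step(unclass(params), unclass(config),
                        val_masks$input_ids[idx, , drop = FALSE],
                        val_masks$lengths[idx],
                        val_masks$target_ids[idx, , drop = FALSE],
                        want_grads = FALSE, per_position = TRUE)
    reg <- val_masks$regions[idx, , drop = FALSE]
    pos_regions <- reg[cbind(res$target_row, res$target_col)]
    losses <- c(losses, res$per_loss)
    buckets <- c(buckets, region_bucket(pos_regions))
  }
  ok <- !is.na(buckets)
  per_region <- tapply(losses[ok], buckets[ok], mean)
  counts <- tapply(losses[ok], buckets[ok], length)
  list(overall = stats::weighted.mean(per_region, counts),
       regions = per_region[!is.na(per_region)],
       counts = counts)
}

#' Pre-train a masked language model
#'
#' Trains the encoder with dynamically re-drawn corruption from a precomputed
#' masking-plan cache (uniform or preferential), AdamW, and a linear
#' warmup/decay schedule. Cross-entropy is computed over selected positions
#' only. Validation (if a validation set is supplied) always uses fixed
#' uniform masks. The run is fully seeded: identical inputs and seed give an
#' identical loss trace.
#'
#' @param dataset Encoded training dataset from [encode_dataset()].
#' @param cache Masking-plan cache from [build_plan_cache()]; its strategy is
#'   the training strategy, and it must have been built on `dataset`.
#' @param model_cfg An `abmlm_model_config`.
#' @param schedule An `abmlm_schedule`.
#' @param vocab Vocabulary.
#' @param val_masks Optional fixed validation masks from
#'   [make_validation_masks()].
#' @param eval_interval Steps between validation evaluations (default: the
#'   schedule's checkpoint interval).
#' @param seed Integer seed for init, batch sampling and corruption.
#' @return List of class `abmlm_run`: `params` (final), `checkpoints` (list of
#'   parameter snapshots keyed by step), `trace` (data frame `step`, `split`,
#'   `region`, `loss`), `strategy`, `seed`.
#' @export
train_mlm <- function(dataset, cache, model_cfg, schedule, vocab,
                      val_masks = NULL, eval_interval = NULL, seed = 0L) {
  if (!identical(cache$dataset_checksum, dataset_checksum(dataset))) {
    stop(structure(class = c("abmlm_stale_cache", "error", "condition"),
                   list(message = "plan cache was not built on this dataset",
                        call = NULL)))
  }
  eval_interval <- as.integer(eval_interval %||% schedule$checkpoint_interval)
  L <- trim_len(dataset)
  keep <- seq_len(L)
  tokens <- dataset$tokens[, keep, drop = FALSE]
  probs <- cache$probs[, keep, drop = FALSE]
  lens <- rowSums(dataset$attention)
  params <- init_model(model_cfg, seed = seed)
  res <- with_seed(seed + 1L, {
    cpp_train_loop(unclass(params), unclass(model_cfg), tokens, lens, probs,
                   vocab$residue_ids, vocab$mask_id,
                   schedule$total_steps, schedule$batch_size,
                   schedule$peak_lr, schedule$warmup_steps,
                   schedule$checkpoint_interval, weight_decay = 0.01)
  })
  as_params <- function(p) {
    structure(p, class = "abmlm_params", config = model_cfg)
  }
  params <- as_params(res$params)
  checkpoints <- lapply(res$checkpoints, as_params)
  trace <- data.frame(step = seq_len(schedule$total_steps), split = "train",
                      region = "overall", loss = res$losses)
  if (!is.null(val_masks)) {
    for (step_chr in names(checkpoints)) {
      v <- validate_mlm(checkpoints[[step_chr]], val_masks)
      trace <- rbind(trace, data.frame(
        step = as.integer(step_chr), split = "val",
        region = c("overall", names(v$regions)),
        loss = c(v$overall, unname(v$regions))))
    }
  }
  structure(list(params = params, checkpoints = checkpoints,
                 trace = trace, strategy = cache$strategy,
                 seed = as.integer(seed)),
            class = "abmlm_run")
}

#' Pick the checkpoint with the lowest overall validation loss
#'
#' @param trace A loss-trace data frame from [train_mlm()] with validation
#'   rows, or an `abmlm_run`.
#' @return The selected step (integer). Ties go to the earliest step.
#' @export
select_checkpoint <- function(trace) {
  if (inherits(trace, "abmlm_run")) trace <- trace$trace
  v <- trace[trace$split == "val" & trace$region == "overall", ]
  if (nrow(v) == 0L) stop("no validation evaluations in trace", call. = FALSE)
  v$step[which.min(v$loss)]
}

#' Write a loss trace as CSV
#'
#' @param run An `abmlm_run` (or its trace data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_loss_trace <- function(run, path) {
  trace <- if (inherits(run, "abmlm_run")) run$trace else run
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
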