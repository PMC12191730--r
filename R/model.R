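#' Encoder model configuration
#'
#' Two presets are provided: `"paper_350m"`, the full-scale configuration
#' (32 layers, 20 heads, hidden 960, intermediate 3840, ~350M parameters,
#' never trained in tests), and `"tiny"` (2 layers, 4 heads, hidden 64,
#' intermediate 256), the desk-scale default used throughout the package's
#' experiments. The architecture is encoder-only with pre-layer-norm blocks,
#' rotary position embedding and a tied masked-language-model head.
#'
#' @param preset `"tiny"` or `"paper_350m"`; individual fields may be
#'   overridden.
#' @param n_layers,n_heads,hidden_size,intermediate_size,vocab_size,max_len
#'   Architecture fields; `hidden_size` must be divisible by `n_heads`.
#' @return An object of class `abmlm_model_config`.
#' @export
model_config <- function(preset = c("tiny", "paper_350m"),
                         n_layers = NULL, n_heads = NULL, hidden_size = NULL,
                         intermediate_size = NULL, vocab_size = 26L,
                         max_len = 320L) {
  preset <- match.arg(preset)
  base <- switch(preset,
    tiny = list(n_layers = 2L, n_heads = 4L, hidden_size = 64L,
                intermediate_size = 256L),
    paper_350m = list(n_layers = 32L, n_heads = 20L, hidden_size = 960L,
                      intermediate_size = 3840L)
  )
  cfg <- list(
    n_layers = as.integer(n_layers %||% base$n_layers),
    n_heads = as.integer(n_heads %||% base$n_heads),
    hidden_size = as.integer(hidden_size %||% base$hidden_size),
    intermediate_size = as.integer(intermediate_size %||% base$intermediate_size),
    vocab_size = as.integer(vocab_size),
    max_len = as.integer(max_len),
    positional = "rotary",
    pre_layer_norm = TRUE,
    preset = preset
  )
  if (cfg$hidden_size %% cfg$n_heads != 0L) {
    stop("hidden_size must be divisible by n_heads", call. = FALSE)
  }
  structure(cfg, class = "abmlm_model_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shapes of every parameter tensor, in a fixed order. The count and the
# instantiated model enumerate the same table.
param_shapes <- function(config) {
  H <- config$hidden_size
  I <- config$intermediate_size
  V <- config$vocab_size
  shapes <- list(embed = c(V, H))
  for (l in seq_len(config$n_layers)) {
    p <- function(s) paste0("l", l, "_", s)
    layer <- list(c(1L, H), c(1L, H),                    # ln1 g, b
                  c(H, H), c(1L, H), c(H, H), c(1L, H),  # Wq bq Wk bk
                  c(H, H), c(1L, H), c(H, H), c(1L, H),  # Wv bv Wo bo
                  c(1L, H), c(1L, H),                    # ln2 g, b
                  c(H, I), c(1L, I), c(I, H), c(1L, H))  # W1 b1 W2 b2
    names(layer) <- p(c("ln1_g", "ln1_b", "Wq", "bq", "Wk", "bk",
                        "Wv", "bv", "Wo", "bo", "ln2_g", "ln2_b",
                        "W1", "b1", "W2", "b2"))
    shapes <- c(shapes, layer)
  }
  c(shapes, list(final_ln_g = c(1L, H), final_ln_b = c(1L, H),
                 head_W = c(H, H), head_b = c(1L, H),
                 head_ln_g = c(1L, H), head_ln_b = c(1L, H),
                 lm_bias = c(1L, V)))
}

#' Count trainable parameters
#'
#' Exact analytic enumeration of every weight tensor's shape product for a
#' model configuration. The word embedding is tied to the language-model
#' decoder, so it is counted once.
#'
#' @param config An `abmlm_model_config`.
#' @return Integer parameter count (as a double, counts exceed
#'   `.Machine$integer.max` for the full-scale preset).
#' @export
count_parameters <- function(config) {
  sum(vapply(param_shapes(config), function(s) prod(as.numeric(s)), 0))
}

#' Initialize model parameters
#'
#' Weight matrices are drawn N(0, 0.02^2), biases start at zero, layer-norm
#' gains at one. The returned list is the model: every training and inference
#' entry point takes it by value, so snapshots are plain copies.
#'
#' @param config An `abmlm_model_config`.
#' @param seed Integer seed.
#' @return Named list of parameter matrices (class `abmlm_params`).
#' @export
init_model <- function(config, seed = 0L) {
  shapes <- param_shapes(config)
  with_seed(seed, {
    params <- lapply(names(shapes), function(nm) {
      s <- shapes[[nm]]
      if (grepl("ln_g|ln1_g|ln2_g", nm)) {
        matrix(1, s[1L], s[2L])
      } else if (grepl("_b$|bias|bq$|bk$|bv$|bo$|b1$|b2$", nm)) {
        matrix(0, s[1L], s[2L])
      } else {
        matrix(stats::rnorm(prod(s), 0, 0.02), s[1L], s[2L])
      }
    })
    names(params) <- names(shapes)
    structure(params, class = "abmlm_params", config = config)
  })
}

#' Training schedule
#'
#' @param preset `"tiny"` (2000 steps, batch 8, peak 1e-3, 100 warmup,
#'   checkpoint every 500) or `"paper"` (500000 steps, batch 256, peak 1e-4,
#'   30000 warmup, checkpoint every 50000). Fields may be overridden.
#' @param total_steps,batch_size,peak_lr,warmup_steps,checkpoint_interval,seed
#'   Schedule fields; warmup must be shorter than the run.
#' @return An object of class `abmlm_schedule` (decay is always linear).
#' @export
train_schedule <- function(preset = c("tiny", "paper"), total_steps = NULL,
                           batch_size = NULL, peak_lr = NULL,
                           warmup_steps = NULL, checkpoint_interval = NULL,
                           seed = 0L) {
  preset <- match.arg(preset)
  base <- switch(preset,
    tiny = list(total_steps = 2000L, batch_size = 8L, peak_lr = 1e-3,
                warmup_steps = 100L, checkpoint_interval = 500L),
    paper = list(total_steps = 500000L, batch_size = 256L, peak_lr = 1e-4,
                 warmup_steps = 30000L, checkpoint_interval = 50000L)
  )
  out <- list(
    total_steps = as.integer(total_steps %||% base$total_steps),
    batch_size = as.integer(batch_size %||% base$batch_size),
    peak_lr = peak_lr %||% base$peak_lr,
    warmup_steps = as.integer(warmup_steps %||% base$warmup_steps),
    decay = "linear",
    checkpoint_interval = as.integer(checkpoint_interval %||% base$checkpoint_interval),
    seed = as.integer(seed),
    preset = preset
  )
  if (out$warmup_steps >= out$total_steps) {
    stop("warmup_steps must be smaller than total_steps", call. = FALSE)
  }
  structure(out, class = "abmlm_schedule")
}

# Columns 1..trim_len(dataset) carry every real token of every record.
trim_len <- function(dataset) max(rowSums(dataset$attention))

#' Pooled sequence embeddings from a frozen base model
#'
#' Runs the encoder forward and pools the final hidden states, either at the
#' leading `<cls>` position or as the mean over residue positions.
#'
#' @param params Model parameters.
#' @param dataset Encoded dataset from [encode_dataset()].
#' @param pooling `"cls"` or `"mean"`.
#' @param chunk Forward-pass batch size.
#' @return Numeric matrix, one pooled embedding per record.
#' @export
pooled_features <- function(params, dataset, pooling = c("cls", "mean"),
                            chunk = 32L) {
  pooling <- match.arg(pooling)
  config <- attr(params, "config")
  L <- trim_len(dataset)
  tokens <- dataset$tokens[, seq_len(L), drop = FALSE]
  lens <- rowSums(dataset$attention)
  resmask <- 1 * (!dataset$regions[, seq_len(L), drop = FALSE] %in%
                    c("SPECIAL", "PAD"))
  resmask <- matrix(resmask, nrow(tokens), L)
  n <- nrow(tokens)
  out <- matrix(0, n, config$hidden_size)
  pool_code <- if (pooling == "cls") 0L else 1L
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    out[idx, ] <- cpp_pooled(unclass(params), unclass(config),
                             tokens[idx, , drop = FALSE], lens[idx],
                             pool_code, resmask[idx, , drop = FALSE])
  }
  out
}

params_checksum <- function(params) {
  sum(vapply(params, function(p) sum(abs(p)), 0))
}
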