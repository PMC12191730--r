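#' Hand-parameterized base model that exposes a CDR-H3 motif
#'
#' Constructs an encoder whose pooled representation is linearly separable by
#' the presence of a given residue 5-mer, without any training: a reference
#' "base that exposes the motif" for exercising the frozen-base classifier
#' head and the attribution pipeline on a signal whose ground truth is known
#' exactly.
#'
#' The construction uses one layer and four heads. Queries and keys are
#' content-free rotary biases, so each head attends almost deterministically
#' to a fixed relative offset (-2, -1, +1, +2); its value is an indicator of
#' whether the token at that offset is the motif residue expected there,
#' relative to the motif's center. The feed-forward block thresholds the sum
#' of the four neighbor indicators plus the center-residue identity (an AND
#' gate over the full 5-mer), and the final layer-norm gain keeps only the
#' gate's output dimension, so the mean-pooled state is essentially a count
#' of motif occurrences. All indicator magnitudes follow in closed form from
#' the layer-norm arithmetic of the one-hot embedding, so the gate threshold
#' is calibrated analytically, midway between a full match and the best
#' partial match.
#'
#' @param motif Residue 5-mer (default the simulator's default motif).
#' @param vocab Vocabulary from [build_vocab()].
#' @return An `abmlm_params` model (1 layer, 4 heads, hidden 64,
#'   intermediate 256) usable anywhere a trained base is.
#' @export
motif_probe_base <- function(motif = "WGRDY", vocab = build_vocab()) {
  k <- nchar(motif)
  stopifnot(k == 5L)
  config <- model_config("tiny", n_layers = 1L, n_heads = 4L,
                         hidden_size = 64L, intermediate_size = 256L)
  params <- init_model(config, seed = 0L)
  for (nm in names(params)) {
    if (grepl("ln._g$|ln_g$", nm)) params[[nm]][] <- 1 else params[[nm]][] <- 0
  }
  dh <- 16L
  chars <- strsplit(motif, "")[[1L]]
  center <- 3L
  center_dim <- vocab$index[[chars[center]]]
  s <- 4  # one-hot embedding scale (layer norm makes the choice immaterial)
  for (t in seq_len(26L)) params$embed[t, t] <- s
  offsets <- c(-2L, -1L, 1L, 2L)
  amp <- 6
  thetas <- 10000^(-2 * (0:(dh / 2 - 1)) / dh)
  for (h in seq_along(offsets)) {
    d <- offsets[h]
    base_col <- (h - 1L) * dh
    for (i in seq_len(dh / 2)) {
      # q_p . k_m = amp^2 * sum_i cos(theta_i * (m - p - d)): sharp peak at
      # relative offset d
      params$l1_bq[1L, base_col + 2L * i - 1L] <- amp * cos(thetas[i] * d)
      params$l1_bq[1L, base_col + 2L * i] <- amp * sin(thetas[i] * d)
      params$l1_bk[1L, base_col + 2L * i - 1L] <- amp
    }
    # value = indicator that the attended token is the expected residue
    params$l1_Wv[vocab$index[[chars[center + d]]], base_col + 1L] <- 1
    # route each head's indicator to its own residual dimension
    params$l1_Wo[base_col + 1L, 30L + h] <- 1
  }
  flag_dims <- 30L + seq_along(offsets)

  # closed-form indicator arithmetic ---------------------------------------
  # LN of a one-hot at scale s: hit = (s - s/64)/sigma, sigma = s*sqrt(63)/64
  sigma1 <- s * sqrt(63) / 64
  hit <- (s - s / 64) / sigma1            # ~7.94 at the matched dimension
  # x2 at a candidate center = own one-hot (s) + B matched flags (~hit each);
  # gate input = sum of LN2(x2) over the 4 flag dims + the center dim
  gate_z <- function(B) {
    x2 <- numeric(64L)
    x2[center_dim] <- s
    x2[flag_dims[seq_len(B)]] <- hit
    mu <- mean(x2)
    sd2 <- sqrt(mean((x2 - mu)^2))
    sum((x2[c(flag_dims, center_dim)] - mu) / sd2)
  }
  z_full <- gate_z(4L)
  z_partial <- gate_z(3L)
  params$l1_W1[c(flag_dims, center_dim), 1L] <- 1
  params$l1_b1[1L, 1L] <- -(z_full + z_partial) / 2
  params$l1_W2[1L, 41L] <- 8
  # keep only the gate output after the final layer norm
  params$final_ln_g[] <- 0
  params$final_ln_g[1L, 41L] <- 1
  attr(params, "config") <- config
  class(params) <- "abmlm_params"
  params
}
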