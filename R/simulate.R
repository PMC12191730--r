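AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_peptide <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Parameters of the synthetic paired-repertoire generator. Defaults are the
#' package's standing model of a healthy paired repertoire: roughly half naive
#' cells, memory cells carrying a shared per-cell maturation intensity (mean
#' `mutation_rate_scale` heavy-chain mutations) with light chains at 0.8x that
#' intensity, CDR-biased mutation placement, and junctional diversity from
#' geometric trimming plus Poisson non-templated insertion.
#'
#' @param n_pairs Number of paired records to generate.
#' @param naive_fraction Probability a cell is naive (zero mutations).
#' @param mutation_rate_scale Expected heavy-chain mutation count for a
#'   mutated (memory) cell; the per-cell latent intensity is Gamma-distributed
#'   with this mean so heavy and light counts are positively correlated.
#' @param cdr_hotspot_weight Multiplier (>= 1) up-weighting CDR positions when
#'   placing mutations.
#' @param cdr3_insertion_mean Expected number of non-templated residues
#'   inserted at each junction (Poisson).
#' @param trim_geometric_p Success parameter of the geometric junction-trim
#'   distribution (counts trimmed residues from each segment end).
#' @param motif Residue k-mer implanted in positive-class CDRH3s.
#' @param motif_implant_prob Probability a positive record receives the motif.
#' @param n_donors Number of donors (independent replicate streams).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   repertoires.
#' @return An object of class `abmlm_sim_config`.
#' @export
sim_config <- function(n_pairs = 1000L, naive_fraction = 0.5,
                       mutation_rate_scale = 8, cdr_hotspot_weight = 3,
                       cdr3_insertion_mean = 4, trim_geometric_p = 0.5,
                       motif = "WGRDY", motif_implant_prob = 0.8,
                       n_donors = 4L, seed = 42L) {
  stopifnot(naive_fraction >= 0, naive_fraction <= 1,
            motif_implant_prob >= 0, motif_implant_prob <= 1,
            mutation_rate_scale >= 0, cdr_hotspot_weight >= 1,
            trim_geometric_p > 0, trim_geometric_p <= 1,
            cdr3_insertion_mean >= 0, n_pairs >= 1, n_donors >= 1)
  structure(list(
    n_pairs = as.integer(n_pairs), naive_fraction = naive_fraction,
    mutation_rate_scale = mutation_rate_scale,
    cdr_hotspot_weight = cdr_hotspot_weight,
    cdr3_insertion_mean = cdr3_insertion_mean,
    trim_geometric_p = trim_geometric_p,
    motif = motif, motif_implant_prob = motif_implant_prob,
    n_donors = as.integer(n_donors), seed = as.integer(seed)
  ), class = "abmlm_sim_config")
}

# Region length defaults (residues); jittered a little per germline segment.
GERMLINE_REGION_LEN <- c(FR1 = 25L, CDR1 = 8L, FR2 = 17L, CDR2 = 8L, FR3 = 38L)
FR4_LEN <- 11L
V_TAIL_LEN <- 4L   # germline CDR3 head contributed by V
J_HEAD_LEN <- 4L   # germline CDR3 tail contributed by J
D_LEN <- 5L        # heavy-only diversity segment

#' Build a synthetic germline segment library
#'
#' Generates random V, D and J amino-acid segments for one locus. V segments
#' carry complete FR1, CDR1, FR2, CDR2, FR3 boundary annotations plus a short
#' CDR3 head (the V tail); J segments carry a CDR3 tail (the J head) plus FR4;
#' D segments exist only for the heavy locus. Region lengths are the package
#' defaults (FR1 ~25, CDR1 ~8, FR2 ~17, CDR2 ~8, FR3 ~38, FR4 ~11) with small
#' per-segment jitter.
#'
#' @param locus `"heavy"`, `"kappa"` or `"lambda"`.
#' @param n_v,n_d,n_j Segment counts; `n_d` must be 0 unless `locus` is heavy.
#' @param seed Integer seed; the library is a pure function of its arguments.
#' @return An object of class `abmlm_germline`: lists `v_segments`,
#'   `d_segments`, `j_segments`, each entry a list with the segment `name`,
#'   residue string(s) and region boundaries.
#' @export
build_germline_library <- function(locus = c("heavy", "kappa", "lambda"),
                                   n_v, n_d = 0L, n_j, seed) {
  locus <- match.arg(locus)
  stopifnot(n_v >= 1, n_j >= 1)
  if (locus != "heavy" && n_d > 0L) {
    stop("D segments requested for a light locus", call. = FALSE)
  }
  if (locus == "heavy" && n_d < 1L) {
    stop("heavy locus requires n_d >= 1", call. = FALSE)
  }
  prefix <- switch(locus, heavy = "IGH", kappa = "IGK", lambda = "IGL")
  with_seed(seed, {
    v_segments <- lapply(seq_len(n_v), function(i) {
      lens <- GERMLINE_REGION_LEN +
        vapply(c(2L, 1L, 2L, 1L, 2L), function(j) sample(-j:j, 1L), 0L)
      bounds <- data.frame(
        region = names(GERMLINE_REGION_LEN),
        start = c(0L, cumsum(lens)[-5L]),
        end = unname(cumsum(lens)),
        stringsAsFactors = FALSE
      )
      list(name = sprintf("%sV-%02d", prefix, i),
           fr_cdr = rand_peptide(sum(lens)),
           bounds = bounds,
           cdr3_tail = rand_peptide(V_TAIL_LEN + sample(-1:1, 1L)))
    })
    d_segments <- if (locus == "heavy") {
      lapply(seq_len(n_d), function(i) {
        list(name = sprintf("%sD-%02d", prefix, i),
             seq = rand_peptide(D_LEN + sample(-2:2, 1L)))
      })
    } else list()
    j_segments <- lapply(seq_len(n_j), function(i) {
      list(name = sprintf("%sJ-%02d", prefix, i),
           cdr3_head = rand_peptide(J_HEAD_LEN + sample(-1:1, 1L)),
           fr4 = rand_peptide(FR4_LEN + sample(-1:1, 1L)))
    })
    structure(list(locus = locus, seed = as.integer(seed),
                   v_segments = v_segments, d_segments = d_segments,
                   j_segments = j_segments),
              class = "abmlm_germline")
  })
}

rtrim <- function(p) stats::rgeom(1L, p)

# Trim a segment from the left and/or right by geometric counts, capped at
# the segment length.
trim_segment <- function(seq, p, left = FALSE, right = FALSE) {
  n <- nchar(seq)
  l <- if (left) min(rtrim(p), n) else 0L
  r <- if (right) min(rtrim(p), n - l) else 0L
  if (n - l - r <= 0L) return("")
  substr(seq, l + 1L, n - r)
}

# Recombine one chain from a germline library; uses the current RNG stream.
recombine_chain <- function(library, config) {
  v <- library$v_segments[[sample.int(length(library$v_segments), 1L)]]
  j <- library$j_segments[[sample.int(length(library$j_segments), 1L)]]
  heavy <- library$locus == "heavy"
  repeat {
    v_tail <- trim_segment(v$cdr3_tail, config$trim_geometric_p, right = TRUE)
    d_part <- if (heavy) {
      d <- library$d_segments[[sample.int(length(library$d_segments), 1L)]]
      trim_segment(d$seq, config$trim_geometric_p, left = TRUE, right = TRUE)
    } else ""
    n_ins1 <- stats::rpois(1L, config$cdr3_insertion_mean / (if (heavy) 2 else 1))
    n_ins2 <- if (heavy) stats::rpois(1L, config$cdr3_insertion_mean / 2) else 0L
    ins1 <- if (n_ins1 > 0L) rand_peptide(n_ins1) else ""
    ins2 <- if (n_ins2 > 0L) rand_peptide(n_ins2) else ""
    j_head <- trim_segment(j$cdr3_head, config$trim_geometric_p, left = TRUE)
    cdr3 <- if (heavy) {
      paste0(v_tail, ins1, d_part, ins2, j_head)
    } else {
      paste0(v_tail, ins1, j_head)
    }
    if (nchar(cdr3) >= 1L) break  # never emit an empty CDR3
  }
  templated <- c(
    strsplit(v_tail, "", fixed = TRUE)[[1L]],
    if (n_ins1 > 0L) rep(NA_character_, n_ins1),
    if (heavy) strsplit(d_part, "", fixed = TRUE)[[1L]],
    if (n_ins2 > 0L) rep(NA_character_, n_ins2),
    strsplit(j_head, "", fixed = TRUE)[[1L]]
  )
  seq <- paste0(v$fr_cdr, cdr3, j$fr4)
  fr3_end <- v$bounds$end[5L]
  regions <- data.frame(
    region = REGION_ORDER,
    start = c(v$bounds$start, fr3_end, fr3_end + nchar(cdr3)),
    end = c(v$bounds$end, fr3_end + nchar(cdr3),
            fr3_end + nchar(cdr3) + nchar(j$fr4)),
    stringsAsFactors = FALSE
  )
  germline_full <- c(strsplit(v$fr_cdr, "", fixed = TRUE)[[1L]], templated,
                     strsplit(j$fr4, "", fixed = TRUE)[[1L]])
  ch <- annotated_chain(seq, regions, library$locus,
                        germline_v = v$fr_cdr, v_mutation_count = 0L,
                        germline_full = germline_full)
  ch$v_call <- v$name
  ch$j_call <- j$name
  ch
}

#' Recombine one paired record
#'
#' Assembles a heavy and a light chain by the simulator's junctional model:
#' CDR3 = geometrically trimmed V tail + (heavy only: trimmed D segment) +
#' Poisson-many uniform non-templated insertions + trimmed J head. All
#' non-CDR3 residues equal germline and true per-position germline provenance
#' is stored. Consumes the caller's RNG stream.
#'
#' @param library_h Heavy-locus germline library.
#' @param library_l Light-locus (kappa or lambda) germline library.
#' @param config An `abmlm_sim_config`.
#' @param pair_id,donor_id,cell_type Record metadata.
#' @return An `abmlm_pair` with unmutated chains.
#' @export
recombine_pair <- function(library_h, library_l, config,
                           pair_id = "P1", donor_id = "d1",
                           cell_type = "naive") {
  stopifnot(library_h$locus == "heavy", library_l$locus != "heavy")
  paired_record(recombine_chain(library_h, config),
                recombine_chain(library_l, config),
                pair_id = pair_id, donor_id = donor_id, cell_type = cell_type)
}

mutate_chain <- function(chain, m, config) {
  n <- nchar(chain$sequence)
  m <- min(m, n)
  if (m == 0L) return(chain)
  labels <- region_labels_per_position(chain)
  w <- ifelse(labels %in% c("CDR1", "CDR2", "CDR3"), config$cdr_hotspot_weight, 1)
  pos <- sample.int(n, m, prob = w)
  chars <- strsplit(chain$sequence, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
  }
  chain$sequence <- paste(chars, collapse = "")
  chain$mutated_positions <- sort(pos)
  chain$v_mutation_count <- count_v_mutations(chain)
  chain
}

#' Apply somatic hypermutation to a paired record
#'
#' Memory cells draw one latent maturation intensity per pair (Gamma with
#' shape 2 and mean `mutation_rate_scale`); the heavy chain receives
#' Poisson(intensity) mutations and the light chain Poisson(0.8 x intensity),
#' which couples the two chains' mutation loads the way native pairs couple
#' them. Mutated positions are sampled with CDR positions up-weighted by
#' `cdr_hotspot_weight`; substitutions are uniform over the 19 alternative
#' residues. Naive cells are returned untouched with zero counts. Consumes the
#' caller's RNG stream.
#'
#' @param record An `abmlm_pair` fresh from [recombine_pair()].
#' @param config An `abmlm_sim_config`.
#' @return The mutated record; each chain's `v_mutation_count` is updated and
#'   the realized per-chain mutation totals are stored as `n_mutations`.
#' @export
apply_shm <- function(record, config) {
  if (record$cell_type == "naive") {
    record$heavy$n_mutations <- 0L
    record$light$n_mutations <- 0L
    return(record)
  }
  lambda_pair <- stats::rgamma(1L, shape = 2, scale = config$mutation_rate_scale / 2)
  m_h <- stats::rpois(1L, lambda_pair)
  m_l <- stats::rpois(1L, 0.8 * lambda_pair)
  record$heavy <- mutate_chain(record$heavy, m_h, config)
  record$light <- mutate_chain(record$light, m_l, config)
  record$heavy$n_mutations <- length(record$heavy$mutated_positions)
  record$light$n_mutations <- length(record$light$mutated_positions)
  record
}

#' Implant a specificity motif into positive-class CDRH3s
#'
#' Gives a learnable sequence signal to the positive specificity class:
#' each positive-labeled record receives the configured motif at a random
#' offset inside its heavy-chain CDR3 with probability `motif_implant_prob`
#' (residues are overwritten, length is preserved, implanted positions are
#' marked non-templated). Negatives are never implanted. Records whose CDRH3
#' is shorter than the motif are skipped and counted.
#'
#' @param records List of `abmlm_pair` records. If every record is
#'   `"unlabeled"`, a balanced random positive/negative labeling is assigned
#'   first.
#' @param config An `abmlm_sim_config` (fields `motif`, `motif_implant_prob`).
#' @return The records, with attribute `n_skipped` counting motif-too-long
#'   skips.
#' @export
implant_specificity <- function(records, config) {
  labs <- vapply(records, function(r) r$specificity_label, "")
  if (all(labs == "unlabeled")) {
    n <- length(records)
    pos <- sample.int(n, n %/% 2L)
    for (i in seq_len(n)) {
      records[[i]]$specificity_label <- if (i %in% pos) "positive" else "negative"
    }
  }
  k <- nchar(config$motif)
  n_skipped <- 0L
  for (i in seq_along(records)) {
    if (records[[i]]$specificity_label != "positive") next
    if (stats::runif(1L) > config$motif_implant_prob) next
    ch <- records[[i]]$heavy
    span <- region_span(ch, "CDR3")
    len3 <- span[["end"]] - span[["start"]]
    if (len3 < k) {
      n_skipped <- n_skipped + 1L
      next
    }
    off <- span[["start"]] + sample.int(len3 - k + 1L, 1L) - 1L  # 0-based
    chars <- strsplit(ch$sequence, "", fixed = TRUE)[[1L]]
    chars[(off + 1L):(off + k)] <- strsplit(config$motif, "", fixed = TRUE)[[1L]]
    ch$sequence <- paste(chars, collapse = "")
    if (!is.null(ch$germline_full)) {
      ch$germline_full[(off + 1L):(off + k)] <- NA_character_
    }
    records[[i]]$heavy <- ch
  }
  attr(records, "n_skipped") <- n_skipped
  records
}

#' Simulate a paired antibody repertoire
#'
#' End-to-end generator: builds heavy and kappa/lambda germline libraries from
#' the config seed, recombines `n_pairs` records across `n_donors` donors,
#' assigns naive/memory cell types by a per-record Bernoulli draw, and applies
#' somatic hypermutation. Identical config (including seed) gives a
#' byte-identical repertoire.
#'
#' @param config An `abmlm_sim_config`.
#' @param n_v,n_d,n_j Germline library sizes per locus.
#' @return List of `abmlm_pair` records, with the libraries attached as
#'   attribute `libraries`.
#' @export
simulate_repertoire <- function(config, n_v = 20L, n_d = 8L, n_j = 4L) {
  lib_h <- build_germline_library("heavy", n_v, n_d, n_j, seed = config$seed + 1L)
  lib_k <- build_germline_library("kappa", n_v, 0L, n_j, seed = config$seed + 2L)
  lib_l <- build_germline_library("lambda", n_v, 0L, n_j, seed = config$seed + 3L)
  with_seed(config$seed, {
    records <- vector("list", config$n_pairs)
    for (i in seq_len(config$n_pairs)) {
      light_lib <- if (stats::runif(1L) < 0.6) lib_k else lib_l
      cell_type <- if (stats::runif(1L) < config$naive_fraction) "naive" else "memory"
      rec <- recombine_pair(lib_h, light_lib, config,
                            pair_id = sprintf("P%06d", i),
                            donor_id = sprintf("donor%02d",
                                               sample.int(config$n_donors, 1L)),
                            cell_type = cell_type)
      records[[i]] <- apply_shm(rec, config)
    }
    attr(records, "libraries") <- list(heavy = lib_h, kappa = lib_k, lambda = lib_l)
    records
  })
}
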