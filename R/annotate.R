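REGION_ORDER <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")

#' Construct an annotated antibody chain
#'
#' An annotated chain is a residue string plus an ordered set of region
#' boundaries (FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4) in 0-based half-open
#' coordinates, the germline V reference (FR1..FR3 span) when known, and the
#' V-gene amino-acid mutation count.
#'
#' @param sequence Residue string (one-letter amino-acid codes).
#' @param regions Data frame with columns `region`, `start`, `end` (0-based
#'   half-open), rows in the canonical order FR1..FR4, tiling the sequence.
#' @param locus `"heavy"`, `"kappa"` or `"lambda"`.
#' @param germline_v Germline V amino-acid string covering FR1..FR3, or `NA`.
#' @param v_mutation_count Integer count of amino-acid mutations in the V
#'   span, or `NA` to leave unset.
#' @param germline_full Optional per-position germline character vector for
#'   the whole chain (`NA` at non-templated CDR3 positions); used by the
#'   simulator to keep mutation bookkeeping exact.
#' @return An object of class `abmlm_chain`.
#' @export
annotated_chain <- function(sequence, regions, locus,
                            germline_v = NA_character_,
                            v_mutation_count = NA_integer_,
                            germline_full = NULL) {
  chain <- structure(list(
    sequence = sequence,
    regions = regions,
    locus = locus,
    germline_v = germline_v,
    v_mutation_count = as.integer(v_mutation_count),
    germline_full = germline_full
  ), class = "abmlm_chain")
  validate_chain(chain)
  chain
}

# Region-tiling invariants; errors have class "abmlm_mask_error" so QC
# filtering can catch them without masking real bugs.
validate_chain <- function(chain) {
  if (!inherits(chain, "abmlm_chain")) {
    stop("expected an abmlm_chain object", call. = FALSE)
  }
  r <- chain$regions
  n <- nchar(chain$sequence)
  ok <- is.data.frame(r) && nrow(r) == 7L &&
    identical(as.character(r$region), REGION_ORDER) &&
    r$start[1L] == 0L && r$end[7L] == n &&
    all(r$end > r$start) &&
    all(r$start[-1L] == r$end[-7L])
  if (!ok || n < 7L) {
    stop(structure(class = c("abmlm_mask_error", "error", "condition"),
                   list(message = "region annotations do not tile the sequence in canonical order (mask-alignment error)",
                        call = NULL)))
  }
  if (!chain$locus %in% c("heavy", "kappa", "lambda")) {
    stop("locus must be heavy, kappa or lambda", call. = FALSE)
  }
  invisible(chain)
}

# Per-position region labels ("FR1", "FR1", ..., "FR4") for one chain.
region_labels_per_position <- function(chain) {
  r <- chain$regions
  rep(as.character(r$region), r$end - r$start)
}

region_span <- function(chain, region) {
  r <- chain$regions
  i <- match(region, r$region)
  c(start = r$start[i], end = r$end[i])
}

# V span = FR1..FR3 (0-based half-open end).
v_span_end <- function(chain) {
  region_span(chain, "FR3")[["end"]]
}

#' Construct a paired record
#'
#' @param heavy,light `abmlm_chain` objects.
#' @param pair_id Unique identifier.
#' @param donor_id Donor label.
#' @param cell_type `"naive"` or `"memory"`.
#' @param pairing_label `"native"` (default at generation) or `"shuffled"`.
#' @param specificity_label `"positive"`, `"negative"` or `"unlabeled"`.
#' @return An object of class `abmlm_pair`.
#' @export
paired_record <- function(heavy, light, pair_id, donor_id = "d1",
                          cell_type = c("naive", "memory"),
                          pairing_label = "native",
                          specificity_label = "unlabeled") {
  cell_type <- match.arg(cell_type)
  structure(list(
    heavy = heavy, light = light, pair_id = pair_id, donor_id = donor_id,
    cell_type = cell_type, pairing_label = pairing_label,
    specificity_label = specificity_label
  ), class = "abmlm_pair")
}

#' Build the chain-qualified region mask for an encoded pair
#'
#' Aligns region labels to the token layout of [encode_pair()]: each residue
#' position carries one of the 14 chain-qualified labels (7 regions x 2
#' chains, e.g. `"H:CDR3"`), special tokens are labeled `"SPECIAL"` and pads
#' `"PAD"`. Records whose annotations violate the region-tiling invariants
#' (for example an empty framework placing two CDRs adjacently) raise a
#' condition of class `abmlm_mask_error` and are meant to be removed by
#' [filter_dataset()].
#'
#' @param pair An `abmlm_pair` record.
#' @param vocab Vocabulary from [build_vocab()].
#' @param max_len Encoded length (default 320).
#' @return Character vector of per-position labels, length `max_len`.
#' @export
build_region_mask <- function(pair, vocab, max_len = 320L) {
  encode_pair(pair$heavy, pair$light, vocab, max_len = max_len,
              pair_id = pair$pair_id)$region_mask
}

#' Fraction of residue positions lying in either chain's CDR3
#'
#' @param region_mask Per-position label vector from [build_region_mask()].
#' @return `p_hat_cdr3`, the CDR3 residue fraction used by the preferential
#'   masking equation.
#' @export
cdr3_fraction <- function(region_mask) {
  residue <- !region_mask %in% c("SPECIAL", "PAD")
  sum(region_mask %in% c("H:CDR3", "L:CDR3")) / sum(residue)
}

#' Remove duplicate pairs and mask-alignment failures
#'
#' Mirrors the dataset QC applied before pre-training: exact duplicates of the
#' concatenated heavy+light amino-acid sequence are dropped (first occurrence
#' kept, in input order) and records whose region annotations fail the tiling
#' invariants are dropped. Every rejection is logged with its reason.
#'
#' @param records List of `abmlm_pair` records.
#' @param vocab Vocabulary (defaults to [build_vocab()]); used to exercise the
#'   mask construction that detects alignment errors.
#' @param max_len Encoded length for the mask-alignment check.
#' @return List with `kept` (records) and `rejected` (data frame `pair_id`,
#'   `reason` with reasons `"duplicate"` or `"mask_alignment_error"`).
#' @export
filter_dataset <- function(records, vocab = build_vocab(), max_len = 320L) {
  kept <- list()
  rej_id <- character(0)
  rej_reason <- character(0)
  seen <- new.env(parent = emptyenv())
  for (rec in records) {
    mask_ok <- tryCatch({
      build_region_mask(rec, vocab, max_len = max_len)
      TRUE
    }, abmlm_mask_error = function(e) FALSE)
    if (!mask_ok) {
      rej_id <- c(rej_id, rec$pair_id)
      rej_reason <- c(rej_reason, "mask_alignment_error")
      next
    }
    key <- paste0(rec$heavy$sequence, "|", rec$light$sequence)
    if (!is.null(seen[[key]])) {
      rej_id <- c(rej_id, rec$pair_id)
      rej_reason <- c(rej_reason, "duplicate")
      next
    }
    seen[[key]] <- TRUE
    kept[[length(kept) + 1L]] <- rec
  }
  list(kept = kept,
       rejected = data.frame(pair_id = rej_id, reason = rej_reason,
                             stringsAsFactors = FALSE))
}

#' Count amino-acid mutations in the V span
#'
#' Compares the FR1..FR3 span of the observed sequence to the germline V
#' reference position by position. CDR3 differences never count: the CDR3 is
#' outside the V-span comparison.
#'
#' @param chain An `abmlm_chain` with `germline_v` present.
#' @return Integer mutation count.
#' @export
count_v_mutations <- function(chain) {
  validate_chain(chain)
  if (is.na(chain$germline_v)) {
    stop("unsupported record: chain has no germline V reference", call. = FALSE)
  }
  end <- v_span_end(chain)
  obs <- strsplit(substr(chain$sequence, 1L, end), "", fixed = TRUE)[[1L]]
  ref <- strsplit(chain$germline_v, "", fixed = TRUE)[[1L]]
  if (length(ref) < end) {
    stop("germline V reference shorter than the FR1..FR3 span", call. = FALSE)
  }
  sum(obs != ref[seq_len(end)])
}

# Global-alignment identity between two residue strings: exact matches over
# the alignment length (gap columns count against identity).
pair_identity <- function(a, b, submat, gap_open = 10, gap_ext = 0.5) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = submat, gapOpening = gap_open, gapExtension = gap_ext
  )
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

identity_submat <- function() {
  letters <- Biostrings::AA_ALPHABET
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m
}

#' Greedy identity clustering of paired sequences
#'
#' Deduplicates a repertoire at a pairwise-identity threshold the way
#' repertoire pipelines do before training (e.g. at 95% or 96% identity).
#' Records are processed in descending length of the concatenated heavy+light
#' string (ties broken by `pair_id`); each record joins the first existing
#' cluster whose representative it matches at or above the threshold, else
#' founds a new cluster. Identity is exact matches over the global-alignment
#' length, so gaps count as mismatches. The representative is the first
#' (longest) member; output order is deterministic.
#'
#' @param records List of `abmlm_pair` records.
#' @param threshold Identity threshold in (0, 1]; 0.95 and 0.96 are the
#'   conventional choices.
#' @return List of representative records, in processing order.
#' @export
cluster_identity <- function(records, threshold = 0.96) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(records) == 0L) return(list())
  seqs <- vapply(records, function(r) paste0(r$heavy$sequence, r$light$sequence), "")
  ids <- vapply(records, function(r) r$pair_id, "")
  ord <- order(-nchar(seqs), ids)
  submat <- identity_submat()
  reps <- list()
  rep_seqs <- character(0)
  for (i in ord) {
    s <- seqs[i]
    hit <- FALSE
    for (j in seq_along(rep_seqs)) {
      # identity is bounded by length ratio; skip alignments that cannot reach
      # the threshold
      if (nchar(s) / nchar(rep_seqs[j]) < threshold) next
      if (rep_seqs[j] == s || pair_identity(rep_seqs[j], s, submat) >= threshold) {
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      reps[[length(reps) + 1L]] <- records[[i]]
      rep_seqs <- c(rep_seqs, s)
    }
  }
  reps
}
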