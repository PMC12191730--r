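region_string <- function(chain, region) {
  s <- region_span(chain, region)
  substr(chain$sequence, s[["start"]] + 1L, s[["end"]])
}

#' Write records as an AIRR-rearrangement-style TSV
#'
#' One row per chain with the columns repertoire pipelines emit:
#' `sequence_id`, `cell_id`, `locus`, `sequence_aa`, `fwr1_aa`..`fwr4_aa`,
#' `cdr1_aa`..`cdr3_aa`, `v_call`, `v_mutation_count`, `donor_id`,
#' `cell_type`. Tab-separated, UTF-8, with header.
#'
#' @param records List of `abmlm_pair` records.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_airr_tsv <- function(records, path) {
  rows <- lapply(records, function(rec) {
    do.call(rbind, lapply(list(c("H", "heavy"), c("L", "light")), function(side) {
      ch <- rec[[side[2L]]]
      data.frame(
        sequence_id = paste0(rec$pair_id, "_", side[1L]),
        cell_id = rec$pair_id,
        locus = ch$locus,
        sequence_aa = ch$sequence,
        fwr1_aa = region_string(ch, "FR1"), cdr1_aa = region_string(ch, "CDR1"),
        fwr2_aa = region_string(ch, "FR2"), cdr2_aa = region_string(ch, "CDR2"),
        fwr3_aa = region_string(ch, "FR3"), cdr3_aa = region_string(ch, "CDR3"),
        fwr4_aa = region_string(ch, "FR4"),
        v_call = if (is.null(ch$v_call)) NA_character_ else ch$v_call,
        v_mutation_count = ch$v_mutation_count,
        donor_id = rec$donor_id,
        cell_type = rec$cell_type,
        stringsAsFactors = FALSE
      )
    }))
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the pairing/specificity label table
#'
#' Comma-separated companion table to the AIRR TSV: `pair_id`,
#' `heavy_sequence_id`, `light_sequence_id`, `pairing_label`,
#' `specificity_label`.
#'
#' @param records List of `abmlm_pair` records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pairs_csv <- function(records, path) {
  tab <- data.frame(
    pair_id = vapply(records, function(r) r$pair_id, ""),
    heavy_sequence_id = vapply(records, function(r) paste0(r$pair_id, "_H"), ""),
    light_sequence_id = vapply(records, function(r) paste0(r$pair_id, "_L"), ""),
    pairing_label = vapply(records, function(r) r$pairing_label, ""),
    specificity_label = vapply(records, function(r) r$specificity_label, ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read paired records from AIRR TSV + pairs CSV
#'
#' Reconstructs `abmlm_pair` records from the two tables written by
#' [write_airr_tsv()] and [write_pairs_csv()]. Region boundaries are rebuilt
#' from the per-region amino-acid columns; the germline V reference is not
#' part of the AIRR columns, so `germline_v` is absent on read and the stored
#' `v_mutation_count` column is trusted.
#'
#' @param airr_path TSV path.
#' @param pairs_path CSV path.
#' @return List of `abmlm_pair` records.
#' @export
read_airr_pairs <- function(airr_path, pairs_path) {
  airr <- utils::read.delim(airr_path, stringsAsFactors = FALSE)
  pairs <- utils::read.csv(pairs_path, stringsAsFactors = FALSE)
  rownames(airr) <- airr$sequence_id
  chain_from_row <- function(row) {
    parts <- c(row$fwr1_aa, row$cdr1_aa, row$fwr2_aa, row$cdr2_aa,
               row$fwr3_aa, row$cdr3_aa, row$fwr4_aa)
    lens <- nchar(parts)
    regions <- data.frame(region = REGION_ORDER,
                          start = c(0L, cumsum(lens)[-7L]),
                          end = unname(cumsum(lens)),
                          stringsAsFactors = FALSE)
    ch <- annotated_chain(paste(parts, collapse = ""), regions, row$locus,
                          v_mutation_count = row$v_mutation_count)
    ch$v_call <- row$v_call
    ch
  }
  lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    hrow <- airr[p$heavy_sequence_id, ]
    lrow <- airr[p$light_sequence_id, ]
    paired_record(chain_from_row(hrow), chain_from_row(lrow),
                  pair_id = p$pair_id, donor_id = hrow$donor_id,
                  cell_type = hrow$cell_type,
                  pairing_label = p$pairing_label,
                  specificity_label = p$specificity_label)
  })
}

#' Export concatenated pairs as FASTA
#'
#' Writes each record's concatenated heavy+light residue string as one FASTA
#' entry named by `pair_id`, the form identity clustering consumes.
#'
#' @param records List of `abmlm_pair` records.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_pairs_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(vapply(records, function(r) {
    paste0(r$heavy$sequence, r$light$sequence)
  }, ""))
  names(seqs) <- vapply(records, function(r) r$pair_id, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
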