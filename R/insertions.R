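# Detection of focal-lineage-specific insertion blocks in protein MSAs.
#
# A column is an insertion candidate when at least one focal taxon carries a
# residue while the background is (almost) entirely gapped there. Maximal
# candidate runs, optionally merged across short non-candidate gaps, become
# per-focal-taxon blocks, which in turn feed the per-alignment insertion
# fraction -- the share of alignment columns occupied by a taxon's
# lineage-specific insertions.

check_partition <- function(aln, focal, background) {
  if (length(focal) == 0L || length(background) == 0L)
    ks_abort("partition_mismatch", "focal and background must be non-empty")
  if (length(intersect(focal, background)))
    ks_abort("partition_mismatch", "focal and background overlap: %s",
             paste(intersect(focal, background), collapse = ", "))
  unknown <- setdiff(c(focal, background), aln$taxa)
  if (length(unknown))
    ks_abort("partition_mismatch", "taxa not in alignment '%s': %s",
             aln$id, paste(unknown, collapse = ", "))
  invisible(TRUE)
}

# logical candidate mask over columns
candidate_cols <- function(aln, focal, background, bg_gap_frac = 1,
                           ignore_terminal_gaps = FALSE) {
  check_partition(aln, focal, background)
  if (!(bg_gap_frac > 0 && bg_gap_frac <= 1))
    ks_abort("invalid_params", "bg_gap_frac must be in (0, 1]")
  fm <- aln$mat[focal, , drop = FALSE] != "-"
  focal_has <- colSums(fm) >= 1L
  bg <- aln$mat[background, , drop = FALSE] == "-"
  scored <- matrix(TRUE, nrow(bg), ncol(bg))
  if (ignore_terminal_gaps) {
    # leading/trailing gap runs of a background row are missing data, not gaps
    for (i in seq_len(nrow(bg))) {
      res <- which(!bg[i, ])
      if (length(res) == 0L) {
        scored[i, ] <- FALSE
      } else {
        if (res[1L] > 1L) scored[i, seq_len(res[1L] - 1L)] <- FALSE
        if (res[length(res)] < ncol(bg))
          scored[i, (res[length(res)] + 1L):ncol(bg)] <- FALSE
      }
    }
  }
  n_scored <- colSums(scored)
  n_gap <- colSums(bg & scored)
  # columns where no background row is scored cannot be called
  frac <- ifelse(n_scored > 0L, n_gap / pmax(n_scored, 1L), 0)
  focal_has & n_scored > 0L & frac >= bg_gap_frac
}

#' Classify alignment columns as insertion candidates
#'
#' A column is labelled `insertion_candidate` iff at least one focal taxon
#' has a residue there and the fraction of background taxa with a gap is at
#' least `bg_gap_frac`; all other columns are `other`.
#'
#' @param aln An [msa()] alignment.
#' @param focal Character vector of focal taxon ids.
#' @param background Character vector of background taxon ids; defaults to
#'   all remaining taxa.
#' @param bg_gap_frac Minimum background gap fraction in `(0, 1]`
#'   (default 1: the background must be entirely gapped).
#' @param ignore_terminal_gaps If `TRUE`, leading/trailing gap runs in
#'   background rows are treated as missing data (truncated models) rather
#'   than gaps.
#' @return Character vector of length `n_cols` with values
#'   `"insertion_candidate"` / `"other"`.
#' @export
classify_columns <- function(aln, focal,
                             background = setdiff(aln$taxa, focal),
                             bg_gap_frac = 1, ignore_terminal_gaps = FALSE) {
  cand <- candidate_cols(aln, focal, background, bg_gap_frac,
                         ignore_terminal_gaps)
  ifelse(cand, "insertion_candidate", "other")
}

# maximal TRUE runs of a logical vector as 0-based half-open intervals
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect focal-lineage-specific insertion blocks
#'
#' Finds maximal runs of insertion-candidate columns (see
#' [classify_columns()]), merges runs separated by at most `merge_gap`
#' non-candidate columns, and emits one block per focal taxon per run where
#' that taxon contributes at least `min_len` residues in candidate columns.
#' Residue intervals are obtained with [map_columns_to_residues()] over the
#' block's column span; `length_res` counts the taxon's residues in candidate
#' columns only, so for `merge_gap = 0` the two agree exactly.
#'
#' @inheritParams classify_columns
#' @param merge_gap Maximum number of intervening non-candidate columns
#'   bridged when merging adjacent runs (default 0, no merging).
#' @param min_len Minimum number of focal-taxon residues inside the run for
#'   a block to be emitted (default 3; suppresses single-residue alignment
#'   noise).
#' @return An [insertion_blocks()] data frame sorted by `(taxon, col_start)`.
#' @export
detect_insertion_blocks <- function(aln, focal,
                                    background = setdiff(aln$taxa, focal),
                                    bg_gap_frac = 1, merge_gap = 0,
                                    min_len = 3,
                                    ignore_terminal_gaps = FALSE) {
  if (merge_gap < 0 || min_len < 1)
    ks_abort("invalid_params", "merge_gap must be >= 0 and min_len >= 1")
  cand <- candidate_cols(aln, focal, background, bg_gap_frac,
                         ignore_terminal_gaps)
  runs <- runs_of(cand)
  if (nrow(runs) == 0L) return(insertion_blocks())
  # merge runs separated by <= merge_gap non-candidate columns
  merged <- list(runs[1L, ])
  if (nrow(runs) > 1L) for (i in 2L:nrow(runs)) {
    last <- merged[[length(merged)]]
    if (runs[i, "start"] - last["end"] <= merge_gap)
      merged[[length(merged)]]["end"] <- runs[i, "end"]
    else merged[[length(merged) + 1L]] <- runs[i, ]
  }
  rows <- list()
  for (span in merged) {
    s <- span[["start"]]; e <- span[["end"]]
    in_span_cand <- which(cand[(s + 1L):e]) + s   # 1-based column indices
    n_cand <- length(in_span_cand)
    for (tx in focal) {
      len_res <- sum(aln$mat[tx, in_span_cand] != "-")
      if (len_res < min_len) next
      res <- map_columns_to_residues(aln, tx, s, e)
      rows[[length(rows) + 1L]] <- data.frame(
        orthogroup = aln$id, taxon = tx,
        col_start = s, col_end = e,
        res_start = res[[1L]], res_end = res[[2L]],
        length_res = len_res, cand_cols = n_cand,
        merged_span_cols = e - s, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(insertion_blocks())
  out <- do.call(rbind, rows)
  out <- out[order(out$taxon, out$col_start), ]
  insertion_blocks(out)
}

#' Map an alignment column interval to a taxon's residue interval
#'
#' Converts a 0-based half-open column interval to the corresponding 0-based
#' half-open interval in the taxon's ungapped sequence by counting non-gap
#' characters before each boundary. The result may be empty if the taxon is
#' gapped throughout the interval.
#'
#' @param aln An [msa()] alignment.
#' @param taxon Taxon id present in the alignment.
#' @param col_start,col_end 0-based half-open column interval,
#'   `0 <= col_start <= col_end <= n_cols`.
#' @return Integer vector `c(res_start, res_end)`, 0-based half-open.
#' @export
map_columns_to_residues <- function(aln, taxon, col_start, col_end) {
  if (!taxon %in% aln$taxa)
    ks_abort("unknown_taxon", "taxon '%s' not in alignment '%s'",
             taxon, aln$id)
  if (col_start < 0 || col_end > aln$n_cols || col_start > col_end)
    ks_abort("out_of_range",
             "column interval [%d, %d) outside [0, %d]",
             col_start, col_end, aln$n_cols)
  nongap <- aln$mat[taxon, ] != "-"
  cum <- c(0L, cumsum(nongap))
  c(res_start = cum[[col_start + 1L]], res_end = cum[[col_end + 1L]])
}

#' Per-taxon insertion fraction of an alignment
#'
#' `inserted_cols` counts the insertion-candidate columns inside the taxon's
#' blocks (columns bridged by merging are not counted); the denominator is
#' the total number of alignment columns.
#'
#' @param aln An [msa()] alignment.
#' @param blocks Blocks produced from this alignment by
#'   [detect_insertion_blocks()].
#' @param taxon Taxon id to quantify.
#' @return A one-row `data.frame` of class `"fraction_record"` with columns
#'   `orthogroup`, `taxon`, `inserted_cols`, `total_cols`, `fraction`.
#' @export
insertion_fraction <- function(aln, blocks, taxon) {
  blocks <- insertion_blocks(blocks)
  if (nrow(blocks) && any(blocks$orthogroup != aln$id))
    ks_abort("foreign_blocks",
             "blocks belong to %s, alignment is '%s'",
             paste(sQuote(unique(blocks$orthogroup)), collapse = ", "),
             aln$id)
  if (!taxon %in% aln$taxa)
    ks_abort("unknown_taxon", "taxon '%s' not in alignment '%s'",
             taxon, aln$id)
  b <- blocks[blocks$taxon == taxon, , drop = FALSE]
  inserted <- if (nrow(b)) sum(b$cand_cols) else 0L
  out <- data.frame(orthogroup = aln$id, taxon = taxon,
                    inserted_cols = as.integer(inserted),
                    total_cols = aln$n_cols,
                    fraction = inserted / aln$n_cols,
                    stringsAsFactors = FALSE)
  class(out) <- c("fraction_record", "data.frame")
  out
}
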