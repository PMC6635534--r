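# Insertion blocks live in memory with 0-based half-open column and residue
# intervals; on disk they are 1-based inclusive. cand_cols (number of
# insertion-candidate columns inside the span) and merged_span_cols are kept
# in the file so the write->read round trip is lossless.

BLOCK_COLS <- c("orthogroup", "taxon", "col_start", "col_end",
                "res_start", "res_end", "length_res", "cand_cols",
                "merged_span_cols")

#' Construct an insertion-block table
#'
#' Validates a data frame of lineage-specific insertion blocks (0-based
#' half-open intervals). `length_res` counts the focal taxon's residues in
#' insertion-candidate columns of the block; with merging disabled
#' (`merge_gap = 0`, the default in [detect_insertion_blocks()]) this equals
#' `res_end - res_start`.
#'
#' @param df Data frame with columns `orthogroup`, `taxon`, `col_start`,
#'   `col_end`, `res_start`, `res_end`, `length_res`, `cand_cols`,
#'   `merged_span_cols`.
#' @return A `data.frame` of class `"insertion_blocks"`.
#' @export
insertion_blocks <- function(df = NULL) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0L) {
    df <- data.frame(orthogroup = character(), taxon = character(),
                     col_start = integer(), col_end = integer(),
                     res_start = integer(), res_end = integer(),
                     length_res = integer(), cand_cols = integer(),
                     merged_span_cols = integer(), stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(df)
    miss <- setdiff(BLOCK_COLS, names(df))
    if (length(miss))
      ks_abort("missing_column", "missing block column(s): %s",
               paste(miss, collapse = ", "))
    df <- df[BLOCK_COLS]
    for (col in BLOCK_COLS[3:9]) df[[col]] <- as.integer(df[[col]])
    with(df, {
      if (any(col_start >= col_end))
        ks_abort("invalid_params", "block col_start must be < col_end")
      if (any(res_end - res_start < length_res) || any(length_res < 1L))
        ks_abort("invalid_params",
                 "block residue interval inconsistent with length_res")
      if (any(merged_span_cols != col_end - col_start))
        ks_abort("invalid_params", "merged_span_cols must equal col span")
      if (any(cand_cols > merged_span_cols) || any(cand_cols < 1L))
        ks_abort("invalid_params", "cand_cols out of range")
    })
  }
  rownames(df) <- NULL
  class(df) <- c("insertion_blocks", "data.frame")
  df
}

#' Write insertion blocks as TSV (1-based inclusive coordinates)
#'
#' Internal 0-based half-open intervals `[s, e)` become 1-based inclusive
#' `s+1 .. e` in the file, matching the usual biological convention.
#'
#' @param blocks An `"insertion_blocks"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path) {
  blocks <- insertion_blocks(blocks)
  out <- as.data.frame(blocks)
  out$col_start <- out$col_start + 1L
  out$res_start <- out$res_start + 1L
  tryCatch(utils::write.table(out, path, sep = "\t", quote = FALSE,
                              row.names = FALSE, fileEncoding = "UTF-8"),
           error = function(e)
             ks_abort("io_error", "cannot write %s: %s", path,
                      conditionMessage(e)))
  invisible(path)
}

#' Read an insertion-block TSV back into memory (0-based half-open)
#'
#' @param path Path to a TSV written by [write_blocks_tsv()].
#' @return An `"insertion_blocks"` data frame.
#' @export
read_blocks_tsv <- function(path) {
  if (!file.exists(path))
    ks_abort("io_error", "no such file: %s", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(df)) {
    df$col_start <- df$col_start - 1L
    df$res_start <- df$res_start - 1L
  }
  insertion_blocks(df)
}
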