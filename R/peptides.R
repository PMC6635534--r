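# Mapping mass-spectrometry peptides onto insertion residue intervals:
# an insertion is "confirmed in the mature protein" when some exact peptide
# occurrence overlaps it by at least one residue.

#' Read a peptide list (TSV)
#'
#' Two tab-separated columns, `protein` and `peptide`; `#` comments ignored.
#' Peptides must be uppercase amino-acid strings of length >= 5.
#'
#' @param path Path to the TSV file.
#' @return Named list mapping protein id to a character vector of peptides.
#' @export
read_peptides <- function(path) {
  if (!file.exists(path))
    ks_abort("io_error", "no such file: %s", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(c("protein", "peptide"), names(df))
  if (length(miss))
    ks_abort("missing_column", "missing column(s): %s",
             paste(miss, collapse = ", "))
  peps <- toupper(df$peptide)
  if (any(nchar(peps) < 5L) || any(!grepl("^[A-Z]+$", peps)))
    ks_abort("invalid_params",
             "peptides must be uppercase amino-acid strings of length >= 5")
  split(peps, df$protein)
}

# all 0-based half-open occurrence intervals of pattern in subject
all_occurrences <- function(subject, pattern) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(matrix(integer(), ncol = 2L))
  cbind(start = hits - 1L, end = hits - 1L + nchar(pattern))
}

#' Peptide coverage of insertion intervals
#'
#' A peptide covers an interval iff some exact occurrence of the peptide in
#' the protein overlaps the interval by at least one residue; every
#' occurrence is considered. With `il_equiv = TRUE`, isoleucine and leucine
#' are treated as indistinguishable (they are isobaric in mass spectra).
#'
#' @param protein Ungapped protein sequence (uppercase string).
#' @param intervals Two-column matrix or data frame of 0-based half-open
#'   residue intervals (`res_start`, `res_end`).
#' @param peptides Character vector of peptides.
#' @param il_equiv Treat I and L as equal (default `FALSE`).
#' @return Data frame with columns `res_start`, `res_end`, `covered`
#'   (logical) and `peptides` (semicolon-joined covering peptides).
#' @export
peptide_coverage <- function(protein, intervals, peptides, il_equiv = FALSE) {
  intervals <- as.matrix(as.data.frame(intervals))[, 1:2, drop = FALSE]
  n <- nchar(protein)
  if (nrow(intervals) && (any(intervals[, 1L] < 0) ||
                          any(intervals[, 2L] > n) ||
                          any(intervals[, 1L] > intervals[, 2L])))
    ks_abort("interval_out_of_range",
             "residue interval outside [0, %d]", n)
  subj <- if (il_equiv) chartr("L", "I", toupper(protein)) else toupper(protein)
  pats <- if (il_equiv) chartr("L", "I", toupper(peptides)) else toupper(peptides)
  covered <- logical(nrow(intervals))
  hits <- character(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    s <- intervals[i, 1L]; e <- intervals[i, 2L]
    who <- vapply(seq_along(pats), function(j) {
      occ <- all_occurrences(subj, pats[j])
      any(occ[, 1L] < e & occ[, 2L] > s)
    }, logical(1L))
    covered[i] <- any(who)
    hits[i] <- paste(unique(peptides[who]), collapse = ";")
  }
  data.frame(res_start = intervals[, 1L], res_end = intervals[, 2L],
             covered = covered, peptides = hits, stringsAsFactors = FALSE)
}
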