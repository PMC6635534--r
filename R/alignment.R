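# In-memory model of a gapped protein multiple sequence alignment.
# Coordinates are 0-based half-open everywhere in memory; on-disk TSV
# coordinates are 1-based inclusive (see write_blocks_tsv).

#' The twenty standard amino acids
#'
#' One-letter codes, alphabetical. `"X"` (unknown residue) occupies alignment
#' positions but is excluded from composition statistics; `"*"` is rejected
#' on input.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

ALN_ALPHABET <- c(AA20, "X", "-")

#' Construct a protein multiple sequence alignment
#'
#' Builds the validated alignment object used throughout the package from a
#' named character vector of gapped sequences. Input is normalized first:
#' letters are uppercased and `'.'` gap characters are mapped to `'-'`.
#'
#' @param id Orthogroup identifier (single string).
#' @param seqs Named character vector; names are taxon ids, values are
#'   equal-length gapped amino-acid strings.
#' @return An object of class `"msa"`: a list with elements `id`, `taxa`
#'   (ordered taxon ids), `mat` (taxa x columns character matrix) and
#'   `n_cols`.
#' @examples
#' aln <- msa("og1", c(sp1 = "MKAAPQRST", sp2 = "MKA---RST"))
#' aln$n_cols
#' @export
msa <- function(id, seqs) {
  if (length(seqs) < 1L)
    ks_abort("empty_file", "alignment '%s' has no sequences", id)
  taxa <- names(seqs)
  if (is.null(taxa) || anyNA(taxa) || any(taxa == ""))
    ks_abort("invalid_params", "all sequences must be named by taxon id")
  if (anyDuplicated(taxa))
    ks_abort("duplicate_taxon", "duplicated taxon id(s): %s",
             paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  seqs <- chartr(".", "-", toupper(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    ks_abort("ragged_alignment",
             "rows differ in length (%s) in alignment '%s'",
             paste(unique(lens), collapse = ", "), id)
  n_cols <- lens[[1L]]
  if (n_cols < 1L)
    ks_abort("ragged_alignment", "alignment '%s' has zero columns", id)
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), ncol = n_cols, byrow = TRUE,
                dimnames = list(taxa, NULL))
  bad <- setdiff(unique(as.vector(mat)), ALN_ALPHABET)
  if (length(bad))
    ks_abort("illegal_character",
             "illegal character(s) %s in alignment '%s'",
             paste(sQuote(bad), collapse = ", "), id)
  structure(list(id = id, taxa = taxa, mat = mat, n_cols = n_cols),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> '%s': %d taxa x %d columns\n",
              x$id, length(x$taxa), x$n_cols))
  invisible(x)
}

#' Gapped row strings of an alignment
#'
#' @param aln An [msa()] object.
#' @return Named character vector of gapped sequences, one per taxon.
#' @export
aln_strings <- function(aln) {
  stats::setNames(apply(aln$mat, 1L, paste, collapse = ""), aln$taxa)
}

# ungapped (residue) sequence of one taxon
aln_ungapped <- function(aln, taxon) {
  row <- aln$mat[taxon, ]
  paste(row[row != "-"], collapse = "")
}

#' Read an aligned FASTA file
#'
#' Parses a gapped protein FASTA into an [msa()] object. `'.'` gaps become
#' `'-'` and lowercase residues are uppercased. Taxon ids are the first
#' whitespace-delimited word of each header.
#'
#' @param path Path to an aligned FASTA file with at least two records.
#' @param id Orthogroup id; defaults to the file name without extension.
#' @return An `"msa"` object.
#' @seealso [write_alignment()]
#' @export
read_alignment <- function(path, id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path))
    ks_abort("io_error", "no such file: %s", path)
  ss <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e)
                   ks_abort("empty_file", "cannot parse FASTA '%s': %s",
                            path, conditionMessage(e)))
  if (length(ss) == 0L)
    ks_abort("empty_file", "no FASTA records in %s", path)
  if (length(ss) < 2L)
    ks_abort("too_few_records", "alignment %s has < 2 records", path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  msa(id, seqs)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An `"msa"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "msa"))
  ss <- Biostrings::AAStringSet(aln_strings(aln))
  tryCatch(Biostrings::writeXStringSet(ss, path),
           error = function(e)
             ks_abort("io_error", "cannot write %s: %s", path,
                      conditionMessage(e)))
  invisible(path)
}
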