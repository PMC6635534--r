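# Phyletic profile: species x {Ku70, Ku80, Lig4} presence joined to genome
# size and lifestyle. NA presence means "no call" (absence of evidence) and
# is never coerced to 0.

PROFILE_COLS <- c("species", "clade", "lifestyle", "genome_size_mb",
                  "ku70", "ku80", "lig4")
LIFESTYLES <- c("parasite", "free_living", "unknown")

#' Construct a phyletic profile
#'
#' Validates and types a data frame of per-species C-NHEJ component presence.
#'
#' @param df Data frame with columns `species`, `clade`, `lifestyle`
#'   (`parasite`, `free_living` or `unknown`), `genome_size_mb` (positive,
#'   may be NA) and `ku70`, `ku80`, `lig4` (0, 1 or NA).
#' @return A `data.frame` of class `"phyletic_profile"`.
#' @export
phyletic_profile <- function(df) {
  miss <- setdiff(PROFILE_COLS, names(df))
  if (length(miss))
    ks_abort("missing_column", "missing column(s): %s",
             paste(miss, collapse = ", "))
  df <- as.data.frame(df)[PROFILE_COLS]
  df$species <- as.character(df$species)
  if (anyDuplicated(df$species))
    ks_abort("duplicate_species", "duplicated species id(s): %s",
             paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  df$clade <- as.character(df$clade)
  df$lifestyle <- as.character(df$lifestyle)
  bad_ls <- setdiff(stats::na.omit(unique(df$lifestyle)), LIFESTYLES)
  if (length(bad_ls))
    ks_abort("invalid_lifestyle", "lifestyle must be one of %s; got %s",
             paste(LIFESTYLES, collapse = "/"), paste(bad_ls, collapse = ", "))
  df$lifestyle[is.na(df$lifestyle)] <- "unknown"
  size <- suppressWarnings(as.numeric(df$genome_size_mb))
  if (any(!is.na(size) & size <= 0))
    ks_abort("non_positive_size", "genome_size_mb must be > 0 when present")
  df$genome_size_mb <- size
  for (comp in c("ku70", "ku80", "lig4")) {
    v <- suppressWarnings(as.integer(df[[comp]]))
    if (any(!is.na(v) & !v %in% c(0L, 1L)))
      ks_abort("invalid_presence", "column '%s' must be 0, 1 or NA", comp)
    df[[comp]] <- v
  }
  rownames(df) <- NULL
  class(df) <- c("phyletic_profile", "data.frame")
  df
}

#' Read a phyletic profile table (TSV)
#'
#' Tab-separated, UTF-8, `#`-prefixed comment lines ignored. Header must name
#' the seven required columns (order free). Empty fields and `NA` are read as
#' missing, never as 0.
#'
#' @param path Path to the TSV file.
#' @return A `"phyletic_profile"` data frame.
#' @export
read_profile_table <- function(path) {
  if (!file.exists(path))
    ks_abort("io_error", "no such file: %s", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          na.strings = c("NA", ""), stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  phyletic_profile(df)
}

#' Write a phyletic profile table (TSV)
#'
#' @param profile A `"phyletic_profile"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
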