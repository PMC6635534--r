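# Statistical layer over detected insertion blocks: amino-acid composition
# enrichment of inserted vs non-inserted sequence, cross-taxon enrichment
# similarity, the paired per-orthogroup fraction comparison, elevated
# divergence in insertion flanks, and the conservation-vs-insertion
# correlation.

# taxon's insertion residues and background residues over one alignment,
# taken from the blocks' residue intervals
split_residue_pools <- function(aln, blocks, taxon) {
  seq <- aln_ungapped(aln, taxon)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  b <- blocks[blocks$orthogroup == aln$id & blocks$taxon == taxon, ,
              drop = FALSE]
  ins_idx <- integer()
  for (i in seq_len(nrow(b)))
    if (b$res_end[i] > b$res_start[i])
      ins_idx <- c(ins_idx, (b$res_start[i] + 1L):b$res_end[i])
  ins_idx <- unique(ins_idx)
  list(insertion = chars[ins_idx],
       background = if (length(ins_idx)) chars[-ins_idx] else chars)
}

#' Amino-acid composition enrichment inside vs outside insertions
#'
#' Counts a taxon's residues inside its insertion blocks and outside them
#' (pooled over alignments), and computes per-amino-acid enrichment as the
#' ratio of relative frequencies (insertion / background). Each amino acid
#' gets a 2x2 G-test (this residue vs the rest, insertion vs background)
#' with Benjamini-Hochberg q-values; an omnibus 2xK G-test over all amino
#' acids is attached as an attribute. `'X'` is excluded from both pools.
#'
#' @param alignments An [msa()] or list of them.
#' @param blocks [insertion_blocks()] produced from those alignments.
#' @param taxon Taxon whose composition is profiled.
#' @return Data frame of class `"composition_table"` with one row per
#'   standard amino acid: `aa`, `count_insertion`, `count_background`,
#'   `freq_insertion`, `freq_background`, `enrichment` (NA where the
#'   background frequency is zero), `p_value`, `q_value`. Attributes:
#'   `taxon`, `omnibus`.
#' @export
composition_enrichment <- function(alignments, blocks, taxon) {
  if (inherits(alignments, "msa")) alignments <- list(alignments)
  blocks <- insertion_blocks(blocks)
  ins <- character(); bg <- character()
  for (aln in alignments) {
    pools <- split_residue_pools(aln, blocks, taxon)
    ins <- c(ins, pools$insertion)
    bg <- c(bg, pools$background)
  }
  ins <- ins[ins %in% AA20]
  bg <- bg[bg %in% AA20]
  if (length(ins) == 0L)
    ks_abort("empty_pool", "no insertion residues for taxon '%s'", taxon)
  ci <- stats::setNames(integer(20L), AA20)
  cb <- ci
  ti <- table(factor(ins, levels = AA20)); ci[names(ti)] <- as.integer(ti)
  tb <- table(factor(bg, levels = AA20)); cb[names(tb)] <- as.integer(tb)
  fi <- ci / sum(ci)
  fb <- if (sum(cb) > 0) cb / sum(cb) else rep(NA_real_, 20L)
  enr <- ifelse(!is.na(fb) & fb > 0, fi / fb, NA_real_)
  pv <- vapply(seq_len(20L), function(i) {
    g_test(rbind(c(ci[i], sum(ci) - ci[i]),
                 c(cb[i], sum(cb) - cb[i])))$p_value
  }, numeric(1L))
  out <- data.frame(aa = AA20,
                    count_insertion = unname(ci),
                    count_background = unname(cb),
                    freq_insertion = unname(fi),
                    freq_background = unname(fb),
                    enrichment = unname(enr),
                    p_value = pv,
                    q_value = stats::p.adjust(pv, method = "BH"),
                    stringsAsFactors = FALSE)
  class(out) <- c("composition_table", "data.frame")
  attr(out, "taxon") <- taxon
  attr(out, "omnibus") <- g_test(rbind(ci, cb))
  out
}

#' Pairwise similarity of enrichment patterns across taxa
#'
#' Pearson correlation of log2 enrichment over the amino acids with a
#' defined, positive, finite enrichment in both tables of a pair.
#'
#' @param tables List of `"composition_table"`s (>= 2).
#' @param min_shared Minimum number of shared defined-enrichment amino
#'   acids required per pair (default 5).
#' @return Symmetric correlation matrix with taxon dimnames.
#' @export
enrichment_similarity <- function(tables, min_shared = 5) {
  if (length(tables) < 2L)
    ks_abort("invalid_params", "need at least two composition tables")
  taxa <- vapply(tables, function(t) {
    tx <- attr(t, "taxon"); if (is.null(tx)) NA_character_ else tx
  }, character(1L))
  taxa[is.na(taxa)] <- paste0("table", which(is.na(taxa)))
  logs <- lapply(tables, function(t) {
    v <- log2(t$enrichment)
    v[!is.finite(v)] <- NA
    stats::setNames(v, t$aa)
  })
  k <- length(tables)
  m <- diag(1, k)
  dimnames(m) <- list(taxa, taxa)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    shared <- !is.na(logs[[i]]) & !is.na(logs[[j]])
    if (sum(shared) < min_shared)
      ks_abort("insufficient_overlap",
               "only %d shared defined-enrichment amino acids between %s and %s (need >= %d)",
               sum(shared), taxa[i], taxa[j], min_shared)
    m[i, j] <- m[j, i] <- stats::cor(logs[[i]][shared], logs[[j]][shared])
  }
  m
}

as_fraction_vector <- function(x) {
  if (is.data.frame(x)) stats::setNames(x$fraction, x$orthogroup)
  else x
}

#' Paired comparison of insertion fractions between two taxa
#'
#' Two-sided Wilcoxon signed-rank test on per-orthogroup differences in
#' insertion fraction (focal minus reference); zero differences are dropped,
#' exact for up to 25 non-zero pairs.
#'
#' @param fractions_focal,fractions_reference Named numeric vectors of
#'   per-alignment fractions keyed by orthogroup id, or data frames with
#'   `orthogroup` and `fraction` columns (e.g. row-bound
#'   [insertion_fraction()] records). Pairing is by orthogroup.
#' @param focal,reference Optional taxon labels carried into the result.
#' @return List of class `"paired_comparison"`: `focal`, `reference`,
#'   `n_alignments`, `pairs` (data frame), `statistic` (centered
#'   signed-rank statistic; flips sign when the vectors are swapped), `V`,
#'   `p_value`, `test_name`, `exact`.
#' @export
compare_fraction_paired <- function(fractions_focal, fractions_reference,
                                    focal = NA_character_,
                                    reference = NA_character_) {
  f <- as_fraction_vector(fractions_focal)
  r <- as_fraction_vector(fractions_reference)
  shared <- intersect(names(f), names(r))
  if (length(shared) < 3L)
    ks_abort("too_few_pairs", "only %d shared orthogroups (need >= 3)",
             length(shared))
  d <- f[shared] - r[shared]
  res <- signed_rank_test(d)
  structure(list(
    focal = focal, reference = reference,
    n_alignments = length(shared),
    pairs = data.frame(orthogroup = shared,
                       fraction_focal = unname(f[shared]),
                       fraction_reference = unname(r[shared]),
                       stringsAsFactors = FALSE),
    statistic = res$centered, V = res$statistic,
    p_value = res$p_value, test_name = "wilcoxon_signed_rank",
    exact = res$exact), class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "Paired insertion-fraction comparison%s: n = %d, V = %.1f, p = %.3g (%s)\n",
    if (is.na(x$focal)) "" else sprintf(" (%s vs %s)", x$focal, x$reference),
    x$n_alignments, x$V, x$p_value,
    if (x$exact) "exact" else "normal approx."))
  invisible(x)
}

#' Divergence in insertion flanks vs distal alignment regions
#'
#' Compares the residue mismatch rate between focal and background taxa in
#' the columns flanking insertion blocks (within `flank_width` columns of a
#' block boundary) against all other non-block columns. A pair contributes
#' at a column only when both taxa carry a non-X residue there. If the
#' distal rate is zero the ratio is `Inf` when the flank rate is positive
#' and 1 (by convention) when both are zero.
#'
#' @param aln An [msa()] alignment.
#' @param blocks Blocks detected on this alignment; their taxa define the
#'   focal set, all remaining taxa the background.
#' @param flank_width Flank half-width in columns (default 5).
#' @return List with `flank_mismatch_rate`, `distal_mismatch_rate`, `ratio`,
#'   `n_flank_pairs`, `n_distal_pairs`.
#' @export
flank_divergence <- function(aln, blocks, flank_width = 5) {
  if (flank_width < 1) ks_abort("invalid_params", "flank_width must be >= 1")
  blocks <- insertion_blocks(blocks)
  blocks <- blocks[blocks$orthogroup == aln$id, , drop = FALSE]
  focal <- unique(blocks$taxon)
  if (length(focal) == 0L)
    ks_abort("no_flank_columns", "no blocks on alignment '%s'", aln$id)
  background <- setdiff(aln$taxa, focal)
  if (length(background) == 0L)
    ks_abort("partition_mismatch", "no background taxa left")
  in_block <- logical(aln$n_cols)
  flank <- logical(aln$n_cols)
  for (i in seq_len(nrow(blocks))) {
    s <- blocks$col_start[i]; e <- blocks$col_end[i]
    in_block[(s + 1L):e] <- TRUE
    lo <- max(0L, s - flank_width); hi <- min(aln$n_cols, e + flank_width)
    if (s > lo) flank[(lo + 1L):s] <- TRUE
    if (hi > e) flank[(e + 1L):hi] <- TRUE
  }
  flank <- flank & !in_block
  distal <- !flank & !in_block
  count_pairs <- function(colmask) {
    cols <- which(colmask)
    tot <- 0L; mis <- 0L
    for (f in focal) for (b in background) {
      fr <- aln$mat[f, cols]; br <- aln$mat[b, cols]
      ok <- fr != "-" & br != "-" & fr != "X" & br != "X"
      tot <- tot + sum(ok)
      mis <- mis + sum(fr[ok] != br[ok])
    }
    c(tot = tot, mis = mis)
  }
  fl <- count_pairs(flank)
  di <- count_pairs(distal)
  if (fl[["tot"]] == 0L)
    ks_abort("no_flank_columns", "no scorable flank pairs")
  if (di[["tot"]] == 0L)
    ks_abort("no_distal_columns", "no scorable distal pairs")
  fr <- fl[["mis"]] / fl[["tot"]]
  dr <- di[["mis"]] / di[["tot"]]
  ratio <- if (dr > 0) fr / dr else if (fr > 0) Inf else 1
  list(flank_mismatch_rate = fr, distal_mismatch_rate = dr, ratio = ratio,
       n_flank_pairs = unname(fl[["tot"]]),
       n_distal_pairs = unname(di[["tot"]]))
}

#' Mean pairwise identity over non-candidate, gap-free columns
#'
#' Conservation of an alignment outside its insertion-candidate columns:
#' for every pair of rows, the fraction of identical residues over columns
#' that are gap-free in all rows, non-candidate, and non-X in both rows of
#' the pair; averaged over all row pairs.
#'
#' @param aln An [msa()] alignment.
#' @param candidate Optional logical mask (or the label vector from
#'   [classify_columns()]) of columns to exclude.
#' @return Scalar in `[0, 1]`, or `NA` (with a warning) if no columns
#'   qualify.
#' @export
alignment_conservation <- function(aln, candidate = NULL) {
  if (is.null(candidate)) candidate <- logical(aln$n_cols)
  if (is.character(candidate)) candidate <- candidate == "insertion_candidate"
  gap_free <- colSums(aln$mat == "-") == 0L
  cols <- which(gap_free & !candidate)
  if (length(cols) == 0L) {
    ks_warn("no_columns", "no gap-free non-candidate columns in '%s'", aln$id)
    return(NA_real_)
  }
  taxa <- aln$taxa
  if (length(taxa) < 2L)
    ks_abort("invalid_params", "need at least two rows")
  idents <- c()
  for (i in seq_len(length(taxa) - 1L)) for (j in (i + 1L):length(taxa)) {
    a <- aln$mat[i, cols]; b <- aln$mat[j, cols]
    ok <- a != "X" & b != "X"
    if (any(ok)) idents <- c(idents, mean(a[ok] == b[ok]))
  }
  if (length(idents) == 0L) return(NA_real_)
  mean(idents)
}

#' Correlation between alignment conservation and insertion fraction
#'
#' Spearman rank correlation (two-sided) across alignments between each
#' alignment's conservation and its insertion fraction; tests whether
#' insertions are depleted from the most conserved genes.
#'
#' @param records Data frame with numeric columns `conservation` and
#'   `fraction`, one row per alignment.
#' @return List with `rho`, `p_value`, `n`.
#' @export
conservation_vs_insertion <- function(records) {
  records <- as.data.frame(records)
  records <- records[stats::complete.cases(records[c("conservation",
                                                     "fraction")]), ]
  n <- nrow(records)
  if (n < 4L)
    ks_abort("too_few_alignments", "need >= 4 alignments, got %d", n)
  if (length(unique(records$conservation)) == 1L ||
      length(unique(records$fraction)) == 1L)
    ks_abort("constant_input", "conservation or fraction is constant")
  ct <- suppressWarnings(stats::cor.test(records$conservation,
                                         records$fraction,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}
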