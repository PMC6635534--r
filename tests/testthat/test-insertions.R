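test_that("column classification follows the focal-residue / background-gap rule", {
  aln <- toy_aln(sp1 = "MKAAPQRST", sp2 = "MKA---RST", sp3 = "MKA---RST")
  lab <- classify_columns(aln, "sp1")
  expect_equal(which(lab == "insertion_candidate"), 4:6)  # cols 3..5, 0-based

  nogap <- toy_aln(a = "MKAAP", b = "MKAAP", c = "MKWAP")
  expect_true(all(classify_columns(nogap, "a") == "other"))

  # threshold: 1 of 2 background rows gapped passes at bg_gap_frac = 0.5
  half <- toy_aln(f = "MKAAP", b1 = "MK-AP", b2 = "MKAAP")
  expect_equal(classify_columns(half, "f", bg_gap_frac = 0.5)[3],
               "insertion_candidate")
  expect_equal(classify_columns(half, "f", bg_gap_frac = 1)[3], "other")

  expect_error(classify_columns(aln, "nope"),
               class = "kuscape_partition_mismatch")
  expect_error(classify_columns(aln, aln$taxa),
               class = "kuscape_partition_mismatch")
})

test_that("terminal background gaps can be treated as missing data", {
  # bg2 is truncated: its leading gaps should not create a false insertion
  aln <- toy_aln(f = "MKAAPQRST", b1 = "MKAAPQRST", b2 = "----PQRST")
  expect_true(all(classify_columns(aln, "f") == "other"))
  aln2 <- toy_aln(f = "MKAAPQRST", b2 = "----PQRST")
  expect_equal(which(classify_columns(aln2, "f") == "insertion_candidate"),
               1:4)
  expect_true(all(classify_columns(aln2, "f",
                                   ignore_terminal_gaps = TRUE) == "other"))
})

test_that("block detection: maximal runs, min_len filter, merging", {
  aln <- toy_aln(sp1 = "MKAAPQRST", sp2 = "MKA---RST", sp3 = "MKA---RST")
  b <- detect_insertion_blocks(aln, "sp1", min_len = 3)
  expect_equal(nrow(b), 1L)
  expect_equal(b$col_start, 3L); expect_equal(b$col_end, 6L)
  expect_equal(b$res_start, 3L); expect_equal(b$res_end, 6L)
  expect_equal(b$length_res, 3L)

  expect_equal(nrow(detect_insertion_blocks(aln, "sp1", min_len = 4)), 0L)

  m <- toy_aln(f = "MKAAPWQRST", b = "MKA--W-RST")
  mb <- detect_insertion_blocks(m, "f", merge_gap = 1, min_len = 3)
  expect_equal(nrow(mb), 1L)
  expect_equal(mb$col_start, 3L); expect_equal(mb$col_end, 7L)
  expect_equal(mb$length_res, 3L)          # candidate-column residues only
  expect_equal(mb$merged_span_cols, 4L)
  expect_equal(mb$cand_cols, 3L)
  # without merging neither run alone reaches min_len = 3
  expect_equal(nrow(detect_insertion_blocks(m, "f", min_len = 3)), 0L)
  expect_equal(nrow(detect_insertion_blocks(m, "f", min_len = 2)), 1L)
})

test_that("insertion fraction counts candidate columns over total columns", {
  aln <- toy_aln(sp1 = "MKAAPQRST", sp2 = "MKA---RST", sp3 = "MKA---RST")
  blocks <- detect_insertion_blocks(aln, "sp1")
  fr <- insertion_fraction(aln, blocks, "sp1")
  expect_equal(fr$fraction, 3 / 9, tolerance = 1e-12)

  none <- insertion_fraction(aln, insertion_blocks(), "sp2")
  expect_equal(none$fraction, 0)

  other <- blocks; other$orthogroup <- "other_og"
  expect_error(insertion_fraction(aln, other, "sp1"),
               class = "kuscape_foreign_blocks")
})

test_that("fractions are invariant under background permutation and shrink with added flanks", {
  set.seed(5)
  for (rep in 1:10) {
    aln <- random_aln(5, 25)
    focal <- aln$taxa[1]
    blocks <- detect_insertion_blocks(aln, focal, min_len = 1)
    f0 <- insertion_fraction(aln, blocks, focal)$fraction
    # permute background rows
    perm <- msa(aln$id, aln_strings(aln)[c(1, sample(2:5))])
    bp <- detect_insertion_blocks(perm, focal, min_len = 1)
    expect_equal(insertion_fraction(perm, bp, focal)$fraction, f0)
    # appending gap-free columns dilutes the fraction proportionally
    ext <- msa(aln$id, vapply(aln_strings(aln), paste0, "", "AAAAA"))
    be <- detect_insertion_blocks(ext, focal, min_len = 1)
    fe <- insertion_fraction(ext, be, focal)$fraction
    expect_equal(fe, f0 * 25 / 30)
    if (f0 > 0) expect_lt(fe, f0)
  }
})

test_that("column-to-residue mapping counts non-gap prefix characters", {
  ungapped <- toy_aln(a = "MKAAP", b = "MKAAP")
  expect_equal(unname(map_columns_to_residues(ungapped, "a", 2, 5)), c(2, 5))

  g <- toy_aln(a = "M-KA-", b = "MKKAA")
  expect_equal(unname(map_columns_to_residues(g, "a", 2, 4)), c(1, 3))
  expect_equal(unname(map_columns_to_residues(g, "a", 1, 2)), c(1, 1))
  expect_equal(unname(map_columns_to_residues(g, "a", 0, 0)), c(0, 0))

  expect_error(map_columns_to_residues(g, "zz", 0, 1),
               class = "kuscape_unknown_taxon")
  expect_error(map_columns_to_residues(g, "a", 0, 6),
               class = "kuscape_out_of_range")
})

test_that("block residues equal the taxon's characters in candidate columns (merge_gap = 0)", {
  set.seed(17)
  for (rep in 1:25) {
    aln <- random_aln(sample(3:6, 1), sample(15:40, 1))
    focal <- sample(aln$taxa, sample(1:2, 1))
    blocks <- detect_insertion_blocks(aln, focal, min_len = 1)
    lab <- classify_columns(aln, focal)
    for (i in seq_len(nrow(blocks))) {
      tx <- blocks$taxon[i]
      seq <- paste(aln$mat[tx, ][aln$mat[tx, ] != "-"], collapse = "")
      inside <- substr(seq, blocks$res_start[i] + 1, blocks$res_end[i])
      cand_cols <- which(lab == "insertion_candidate")
      cand_in_block <- cand_cols[cand_cols > blocks$col_start[i] &
                                   cand_cols <= blocks$col_end[i]]
      chars <- aln$mat[tx, cand_in_block]
      expect_equal(inside, paste(chars[chars != "-"], collapse = ""))
      expect_equal(blocks$res_end[i] - blocks$res_start[i],
                   blocks$length_res[i])
    }
  }
})

test_that("peptide coverage considers every exact occurrence, with optional I/L equivalence", {
  prot <- "MKAAPQRST"
  iv <- rbind(c(3, 6))
  expect_true(peptide_coverage(prot, iv, "AAPQR")$covered)
  expect_false(peptide_coverage(prot, iv, "MKA")$covered)

  # two occurrences, only the second overlaps
  prot2 <- "APQRWWAPQR"
  expect_true(peptide_coverage(prot2, rbind(c(6, 9)), "APQR")$covered)

  # I/L equivalence
  expect_false(peptide_coverage("MKILPQRST", rbind(c(2, 5)), "KLIPQ")$covered)
  expect_true(peptide_coverage("MKILPQRST", rbind(c(2, 5)), "KLIPQ",
                               il_equiv = TRUE)$covered)

  expect_error(peptide_coverage(prot, rbind(c(3, 20)), "AAPQR"),
               class = "kuscape_interval_out_of_range")
})
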