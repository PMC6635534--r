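# One hand-checkable scenario reused across several composition tests:
# focal residues inside blocks are A-rich, background is A/G-balanced.
composition_fixture <- function() {
  # sp1 insertion (cols 5..14, 0-based) = AAAAAAAAGG; outside: 25 A, 25 G
  ins <- "AAAAAAAAGG"
  out1 <- paste(rep("AG", 25 / 2.5), collapse = "")  # 10 A, 10 G
  out2 <- paste(rep("GA", 15), collapse = "")        # 15 G, 15 A
  sp1 <- paste0(substr(out1, 1, 20), ins, substr(out2, 1, 30))
  bg <- paste0(substr(out1, 1, 20), strrep("-", nchar(ins)),
               substr(out2, 1, 30))
  toy_aln(sp1 = sp1, b1 = bg, b2 = bg, id = "ogc")
}

test_that("composition enrichment is the ratio of relative frequencies", {
  aln <- composition_fixture()
  blocks <- detect_insertion_blocks(aln, "sp1")
  ct <- composition_enrichment(aln, blocks, "sp1")
  # insertion counts {A:8, G:2}; background {A:25, G:25}
  expect_equal(ct$count_insertion[ct$aa == "A"], 8L)
  expect_equal(ct$count_insertion[ct$aa == "G"], 2L)
  expect_equal(ct$count_background[ct$aa == "A"], 25L)
  expect_equal(ct$enrichment[ct$aa == "A"], 1.6, tolerance = 1e-12)
  expect_equal(ct$enrichment[ct$aa == "G"], 0.4, tolerance = 1e-12)
  # enrichment undefined where background frequency is zero
  expect_true(all(is.na(ct$enrichment[!ct$aa %in% c("A", "G")])))
  expect_gt(attr(ct, "omnibus")$statistic, 0)
})

test_that("identical insertion and background proportions give enrichment 1", {
  # insertion AAGG (2:2) vs background with equal A:G
  aln <- toy_aln(sp1 = "AGAGAAGGAGAG", b1 = "AGAG----AGAG",
                 b2 = "AGAG----AGAG", id = "oge")
  blocks <- detect_insertion_blocks(aln, "sp1")
  ct <- composition_enrichment(aln, blocks, "sp1")
  defined <- !is.na(ct$enrichment)
  expect_true(all(abs(ct$enrichment[defined] - 1) < 1e-12))
  expect_equal(attr(ct, "omnibus")$statistic, 0, tolerance = 1e-9)
})

test_that("empty insertion pool and X exclusion are handled", {
  aln <- toy_aln(sp1 = "AGAGAG", b1 = "AGAGAG", id = "og0")
  expect_error(composition_enrichment(aln, insertion_blocks(), "sp1"),
               class = "kuscape_empty_pool")
  # X occupies columns but never enters the counts
  alnx <- toy_aln(sp1 = "AGAGXAXG", b1 = "AGAG---G", id = "ogx")
  bl <- detect_insertion_blocks(alnx, "sp1", min_len = 1)
  ct <- composition_enrichment(alnx, bl, "sp1")
  expect_equal(sum(ct$count_insertion), 1L)  # only the A at col 5
})

test_that("q-values are BH-monotone in raw-p order and bounded by 1", {
  aln <- composition_fixture()
  blocks <- detect_insertion_blocks(aln, "sp1")
  ct <- composition_enrichment(aln, blocks, "sp1")
  ord <- order(ct$p_value)
  expect_true(all(diff(ct$q_value[ord]) >= -1e-12))
  expect_true(all(ct$q_value <= 1))
  expect_true(all(ct$q_value >= ct$p_value - 1e-12))
})

test_that("enrichment similarity is Pearson on shared log2 enrichments", {
  aln <- composition_fixture()
  blocks <- detect_insertion_blocks(aln, "sp1")
  ct <- composition_enrichment(aln, blocks, "sp1")
  sim <- enrichment_similarity(list(ct, ct), min_shared = 2)
  expect_equal(sim[1, 2], 1.0, tolerance = 1e-12)

  t1 <- mock_composition("u", c(2, 1, 0.5))    # log2 = (1, 0, -1)
  t2 <- mock_composition("v", c(0.5, 1, 2))    # log2 = (-1, 0, 1)
  sim2 <- enrichment_similarity(list(t1, t2), min_shared = 3)
  expect_equal(sim2["u", "v"], -1.0, tolerance = 1e-12)

  t3 <- mock_composition("w", c(2, NA, NA))
  expect_error(enrichment_similarity(list(t1, t3), min_shared = 3),
               class = "kuscape_insufficient_overlap")
})

test_that("taxa sharing an insertion composition show correlated enrichment patterns", {
  set.seed(31)
  freqs <- rep(0.01, 20); freqs[c(1, 6, 13, 16, 17)] <- 0.17  # A,G,P,S,T-rich
  stopifnot(abs(sum(freqs) - 1) < 1e-9)
  cors <- replicate(100, {
    tabs <- lapply(1:2, function(i) {
      p <- orthogroup_sim_params(L = 400, d = 0.02, ins_rate = 0.05,
                                 ins_mean_len = 8, ins_freqs = freqs,
                                 seed = NULL)
      sim <- simulate_orthogroup(p, id = paste0("og", i))
      composition_enrichment(sim$alignment,
                             sim$blocks[sim$blocks$taxon == "jac1", ],
                             "jac1")
    })
    tryCatch(enrichment_similarity(tabs, min_shared = 5)[1, 2],
             kuscape_insufficient_overlap = function(e) NA_real_)
  })
  expect_gt(mean(cors, na.rm = TRUE), 0.8)
})

test_that("paired fraction comparison: exact p, convention cases, errors", {
  same <- stats::setNames(c(0.1, 0.2, 0.3), c("a", "b", "c"))
  expect_equal(compare_fraction_paired(same, same)$p_value, 1)

  f <- stats::setNames(c(0.2, 0.3, 0.25), c("a", "b", "c"))
  r <- stats::setNames(c(0.1, 0.1, 0.1), c("a", "b", "c"))
  pc <- compare_fraction_paired(f, r)
  expect_equal(pc$p_value, 0.25, tolerance = 1e-12)
  expect_equal(pc$n_alignments, 3L)

  swapped <- compare_fraction_paired(r, f)
  expect_equal(swapped$p_value, pc$p_value)
  expect_equal(swapped$statistic, -pc$statistic)

  expect_error(compare_fraction_paired(f[1:2], r[1:2]),
               class = "kuscape_too_few_pairs")
  # pairing is by orthogroup id, not position
  expect_equal(compare_fraction_paired(f, r[c("c", "a", "b")])$p_value,
               pc$p_value)
})

test_that("flank divergence: hand-counted rates and the convention cases", {
  # block cols [4, 8); flank width 2 -> flank cols {2,3,8,9}, distal rest
  aln <- toy_aln(f = "MKWAPQRSTACDEF",
                 b = "MKYA----TACDEF", id = "ogf")
  blocks <- detect_insertion_blocks(aln, "f", min_len = 1)
  expect_equal(blocks$col_start, 4L); expect_equal(blocks$col_end, 8L)
  fd <- flank_divergence(aln, blocks, flank_width = 2)
  # flank pairs: cols 2,3,8,9 -> W/Y mismatch at col 2; 4 scored pairs
  expect_equal(fd$n_flank_pairs, 4L)
  expect_equal(fd$flank_mismatch_rate, 0.25)
  expect_equal(fd$distal_mismatch_rate, 0)
  expect_true(is.infinite(fd$ratio))

  # identical focal and background outside blocks -> both 0, ratio 1
  aln2 <- toy_aln(f = "MKAAPQRSTACDEF", b = "MKAA----TACDEF", id = "ogf2")
  b2 <- detect_insertion_blocks(aln2, "f", min_len = 1)
  fd2 <- flank_divergence(aln2, b2, flank_width = 2)
  expect_equal(fd2$ratio, 1)

  expect_error(flank_divergence(aln, insertion_blocks(), 2),
               class = "kuscape_no_flank_columns")
})

test_that("simulated 3x flank substitution yields median flank/distal ratio > 2", {
  set.seed(32)
  ratios <- replicate(200, {
    p <- orthogroup_sim_params(L = 300, d = 0.05, ins_rate = 0.01,
                               ins_mean_len = 6, flank_mult = 3,
                               flank_width = 5, seed = NULL)
    sim <- simulate_orthogroup(p)
    if (nrow(sim$blocks) == 0) return(NA_real_)
    fb <- sim$blocks[sim$blocks$taxon %in% p$focal, ]
    tryCatch(flank_divergence(sim$alignment, fb, flank_width = 5)$ratio,
             kuscape_error = function(e) NA_real_)
  })
  expect_gt(stats::median(ratios, na.rm = TRUE), 2)
})

test_that("conservation-vs-insertion correlation behaves on ranks", {
  recs <- data.frame(conservation = c(0.9, 0.8, 0.5, 0.4),
                     fraction = c(0.00, 0.05, 0.10, 0.20))
  res <- conservation_vs_insertion(recs)
  expect_equal(res$rho, -1.0, tolerance = 1e-12)
  # permutation invariance
  res2 <- conservation_vs_insertion(recs[c(3, 1, 4, 2), ])
  expect_equal(res2$rho, res$rho)

  expect_error(conservation_vs_insertion(
    data.frame(conservation = c(0.9, 0.8, 0.5, 0.4),
               fraction = rep(0.1, 4))), class = "kuscape_constant_input")
  expect_error(conservation_vs_insertion(recs[1:3, ]),
               class = "kuscape_too_few_alignments")
})

test_that("alignment conservation is mean pairwise identity off-candidate", {
  aln <- toy_aln(a = "MKAA", b = "MKAW", c = "MKTA")
  # all columns gap-free; pairs: ab 3/4, ac 3/4, bc 2/4 -> mean 2/3
  expect_equal(alignment_conservation(aln), mean(c(.75, .75, .5)))
  # excluding the last column via a candidate mask changes the pool
  mask <- c(FALSE, FALSE, FALSE, TRUE)
  expect_equal(alignment_conservation(aln, mask), mean(c(1, 2 / 3, 2 / 3)))
})
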