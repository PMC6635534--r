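# Independent oracles and fixture builders. Every oracle is a plain,
# direct-enumeration implementation kept deliberately separate from the
# package's algorithms.

toy_aln <- function(..., id = "og1") msa(id, c(...))

# ---- brute-force insertion-block oracle -------------------------------

# per-column candidate call by explicit loops
oracle_candidates <- function(aln, focal, background, bg_gap_frac) {
  sapply(seq_len(aln$n_cols), function(j) {
    focal_res <- FALSE
    for (f in focal) if (aln$mat[f, j] != "-") focal_res <- TRUE
    gaps <- 0
    for (b in background) if (aln$mat[b, j] == "-") gaps <- gaps + 1
    focal_res && (gaps / length(background)) >= bg_gap_frac
  })
}

# full brute-force block detection: scan runs, merge, filter by min_len
oracle_blocks <- function(aln, focal, background = setdiff(aln$taxa, focal),
                          bg_gap_frac = 1, merge_gap = 0, min_len = 3) {
  cand <- oracle_candidates(aln, focal, background, bg_gap_frac)
  spans <- list()
  j <- 1
  while (j <= aln$n_cols) {
    if (cand[j]) {
      k <- j
      while (k < aln$n_cols && cand[k + 1]) k <- k + 1
      spans[[length(spans) + 1]] <- c(j, k)  # 1-based inclusive
      j <- k + 1
    } else j <- j + 1
  }
  # merge spans separated by <= merge_gap non-candidate columns
  merged <- list()
  for (sp in spans) {
    if (length(merged) && sp[1] - merged[[length(merged)]][2] - 1 <= merge_gap)
      merged[[length(merged)]][2] <- sp[2]
    else merged[[length(merged) + 1]] <- sp
  }
  rows <- list()
  for (sp in merged) for (tx in focal) {
    cols <- sp[1]:sp[2]
    len <- sum(aln$mat[tx, cols[cand[cols]]] != "-")
    if (len < min_len) next
    before <- if (sp[1] > 1) sum(aln$mat[tx, 1:(sp[1] - 1)] != "-") else 0
    inside <- sum(aln$mat[tx, cols] != "-")
    rows[[length(rows) + 1]] <- data.frame(
      orthogroup = aln$id, taxon = tx,
      col_start = sp[1] - 1L, col_end = sp[2],
      res_start = as.integer(before), res_end = as.integer(before + inside),
      length_res = as.integer(len), cand_cols = as.integer(sum(cand[cols])),
      merged_span_cols = as.integer(sp[2] - sp[1] + 1),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(insertion_blocks())
  out <- do.call(rbind, rows)
  insertion_blocks(out[order(out$taxon, out$col_start), ])
}

random_aln <- function(n_taxa, n_cols, gap_prob = 0.3, id = "rnd") {
  mat <- matrix(sample(c(AA20, "-"), n_taxa * n_cols, replace = TRUE,
                       prob = c(rep((1 - gap_prob) / 20, 20), gap_prob)),
                nrow = n_taxa)
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- paste0("t", seq_len(n_taxa))
  msa(id, seqs)
}

# ---- Dollo brute force ------------------------------------------------

# minimum losses over all internal-state assignments under a single origin:
# the (virtual) edge above the root starts at 1, regain (0 -> 1) is
# forbidden everywhere, and every 1 -> 0 edge (including the root edge)
# counts as one loss
oracle_dollo <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  root <- ntip + 1L
  tipst <- as.integer(tip_states[tree$tip.label])
  frees <- root:(ntip + nnode)   # root included: loss may sit on root edge
  best <- Inf
  n_free <- length(frees)
  for (code in 0:(2^n_free - 1)) {
    st <- integer(ntip + nnode)
    st[seq_len(ntip)] <- tipst
    st[frees] <- bitwAnd(bitwShiftR(code, seq_len(n_free) - 1L), 1L)
    ok <- TRUE
    losses <- as.integer(st[root] == 0L)   # virtual root edge 1 -> 0
    for (e in seq_len(nrow(edge))) {
      p <- st[edge[e, 1]]; c <- st[edge[e, 2]]
      if (p == 0L && c == 1L) { ok <- FALSE; break }
      if (p == 1L && c == 0L) losses <- losses + 1L
    }
    if (ok && losses < best) best <- losses
  }
  best
}

# random rooted tree, optionally with polytomies
random_tree <- function(n, polytomy = FALSE) {
  tr <- ape::rtree(n, rooted = TRUE)
  if (polytomy && n >= 4) {
    # collapse a random internal edge into a polytomy
    internal <- which(tr$edge[, 2] > n)
    if (length(internal)) {
      tr$edge.length[] <- 1
      tr$edge.length[sample(internal, 1)] <- 0
      tr <- ape::di2multi(tr, tol = 1e-8)
    }
  }
  tr
}

# ---- exact rank-test oracles ------------------------------------------

# two-sided Mann-Whitney by enumerating all group assignments
oracle_mw_p <- function(x, y) {
  n <- length(x); N <- n + length(y)
  pool <- c(x, y)
  r <- rank(pool)
  mu <- n * mean(r)
  obs <- sum(r[seq_len(n)])
  sets <- utils::combn(N, n)
  stats <- apply(sets, 2, function(idx) sum(r[idx]))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# two-sided Wilcoxon signed rank by enumerating all 2^n sign assignments
oracle_sr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  stats <- apply(signs, 1, function(s) sum(r[s]))
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# ---- misc --------------------------------------------------------------

# minimal composition table with prescribed enrichments, for similarity tests
mock_composition <- function(taxon, enrichment, aas = AA20[seq_along(enrichment)]) {
  out <- data.frame(aa = aas, enrichment = enrichment,
                    stringsAsFactors = FALSE)
  attr(out, "taxon") <- taxon
  out
}
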