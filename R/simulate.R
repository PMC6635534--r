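# Ground-truth generators. simulate_orthogroup emits the TRUE alignment
# directly from known homology (no aligner), so detection performance is
# measured free of aligner error; simulate_phyletic_table couples component
# loss to genome size through a logistic model.

#' Parameters for the orthogroup simulator
#'
#' @param L Ancestral sequence length (columns before insertions).
#' @param focal Character vector of focal-lineage taxon ids (share every
#'   focal insertion, as expected for insertions arising in their common
#'   ancestor).
#' @param background Character vector of background taxon ids.
#' @param reference Optional reference taxon id (gets its own insertions at
#'   `ins_rate_ref`).
#' @param d Per-branch, per-site substitution probability in `[0, 1)`;
#'   replacements are uniform over the 19 alternative residues.
#' @param ins_rate Focal insertion rate per ancestral site (events ~
#'   Poisson(`ins_rate * L`)).
#' @param ins_rate_ref Reference-lineage insertion rate (default 0).
#' @param ins_mean_len Mean insertion length `m >= 1`; lengths are geometric
#'   on `1, 2, ...` with mean `m`.
#' @param ins_freqs Amino-acid frequency vector for inserted residues
#'   (length 20, sums to 1); default uniform.
#' @param flank_mult Substitution-probability multiplier applied to every
#'   taxon at ancestral sites within `flank_width` sites of a focal
#'   insertion point (emulates the elevated divergence observed at
#'   insertion flanks, where the alignment is least reliable).
#' @param flank_width Flank half-width in ancestral sites (default 5).
#' @param seed Integer seed; all randomness in [simulate_orthogroup()] flows
#'   from it. `NULL` uses the ambient RNG stream.
#' @return Validated list of class `"orthogroup_sim_params"`.
#' @export
orthogroup_sim_params <- function(L = 1000, focal = c("jac1", "jac2"),
                                  background = c("bg1", "bg2", "bg3", "bg4"),
                                  reference = NULL, d = 0.05,
                                  ins_rate = 0.002, ins_rate_ref = 0,
                                  ins_mean_len = 8,
                                  ins_freqs = rep(1 / 20, 20),
                                  flank_mult = 1, flank_width = 5,
                                  seed = 0) {
  if (L < 1 || d < 0 || d >= 1 || ins_rate < 0 || ins_rate_ref < 0 ||
      ins_mean_len < 1 || flank_mult < 0 || flank_width < 0)
    ks_abort("invalid_params", "parameter out of range")
  if (length(ins_freqs) != 20L || any(ins_freqs < 0) ||
      abs(sum(ins_freqs) - 1) > 1e-8)
    ks_abort("invalid_params", "ins_freqs must be a 20-simplex")
  if (length(focal) == 0L || length(background) == 0L ||
      anyDuplicated(c(focal, background, reference)))
    ks_abort("invalid_params", "taxon sets must be disjoint and non-empty")
  if (ins_rate_ref > 0 && is.null(reference))
    ks_abort("invalid_params", "ins_rate_ref > 0 needs a reference taxon")
  structure(list(L = as.integer(L), focal = focal, background = background,
                 reference = reference, d = d, ins_rate = ins_rate,
                 ins_rate_ref = ins_rate_ref, ins_mean_len = ins_mean_len,
                 ins_freqs = ins_freqs, flank_mult = flank_mult,
                 flank_width = flank_width, seed = seed),
            class = "orthogroup_sim_params")
}

# geometric on 1,2,... with mean m
rgeom1 <- function(n, m) stats::rgeom(n, prob = 1 / m) + 1L

mutate_seq <- function(chars, p) {
  if (length(p) == 1L) p <- rep(p, length(chars))
  hit <- stats::runif(length(chars)) < p
  if (any(hit)) {
    cur <- chars[hit]
    alt <- vapply(cur, function(a) sample(setdiff(AA20, a), 1L), character(1L))
    chars[hit] <- alt
  }
  chars
}

#' Simulate one orthogroup alignment with known insertion ground truth
#'
#' Draws a uniform ancestral sequence, applies independent per-branch
#' substitutions to every taxon, inserts focal-lineage-shared (and
#' optionally reference-specific) segments at Poisson-distributed sites
#' with geometric lengths, and returns the true alignment assembled from
#' known homology together with the true blocks (maximal runs of inserted
#' columns, with exact column and residue coordinates, relative to the
#' focal-vs-rest partition for focal taxa and reference-vs-rest for the
#' reference).
#'
#' @param params An [orthogroup_sim_params()].
#' @param id Orthogroup id for the emitted alignment.
#' @param seed Overrides `params$seed` when not missing.
#' @return List with elements `alignment` (an [msa()]) and `blocks` (an
#'   [insertion_blocks()] of true blocks).
#' @export
simulate_orthogroup <- function(params, id = "sim_og", seed) {
  stopifnot(inherits(params, "orthogroup_sim_params"))
  if (missing(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  L <- params$L
  anc <- sample(AA20, L, replace = TRUE)
  draw_events <- function(rate) {
    n_ev <- stats::rpois(1L, rate * L)
    if (n_ev == 0L)
      return(data.frame(pos = integer(), len = integer()))
    data.frame(pos = sample.int(L + 1L, n_ev, replace = TRUE) - 1L,
               len = rgeom1(n_ev, params$ins_mean_len))
  }
  ev_f <- draw_events(params$ins_rate)
  ev_r <- if (!is.null(params$reference)) draw_events(params$ins_rate_ref)
          else data.frame(pos = integer(), len = integer())
  ev <- rbind(cbind(ev_f, origin = rep("focal", nrow(ev_f))),
              cbind(ev_r, origin = rep("reference", nrow(ev_r))))
  n_ev <- nrow(ev)
  ev$seq <- lapply(ev$len, function(l)
    sample(AA20, l, replace = TRUE, prob = params$ins_freqs))
  # column plan: units are ancestral sites (one column each) and insertion
  # events (len columns); an event at pos p sits between sites p and p + 1
  u_pos <- c(seq_len(L) - 1L, ev$pos)
  u_type <- c(rep(1L, L), rep(0L, n_ev))        # events precede site p + 1
  u_idx <- c(seq_len(L), seq_len(n_ev))
  u_len <- c(rep(1L, L), ev$len)
  u_orig <- c(rep("anc", L), ev$origin)
  o <- order(u_pos, u_type, c(rep(0L, L), seq_len(n_ev)))
  origin <- rep(u_orig[o], u_len[o])
  anc_idx <- rep(ifelse(u_orig[o] == "anc", u_idx[o], NA_integer_), u_len[o])
  ev_idx <- rep(ifelse(u_orig[o] == "anc", NA_integer_, u_idx[o]), u_len[o])
  ins_offset <- unlist(lapply(u_len[o], seq_len), use.names = FALSE)
  n_cols <- length(origin)
  # flank mask over ancestral sites: within flank_width of a focal
  # insertion point (insertion after site pos means flanks pos-w+1..pos+w)
  flank_site <- logical(L)
  if (params$flank_mult != 1 && nrow(ev_f)) {
    for (p in ev_f$pos) {
      lo <- max(1L, p - params$flank_width + 1L)
      hi <- min(L, p + params$flank_width)
      if (hi >= lo) flank_site[lo:hi] <- TRUE
    }
  }
  taxa <- c(params$focal, params$background, params$reference)
  mat <- matrix("-", nrow = length(taxa), ncol = n_cols,
                dimnames = list(taxa, NULL))
  anc_cols <- which(origin == "anc")
  p_sub <- rep(params$d, L)
  p_sub[flank_site] <- pmin(1, params$d * params$flank_mult)
  for (tx in taxa) {
    is_focal <- tx %in% params$focal
    row_anc <- mutate_seq(anc, p_sub)
    mat[tx, anc_cols] <- row_anc[anc_idx[anc_cols]]
    own <- if (is_focal) "focal"
           else if (!is.null(params$reference) && tx == params$reference)
             "reference" else NA_character_
    if (!is.na(own)) {
      cols <- which(origin == own)
      if (length(cols)) {
        base <- vapply(cols, function(cc)
          ev$seq[[ev_idx[cc]]][ins_offset[cc]], character(1L))
        mat[tx, cols] <- mutate_seq(base, params$d)
      }
    }
  }
  aln <- msa(id, apply(mat, 1L, paste, collapse = ""))
  # true blocks: maximal runs of same-origin inserted columns
  block_rows <- list()
  for (own in c("focal", "reference")) {
    runs <- runs_of(origin == own)
    if (nrow(runs) == 0L) next
    carriers <- if (own == "focal") params$focal else params$reference
    for (i in seq_len(nrow(runs))) for (tx in carriers) {
      res <- map_columns_to_residues(aln, tx, runs[i, "start"],
                                     runs[i, "end"])
      block_rows[[length(block_rows) + 1L]] <- data.frame(
        orthogroup = id, taxon = tx,
        col_start = runs[i, "start"], col_end = runs[i, "end"],
        res_start = res[[1L]], res_end = res[[2L]],
        length_res = runs[i, "end"] - runs[i, "start"],
        cand_cols = runs[i, "end"] - runs[i, "start"],
        merged_span_cols = runs[i, "end"] - runs[i, "start"],
        stringsAsFactors = FALSE)
    }
  }
  blocks <- if (length(block_rows)) {
    b <- do.call(rbind, block_rows)
    insertion_blocks(b[order(b$taxon, b$col_start), ])
  } else insertion_blocks()
  list(alignment = aln, blocks = blocks)
}

#' Parameters for the phyletic-profile simulator
#'
#' Genome sizes are log-normal on the log10-Mb scale; the probability that
#' a species has lost all three C-NHEJ components follows a logistic model
#' in log10 genome size, `Pr(absent) = plogis(a + b * log10(size))`, so a
#' negative `b` makes small genomes more likely to have lost the pathway.
#' Defaults emulate a 230-genome survey with a median genome of 100 Mb and
#' a marginal triple-loss rate near 9%.
#'
#' @param n_species Number of species (>= 4).
#' @param mu,sigma Mean and s.d. of log10 genome size in Mb
#'   (defaults 2.0, 0.9).
#' @param a,b Logistic intercept and slope on log10 size
#'   (defaults 1.65, -2.0).
#' @param seed Integer seed (`NULL`: ambient RNG).
#' @return Validated list of class `"phyletic_sim_params"`.
#' @export
phyletic_sim_params <- function(n_species = 230, mu = 2.0, sigma = 0.9,
                                a = 1.65, b = -2.0, seed = 0) {
  if (n_species < 4 || sigma <= 0)
    ks_abort("invalid_params", "need n_species >= 4 and sigma > 0")
  structure(list(n_species = as.integer(n_species), mu = mu, sigma = sigma,
                 a = a, b = b, seed = seed),
            class = "phyletic_sim_params")
}

#' Simulate a phyletic profile with a genome-size/loss effect
#'
#' Species either retain all three components (1,1,1) or have lost all
#' three (0,0,0), with loss probability logistic in log10 genome size.
#' Lifestyle is parasitic with probability 0.8 for losers and 0.3
#' otherwise, reflecting the observed concentration of pathway loss in
#' parasites without making it deterministic.
#'
#' @param params A [phyletic_sim_params()].
#' @param seed Overrides `params$seed` when not missing.
#' @return A [phyletic_profile()].
#' @export
simulate_phyletic_table <- function(params, seed) {
  stopifnot(inherits(params, "phyletic_sim_params"))
  if (missing(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_species
  lsize <- stats::rnorm(n, params$mu, params$sigma)
  p_absent <- stats::plogis(params$a + params$b * lsize)
  absent <- stats::rbinom(n, 1L, p_absent) == 1L
  parasite <- stats::runif(n) < ifelse(absent, 0.8, 0.3)
  phyletic_profile(data.frame(
    species = sprintf("sp%03d", seq_len(n)),
    clade = paste0("clade", (seq_len(n) - 1L) %% 10L + 1L),
    lifestyle = ifelse(parasite, "parasite", "free_living"),
    genome_size_mb = 10^lsize,
    ku70 = as.integer(!absent), ku80 = as.integer(!absent),
    lig4 = as.integer(!absent), stringsAsFactors = FALSE))
}
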