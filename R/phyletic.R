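# Phyletic analyses of C-NHEJ presence/absence: the component census, the
# genome-size contrast between pathway-lacking and pathway-bearing genomes,
# and minimum independent loss counts on a species tree (Dollo parsimony
# with ancestral presence fixed at the root).

COMPONENTS <- c("ku70", "ku80", "lig4")

complete_component_rows <- function(profile) {
  stats::complete.cases(as.data.frame(profile)[COMPONENTS])
}

#' Census of genomes by number of C-NHEJ components present
#'
#' Counts genomes by how many of Ku70, Ku80 and Lig4 they encode
#' (k in 0..3). Rows with an NA presence call cannot be assigned a k and are
#' excluded with a warning -- absence of evidence is not evidence of absence.
#'
#' @param profile A [phyletic_profile()].
#' @param exclude Optional character vector of species ids to drop before
#'   counting (e.g. genomes with engineered pathway deletions).
#' @return List of class `"component_census"` with `counts` (named integer
#'   vector over k = "0".."3"), `excluded` (NA rows) and `n_total`.
#' @export
component_census <- function(profile, exclude = NULL) {
  profile <- phyletic_profile(profile)
  if (!is.null(exclude))
    profile <- phyletic_profile(profile[!profile$species %in% exclude, ])
  if (nrow(profile) == 0L)
    ks_abort("empty_profile", "profile has no rows")
  ok <- complete_component_rows(profile)
  if (any(!ok))
    ks_warn("na_excluded", "%d row(s) with NA presence calls excluded",
            sum(!ok))
  k <- rowSums(as.data.frame(profile)[ok, COMPONENTS, drop = FALSE])
  counts <- stats::setNames(integer(4L), as.character(0:3))
  tab <- table(factor(k, levels = 0:3))
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts, excluded = sum(!ok),
                 n_total = nrow(profile)),
            class = "component_census")
}

#' @export
print.component_census <- function(x, ...) {
  cat("C-NHEJ component census (k = components present):\n")
  print(x$counts)
  cat(sprintf("excluded (NA calls): %d of %d genomes\n", x$excluded,
              x$n_total))
  invisible(x)
}

#' Genome-size contrast between C-NHEJ-lacking and -bearing genomes
#'
#' "Lacking" means all three of Ku70, Ku80 and Lig4 absent; "bearing" means
#' at least one present (so trypanosomatids, which retain Ku but lost Lig4,
#' count as bearing). The primary test is a two-sided Mann-Whitney U on raw
#' sizes (exact for combined n <= 20, normal approximation with tie
#' correction otherwise); a Welch t-test on log10 sizes is reported
#' alongside, since genome sizes are heavy-tailed.
#'
#' @param profile A [phyletic_profile()].
#' @param exclude Optional species ids to drop first.
#' @return List of class `"size_contrast"`: group sizes, means, medians
#'   (Mb scale), `ratio` (mean bearing / mean lacking), `p_value`,
#'   `test_name`, `statistic` (U), and `welch_log10` with the companion
#'   test.
#' @export
size_contrast <- function(profile, exclude = NULL) {
  profile <- phyletic_profile(profile)
  if (!is.null(exclude))
    profile <- phyletic_profile(profile[!profile$species %in% exclude, ])
  ok <- complete_component_rows(profile) & !is.na(profile$genome_size_mb)
  if (any(!ok))
    ks_warn("na_excluded",
            "%d row(s) with NA presence or size excluded", sum(!ok))
  df <- as.data.frame(profile)[ok, , drop = FALSE]
  lacking <- rowSums(df[COMPONENTS]) == 0L
  x <- df$genome_size_mb[lacking]    # lacking
  y <- df$genome_size_mb[!lacking]   # bearing
  if (length(x) == 0L || length(y) == 0L)
    ks_abort("degenerate_group",
             "both groups must be non-empty (lacking: %d, bearing: %d)",
             length(x), length(y))
  mw <- mann_whitney_test(x, y)
  wt <- if (length(x) >= 2L && length(y) >= 2L)
    stats::t.test(log10(y), log10(x))
  else list(statistic = NA_real_, p.value = NA_real_)
  structure(list(
    n_lacking = length(x), n_bearing = length(y),
    mean_lacking_mb = mean(x), mean_bearing_mb = mean(y),
    median_lacking_mb = stats::median(x), median_bearing_mb = stats::median(y),
    ratio = mean(y) / mean(x),
    statistic = mw$statistic, p_value = mw$p_value,
    test_name = "mann_whitney_u", exact = mw$exact,
    welch_log10 = list(test_name = "welch_t_log10",
                       statistic = unname(wt$statistic),
                       p_value = wt$p.value)),
    class = "size_contrast")
}

#' @export
print.size_contrast <- function(x, ...) {
  cat(sprintf(
    "Genome size, C-NHEJ lacking (n=%d) vs bearing (n=%d):\n",
    x$n_lacking, x$n_bearing))
  cat(sprintf("  mean   %.1f vs %.1f Mb (ratio %.2f)\n",
              x$mean_lacking_mb, x$mean_bearing_mb, x$ratio))
  cat(sprintf("  median %.1f vs %.1f Mb\n",
              x$median_lacking_mb, x$median_bearing_mb))
  cat(sprintf("  Mann-Whitney U = %.1f, p = %.3g (%s)\n", x$statistic,
              x$p_value, if (x$exact) "exact" else "normal approx."))
  cat(sprintf("  Welch t on log10 sizes: t = %.2f, p = %.3g\n",
              x$welch_log10$statistic, x$welch_log10$p_value))
  invisible(x)
}

#' Minimum independent losses under Dollo parsimony
#'
#' With the ancestral state fixed to "present" at the root and regain
#' forbidden (a single origin), the minimum number of independent losses
#' explaining a binary tip pattern equals the number of maximal subtrees
#' whose tips are all absent; the loss edges are the edges subtending those
#' subtrees. If every tip is absent the single loss is placed on the root
#' edge. Tips on the tree without a state are pruned with a warning.
#'
#' @param tree A rooted `"phylo"` tree (polytomies allowed).
#' @param tip_states Named vector of 0/1 (0 = absent) keyed by tip label.
#' @param component Optional component id carried into the result.
#' @return List of class `"dollo"` with `component`, `min_losses`,
#'   `loss_edges` (child-node identifiers: tip labels, or internal labels /
#'   `"node<k>"` / `"root"`).
#' @export
dollo_min_losses <- function(tree, tip_states, component = NA_character_) {
  stopifnot(inherits(tree, "phylo"))
  states <- tip_states
  unknown <- setdiff(names(states), tree$tip.label)
  if (length(unknown))
    ks_abort("unknown_tip", "state(s) given for tip(s) not on the tree: %s",
             paste(unknown, collapse = ", "))
  if (anyNA(states) || !all(states %in% c(0, 1)))
    ks_abort("invalid_params", "tip states must be 0 or 1")
  unscored <- setdiff(tree$tip.label, names(states))
  if (length(unscored)) {
    ks_warn("pruned_tips", "pruning %d unscored tip(s)", length(unscored))
    tree <- ape::drop.tip(tree, unscored,
                          collapse.singles = TRUE)
    if (is.null(tree) || length(tree$tip.label) == 0L)
      ks_abort("invalid_params", "no scored tips remain on the tree")
  }
  ntip <- length(tree$tip.label)
  if (ntip == 1L) {
    absent <- states[[tree$tip.label]] == 0
    return(structure(list(component = component,
                          min_losses = as.integer(absent),
                          loss_edges = if (absent) "root" else character()),
                     class = "dollo"))
  }
  nnode <- tree$Nnode
  root <- ntip + 1L
  all_absent <- logical(ntip + nnode)
  all_absent[seq_len(ntip)] <- states[tree$tip.label] == 0
  edge <- tree$edge
  # postorder over edges fills internal nodes children-first
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  kids <- split(ord[, 2L], ord[, 1L])
  for (nd in unique(ord[, 1L]))          # postorder: children precede parents
    all_absent[nd] <- all(all_absent[kids[[as.character(nd)]]])
  parent <- integer(ntip + nnode)
  parent[edge[, 2L]] <- edge[, 1L]
  node_id <- function(nd) {
    if (nd <= ntip) return(tree$tip.label[nd])
    if (!is.null(tree$node.label) &&
        nzchar(tree$node.label[nd - ntip]) &&
        !is.na(tree$node.label[nd - ntip]))
      return(tree$node.label[nd - ntip])
    paste0("node", nd)
  }
  if (all_absent[root]) {
    return(structure(list(component = component, min_losses = 1L,
                          loss_edges = "root"), class = "dollo"))
  }
  loss_nodes <- which(all_absent & seq_along(all_absent) != root &
                        !all_absent[pmax(parent, 1L)])
  structure(list(component = component,
                 min_losses = length(loss_nodes),
                 loss_edges = vapply(loss_nodes, node_id, character(1L))),
            class = "dollo")
}

#' @export
print.dollo <- function(x, ...) {
  cat(sprintf("Dollo minimum losses%s: %d\n",
              if (is.na(x$component)) "" else paste0(" (", x$component, ")"),
              x$min_losses))
  if (x$min_losses)
    cat("  on edges to:", paste(x$loss_edges, collapse = ", "), "\n")
  invisible(x)
}
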