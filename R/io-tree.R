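# Species trees are ape "phylo" objects; the ape root node is taken as the
# root (a basal polytomy is legal). Tip labels must match profile species ids.

#' Read a rooted species tree (Newick)
#'
#' @param path Path to a file containing one Newick string.
#' @return An [ape::read.tree()] `"phylo"` object with unique tip labels.
#' @export
read_newick <- function(path) {
  if (!file.exists(path))
    ks_abort("io_error", "no such file: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                 error = function(e)
                   ks_abort("parse_error", "cannot parse Newick '%s': %s",
                            path, conditionMessage(e)))
  if (is.null(tr) || inherits(tr, "multiPhylo"))
    ks_abort("parse_error", "expected exactly one Newick tree in %s", path)
  if (anyDuplicated(tr$tip.label))
    ks_abort("duplicate_tip", "duplicated tip label(s): %s",
             paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                   collapse = ", "))
  tr
}

#' Write a tree as Newick
#'
#' @param tree A `"phylo"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
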