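# Orchestration: runs the phyletic and/or insertion analyses from a single
# declarative configuration and writes a schema-versioned JSON report plus
# TSV tables. Identical inputs + seed give byte-identical reports.

REPORT_SCHEMA <- "kuscape-report/1"

#' Build a pipeline configuration
#'
#' Either analysis is run when its inputs are supplied: the phyletic stage
#' needs `profile` (and `tree` for Dollo loss counts); the insertion stage
#' needs `msa_dir` and `focal`.
#'
#' @param profile Path to a phyletic-profile TSV, or `NULL`.
#' @param tree Path to a Newick species tree, or `NULL`.
#' @param msa_dir Directory of aligned FASTA files (`.fa`, `.fasta`,
#'   `.faa`), or `NULL`.
#' @param peptides Path to a peptide TSV, or `NULL`.
#' @param focal Focal taxon ids (jointly focal, sharing insertions).
#' @param reference Optional reference taxon id for the paired comparison.
#' @param exclude Species ids excluded from the phyletic stage.
#' @param out_dir Output directory (created if absent).
#' @param bg_gap_frac,merge_gap,min_len,ignore_terminal_gaps,flank_width
#'   Stage parameters, see [detect_insertion_blocks()] and
#'   [flank_divergence()].
#' @param seed Integer seed recorded in the report (analyses are
#'   deterministic; the seed matters when configs drive simulators).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(profile = NULL, tree = NULL, msa_dir = NULL,
                            peptides = NULL, focal = NULL, reference = NULL,
                            exclude = character(), out_dir = "kuscape_out",
                            bg_gap_frac = 1, merge_gap = 0, min_len = 3,
                            ignore_terminal_gaps = FALSE, flank_width = 5,
                            seed = 0) {
  cfg <- list(profile = profile, tree = tree, msa_dir = msa_dir,
              peptides = peptides, focal = focal, reference = reference,
              exclude = exclude, out_dir = out_dir,
              bg_gap_frac = bg_gap_frac, merge_gap = merge_gap,
              min_len = min_len, ignore_terminal_gaps = ignore_terminal_gaps,
              flank_width = flank_width, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys match
#'   the arguments of [pipeline_config()].
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    ks_abort("config_error", "no such config file: %s", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else ks_abort("config_error", "config must be YAML or JSON: %s", path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown))
    ks_abort("config_error", "unknown config key(s): %s",
             paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

check_config_paths <- function(cfg) {
  for (key in c("profile", "tree", "peptides"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      ks_abort("config_error", "%s path does not exist: %s", key, cfg[[key]])
  if (!is.null(cfg$msa_dir) && !dir.exists(cfg$msa_dir))
    ks_abort("config_error", "msa_dir does not exist: %s", cfg$msa_dir)
  if (!is.null(cfg$msa_dir) && is.null(cfg$focal))
    ks_abort("config_error", "insertion stage needs focal taxa")
  invisible(TRUE)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, kuscape_error = function(e) {
    ks_abort("stage_error", "stage '%s' failed: %s", stage,
             conditionMessage(e))
  })
}

list_msa_files <- function(dir) {
  sort(list.files(dir, pattern = "\\.(fa|fasta|faa)$", full.names = TRUE))
}

#' Run the configured analyses and write the report bundle
#'
#' Executes the phyletic stage (component census, genome-size contrast,
#' per-component Dollo loss counts) and/or the insertion stage (block
#' detection, per-alignment fractions, pooled and mean summaries,
#' composition enrichment, paired focal-vs-reference comparison,
#' conservation correlation) depending on the configured inputs, and writes
#' `report.json` (embedding the resolved configuration, package version and
#' input checksums), `blocks.tsv` and `fractions.tsv` under `out_dir`.
#'
#' @param config A [pipeline_config()], or a path handled by
#'   [read_pipeline_config()].
#' @return Invisibly, the report as an R list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  check_config_paths(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(schema = REPORT_SCHEMA,
                 package_version = as.character(utils::packageVersion("kuscape")),
                 config = unclass(config),
                 input_checksums = list())
  for (key in c("profile", "tree", "peptides"))
    if (!is.null(config[[key]]))
      report$input_checksums[[key]] <- unname(tools::md5sum(config[[key]]))

  if (!is.null(config$profile)) {
    report$phyletic <- with_stage("phyletic", {
      prof <- read_profile_table(config$profile)
      census <- suppressWarnings(component_census(prof, config$exclude))
      contrast <- tryCatch(
        suppressWarnings(size_contrast(prof, config$exclude)),
        kuscape_degenerate_group = function(e) NULL)
      out <- list(census = list(counts = as.list(census$counts),
                                excluded = census$excluded,
                                n_total = census$n_total))
      if (!is.null(contrast))
        out$size_contrast <- contrast[c(
          "n_lacking", "n_bearing", "mean_lacking_mb", "mean_bearing_mb",
          "median_lacking_mb", "median_bearing_mb", "ratio", "statistic",
          "p_value", "test_name", "welch_log10")]
      if (!is.null(config$tree)) {
        tree <- read_newick(config$tree)
        keep <- !prof$species %in% config$exclude
        out$dollo <- lapply(COMPONENTS, function(comp) {
          st <- stats::setNames(prof[[comp]][keep], prof$species[keep])
          st <- st[!is.na(st) & names(st) %in% tree$tip.label]
          d <- suppressWarnings(dollo_min_losses(tree, st, comp))
          list(component = comp, min_losses = d$min_losses,
               loss_edges = as.list(d$loss_edges))
        })
      }
      out
    })
  }

  if (!is.null(config$msa_dir)) {
    report$insertions <- with_stage("insertions", {
      files <- list_msa_files(config$msa_dir)
      if (length(files) == 0L)
        ks_abort("config_error", "no alignments in %s", config$msa_dir)
      alns <- lapply(files, read_alignment)
      all_blocks <- list(); fracs <- list(); cons <- list()
      for (aln in alns) {
        partitions <- list(config$focal)
        if (!is.null(config$reference))
          partitions <- c(partitions, list(config$reference))
        aln_blocks <- list()
        for (fset in partitions) {
          fset <- intersect(fset, aln$taxa)
          if (length(fset) == 0L ||
              length(setdiff(aln$taxa, fset)) == 0L) next
          blocks <- detect_insertion_blocks(
            aln, fset, bg_gap_frac = config$bg_gap_frac,
            merge_gap = config$merge_gap, min_len = config$min_len,
            ignore_terminal_gaps = config$ignore_terminal_gaps)
          aln_blocks[[length(aln_blocks) + 1L]] <- blocks
          for (tx in fset)
            fracs[[length(fracs) + 1L]] <- insertion_fraction(aln, blocks, tx)
          if (identical(fset, intersect(config$focal, aln$taxa))) {
            cand <- candidate_cols(aln, fset, setdiff(aln$taxa, fset),
                                   config$bg_gap_frac,
                                   config$ignore_terminal_gaps)
            cons[[aln$id]] <- alignment_conservation(aln, cand)
          }
        }
        all_blocks <- c(all_blocks, aln_blocks)
      }
      blocks <- if (length(all_blocks))
        insertion_blocks(do.call(rbind, lapply(all_blocks, as.data.frame)))
      else insertion_blocks()
      write_blocks_tsv(blocks, file.path(config$out_dir, "blocks.tsv"))
      fr <- do.call(rbind, lapply(fracs, as.data.frame))
      utils::write.table(fr, file.path(config$out_dir, "fractions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      by_tax <- split(fr, fr$taxon)
      summaries <- lapply(by_tax, function(g)
        list(n_alignments = nrow(g),
             pooled_fraction = sum(g$inserted_cols) / sum(g$total_cols),
             mean_fraction = mean(g$fraction)))
      out <- list(n_alignments = length(alns),
                  fractions = summaries)
      comp <- lapply(intersect(config$focal, unique(blocks$taxon)),
                     function(tx) {
        ct <- tryCatch(composition_enrichment(alns, blocks, tx),
                       kuscape_empty_pool = function(e) NULL)
        if (is.null(ct)) return(NULL)
        list(taxon = tx,
             top_enriched = ct$aa[order(-ct$enrichment)][1:3],
             omnibus_p = attr(ct, "omnibus")$p_value)
      })
      out$composition <- Filter(Negate(is.null), comp)
      if (!is.null(config$reference)) {
        paired <- lapply(config$focal, function(tx) {
          ff <- fr[fr$taxon == tx, ]
          rr <- fr[fr$taxon == config$reference, ]
          pc <- tryCatch(
            compare_fraction_paired(ff, rr, tx, config$reference),
            kuscape_too_few_pairs = function(e) NULL)
          if (is.null(pc)) return(NULL)
          pc[c("focal", "reference", "n_alignments", "statistic", "V",
               "p_value", "test_name", "exact")]
        })
        out$paired <- Filter(Negate(is.null), paired)
      }
      cons_df <- data.frame(
        orthogroup = names(cons),
        conservation = unlist(cons, use.names = FALSE))
      pooled_focal <- fr[fr$taxon %in% config$focal, ]
      if (nrow(cons_df) >= 4L && nrow(pooled_focal)) {
        mean_fr <- tapply(pooled_focal$fraction, pooled_focal$orthogroup,
                          mean)
        recs <- data.frame(conservation = cons_df$conservation,
                           fraction = as.numeric(
                             mean_fr[cons_df$orthogroup]))
        cvi <- tryCatch(conservation_vs_insertion(recs),
                        kuscape_error = function(e) NULL)
        if (!is.null(cvi)) out$conservation_vs_insertion <- cvi
      }
      out
    })
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
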