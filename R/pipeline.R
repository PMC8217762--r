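#' Run the full gene-family analysis pipeline from a config
#'
#' Orchestrates the stages in dependency order — domain-hit scan, protein
#' properties, tandem detection, phylogeny, phylostratigraphy, MirrorTree
#' co-evolution, differential expression — skipping any stage whose inputs
#' are absent from the config. Every stage writes its table under
#' `out_dir` and contributes to a machine-readable `summary.json`
#' containing each reported statistic and the exact parameters used. The
#' summary carries no timestamps, so a rerun with the same config is
#' byte-identical.
#'
#' @param config Path to a YAML config, or an equivalent named list.
#'   Recognised entries (all optional except `out_dir`):
#'   \describe{
#'     \item{out_dir}{Output directory (created if needed).}
#'     \item{seed}{Integer seed used by stochastic stages (bootstrap).}
#'     \item{scan}{`domtbl` path, `e_max` (default 1e-5), `score_min` (0).}
#'     \item{props}{`fasta` path.}
#'     \item{tandem}{`genes` TSV path, `family` label.}
#'     \item{tree}{`aln` aligned-FASTA path, `model` ("poisson"/"p"),
#'       `bootstrap` replicate count (0 = no supports).}
#'     \item{strata}{`orthologs` TSV path; optional `background` named
#'       counts (label -> count).}
#'     \item{mirrortree}{`family_a`, `family_b`: directories of aligned
#'       FASTA files (one per member); `model`; `min_common`.}
#'     \item{de}{`matrix` TSV, `groups` TSV (columns sample, group),
#'       `case`, `control`, `lfc_min` (1), `alpha` (0.05), `mode`.}
#'   }
#' @return The summary list, invisibly; also written to
#'   `out_dir/summary.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L

  check_inputs <- function(stage, paths) {
    missing <- paths[!vapply(paths, file.exists, logical(1))]
    if (length(missing) > 0L) {
      stop("stage ", stage, ": missing input file(s): ",
           paste(missing, collapse = ", "))
    }
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  write_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }

  summary <- list(parameters = list(seed = seed), stages = list())
  skipped <- character(0)

  if (!is.null(config$scan)) {
    summary$stages$scan <- run_stage("scan", function() {
      cf <- config$scan
      check_inputs("scan", cf$domtbl)
      e_max <- cf$e_max %||% 1e-5
      score_min <- cf$score_min %||% 0
      hits <- read_domtbl(cf$domtbl)
      acc <- filter_hits(hits, e_max = e_max, score_min = score_min)
      write_tsv(acc, "scan_accepted.tsv")
      list(n_hits = nrow(hits), n_accepted = nrow(acc),
           n_targets = length(unique(acc$target_id)),
           e_max = e_max, score_min = score_min)
    })
  } else skipped <- c(skipped, "scan")

  if (!is.null(config$props)) {
    summary$stages$props <- run_stage("props", function() {
      cf <- config$props
      check_inputs("props", cf$fasta)
      seqs <- read_fasta(cf$fasta)
      props <- protein_properties(seqs)
      write_tsv(props, "protein_properties.tsv")
      list(n_proteins = nrow(props),
           mw_range = range(props$mw_da),
           pi_range = range(props$pi))
    })
  } else skipped <- c(skipped, "props")

  if (!is.null(config$tandem)) {
    summary$stages$tandem <- run_stage("tandem", function() {
      cf <- config$tandem
      check_inputs("tandem", cf$genes)
      loci <- read_gene_table(cf$genes)
      fam <- cf$family %||% "Wnt"
      groups <- detect_tandem(loci, fam)
      write_tsv(groups, "tandem_groups.tsv")
      n_fam <- sum(loci$family == fam)
      list(family = fam,
           n_groups = length(unique(groups$group_id)),
           n_tandem_genes = nrow(groups),
           n_family_genes = n_fam,
           tandem_pct = round(100 * nrow(groups) / n_fam, 1))
    })
  } else skipped <- c(skipped, "tandem")

  if (!is.null(config$tree)) {
    summary$stages$tree <- run_stage("tree", function() {
      cf <- config$tree
      check_inputs("tree", cf$aln)
      aln <- read_alignment(cf$aln)
      model <- cf$model %||% "poisson"
      n_boot <- cf$bootstrap %||% 1000L
      tree <- if (n_boot >= 1L) {
        bootstrap_support(aln, model = model, n_reps = n_boot, seed = seed)
      } else {
        nj_tree(pairwise_distance(aln, model))
      }
      write_newick(tree, file.path(out_dir, "tree.nwk"))
      list(model = model, bootstrap = n_boot, n_taxa = length(aln),
           supports = if (n_boot >= 1L) as.numeric(tree$node.label) else NULL)
    })
  } else skipped <- c(skipped, "tree")

  if (!is.null(config$strata)) {
    summary$stages$strata <- run_stage("strata", function() {
      cf <- config$strata
      check_inputs("strata", cf$orthologs)
      presence <- read_ortholog_table(cf$orthologs)
      patterns <- classify_pattern(presence)
      write_tsv(patterns, "phylo_patterns.tsv")
      props <- stratum_proportions(patterns)
      out <- list(n_genes = nrow(patterns),
                  pct = as.list(props$pct),
                  post_vertebrate_split_pct = props$post_vertebrate_split_pct)
      if (!is.null(cf$background)) {
        cmp <- compare_to_background(as.integer(props$counts) |>
                                       stats::setNames(pattern_labels()),
                                     unlist(cf$background))
        write_tsv(cmp, "strata_vs_background.tsv")
        out$background_ratio <- stats::setNames(as.list(round(cmp$ratio, 2)),
                                                cmp$label)
      }
      out
    })
  } else skipped <- c(skipped, "strata")

  if (!is.null(config$mirrortree)) {
    summary$stages$mirrortree <- run_stage("mirrortree", function() {
      cf <- config$mirrortree
      read_dir <- function(dir) {
        files <- sort(list.files(dir, pattern = "\\.(fa|fasta|afa)$",
                                 full.names = TRUE))
        if (length(files) == 0L) stop("no alignments in ", dir)
        alns <- lapply(files, read_alignment)
        names(alns) <- sub("\\.[^.]*$", "", basename(files))
        alns
      }
      res <- family_coevolution(read_dir(cf$family_a), read_dir(cf$family_b),
                                model = cf$model %||% "poisson",
                                min_common = cf$min_common %||% 4L)
      write_tsv(cbind(member_a = rownames(res$r), as.data.frame(res$r)),
                "coevolution_r.tsv")
      list(n_pairs = res$n_pairs, n_missing = res$n_missing,
           mean_r = res$mean_r)
    })
  } else skipped <- c(skipped, "mirrortree")

  if (!is.null(config$de)) {
    summary$stages$de <- run_stage("de", function() {
      cf <- config$de
      check_inputs("de", c(cf$matrix, cf$groups))
      mat <- read_expression_tsv(cf$matrix)
      gdf <- utils::read.delim(cf$groups, stringsAsFactors = FALSE)
      groups <- stats::setNames(gdf$group, gdf$sample)
      calls <- classify_de(mat, groups, case = cf$case, control = cf$control,
                           lfc_min = cf$lfc_min %||% 1.0,
                           alpha = cf$alpha %||% 0.05,
                           mode = cf$mode %||% "welch")
      write_tsv(calls, "de_calls.tsv")
      hm <- heatmap_matrix(mat)
      write_tsv(cbind(gene_id = rownames(hm), as.data.frame(hm)),
                "heatmap_matrix.tsv")
      props <- de_proportions(calls)
      list(case = cf$case, control = cf$control,
           counts = as.list(as.integer(props$counts) |>
                              stats::setNames(names(props$proportions))),
           pct = as.list(props$pct))
    })
  } else skipped <- c(skipped, "de")

  summary$skipped_stages <- skipped
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
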