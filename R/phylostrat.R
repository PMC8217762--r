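#' The reference-species ladder for phylostratigraphy
#'
#' The four reference species, ordered from most to least related to the
#' focal mammal: zebrafish (vertebrate), sea urchin (invertebrate
#' deuterostome), nematode (lower multicellular animal), yeast (unicellular
#' eukaryote). Ortholog presence across this ladder dates a gene's
#' evolutionary origin.
#'
#' @return Character vector of length 4.
#' @export
phylostrat_species <- function() {
  c("zebrafish", "sea_urchin", "nematode", "yeast")
}

#' The five phylostratigraphic pattern labels
#'
#' `"++++"` (ortholog in all four species, i.e. as old as eukaryotes) down
#' to `"----"` (no ortholog in any, i.e. lineage-specific). ASCII `+`/`-`
#' are used throughout.
#'
#' @return Character vector of the five labels, oldest first.
#' @export
pattern_labels <- function() {
  c("++++", "+++-", "++--", "+---", "----")
}

#' Classify an ortholog presence pattern
#'
#' The stratum label is determined by the most distant species in which an
#' ortholog is present: yeast -> `"++++"`, nematode -> `"+++-"`, sea urchin
#' -> `"++--"`, zebrafish -> `"+---"`, none -> `"----"`. A presence vector
#' with a gap (e.g. present in nematode but absent in sea urchin) is not
#' representable in the five nested symbols; it is classified by the
#' deepest presence and flagged `non_nested`.
#'
#' @param flags Logical vector of length 4 in [phylostrat_species()] order,
#'   or a logical matrix (genes x 4) for the vectorised form.
#' @return For a vector: list with `label` and `non_nested`. For a matrix:
#'   data frame `gene_id`, `label`, `non_nested`.
#' @export
classify_pattern <- function(flags) {
  if (is.matrix(flags)) {
    if (ncol(flags) != 4L) stop("presence matrix must have 4 columns")
    res <- apply(flags, 1L, classify_pattern)
    return(data.frame(
      gene_id = if (is.null(rownames(flags))) as.character(seq_len(nrow(flags)))
                else rownames(flags),
      label = vapply(res, `[[`, character(1), "label"),
      non_nested = vapply(res, `[[`, logical(1), "non_nested"),
      stringsAsFactors = FALSE, row.names = NULL
    ))
  }
  flags <- as.logical(flags)
  if (length(flags) != 4L || anyNA(flags)) {
    stop("expected 4 boolean presence flags")
  }
  k <- if (any(flags)) max(which(flags)) else 0L
  label <- paste0(strrep("+", k), strrep("-", 4L - k))
  list(label = label, non_nested = k > 0L && !all(flags[seq_len(k)]))
}

#' Stratum proportions for a gene set
#'
#' Proportion of genes in each of the five pattern labels, plus the
#' "post-vertebrate-split" aggregate (`"+---"` together with `"----"`:
#' genes that emerged after the invertebrate-vertebrate separation).
#' Percentages are reported to 2 decimals; the aggregate percentage is the
#' sum of the two already-rounded per-stratum percentages, so that printed
#' per-stratum values and their printed total are consistent.
#'
#' @param labels Character vector of pattern labels (one per gene), or the
#'   data frame returned by [classify_pattern()] on a matrix.
#' @return List with `counts` (named, all five labels), `proportions`
#'   (sum to 1), `pct` (2 dp), and `post_vertebrate_split_pct`.
#' @export
stratum_proportions <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  if (length(labels) == 0L) stop("empty gene set")
  bad <- setdiff(unique(labels), pattern_labels())
  if (length(bad) > 0L) {
    stop("unknown pattern label(s): ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(labels, levels = pattern_labels()))
  prop <- as.numeric(counts) / sum(counts)
  pct <- round(100 * prop, 2)
  names(prop) <- names(pct) <- pattern_labels()
  list(counts = counts,
       proportions = prop,
       pct = pct,
       post_vertebrate_split_pct = unname(pct["+---"] + pct["----"]))
}

#' Compare family stratum proportions to a genome background
#'
#' For each stratum: the family/background proportion ratio and a two-sided
#' Fisher exact p-value from the 2x2 table (in-stratum vs not, family vs
#' genome). The ratio is the primary output; the test is supplementary
#' (stratum enrichment is usually reported descriptively).
#'
#' @param family_counts,background_counts Named integer vectors of gene
#'   counts per pattern label (missing labels count 0).
#' @return Data frame `label`, `family_prop`, `background_prop`, `ratio`,
#'   `fisher_p`.
#' @export
compare_to_background <- function(family_counts, background_counts) {
  fam <- .complete_counts(family_counts)
  bg <- .complete_counts(background_counts)
  if (sum(bg) == 0L) stop("zero genome background total")
  if (sum(fam) == 0L) stop("zero family total")
  fam_p <- fam / sum(fam)
  bg_p <- bg / sum(bg)
  p <- vapply(pattern_labels(), function(l) {
    m <- matrix(c(fam[l], sum(fam) - fam[l], bg[l], sum(bg) - bg[l]), 2L)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  data.frame(label = pattern_labels(),
             family_prop = as.numeric(fam_p),
             background_prop = as.numeric(bg_p),
             ratio = ifelse(bg_p > 0, as.numeric(fam_p / bg_p), NA_real_),
             fisher_p = as.numeric(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

.complete_counts <- function(counts) {
  stopifnot(!is.null(names(counts)))
  bad <- setdiff(names(counts), pattern_labels())
  if (length(bad) > 0L) {
    stop("unknown pattern label(s): ", paste(bad, collapse = ", "))
  }
  out <- stats::setNames(integer(5L), pattern_labels())
  out[names(counts)] <- as.integer(counts)
  if (any(out < 0L)) stop("negative counts")
  out
}

#' Correlation of two families' sizes across species
#'
#' Pearson correlation between per-species gene counts of two families
#' (e.g. do the Wnt and DIX families expand together over evolution?), with
#' the two-sided p-value from the t distribution on n - 2 df.
#'
#' @param counts_a,counts_b Numeric vectors of per-species counts, matched
#'   by position (or by name if both are named).
#' @return List with `r`, `p_value`, `n`.
#' @export
family_size_correlation <- function(counts_a, counts_b) {
  if (!is.null(names(counts_a)) && !is.null(names(counts_b))) {
    common <- intersect(names(counts_a), names(counts_b))
    counts_a <- counts_a[common]
    counts_b <- counts_b[common]
  }
  if (length(counts_a) != length(counts_b)) stop("length mismatch")
  if (length(counts_a) < 3L) stop("need >= 3 species")
  if (stats::sd(counts_a) == 0 || stats::sd(counts_b) == 0) {
    stop("constant count vector: correlation undefined")
  }
  ct <- stats::cor.test(counts_a, counts_b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(counts_a))
}
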