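#' Classify genes as up/down/unchanged between two sample groups
#'
#' A fully specified differential-expression classifier for normalised
#' log2 matrices: `log2fc = mean(case) - mean(control)`; a gene is `up`
#' when `log2fc >= lfc_min` (and, in `"welch"` mode, the Welch two-sample
#' t-test p-value is `< alpha`), `down` symmetrically, otherwise
#' `unchanged`. The default `"fc_only"` mode classifies on fold change
#' alone (also usable when a group has few samples); `"welch"` adds the
#' significance condition.
#'
#' @param mat Numeric matrix (genes x samples), normalised log2 values.
#' @param groups Named character vector mapping sample (column) names to
#'   group labels.
#' @param case,control Group labels to compare (case minus control).
#' @param lfc_min Absolute log2 fold-change threshold (default 1).
#' @param alpha Significance threshold for `"welch"` mode (default 0.05).
#' @param mode `"welch"` (fold change + Welch t) or `"fc_only"`.
#' @param genes Optional subset of gene ids to classify; unknown ids are
#'   skipped with a warning.
#' @return Data frame `gene_id`, `log2fc`, `p_value` (`NA` in `fc_only`
#'   mode), `class`.
#' @export
classify_de <- function(mat, groups, case, control, lfc_min = 1.0,
                        alpha = 0.05, mode = c("fc_only", "welch"),
                        genes = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mat), !is.null(colnames(mat)), !is.null(rownames(mat)))
  case_s <- names(groups)[groups == case]
  ctrl_s <- names(groups)[groups == control]
  case_s <- intersect(case_s, colnames(mat))
  ctrl_s <- intersect(ctrl_s, colnames(mat))
  if (length(case_s) == 0L || length(ctrl_s) == 0L) {
    stop("case/control group not present in matrix columns")
  }
  if (length(intersect(case_s, ctrl_s)) > 0L) {
    stop("case and control groups overlap")
  }
  if (mode == "welch" && (length(case_s) < 2L || length(ctrl_s) < 2L)) {
    stop("welch mode needs >= 2 samples per group (use mode = \"fc_only\")")
  }
  if (!is.null(genes)) {
    unknown <- setdiff(genes, rownames(mat))
    if (length(unknown) > 0L) {
      warning("skipping unknown gene(s): ", paste(unknown, collapse = ", "))
    }
    mat <- mat[intersect(genes, rownames(mat)), , drop = FALSE]
  }
  lfc <- rowMeans(mat[, case_s, drop = FALSE]) -
    rowMeans(mat[, ctrl_s, drop = FALSE])
  p <- if (mode == "welch") {
    vapply(rownames(mat), function(g) {
      stats::t.test(mat[g, case_s], mat[g, ctrl_s])$p.value
    }, numeric(1))
  } else rep(NA_real_, nrow(mat))
  signif_ok <- if (mode == "welch") p < alpha else TRUE
  cls <- ifelse(lfc >= lfc_min & signif_ok, "up",
                ifelse(lfc <= -lfc_min & signif_ok, "down", "unchanged"))
  data.frame(gene_id = rownames(mat),
             log2fc = unname(lfc),
             p_value = unname(p),
             class = unname(cls),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Proportions of up/down/unchanged calls
#'
#' @param calls Data frame from [classify_de()], or a character vector of
#'   classes, or a named count vector.
#' @return List with `counts`, `proportions` (sum to 1) and `pct` (2 dp)
#'   over the classes up/down/unchanged.
#' @export
de_proportions <- function(calls) {
  classes <- c("up", "down", "unchanged")
  if (is.data.frame(calls)) {
    cls <- calls$class
  } else if (!is.null(names(calls)) && is.numeric(calls)) {
    bad <- setdiff(names(calls), classes)
    if (length(bad) > 0L) stop("unknown class(es): ", paste(bad, collapse = ", "))
    counts <- stats::setNames(integer(3L), classes)
    counts[names(calls)] <- as.integer(calls)
    prop <- counts / sum(counts)
    return(list(counts = counts, proportions = prop,
                pct = round(100 * prop, 2)))
  } else {
    cls <- as.character(calls)
  }
  if (length(cls) == 0L) stop("no calls")
  bad <- setdiff(unique(cls), classes)
  if (length(bad) > 0L) stop("unknown class(es): ", paste(bad, collapse = ", "))
  counts <- table(factor(cls, levels = classes))
  prop <- as.numeric(counts) / sum(counts)
  names(prop) <- classes
  list(counts = counts, proportions = prop, pct = round(100 * prop, 2))
}

#' Row-scaled matrix for heatmap display
#'
#' Centres and scales each gene row to zero mean and unit variance
#' (constant rows are centred only), the usual transform before drawing an
#' expression heatmap.
#'
#' @param mat Numeric matrix (genes x samples).
#' @return Matrix of the same shape.
#' @export
heatmap_matrix <- function(mat) {
  s <- apply(mat, 1L, stats::sd)
  s[s == 0] <- 1
  (mat - rowMeans(mat)) / s
}
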