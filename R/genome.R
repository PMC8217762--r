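#' Assign genome-wide gene-order indices
#'
#' Ranks all annotated genes within each chromosome by start coordinate
#' (ties by end coordinate, then gene id) and adds an `order_index` column.
#' Tandem detection is defined on this index, so the input must contain
#' every annotated gene, not only family members.
#'
#' @param loci Gene table (see [read_gene_table()]).
#' @return The table sorted by chromosome and position, with `order_index`.
#' @export
assign_order_index <- function(loci) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end") %in% names(loci)))
  ord <- order(loci$chromosome, loci$start, loci$end, loci$gene_id)
  out <- loci[ord, , drop = FALSE]
  out$order_index <- stats::ave(seq_len(nrow(out)), out$chromosome,
                                FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Detect tandemly duplicated family genes
#'
#' Implements the adjacency rule for tandem duplication: family genes that
#' are consecutive in the genome-wide gene order on one chromosome, with no
#' spacer gene of any kind between them, form a tandem group. Runs of three
#' or more adjacent family genes are chained into a single group. The rule
#' is strand-agnostic and uses gene order, not a bp-distance cutoff
#' (an optional `max_gap_bp` adds a distance condition on top).
#'
#' @param loci All annotated genes with a `family` column; if `order_index`
#'   is absent it is computed with [assign_order_index()].
#' @param family Family label whose tandem groups are sought (e.g. `"Wnt"`).
#' @param max_gap_bp Optional maximum bp gap between consecutive members
#'   (off by default; the adjacency rule alone defines groups).
#' @return Data frame with one row per tandem gene: `group_id`,
#'   `chromosome`, `gene_id`, ordered by position; zero rows when the
#'   family has no tandem genes.
#' @export
detect_tandem <- function(loci, family, max_gap_bp = NULL) {
  if (!"order_index" %in% names(loci)) loci <- assign_order_index(loci)
  dup <- stats::aggregate(order_index ~ chromosome, data = loci,
                          FUN = function(x) anyDuplicated(x) > 0L)
  if (any(dup$order_index)) {
    stop("duplicate order_index on chromosome(s): ",
         paste(dup$chromosome[dup$order_index], collapse = ", "))
  }
  loci <- loci[order(loci$chromosome, loci$order_index), , drop = FALSE]
  fam <- loci[loci$family == family, , drop = FALSE]
  out <- fam[0, c("chromosome", "gene_id")]
  out$group_id <- integer(0)
  gid <- 0L
  res <- list()
  for (chr in unique(fam$chromosome)) {
    f <- fam[fam$chromosome == chr, , drop = FALSE]
    if (nrow(f) < 2L) next
    adjacent <- diff(f$order_index) == 1L
    if (!is.null(max_gap_bp)) {
      gap <- f$start[-1] - f$end[-nrow(f)] - 1L
      adjacent <- adjacent & gap <= max_gap_bp
    }
    run_id <- cumsum(c(TRUE, !adjacent))
    for (r in split(seq_len(nrow(f)), run_id)) {
      if (length(r) >= 2L) {
        gid <- gid + 1L
        res[[gid]] <- data.frame(group_id = gid, chromosome = chr,
                                 gene_id = f$gene_id[r],
                                 stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(group_id = integer(), chromosome = character(),
                      gene_id = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Per-chromosome counts and top-k concentration
#'
#' Summarises how a family is distributed over chromosomes and what fraction
#' of its genes sit on the `k` most populous chromosomes (local
#' accumulation).
#'
#' @param loci Gene table with a `family` column.
#' @param family Family label.
#' @param top_k Number of most populous chromosomes for the concentration
#'   fraction.
#' @return List with `counts` (named, decreasing), `total`, `top_k_fraction`
#'   and `top_k_pct` (percentage, 2 dp).
#' @export
chromosome_summary <- function(loci, family, top_k = 3L) {
  fam <- loci[loci$family == family, , drop = FALSE]
  if (nrow(fam) == 0L) stop("no loci for family ", family)
  counts <- sort(table(fam$chromosome), decreasing = TRUE)
  if (top_k > length(counts)) {
    stop("top_k (", top_k, ") exceeds number of chromosomes (",
         length(counts), ")")
  }
  frac <- sum(counts[seq_len(top_k)]) / sum(counts)
  list(counts = counts, total = sum(counts),
       top_k = as.integer(top_k),
       top_k_fraction = unname(frac),
       top_k_pct = round(100 * unname(frac), 2))
}
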