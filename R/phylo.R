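#' Pairwise evolutionary distances from a protein alignment
#'
#' For every pair of rows, columns in which either sequence has a gap are
#' discarded (pairwise deletion); `p` is the proportion of mismatching
#' remaining columns. `model = "p"` returns `p` itself; `model = "poisson"`
#' returns the Poisson-corrected distance `d = -ln(1 - p)` (the usual
#' correction for multiple hits in protein sequences, and the default).
#'
#' @param aln Named character vector of aligned sequences
#'   (see [as_alignment()]).
#' @param model `"poisson"` (default) or `"p"`.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
pairwise_distance <- function(aln, model = c("poisson", "p")) {
  model <- match.arg(model)
  aln <- as_alignment(aln)
  taxa <- names(aln)
  chars <- do.call(rbind, strsplit(aln, ""))
  rownames(chars) <- taxa
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable (gap-free) columns between ",
             taxa[i], " and ", taxa[j])
      }
      p <- mean(chars[i, ok] != chars[j, ok])
      dij <- if (model == "p") p else {
        if (p >= 1) {
          stop("Poisson distance undefined (p = 1) between ",
               taxa[i], " and ", taxa[j])
        }
        -log(1 - p)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: repeatedly join the pair (i, j) minimising
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j`, with ties broken by the lowest
#' (row, column) index pair for determinism. Pendant branch lengths use the
#' standard formulas; negative lengths are clamped to 0 (the number of
#' clamped branches is recorded in attribute `"n_clamped"`). The result is
#' an unrooted `phylo` object.
#'
#' @param d Symmetric distance matrix with taxon dimnames (>= 2 taxa).
#' @return An unrooted [ape] `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  taxa <- rownames(d)
  if (is.null(taxa)) taxa <- colnames(d)
  if (is.null(taxa)) stop("distance matrix must have taxon dimnames")
  n <- nrow(d)
  if (n < 2L) stop("need >= 2 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8, check.attributes = FALSE))) {
    stop("distance matrix is not symmetric")
  }
  if (any(!is.finite(d))) stop("non-finite distances")
  n_clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { n_clamped <<- n_clamped + 1L; 0 } else x
  }
  fmt <- function(x) sprintf("%.10g", x)
  # labels holds a growing Newick fragment per active node
  labels <- taxa
  D <- d
  while (length(labels) > 3L) {
    m <- length(labels)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # deterministic tie-break: smallest (i, j), i < j, column-major scan
    best <- which(Q == min(Q[upper.tri(Q)]), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    new_label <- paste0("(", labels[i], ":", fmt(li), ",",
                        labels[j], ":", fmt(lj), ")")
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    du <- du[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, du), c(du, 0))
    labels <- c(labels[-c(i, j)], new_label)
  }
  if (length(labels) == 3L) {
    a <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
    b <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
    cc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    nwk <- paste0("(", labels[1], ":", fmt(a), ",", labels[2], ":", fmt(b),
                  ",", labels[3], ":", fmt(cc), ");")
  } else {
    half <- clamp(D[1, 2]) / 2
    nwk <- paste0("(", labels[1], ":", fmt(half), ",",
                  labels[2], ":", fmt(half), ");")
  }
  tree <- ape::read.tree(text = nwk)
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the tree from the full alignment, then resamples alignment
#' columns with replacement `n_reps` times, rebuilds a tree per replicate,
#' and scores each internal edge of the original tree by the fraction of
#' replicate trees containing the same bipartition of taxa. Supports are
#' stored in `tree$node.label` (in `[0, 1]`). Replicates whose resampled
#' columns leave some pair without comparable sites (or saturated under the
#' Poisson correction) are dropped; the number actually used is recorded in
#' attribute `"n_effective"`.
#'
#' @inheritParams pairwise_distance
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed for reproducible resampling.
#' @return A `phylo` tree with node labels holding supports.
#' @export
bootstrap_support <- function(aln, model = c("poisson", "p"),
                              n_reps = 1000L, seed = NULL) {
  model <- match.arg(model)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  aln <- as_alignment(aln)
  L <- nchar(aln[[1]])
  if (L < 1L) stop("alignment length must be >= 1")
  tree <- nj_tree(pairwise_distance(aln, model))
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", n_reps)
  kept <- 0L
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    res <- resample_columns(aln, cols)
    tb <- tryCatch(nj_tree(pairwise_distance(res, model)),
                   error = function(e) NULL)
    if (!is.null(tb)) { kept <- kept + 1L; reps[[kept]] <- tb }
  }
  if (kept == 0L) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(tree, reps[seq_len(kept)], rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- counts / kept
  attr(tree, "n_effective") <- kept
  tree
}

#' Extract alignment columns
#'
#' @param aln Named character vector of aligned rows.
#' @param cols Integer column indices (repeats allowed, as in a bootstrap
#'   resample).
#' @return The column-subsetted alignment.
#' @export
resample_columns <- function(aln, cols) {
  chars <- strsplit(aln, "")
  out <- vapply(chars, function(x) paste(x[cols], collapse = ""),
                character(1))
  names(out) <- names(aln)
  out
}

#' Cluster membership proportions
#'
#' Size of each cluster as a fraction of all assigned taxa, reported both
#' raw and as a percentage rounded to 0.1.
#'
#' @param assignments Named character vector: taxon -> cluster label. Every
#'   taxon must be assigned exactly once (no `NA`s, no duplicates).
#' @return Data frame `cluster`, `n`, `proportion`, `pct` (1 dp), sorted by
#'   decreasing size.
#' @export
cluster_proportions <- function(assignments) {
  if (is.null(names(assignments)) || any(!nzchar(names(assignments)))) {
    stop("assignments must be named by taxon")
  }
  if (anyDuplicated(names(assignments))) {
    stop("taxon assigned more than once: ",
         paste(unique(names(assignments)[duplicated(names(assignments))]),
               collapse = ", "))
  }
  if (anyNA(assignments)) {
    stop("unassigned taxon: ",
         paste(names(assignments)[is.na(assignments)], collapse = ", "))
  }
  tab <- sort(table(assignments), decreasing = TRUE)
  data.frame(cluster = names(tab),
             n = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab),
             pct = round(100 * as.numeric(tab) / sum(tab), 1),
             stringsAsFactors = FALSE, row.names = NULL)
}
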