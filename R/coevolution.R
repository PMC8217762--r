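#' MirrorTree correlation between two distance matrices
#'
#' The co-evolution score of two proteins is the Pearson correlation
#' between their families' inter-species evolutionary distance matrices:
#' both matrices are restricted to their common taxa and the strict upper
#' triangles (n(n-1)/2 entries) are correlated. With fewer than
#' `min_common` shared taxa the score is meaningless and `NA` is returned
#' with a reason.
#'
#' @param d_a,d_b Symmetric distance matrices with taxon dimnames.
#' @param min_common Minimum number of shared taxa (default 4).
#' @return List with `r` (`NA` if not computable), `n_common`, and `reason`
#'   (`NA` when `r` was computed).
#' @export
mirror_correlation <- function(d_a, d_b, min_common = 4L) {
  ta <- rownames(d_a); tb <- rownames(d_b)
  if (is.null(ta) || is.null(tb)) stop("distance matrices must have dimnames")
  common <- sort(intersect(ta, tb))
  if (length(common) < min_common) {
    return(list(r = NA_real_, n_common = length(common),
                reason = sprintf("only %d common taxa (< %d)",
                                 length(common), min_common)))
  }
  a <- d_a[common, common]
  b <- d_b[common, common]
  ut <- upper.tri(a)
  x <- a[ut]; y <- b[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant distance triangle: correlation undefined")
  }
  list(r = stats::cor(x, y), n_common = length(common), reason = NA_character_)
}

#' Co-evolution matrix between two protein families
#'
#' For every (member of family A) x (member of family B) pair, computes the
#' MirrorTree correlation of their ortholog-alignment distance matrices.
#' Distances come from [pairwise_distance()] (Poisson-corrected by
#' default). A member whose alignment covers fewer than `min_common` shared
#' species for a given pair yields `NA` for that pair; the run continues
#' and `NA`s are excluded from the mean.
#'
#' @param alns_a,alns_b Named lists of alignments (one per family member;
#'   row names are species).
#' @param model Distance model passed to [pairwise_distance()].
#' @param min_common Minimum shared species per pair.
#' @return Object of class `"coevolution_result"`: list with `r` (matrix
#'   |A| x |B|), `n_common` (matrix), `n_pairs`, `n_missing`, `mean_r`.
#' @export
family_coevolution <- function(alns_a, alns_b, model = c("poisson", "p"),
                               min_common = 4L) {
  model <- match.arg(model)
  stopifnot(length(alns_a) >= 1L, length(alns_b) >= 1L,
            !is.null(names(alns_a)), !is.null(names(alns_b)))
  dist_of <- function(aln) {
    tryCatch(pairwise_distance(aln, model), error = function(e) NULL)
  }
  da <- lapply(alns_a, dist_of)
  db <- lapply(alns_b, dist_of)
  na <- length(da); nb <- length(db)
  r <- matrix(NA_real_, na, nb, dimnames = list(names(da), names(db)))
  ncom <- matrix(NA_integer_, na, nb, dimnames = dimnames(r))
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (is.null(da[[i]]) || is.null(db[[j]])) next
      mc <- mirror_correlation(da[[i]], db[[j]], min_common = min_common)
      r[i, j] <- mc$r
      ncom[i, j] <- mc$n_common
    }
  }
  out <- list(r = r, n_common = ncom,
              n_pairs = na * nb,
              n_missing = sum(is.na(r)),
              mean_r = mean(r, na.rm = TRUE))
  class(out) <- "coevolution_result"
  out
}

#' @export
print.coevolution_result <- function(x, ...) {
  cat(sprintf(
    "Co-evolution result: %d x %d members, %d pairs (%d missing)\n",
    nrow(x$r), ncol(x$r), x$n_pairs, x$n_missing))
  cat(sprintf("  mean r over non-missing pairs: %.3f\n", x$mean_r))
  invisible(x)
}
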