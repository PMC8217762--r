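# Seeded generators emulating the statistical structure each pipeline stage
# assumes: shared trees with (optionally correlated) rate profiles, genomes
# with planted tandem groups, ortholog tables with planted strata, and
# expression matrices with planted up/down genes.

.aa_states <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate a random phylogeny
#'
#' Equal-rates (Yule-style) random topology with i.i.d. exponential branch
#' lengths (default mean 0.3 substitutions/site). Tips are labelled
#' `sp01`, `sp02`, ...
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Optional integer seed; the same seed gives an identical tree.
#' @param mean_branch Mean branch length in substitutions/site.
#' @return A rooted binary `phylo` tree.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, mean_branch = 0.3) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = TRUE,
                   br = function(k) stats::rexp(k, rate = 1 / mean_branch))
  tr$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
  tr
}

#' Evolve protein sequences along a tree
#'
#' 20-state equal-rates (Jukes-Cantor-style) model: the root sequence is
#' uniform over the 20 amino acids; along each branch of length `t`,
#' substitution events occur at rate `rate` per site with each jump uniform
#' over the other 19 states, so a site ends the branch in a different state
#' with probability `(19/20) * (1 - exp(-(20/19) * rate * t))` (saturating
#' at 19/20), the new state uniform over the other 19. Gapless by
#' construction, so the output is a valid alignment.
#'
#' @param tree Rooted `phylo` tree.
#' @param length Number of sites (>= 1).
#' @param rate Global rate multiplier (>= 0).
#' @param seed Optional integer seed.
#' @param edge_rates Optional per-edge rate multipliers (length
#'   `nrow(tree$edge)`, in `tree$edge` order), multiplied with `rate`.
#' @return Named character vector: one ungapped sequence per tip.
#' @export
evolve_sequences <- function(tree, length, rate = 1, seed = NULL,
                             edge_rates = NULL) {
  if (length < 1L) stop("length must be >= 1")
  if (rate < 0) stop("negative rate")
  if (is.null(edge_rates)) edge_rates <- rep(1, nrow(tree$edge))
  if (any(edge_rates < 0)) stop("negative rate")
  stopifnot(length(edge_rates) == nrow(tree$edge))
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  n_nodes <- n_tip + tree$Nnode
  tr <- stats::reorder(tree, "cladewise")  # edges parent-before-child
  seqs <- matrix(NA_integer_, nrow = n_nodes, ncol = length)
  seqs[root, ] <- sample.int(20L, length, replace = TRUE)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    t_eff <- rate * edge_rates[e] * tr$edge.length[e]
    p_diff <- (19 / 20) * (1 - exp(-(20 / 19) * t_eff))
    s <- seqs[parent, ]
    hit <- stats::runif(length) < p_diff
    if (any(hit)) {
      # uniform over the 19 states other than the current one
      shift <- sample.int(19L, sum(hit), replace = TRUE)
      s[hit] <- ((s[hit] - 1L + shift) %% 20L) + 1L
    }
    seqs[child, ] <- s
  }
  out <- vapply(seq_len(n_tip), function(i) {
    paste(.aa_states[seqs[i, ]], collapse = "")
  }, character(1))
  names(out) <- tree$tip.label
  out
}

#' Simulate two families evolving with correlated rates on a shared tree
#'
#' Ground truth for MirrorTree-style analyses. All members of both families
#' evolve on the same tree; each member's per-branch rate multipliers are
#' log-normal, built from a branch-wise component shared across families
#' and a member-specific component mixed so that the correlation of
#' log-rates between any A-member and any B-member is `rho`. `rho = 1`
#' gives identical rate profiles (maximal mirror correlation up to
#' substitution noise); `rho = 0` gives independent profiles.
#'
#' @param tree Shared `phylo` tree.
#' @param rho Rate correlation across families, in `[0, 1]`.
#' @param n_members_a,n_members_b Members per family.
#' @param length Alignment length per member.
#' @param seed Optional integer seed.
#' @param base_rate Baseline substitution rate.
#' @param sdlog Standard deviation of the log rate multipliers (rate
#'   heterogeneity across branches/members).
#' @return List with `a` and `b`: named lists of member alignments.
#' @export
simulate_family_pair <- function(tree, rho, n_members_a, n_members_b,
                                 length, seed = NULL, base_rate = 1,
                                 sdlog = 1) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_edge <- nrow(tree$edge)
  z_shared <- stats::rnorm(n_edge)
  member <- function() {
    e <- stats::rnorm(n_edge)
    logm <- sdlog * (sqrt(rho) * z_shared + sqrt(1 - rho) * e)
    rates <- exp(logm - sdlog^2 / 2)  # mean-one multipliers
    evolve_sequences(tree, length, rate = base_rate, edge_rates = rates)
  }
  a <- lapply(seq_len(n_members_a), function(i) member())
  b <- lapply(seq_len(n_members_b), function(i) member())
  names(a) <- sprintf("A%02d", seq_len(n_members_a))
  names(b) <- sprintf("B%02d", seq_len(n_members_b))
  list(a = a, b = b)
}

#' Synthesise a genome layout with planted tandem groups
#'
#' Builds a gene table (family genes plus spacer genes) in which the
#' requested tandem groups are adjacent in gene order and every other
#' family gene is separated from family neighbours by at least one spacer,
#' so that [detect_tandem()] must recover exactly the planted groups.
#'
#' @param n_family Total family genes.
#' @param group_sizes Integer vector of planted tandem group sizes
#'   (each >= 2; their sum must not exceed `n_family`).
#' @param n_chromosomes Number of chromosomes to scatter genes over.
#' @param seed Optional integer seed.
#' @param family Family label for the planted genes.
#' @return List with `genes` (gene table including spacers, family
#'   `"other"`) and `truth` (list of planted member-id vectors).
#' @export
synth_genome <- function(n_family = 19L, group_sizes = c(2L, 2L, 2L, 2L),
                         n_chromosomes = 10L, seed = NULL, family = "Wnt") {
  if (any(group_sizes < 2L)) stop("planted group sizes must be >= 2")
  if (sum(group_sizes) > n_family) {
    stop("impossible layout: planted groups exceed the family size")
  }
  if (!is.null(seed)) set.seed(seed)
  n_single <- n_family - sum(group_sizes)
  fam_ids <- sprintf("fam%03d", seq_len(n_family))
  units <- vector("list", length(group_sizes) + n_single)
  k <- 0L
  truth <- list()
  for (g in seq_along(group_sizes)) {
    ids <- fam_ids[(k + 1L):(k + group_sizes[g])]
    units[[g]] <- ids
    truth[[g]] <- ids
    k <- k + group_sizes[g]
  }
  if (n_single > 0L) {
    for (s in seq_len(n_single)) {
      units[[length(group_sizes) + s]] <- fam_ids[k + s]
    }
  }
  units <- units[sample.int(length(units))]
  chrom_of <- sample.int(n_chromosomes, length(units), replace = TRUE)
  rows <- list()
  sp <- 0L
  for (chr in seq_len(n_chromosomes)) {
    pos <- 1L
    emit <- function(id, fam) {
      len <- sample(2000:20000, 1L)
      row <- data.frame(gene_id = id, family = fam,
                        chromosome = sprintf("chr%02d", chr),
                        start = pos, end = pos + len,
                        stringsAsFactors = FALSE)
      pos <<- pos + len + sample(1000:10000, 1L)
      row
    }
    spacer <- function(n) {
      for (i in seq_len(n)) {
        sp <<- sp + 1L
        rows[[length(rows) + 1L]] <<- emit(sprintf("spc%04d", sp), "other")
      }
    }
    here <- which(chrom_of == chr)
    spacer(sample(1:2, 1L))
    for (u in here) {
      for (id in units[[u]]) rows[[length(rows) + 1L]] <- emit(id, family)
      spacer(sample(1:3, 1L))
    }
  }
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  list(genes = genes, truth = truth)
}

#' Synthesise an ortholog presence table with planted strata
#'
#' @param stratum_counts Named integer vector of gene counts per pattern
#'   label (see [pattern_labels()]).
#' @param seed Optional seed (used only to shuffle gene order).
#' @return Logical presence matrix (genes x 4 species) whose
#'   [stratum_proportions()] equal the planted ones exactly.
#' @export
synth_orthologs <- function(stratum_counts, seed = NULL) {
  counts <- .complete_counts(stratum_counts)
  n <- sum(counts)
  if (n == 0L) stop("no genes requested")
  labels <- rep(names(counts), counts)
  if (!is.null(seed)) {
    set.seed(seed)
    labels <- labels[sample.int(n)]
  }
  flags <- t(vapply(labels, function(l) {
    k <- sum(strsplit(l, "")[[1]] == "+")
    seq_len(4L) <= k
  }, logical(4)))
  rownames(flags) <- sprintf("g%03d", seq_len(n))
  colnames(flags) <- phylostrat_species()
  flags
}

#' Synthesise an expression matrix with planted up/down genes
#'
#' Baseline log2 expression per gene drawn from N(8, 1); Gaussian noise
#' with `noise_sd` per sample; the first `n_up` genes get `+effect` added
#' to case samples, the next `n_down` genes get `-effect`.
#'
#' @param n_genes Total genes.
#' @param n_up,n_down Planted up-/down-regulated genes.
#' @param effect Planted shift in log2 units.
#' @param noise_sd Per-sample Gaussian noise SD (log2 units).
#' @param n_per_group Samples per group.
#' @param seed Optional integer seed.
#' @return List with `mat` (genes x samples), `groups` (named vector,
#'   labels `"case"`/`"control"`), `truth` (data frame gene_id, class).
#' @export
synth_expression <- function(n_genes = 19L, n_up = 3L, n_down = 7L,
                             effect = 3, noise_sd = 1, n_per_group = 5L,
                             seed = NULL) {
  if (n_up + n_down > n_genes) stop("more planted genes than n_genes")
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  samples <- c(sprintf("case%d", seq_len(n_per_group)),
               sprintf("ctrl%d", seq_len(n_per_group)))
  groups <- stats::setNames(rep(c("case", "control"), each = n_per_group),
                            samples)
  base <- stats::rnorm(n_genes, mean = 8, sd = 1)
  mat <- matrix(stats::rnorm(n_genes * length(samples), sd = noise_sd),
                nrow = n_genes, dimnames = list(genes, samples)) + base
  cls <- rep("unchanged", n_genes)
  if (n_up > 0L) cls[seq_len(n_up)] <- "up"
  if (n_down > 0L) cls[n_up + seq_len(n_down)] <- "down"
  shift <- ifelse(cls == "up", effect, ifelse(cls == "down", -effect, 0))
  mat[, groups == "case"] <- mat[, groups == "case"] + shift
  list(mat = mat, groups = groups,
       truth = data.frame(gene_id = genes, class = cls,
                          stringsAsFactors = FALSE))
}
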