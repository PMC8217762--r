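#' Filter domain hits by E-value and bit score
#'
#' Applies the family-membership thresholds to parsed `hmmsearch` rows:
#' keep hits with E-value <= `e_max` AND bit score >= `score_min`. Both
#' comparisons are inclusive. By default the full-sequence E-value is
#' filtered; set `use_domain_evalue = TRUE` to filter on the per-domain
#' independent E-value instead.
#'
#' @param hits Data frame from [read_domtbl()].
#' @param e_max Maximum E-value (default `1e-5`).
#' @param score_min Minimum full-sequence bit score (default `0`).
#' @param use_domain_evalue Filter on `domain_ievalue` instead of
#'   `full_seq_evalue`.
#' @return The accepted rows (possibly zero rows). Idempotent.
#' @export
filter_hits <- function(hits, e_max = 1e-5, score_min = 0,
                        use_domain_evalue = FALSE) {
  stopifnot(is.finite(e_max), is.finite(score_min))
  ev <- if (use_domain_evalue) hits$domain_ievalue else hits$full_seq_evalue
  hits[ev <= e_max & hits$full_seq_score >= score_min, , drop = FALSE]
}

#' Collapse isoforms to one representative protein per gene
#'
#' Redundancy removal: for each gene the longest isoform is kept; ties are
#' broken by the lexicographically smallest `protein_id`.
#'
#' @param proteins Data frame with at least `protein_id`, `gene_id`,
#'   `sequence`.
#' @return One row per distinct `gene_id`.
#' @export
deduplicate <- function(proteins) {
  stopifnot(all(c("protein_id", "gene_id", "sequence") %in% names(proteins)))
  if (any(is.na(proteins$gene_id) | !nzchar(proteins$gene_id))) {
    stop("protein(s) without gene_id: ",
         paste(proteins$protein_id[is.na(proteins$gene_id) |
                                     !nzchar(proteins$gene_id)],
               collapse = ", "))
  }
  len <- nchar(proteins$sequence)
  ord <- order(proteins$gene_id, -len, proteins$protein_id)
  sorted <- proteins[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ExPASy-style average residue masses (Da); a residue = amino acid - water.
.aa_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_mass <- 18.01524

#' Protein molecular weight (average masses)
#'
#' Sum of average residue masses plus one water (18.015 Da), as in the
#' ExPASy Compute pI/Mw convention. `X` contributes the mean of the 20
#' residue masses; any other character is an error.
#'
#' @param sequence One amino-acid string (or a character vector of them).
#' @return Molecular weight(s) in Daltons.
#' @export
molecular_weight <- function(sequence) {
  vapply(sequence, .mw_one, numeric(1), USE.NAMES = FALSE)
}

.mw_one <- function(s) {
  if (is.na(s) || !nzchar(s)) stop("empty sequence")
  aa <- strsplit(toupper(s), "")[[1]]
  bad <- setdiff(unique(aa), c(names(.aa_mass), "X"))
  if (length(bad) > 0L) {
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  }
  masses <- c(.aa_mass, X = mean(.aa_mass))
  sum(masses[aa]) + .water_mass
}

#' The Bjellqvist-style pK table used for pI
#'
#' pK values for the ionisable groups (N/C termini plus D, E, C, Y, H, K, R),
#' mirroring the ExPASy server's set. Returned as a list so an alternative
#' table can be passed to [isoelectric_point()].
#'
#' @return List with elements `nterm`, `cterm`, `positive` (named vector for
#'   H, K, R) and `negative` (named vector for D, E, C, Y).
#' @export
pk_bjellqvist <- function() {
  list(nterm = 7.5, cterm = 3.55,
       positive = c(H = 5.98, K = 10.0, R = 12.0),
       negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0))
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch net charge: one N-terminal and one C-terminal group
#' plus the ionisable side chains. `X` residues are ignored. The function is
#' strictly decreasing in pH.
#'
#' @param sequence Amino-acid string.
#' @param pH pH value(s); vectorised.
#' @param pk pK table (see [pk_bjellqvist()]).
#' @return Net charge in elementary charges (same length as `pH`).
#' @export
net_charge <- function(sequence, pH, pk = pk_bjellqvist()) {
  if (!nzchar(sequence)) stop("empty sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  counts <- table(factor(aa, levels = c(names(.aa_mass), "X")))
  pos_pk <- c(pk$nterm, pk$positive)
  pos_n <- c(1, as.numeric(counts[names(pk$positive)]))
  neg_pk <- c(pk$cterm, pk$negative)
  neg_n <- c(1, as.numeric(counts[names(pk$negative)]))
  vapply(pH, function(p) {
    sum(pos_n / (1 + 10^(p - pos_pk))) - sum(neg_n / (1 + 10^(neg_pk - p)))
  }, numeric(1))
}

#' Protein isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge crosses zero, found by
#' bisection on \[0, 14\]. Because the charge is strictly decreasing in pH and
#' every sequence carries the two terminal groups, a root always exists.
#'
#' @inheritParams net_charge
#' @param tol Bisection tolerance in pH units.
#' @return pI in pH units (vectorised over `sequence`).
#' @export
isoelectric_point <- function(sequence, tol = 1e-3, pk = pk_bjellqvist()) {
  vapply(sequence, function(s) {
    lo <- 0; hi <- 14
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (net_charge(s, mid, pk) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-protein physicochemical properties
#'
#' Convenience wrapper computing length, molecular weight and pI for every
#' record of a sequence set.
#'
#' @param seqs Data frame from [read_fasta()] (columns `id`, `sequence`).
#' @return Data frame with `id`, `length`, `mw_da`, `pi`.
#' @export
protein_properties <- function(seqs) {
  data.frame(id = seqs$id,
             length = nchar(seqs$sequence),
             mw_da = molecular_weight(seqs$sequence),
             pi = isoelectric_point(seqs$sequence),
             stringsAsFactors = FALSE)
}

#' Domain architecture string for one protein
#'
#' Orders a protein's domain hits by start coordinate and joins the domain
#' names with `-` (e.g. `"DIX-PDZ-DEP"` for a Dishevelled-like protein,
#' `"RGS-DIX"` for an Axin-like one). Overlapping hits are resolved by
#' keeping the higher bit score (greedy, score-descending).
#'
#' @param hits Data frame with `domain_name`, `start`, `end`, `bit_score`
#'   for a single protein.
#' @return The architecture string; `""` when there are no hits.
#' @export
domain_architecture <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return("")
  stopifnot(all(c("domain_name", "start", "end", "bit_score") %in% names(hits)))
  if (any(hits$start > hits$end)) stop("start > end in domain hit")
  ord <- order(-hits$bit_score, hits$start)
  kept <- hits[0, , drop = FALSE]
  for (i in ord) {
    h <- hits[i, , drop = FALSE]
    overlaps <- nrow(kept) > 0L &&
      any(h$start <= kept$end & h$end >= kept$start)
    if (!overlaps) kept <- rbind(kept, h)
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  paste(kept$domain_name, collapse = "-")
}

#' Family census across species
#'
#' Gene counts per (species, family) with arithmetic group means (e.g.
#' vertebrate vs invertebrate). Species with no genes are counted as 0 and
#' included in their group mean.
#'
#' @param counts Named integer vector: gene count per species.
#' @param groups Named character vector mapping each species in `counts` to
#'   a group label.
#' @return Data frame `species`, `count`, `group`, with the per-group means
#'   in attribute `"group_means"`.
#' @export
census <- function(counts, groups) {
  stopifnot(!is.null(names(counts)), !is.null(names(groups)))
  if (anyDuplicated(names(counts))) stop("duplicate species in counts")
  if (anyDuplicated(names(groups))) {
    stop("species assigned to two groups: ",
         paste(unique(names(groups)[duplicated(names(groups))]),
               collapse = ", "))
  }
  missing <- setdiff(names(counts), names(groups))
  if (length(missing) > 0L) {
    stop("species without group label: ", paste(missing, collapse = ", "))
  }
  if (any(counts < 0)) stop("negative counts")
  df <- data.frame(species = names(counts),
                   count = as.integer(counts),
                   group = unname(groups[names(counts)]),
                   stringsAsFactors = FALSE)
  attr(df, "group_means") <- tapply(df$count, df$group, mean)
  df
}

#' One-way ANOVA with Dunnett-adjusted comparisons against a control
#'
#' Classical one-way ANOVA (F and p from [stats::aov()]); per-comparison
#' p-values against the control group adjusted by Dunnett's method via
#' the multivariate-t distribution (multcomp).
#'
#' @param values Numeric vector of observations.
#' @param groups Factor/character of group labels, same length as `values`.
#' @param control Control group label; defaults to the first factor level.
#' @return List with `F`, `p_value`, and `dunnett` (data frame: comparison,
#'   estimate, adjusted p).
#' @export
compare_groups_anova <- function(values, groups, control = NULL) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  n_per <- table(g)
  if (any(n_per < 2L)) {
    stop("group(s) with < 2 values: ",
         paste(names(n_per)[n_per < 2L], collapse = ", "))
  }
  if (!is.null(control)) g <- stats::relevel(g, ref = control)
  dat <- data.frame(y = values, g = g)
  fit <- stats::aov(y ~ g, data = dat)
  tab <- summary(fit)[[1]]
  Fstat <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  # identical group means with zero between-group variance: F = 0, p = 1
  if (is.na(Fstat)) { Fstat <- 0; p <- 1 }
  dn <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
  dunnett <- data.frame(
    comparison = names(dn$test$coefficients),
    estimate = unname(dn$test$coefficients),
    p_adjusted = unname(as.numeric(dn$test$pvalues)),
    stringsAsFactors = FALSE
  )
  list(F = Fstat, p_value = p, dunnett = dunnett)
}

#' CDS length implied by a protein length
#'
#' An open reading frame codes one codon per residue plus the stop codon,
#' so a protein of `n_aa` residues implies a CDS of `3 * (n_aa + 1)` bp
#' (e.g. a 349-aa protein corresponds to a 1,050-bp ORF).
#'
#' @param n_aa Protein length(s) in residues.
#' @return CDS length(s) in bp, stop codon included.
#' @export
cds_length_bp <- function(n_aa) {
  stopifnot(all(n_aa >= 1))
  3L * (as.integer(n_aa) + 1L)
}
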