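#' Worked-example fixture: the mouse Wnt/DIX family tables
#'
#' The printed summary tables of the motivating mouse Wnt/DIX study,
#' re-encoded as pipeline inputs so every downstream proportion can be
#' recomputed through the package's operations:
#'
#' * `wnt_presence`, `dix_presence` — ortholog presence matrices over the
#'   four-species ladder for the 19 Wnt and 6 DIX genes. The per-pattern
#'   counts (Wnt: 10 `"+++-"`, 7 `"++--"`, 1 `"+---"`, 1 `"----"`; DIX: all
#'   six `"+++-"`) are as published; which individual gene carries which
#'   pattern is not recoverable from the text, so the gene-level assignment
#'   is synthetic (deterministic) and only the counts are meaningful.
#' * `gene_table` — a chromosome layout (with synthetic spacer genes and
#'   coordinates) realising the published tandem structure: pairs
#'   Wnt6–Wnt10a, Wnt3a–Wnt9a, Wnt9b–Wnt3, Wnt10b–Wnt11 adjacent, all other
#'   Wnt genes separated, per-chromosome count multiset
#'   \{4,4,3,2,1,1,1,1,1,1\}. Gene-to-chromosome assignment beyond the
#'   printed pairs is synthetic.
#' * `dix_clusters` — the 57 DIX proteins' tree-group assignment
#'   (Dvl 24, Axin 21, Dixin 12).
#' * `wnt_clusters` — the 118 Wnt proteins' seven tree groups; published
#'   sizes VII = 23, III = 20, I = 18, IV = 10; the remaining 47 are split
#'   16/16/15 over II/V/VI (synthetic split, unreported).
#' * `wnt_de_counts`, `dix_de_counts_tac` — up/down/unchanged counts after
#'   pressure-overload hypertrophy (TAC), for the proportion arithmetic.
#' * `wnt7a_aa`, `wnt10a_aa` — shortest/longest mouse Wnt protein lengths
#'   (349 and 417 residues).
#'
#' @return A named list of fixture objects (see Details).
#' @export
wnt_dix_fixture <- function() {
  wnt_genes <- c("Wnt1", "Wnt2", "Wnt2b", "Wnt3", "Wnt3a", "Wnt4", "Wnt5a",
                 "Wnt5b", "Wnt6", "Wnt7a", "Wnt7b", "Wnt8a", "Wnt8b",
                 "Wnt9a", "Wnt9b", "Wnt10a", "Wnt10b", "Wnt11", "Wnt16")
  dix_genes <- c("Dvl1", "Dvl2", "Dvl3", "Axin1", "Axin2", "Dixdc1")

  wnt_labels <- rep(c("+++-", "++--", "+---", "----"), c(10L, 7L, 1L, 1L))
  names(wnt_labels) <- wnt_genes
  dix_labels <- stats::setNames(rep("+++-", 6L), dix_genes)

  label_flags <- function(labels) {
    m <- t(vapply(labels, function(l) {
      seq_len(4L) <= sum(strsplit(l, "")[[1]] == "+")
    }, logical(4)))
    colnames(m) <- phylostrat_species()
    m
  }

  # chromosome layout: planted pairs adjacent, everything else spacer-separated
  layout <- list(
    chr1  = list(c("Wnt6", "Wnt10a")),
    chr6  = list("Wnt5a", "Wnt2", "Wnt5b", "Wnt16"),
    chr11 = list(c("Wnt3a", "Wnt9a"), c("Wnt9b", "Wnt3")),
    chr15 = list(c("Wnt10b", "Wnt11"), "Wnt7b"),
    chr3  = list("Wnt1"),
    chr4  = list("Wnt4"),
    chr7  = list("Wnt2b"),
    chr14 = list("Wnt7a"),
    chr18 = list("Wnt8a"),
    chr19 = list("Wnt8b")
  )
  rows <- list()
  sp <- 0L
  for (chr in names(layout)) {
    pos <- 1e5
    emit <- function(id, fam) {
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = id, family = fam, chromosome = chr,
        start = as.integer(pos), end = as.integer(pos + 1e4),
        stringsAsFactors = FALSE)
      pos <<- pos + 5e4
    }
    spacer <- function() {
      sp <<- sp + 1L
      emit(sprintf("Gm%04d", sp), "other")
    }
    spacer()
    for (unit in layout[[chr]]) {
      for (g in unit) emit(g, "Wnt")
      spacer()
    }
  }
  gene_table <- do.call(rbind, rows)
  rownames(gene_table) <- NULL

  dix_clusters <- stats::setNames(
    rep(c("Dvl", "Axin", "Dixin"), c(24L, 21L, 12L)),
    sprintf("dix%02d", 1:57))
  wnt_clusters <- stats::setNames(
    rep(c("I", "II", "III", "IV", "V", "VI", "VII"),
        c(18L, 16L, 20L, 10L, 16L, 15L, 23L)),
    sprintf("wnt%03d", 1:118))

  list(
    wnt_genes = wnt_genes,
    dix_genes = dix_genes,
    wnt_labels = wnt_labels,
    dix_labels = dix_labels,
    wnt_presence = label_flags(wnt_labels),
    dix_presence = label_flags(dix_labels),
    gene_table = gene_table,
    planted_pairs = list(c("Wnt6", "Wnt10a"), c("Wnt3a", "Wnt9a"),
                         c("Wnt9b", "Wnt3"), c("Wnt10b", "Wnt11")),
    dix_clusters = dix_clusters,
    wnt_clusters = wnt_clusters,
    wnt_de_counts = c(up = 3L, down = 7L, unchanged = 9L),
    dix_de_counts_tac = c(up = 1L, down = 3L, unchanged = 2L),
    wnt7a_aa = 349L,
    wnt10a_aa = 417L,
    genome_background_pct = c("+++-" = 36.80)
  )
}
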