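# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the pI oracle is a fine grid search (not
# bisection), the 4-taxon topology oracle is the four-point condition, and
# mass/NJ cross-checks go through seqinr/ape.

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# grid-search pI: vectorised Henderson-Hasselbalch charge over a 1e-4 pH
# grid, independent of the package's bisection
pi_grid_oracle <- function(sequence, step = 1e-4) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  cnt <- function(x) sum(aa == x)
  pos <- rbind(c(7.5, 1), c(5.98, cnt("H")), c(10.0, cnt("K")),
               c(12.0, cnt("R")))
  neg <- rbind(c(3.55, 1), c(4.05, cnt("D")), c(4.45, cnt("E")),
               c(9.0, cnt("C")), c(10.0, cnt("Y")))
  grid <- seq(0, 14, by = step)
  charge <- rep(0, length(grid))
  for (i in seq_len(nrow(pos))) {
    charge <- charge + pos[i, 2] / (1 + 10^(grid - pos[i, 1]))
  }
  for (i in seq_len(nrow(neg))) {
    charge <- charge - neg[i, 2] / (1 + 10^(neg[i, 1] - grid))
  }
  grid[which.min(abs(charge))]
}

# four-point condition: which pairing of {1,2,3,4} are neighbours in the
# unique unrooted topology fitting an additive matrix
four_point_topology <- function(d) {
  s <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  which.min(s)  # 1: (12|34), 2: (13|24), 3: (14|23)
}

# split of an unrooted 4-taxon tree as the pairing index above
four_taxon_split <- function(tree, taxa) {
  pair_dist <- ape::cophenetic.phylo(tree)[taxa, taxa]
  four_point_topology(pair_dist)
}

# tiny domtblout fixture writer: 21+ whitespace-separated columns per row
write_domtbl_fixture <- function(path, rows, comments = character(0)) {
  fmt_row <- function(r) {
    fields <- c(r$target, "-", "400", r$query_name %||% "Wnt",
                r$acc %||% "PF00110.20", "300",
                r$evalue, r$score, "0.1", "1", "1", "1.0",
                r$ievalue %||% r$evalue, r$score, "0.1",
                "10", "200", "15", "210",
                r$env_from %||% "12", r$env_to %||% "220", "0.95",
                "description here")
    paste(fields, collapse = " ")
  }
  writeLines(c(comments, vapply(rows, fmt_row, character(1))), path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
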