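hits_df <- function(ev, sc) {
  data.frame(target_id = paste0("p", seq_along(ev)),
             query_accession = "PF00110",
             full_seq_evalue = ev, full_seq_score = sc,
             domain_ievalue = ev, env_from = 1L, env_to = 10L)
}

test_that("hit filtering applies inclusive E-value and score thresholds", {
  h <- hits_df(c(1e-6, 1e-4, 1e-5, 1e-6), c(50, 50, 0, -1))
  kept <- filter_hits(h)
  # 1e-6/50 kept; 1e-4 dropped; boundary E = 1e-5, score = 0 kept; score -1 dropped
  expect_equal(kept$target_id, c("p1", "p3"))
  expect_equal(filter_hits(kept), kept)  # idempotent
  expect_equal(nrow(filter_hits(hits_df(1, -5))), 0L)
})

test_that("per-domain E-value filtering is available as a flag", {
  h <- hits_df(1e-6, 50)
  h$domain_ievalue <- 1e-3
  expect_equal(nrow(filter_hits(h)), 1L)
  expect_equal(nrow(filter_hits(h, use_domain_evalue = TRUE)), 0L)
})

test_that("redundancy removal keeps the longest isoform per gene", {
  p <- data.frame(
    protein_id = c("iso2", "iso1", "isoB", "isoA"),
    gene_id = c("g1", "g1", "g2", "g2"),
    sequence = c(strrep("A", 350), strrep("A", 400),
                 strrep("G", 100), strrep("G", 100)))
  out <- deduplicate(p)
  expect_equal(out$protein_id[out$gene_id == "g1"], "iso1")  # longer
  expect_equal(out$protein_id[out$gene_id == "g2"], "isoA")  # tie: lexicographic
  expect_equal(nrow(out), 2L)

  p$gene_id[1] <- ""
  expect_error(deduplicate(p), "iso2")
})

test_that("a multi-isoform fixture collapses to one record per gene", {
  set.seed(42)
  genes <- sprintf("gene%02d", 1:19)
  iso <- data.frame(
    protein_id = sprintf("prot%02d", 1:30),
    gene_id = c(genes, sample(genes, 11, replace = TRUE)),
    sequence = vapply(1:30, function(i) random_protein(sample(300:420, 1)),
                      character(1)))
  out <- deduplicate(iso)
  expect_equal(nrow(out), 19L)
  expect_setequal(out$gene_id, genes)
})

test_that("molecular weight matches closed-form glycine values", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 0.01 / 75)
  expect_equal(molecular_weight("GG"), 132.12, tolerance = 0.01 / 132)
  expect_error(molecular_weight(""), "empty")
  expect_error(molecular_weight("GZ"), "Z")
})

test_that("molecular weight grows with every appended residue", {
  set.seed(7)
  for (i in 1:20) {
    s <- random_protein(sample(5:200, 1))
    expect_gt(molecular_weight(paste0(s, "A")), molecular_weight(s))
  }
  # X contributes the average residue mass, between the lightest and heaviest
  expect_gt(molecular_weight("X"), molecular_weight("G"))
  expect_lt(molecular_weight("X"), molecular_weight("W"))
})

test_that("molecular weight agrees with seqinr's independent computation", {
  skip_if_not_installed("seqinr")
  set.seed(11)
  for (i in 1:25) {
    s <- random_protein(sample(20:400, 1))
    ours <- molecular_weight(s)
    ref <- seqinr::pmw(strsplit(s, "")[[1]])
    expect_equal(ours, ref, tolerance = 1 / ours)
  }
})

test_that("pI of a glycine peptide is the terminal-group midpoint", {
  # only termini ionisable: root at (7.5 + 3.55) / 2
  expect_equal(isoelectric_point("GGGG"), 5.52, tolerance = 0.05 / 5.52)
})

test_that("pI responds monotonically to basic and acidic residues", {
  expect_gt(isoelectric_point("GGGGK"), isoelectric_point("GGGG"))
  expect_lt(isoelectric_point("GGGGD"), isoelectric_point("GGGG"))
})

test_that("net charge at the returned pI is approximately zero", {
  set.seed(23)
  for (i in 1:10) {
    s <- random_protein(sample(10:300, 1))
    expect_lt(abs(net_charge(s, isoelectric_point(s))), 0.01)
  }
})

test_that("pI depends only on composition, not residue order", {
  set.seed(5)
  s <- random_protein(60)
  shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(isoelectric_point(s), isoelectric_point(shuffled),
               tolerance = 1e-6)
})

test_that("bisection pI matches the fine-grid oracle on random sequences", {
  set.seed(99)
  for (i in 1:30) {
    s <- random_protein(sample(10:300, 1))
    expect_equal(isoelectric_point(s, tol = 1e-4), pi_grid_oracle(s),
                 tolerance = 2e-3)
  }
})

test_that("domain architectures order domains N- to C-terminal", {
  dvl <- data.frame(domain_name = c("PDZ", "DIX", "DEP"),
                    start = c(250, 1, 400), end = c(330, 80, 470),
                    bit_score = c(60, 90, 70))
  expect_equal(domain_architecture(dvl), "DIX-PDZ-DEP")
  axin <- data.frame(domain_name = c("DIX", "RGS"),
                     start = c(760, 80), end = c(830, 200),
                     bit_score = c(85, 75))
  expect_equal(domain_architecture(axin), "RGS-DIX")
  expect_equal(domain_architecture(NULL), "")
})

test_that("overlapping domain hits resolve to the higher bit score", {
  ovl <- data.frame(domain_name = c("DIX", "DIX"),
                    start = c(1, 40), end = c(80, 110),
                    bit_score = c(90, 30))
  expect_equal(domain_architecture(ovl), "DIX")
})

test_that("census computes per-group means and rejects ambiguous groups", {
  counts <- c(m1 = 10L, m2 = 10L, m3 = 10L)
  groups <- c(m1 = "vert", m2 = "vert", m3 = "invert")
  cen <- census(counts, groups)
  expect_equal(unname(attr(cen, "group_means")["vert"]), 10)
  # zero-count species included in its group mean
  cen2 <- census(c(a = 4L, b = 0L), c(a = "g", b = "g"))
  expect_equal(unname(attr(cen2, "group_means")["g"]), 2)
  expect_error(census(counts, c(groups, m1 = "invert")), "two groups")
})

test_that("one-way ANOVA handles identical groups and strong effects", {
  r <- compare_groups_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r$F, 0, tolerance = 1e-10)
  expect_equal(r$p_value, 1, tolerance = 1e-10)

  set.seed(31)
  vals <- c(rnorm(20, 0), rnorm(20, 10))
  r2 <- compare_groups_anova(vals, rep(c("ctl", "trt"), each = 20),
                             control = "ctl")
  expect_lt(r2$p_value, 1e-6)
  expect_lt(r2$dunnett$p_adjusted, 1e-6)
  expect_equal(r2$dunnett$estimate, mean(vals[21:40]) - mean(vals[1:20]))
})

test_that("ANOVA F is invariant to adding a constant to all values", {
  set.seed(13)
  vals <- rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  expect_equal(compare_groups_anova(vals, g)$F,
               compare_groups_anova(vals + 100, g)$F, tolerance = 1e-9)
  expect_error(compare_groups_anova(c(1, 2, 3), c("a", "a", "b")), "< 2")
})

test_that("ORF length includes the stop codon", {
  expect_equal(cds_length_bp(349), 1050L)
  expect_equal(cds_length_bp(417), 1254L)
})
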