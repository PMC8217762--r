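test_that("pairwise distances use pairwise gap deletion", {
  aln <- c(a = "AAAA", b = "AAAA")
  expect_equal(pairwise_distance(aln, "p")["a", "b"], 0)

  aln2 <- c(a = "AAAA", b = "AATT")
  expect_equal(pairwise_distance(aln2, "p")["a", "b"], 0.5)
  expect_equal(pairwise_distance(aln2, "poisson")["a", "b"], -log(0.5),
               tolerance = 1e-12)

  aln3 <- c(a = "AA-A", b = "AAGA")  # gap column dropped for this pair
  expect_equal(pairwise_distance(aln3, "p")["a", "b"], 0)
})

test_that("distance errors: no comparable columns, saturated Poisson", {
  expect_error(pairwise_distance(c(a = "A-", b = "-A"), "p"), "comparable")
  expect_error(pairwise_distance(c(a = "AAAA", b = "TTTT"), "poisson"),
               "p = 1")
})

test_that("pairwise distances are permutation-equivariant in taxa order", {
  set.seed(17)
  tr <- simulate_tree(6, seed = 17)
  aln <- evolve_sequences(tr, 300, seed = 18)
  d1 <- pairwise_distance(aln)
  perm <- sample(names(aln))
  d2 <- pairwise_distance(aln[perm])
  expect_equal(d2[rownames(d1), colnames(d1)], d1)
})

test_that("two-taxon NJ gives a single path of the input distance", {
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- nj_tree(d)
  expect_equal(sum(tr$edge.length), 3)
  expect_equal(ape::cophenetic.phylo(tr)["a", "b"], 3)
})

test_that("three-taxon NJ solves the closed-form pendant lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  ph <- ape::cophenetic.phylo(tr)
  # a = (dAB + dAC - dBC)/2 = 1, b = 1, c = 3
  lens <- tr$edge.length[match(1:3, tr$edge[, 2])]
  names(lens) <- tr$tip.label
  expect_equal(unname(lens[c("A", "B", "C")]), c(1, 1, 3))
  expect_equal(ph[rownames(d), colnames(d)], d)
})

test_that("NJ recovers an additive four-taxon tree exactly", {
  gen <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  d <- ape::cophenetic.phylo(gen)[LETTERS[1:4], LETTERS[1:4]]
  tr <- nj_tree(d)
  # topology by the independent four-point-condition oracle
  expect_equal(four_taxon_split(tr, LETTERS[1:4]), four_point_topology(d))
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-12)
})

test_that("NJ matches ape's reference implementation on random matrices", {
  for (s in 1:20) {
    tr0 <- simulate_tree(sample(4:9, 1), seed = 300 + s)
    d <- ape::cophenetic.phylo(tr0)
    mine <- nj_tree(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(
      as.numeric(ape::dist.topo(ape::unroot(mine), ape::unroot(ref))), 0)
  }
})

test_that("NJ path lengths reproduce additive matrices to 1e-9", {
  for (s in 1:60) {
    tr0 <- simulate_tree(sample(4:10, 1), seed = 900 + s)
    d <- ape::cophenetic.phylo(tr0)
    fit <- nj_tree(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), fit)), 0)
    expect_equal(ape::cophenetic.phylo(fit)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }
})

test_that("negative NJ branch lengths are clamped to zero", {
  # non-additive matrix engineered to force a negative pendant estimate
  d <- matrix(c(0, 1, 5, 5,
                1, 0, 1, 1,
                5, 1, 0, 1,
                5, 1, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_gt(attr(tr, "n_clamped"), 0L)
})

test_that("NJ rejects asymmetric input", {
  d <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), "symmetric")
})

test_that("bootstrap supports are deterministic under a seed and bounded", {
  set.seed(41)
  tr <- simulate_tree(6, seed = 41)
  aln <- evolve_sequences(tr, 120, seed = 42)
  b1 <- bootstrap_support(aln, n_reps = 200, seed = 7)
  b2 <- bootstrap_support(aln, n_reps = 200, seed = 7)
  expect_identical(b1$node.label, b2$node.label)
  expect_true(all(b1$node.label >= 0 & b1$node.label <= 1))
  expect_error(bootstrap_support(aln, n_reps = 0), "n_reps")
})

test_that("a perfectly supported split gets bootstrap support 1", {
  # every column separates {A,B} from {C,D}
  aln <- c(A = strrep("AC", 15), B = strrep("AC", 15),
           C = strrep("TG", 15), D = strrep("TG", 15))
  # introduce within-pair signal so distances are informative but the
  # A|B vs C|D split stays unanimous
  substr(aln["A"], 1, 1) <- "G"
  substr(aln["C"], 1, 1) <- "A"
  b <- bootstrap_support(aln, model = "p", n_reps = 100, seed = 3)
  internal <- b$node.label[-1]  # drop the trivial root "split"
  expect_true(all(internal == 1))
})

test_that("cluster proportions reproduce published group percentages", {
  fx <- wnt_dix_fixture()
  cp <- cluster_proportions(fx$dix_clusters)
  expect_equal(cp$pct[cp$cluster == "Dvl"], 42.1)
  expect_equal(cp$pct[cp$cluster == "Axin"], 36.8)
  expect_equal(cp$pct[cp$cluster == "Dixin"], 21.1)

  wp <- cluster_proportions(fx$wnt_clusters)
  expect_equal(wp$pct[wp$cluster == "VII"], 19.5)
  expect_equal(sum(wp$n), 118L)

  expect_equal(cluster_proportions(c(t1 = "only"))$pct, 100)
  expect_error(cluster_proportions(c(t1 = "x", t1 = "y")), "more than once")
  expect_error(cluster_proportions(c(t1 = NA_character_)), "unassigned")
})
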