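test_that("simulated trees are seed-deterministic with the right leaf count", {
  t1 <- simulate_tree(5, seed = 42)
  t2 <- simulate_tree(5, seed = 42)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  for (n in c(2, 3, 10, 25, 50)) {
    expect_equal(length(simulate_tree(n, seed = n)$tip.label), n)
  }
  expect_error(simulate_tree(1), ">= 2")
})

test_that("zero branch lengths propagate the root sequence unchanged", {
  tr <- simulate_tree(4, seed = 1)
  tr$edge.length[] <- 0
  aln <- evolve_sequences(tr, 50, seed = 2)
  expect_equal(length(unique(aln)), 1L)
  expect_error(evolve_sequences(tr, 0), ">= 1")
  expect_error(evolve_sequences(tr, 10, rate = -1), "negative")
})

test_that("sequence evolution is seed-deterministic and gapless", {
  tr <- simulate_tree(6, seed = 3)
  a1 <- evolve_sequences(tr, 100, seed = 4)
  a2 <- evolve_sequences(tr, 100, seed = 4)
  expect_identical(a1, a2)
  expect_false(any(grepl("-", a1)))
  expect_equal(unique(nchar(a1)), 100L)
})

test_that("an infinitely long branch saturates at p-distance 19/20", {
  tr <- ape::read.tree(text = "(a:0,b:100);")
  aln <- evolve_sequences(tr, 5000, seed = 5)
  expect_equal(pairwise_distance(aln, "p")["a", "b"], 0.95,
               tolerance = 0.02 / 0.95)
})

test_that("NJ on simulated alignments recovers the generating topology", {
  # recovery is limited by identifiability: an internal edge much shorter
  # than the distance sampling noise (~1/sqrt(L)) cannot be resolved at
  # finite alignment length, and the exponential branch-length prior
  # produces such edges in a sizeable minority of trees
  ok <- 0; ok_resolvable <- 0; n_resolvable <- 0
  n_seed <- 100
  for (s in seq_len(n_seed)) {
    tr <- simulate_tree(6, seed = 100 + s)
    aln <- evolve_sequences(tr, 5000, seed = 200 + s)
    fit <- nj_tree(pairwise_distance(aln, "poisson"))
    hit <- as.numeric(ape::dist.topo(ape::unroot(tr), fit)) == 0
    ok <- ok + hit
    internal <- tr$edge[, 2] > length(tr$tip.label)
    if (min(tr$edge.length[internal]) >= 0.05) {
      n_resolvable <- n_resolvable + 1
      ok_resolvable <- ok_resolvable + hit
    }
  }
  expect_gte(ok / n_seed, 0.75)
  expect_gte(ok_resolvable / n_resolvable, 0.90)
})

test_that("family pairs honour member counts and the rho = 1 construction", {
  tr <- simulate_tree(7, seed = 31)
  fp <- simulate_family_pair(tr, 0.4, 3, 5, 40, seed = 32)
  expect_equal(length(fp$a), 3L)
  expect_equal(length(fp$b), 5L)
  expect_error(simulate_family_pair(tr, 1.2, 2, 2, 10), "rho")

  ident <- simulate_family_pair(tr, 1, 1, 1, 2000, seed = 33)
  r <- family_coevolution(ident$a, ident$b)$mean_r
  expect_gt(r, 0.95)
})

test_that("mean mirror correlation increases with planted rate correlation", {
  mean_r <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    rs <- vapply(1:15, function(s) {
      tr <- simulate_tree(8, seed = 800 + s)
      fp <- simulate_family_pair(tr, rho, 2, 2, 150,
                                 seed = 900 + s + round(1e4 * rho))
      family_coevolution(fp$a, fp$b)$mean_r
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("synthetic genomes validate layouts and reproduce bitwise", {
  expect_error(synth_genome(n_family = 3, group_sizes = c(2, 2)),
               "impossible")
  expect_error(synth_genome(group_sizes = c(1, 2)), ">= 2")
  g1 <- synth_genome(seed = 77)
  g2 <- synth_genome(seed = 77)
  expect_identical(g1, g2)
  expect_true(all(g1$genes$start <= g1$genes$end))
})

test_that("synthetic ortholog tables hit planted proportions exactly", {
  counts <- c("+++-" = 10L, "++--" = 7L, "+---" = 1L, "----" = 1L)
  m <- synth_orthologs(counts, seed = 12)
  sp <- stratum_proportions(classify_pattern(m))
  expect_equal(as.integer(sp$counts),
               c(0L, 10L, 7L, 1L, 1L))
  expect_equal(unname(sp$pct["+++-"]), 52.63)
})

test_that("synthetic expression carries the planted mean shift", {
  sim <- synth_expression(n_genes = 200, n_up = 50, n_down = 50,
                          effect = 3, noise_sd = 1, n_per_group = 20,
                          seed = 55)
  lfc <- rowMeans(sim$mat[, sim$groups == "case"]) -
    rowMeans(sim$mat[, sim$groups == "control"])
  expect_equal(mean(lfc[sim$truth$class == "up"]), 3, tolerance = 0.1)
  expect_equal(mean(lfc[sim$truth$class == "down"]), -3, tolerance = 0.1)
  expect_equal(mean(lfc[sim$truth$class == "unchanged"]), 0,
               tolerance = 0.15)
  expect_error(synth_expression(n_genes = 5, n_up = 3, n_down = 3),
               "more planted")
})
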