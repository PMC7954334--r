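test_that("newick round-trips preserve topology, names and lengths", {
  tree <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(length(tree$tip.label), 3L)
  expect_equal(sum(tree$edge.length), 5)
  expect_identical(ape::read.tree(text = write_newick(tree))$tip.label,
                   tree$tip.label)

  g <- generate_corpus(generator_config(n_genera = 6, seed = 2))
  nwk <- generate_tree(g$manifest, seed = 2)
  t2 <- read_newick(nwk)
  expect_equal(as.character(write_newick(t2)), as.character(nwk))

  expect_error(read_newick("((A:1,B:1"), class = "traitminer_parse_error")
  expect_error(read_newick("((A:1,A:1):1,C:2);"), "duplicate")
})

test_that("trait leaf sets drop absent species and exclude training leaves", {
  tree <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_setequal(trait_leaf_set(c("A", "B", "C", "D", "E"), tree,
                                 exclude = c("B", "D")) |>
                    suppressWarnings(),
                  c("A", "C"))
  expect_warning(trait_leaf_set(c("A", "Zz"), tree), "not in tree")
  expect_length(trait_leaf_set(character(), tree), 0L)
})

test_that("unweighted UniFrac matches hand-enumerated branch classes", {
  tree <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  # disjoint cherries share no branch
  expect_equal(unifrac(tree, c("A", "B"), c("C", "D")), 1)
  expect_equal(unifrac(tree, c("A", "B"), c("A", "B")), 0)
  # {A} vs {A,B}: branches A(1) shared? A:1 shared, B:1 unique, AB stem shared
  expect_equal(unifrac(tree, "A", c("A", "B")), 1 / 3)
  expect_equal(unifrac(tree, "A", "B"), 2 / 3)
  expect_error(unifrac(tree, character(), "A"), "non-empty")
  expect_error(unifrac(tree, "A", "Q"), "not tree leaves")
})

test_that("unifrac is symmetric and agrees with brute-force enumeration", {
  set.seed(9)
  for (i in 1:60) {
    n <- sample(4:20, 1)
    tree <- random_labeled_tree(n)
    a <- sample(tree$tip.label, sample(1:(n - 1), 1))
    b <- sample(tree$tip.label, sample(1:(n - 1), 1))
    d1 <- unifrac(tree, a, b)
    expect_equal(d1, oracle_unifrac(tree, a, b), tolerance = 1e-12)
    expect_equal(d1, unifrac(tree, b, a))
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})

test_that("unifrac agrees with phyloseq's unweighted implementation", {
  skip_if_not_installed("phyloseq")
  set.seed(31)
  for (i in 1:3) {
    n <- 12
    tree <- random_labeled_tree(n)
    a <- sample(tree$tip.label, 5)
    b <- sample(tree$tip.label, 6)
    otu <- matrix(0L, nrow = n, ncol = 2,
                  dimnames = list(tree$tip.label, c("A", "B")))
    otu[a, 1] <- 1L; otu[b, 2] <- 1L
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(otu, taxa_are_rows = TRUE), ape::as.phylo(tree))
    ref <- as.numeric(phyloseq::UniFrac(ps, weighted = FALSE))
    expect_equal(unifrac(tree, a, b), ref, tolerance = 1e-10)
  }
})

test_that("zero distance exactly when both sets span the same branches", {
  tree <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  # same span, different sets: impossible here without identical sets of
  # cherries; but A,B vs A,B trivially 0 and supersets are not
  expect_equal(unifrac(tree, c("A", "B"), c("A", "B")), 0)
  expect_gt(unifrac(tree, c("A", "B"), c("A", "B", "C")), 0)
})

test_that("the random-subset null is seeded and respects exclusions", {
  set.seed(77)
  tree <- random_labeled_tree(30)
  obs <- sample(tree$tip.label, 10)
  n1 <- random_null(tree, obs, k = 8, n_draws = 20, seed = 5)
  n2 <- random_null(tree, obs, k = 8, n_draws = 20, seed = 5)
  expect_identical(n1, n2)
  expect_length(n1, 20L)
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_error(random_null(tree, obs, k = 31, n_draws = 5), "exceeds")
  # k equal to the eligible count: every draw is the same subset
  n3 <- random_null(tree, obs, k = 30, n_draws = 5, seed = 1)
  expect_equal(stats::sd(n3), 0)
})

test_that("replicate comparison uses Welch's t-test with constant-group rule", {
  same <- compare_replicates(rep(0.5, 5), rep(0.5, 5))
  expect_equal(same$p_value, 1)
  far <- compare_replicates(c(0.1, 0.11, 0.09, 0.1, 0.105),
                            c(0.9, 0.91, 0.89, 0.9, 0.895))
  expect_lt(far$p_value, 0.001)
  # t statistic equals the closed form on 2+2 values
  out <- compare_replicates(c(0.2, 0.4), c(0.7, 0.9))
  s <- sqrt(0.02 / 2 + 0.02 / 2)
  expect_equal(out$statistic, (0.3 - 0.8) / s, tolerance = 1e-12)
})

test_that("clumped traits sit far below the random null", {
  g <- generate_corpus(generator_config(n_genera = 40, seed = 17))
  nwk <- generate_tree(g$manifest, clade_signal = 1, seed = 17)
  tree <- read_newick(nwk)
  obs <- leaf_name(g$manifest$species_name[g$manifest$trait1_label ==
                                             "positive"])
  # a perfectly clumped trait: observed vs itself is 0; random subsets of
  # the same size land far away
  null_d <- random_null(tree, obs, k = length(obs), n_draws = 50, seed = 3)
  expect_gt(mean(null_d), 0.3)
})
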