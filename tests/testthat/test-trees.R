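test_that("pairwise distances use pairwise deletion and the JC correction", {
  geno <- matrix(0L, 100, 4)
  geno[1:3, 2] <- 1L
  gm <- make_gm(geno, samples = c("a_1", "b_1"), ploidy = c(2L, 2L))
  d <- pairwise_distances(gm)
  expect_equal(d[1, 1], 0)          # self
  expect_equal(d[1, 3], 0)          # identical haplotypes
  expect_equal(d[1, 2], 0.03)       # 3 mismatches over 100 co-called sites
  expect_true(isSymmetric(unname(d)))

  # JC transform of p = 0.03 evaluated from the formula directly
  dj <- pairwise_distances(gm, model = "jc")
  expect_equal(round(dj[1, 2], 4), round(-0.75 * log(1 - 4 * 0.03 / 3), 4))
  expect_equal(round(dj[1, 2], 4), 0.0306)
})

test_that("a zero co-called pair is an error naming the pair", {
  geno <- rbind(c(0L, NA, 1L, 0L), c(0L, NA, 1L, 0L))
  gm <- make_gm(geno, samples = c("a_1", "b_1"))
  expect_error(pairwise_distances(gm), "a_1_2.*zero co-called")
})

test_that("neighbor joining recovers topologies from additive distances", {
  skip_if_not_installed("phangorn")
  # fixed 8-leaf tree, then seeded random trees up to 12 leaves
  set.seed(202)
  for (n in c(8, sample(4:12, 10, replace = TRUE))) {
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    tr <- ape::unroot(tr)
    dm <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(dm)
    expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(rec), tr)), 0)
  }
})

test_that("4-leaf NJ agrees with brute-force least-squares over 3 topologies", {
  set.seed(17)
  for (rep in 1:25) {
    tr <- ape::unroot(ape::rtree(4, br = function(k) runif(k, 0.05, 1)))
    tr$tip.label <- sample(c("P1", "P2", "P3", "O"))
    dm <- ape::cophenetic.phylo(tr)[c("P1", "P2", "P3", "O"),
                                    c("P1", "P2", "P3", "O")]
    ls_top <- oracle_ls_quartet(dm)
    rec <- nj_tree(dm)
    nj_top <- quartet_topology(rec, c(P1 = "P1", P2 = "P2", P3 = "P3",
                                      O = "O"))
    expect_equal(as.integer(nj_top), ls_top)
  }
})

test_that("identical haplotypes become siblings with zero-length tips", {
  geno <- cbind(rep(0:1, 10), rep(0:1, 10), rbinom(20, 1, 0.5),
                rbinom(20, 1, 0.5))
  gm <- make_gm(geno, samples = c("a_1", "b_1"))
  tr <- nj_tree(pairwise_distances(gm))
  # a_1_1 and a_1_2 are identical: zero distance on the tree
  dmat <- ape::cophenetic.phylo(tr)
  expect_equal(dmat["a_1_1", "a_1_2"], 0)
})

test_that("quartet topologies read off correctly, star is unresolved", {
  tr <- ape::read.tree(text = "(((p1:1,p2:1):1,p3:2):1,o:3);")
  expect_equal(as.integer(quartet_topology(tr, c(P1 = "p1", P2 = "p2",
                                                 P3 = "p3", O = "o"))), 1)
  tr2 <- ape::read.tree(text = "(((p2:1,p3:1):1,p1:2):1,o:3);")
  expect_equal(as.integer(quartet_topology(tr2, c(P1 = "p1", P2 = "p2",
                                                  P3 = "p3", O = "o"))), 2)
  star <- ape::read.tree(text = "(((p1:1,p2:1):0,p3:1):1,o:1);")
  expect_true(is.na(quartet_topology(star, c(P1 = "p1", P2 = "p2",
                                             P3 = "p3", O = "o"))))
})

test_that("exact weights are 1 for the species topology on a sorted tree", {
  w <- topology_weights(sorted_tree(), sorted_groups, method = "exact")
  expect_equal(unname(w$w), c(1, 0, 0))
  expect_equal(w$n_combinations, 16)
  expect_equal(w$n_unresolved, 0)
})

test_that("exact weights match brute-force enumeration on a nested tree", {
  tr <- one_nested_tree()
  w <- topology_weights(tr, sorted_groups, method = "exact")
  o <- oracle_weights(tr, sorted_groups)
  expect_equal(unname(w$w), o$w)
  expect_equal(w$n_combinations, o$n)
  expect_equal(sum(w$w), 1)
  expect_true(w$w["introgression"] > 0)  # the nested haplotype contributes
})

test_that("weights are invariant to leaf rotations and within-group relabeling", {
  tr <- one_nested_tree()
  w <- topology_weights(tr, sorted_groups, method = "exact")
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  w2 <- topology_weights(rot, sorted_groups, method = "exact")
  expect_equal(w$w, w2$w)
  # swap the labels of the two P2 haplotypes
  tr3 <- tr
  tr3$tip.label[tr3$tip.label == "p2a"] <- "tmp"
  tr3$tip.label[tr3$tip.label == "p2b"] <- "p2a"
  tr3$tip.label[tr3$tip.label == "tmp"] <- "p2b"
  w3 <- topology_weights(tr3, sorted_groups, method = "exact")
  expect_equal(w$w, w3$w)
})

test_that("Monte-Carlo weights agree with exact within 3 SE and converge", {
  tr <- one_nested_tree()
  exact <- topology_weights(tr, sorted_groups, method = "exact")$w
  mc <- topology_weights(tr, sorted_groups, method = "monte_carlo",
                         draws = 10000, seed = 99)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_true(all(abs(mc$w - exact) <= 3 * se + 1e-12))

  # deviation shrinks roughly as n^(-1/2): compare 100 vs 10000 draws
  dev_small <- mean(vapply(1:20, function(s) {
    max(abs(topology_weights(tr, sorted_groups, "monte_carlo", 100,
                             seed = s)$w - exact))
  }, numeric(1)))
  dev_big <- mean(vapply(1:20, function(s) {
    max(abs(topology_weights(tr, sorted_groups, "monte_carlo", 10000,
                             seed = s)$w - exact))
  }, numeric(1)))
  expect_lt(dev_big, dev_small / 3)  # expected factor 10, generous margin
})

test_that("unresolved combinations are excluded from the weight denominator", {
  star <- ape::read.tree(
    text = "(((p1a:1,p2a:1):0,p3a:1):1,(oa:1,ob:1):1);")
  gr <- list(P1 = "p1a", P2 = "p2a", P3 = "p3a", O = c("oa", "ob"))
  w <- topology_weights(star, gr, method = "exact")
  expect_equal(w$n_unresolved, 2)
  expect_true(all(is.na(w$w)))
})

test_that("monophyly fraction counts clades and matches a planted rate", {
  good <- sorted_tree()
  bad <- one_nested_tree()
  expect_equal(monophyly_fraction(list(good, good), c("p1a", "p1b", "p2a",
                                                      "p2b")), 1)
  expect_equal(monophyly_fraction(list(good, good, bad, bad),
                                  c("p1a", "p1b", "p2a", "p2b")), 0.5)

  # planted discordance rate q over a seeded tree set
  set.seed(301)
  q <- 0.3
  n <- 400
  disc <- runif(n) < q
  trees <- lapply(disc, function(d) if (d) one_nested_tree() else
    sorted_tree())
  frac <- monophyly_fraction(trees, c("p1a", "p1b", "p2a", "p2b"))
  se <- sqrt(q * (1 - q) / n)
  expect_lt(abs(frac - (1 - mean(disc))), 1e-12)
  expect_lt(abs(frac - (1 - q)), 3 * se)
})

test_that("majority topology summarizes window weights", {
  st <- data.frame(w_species = c(1, 0.9, 0.2), w_introgression = c(0, 0.1, 0.8),
                   w_control = c(0, 0, 0))
  m <- majority_species_topology(st)
  expect_equal(m$topology, "species")
  expect_equal(unname(m$fractions), c(2 / 3, 1 / 3, 0))

  st2 <- data.frame(w_species = c(1, 1), w_introgression = c(0, 0),
                    w_control = c(0, 0))
  expect_equal(unname(majority_species_topology(st2)$fractions), c(1, 0, 0))

  # ties and undefined weights count as unresolved
  st3 <- data.frame(w_species = c(0.5, NA), w_introgression = c(0.5, NA),
                    w_control = c(0, NA))
  expect_error(majority_species_topology(st3), "no window")
})

test_that("trees round-trip through Newick files", {
  trees <- list(sorted_tree(), one_nested_tree())
  path <- tempfile(fileext = ".nwk")
  write_trees_newick(trees, path)
  back <- read_trees_newick(path)
  expect_equal(length(back), 2)
  expect_setequal(back[[1]]$tip.label, trees[[1]]$tip.label)
})
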