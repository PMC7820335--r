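test_that("d_XY matches direct proportion counting on constructed data", {
  # two single-haplotype groups differing at 3 of 100 sites -> 0.03
  g <- matrix(0L, 100, 4)
  g[1:3, 2] <- 1L
  gm <- make_gm(g, samples = c("p1_1", "p2_1", "p3_1", "o_1"),
                ploidy = rep(1L, 4))
  pm <- make_pm(gm)
  expect_equal(as.numeric(dxy(gm, pm, "P1", "P2")), 0.03)
  # identical single haplotypes -> 0
  expect_equal(as.numeric(dxy(gm, pm, "P1", "P3")), 0)
})

test_that("d_XY and pi equal brute-force pair counting on random matrices", {
  for (seed in 1:20) {
    gm <- random_role_gm(seed, n_sites = sample(10:50, 1),
                         n_per = sample(1:3, 1), miss_rate = 0.15)
    pm <- make_pm(gm)
    a <- group_columns(gm, pm, "P1")
    b <- group_columns(gm, pm, "P2")
    expect_equal(as.numeric(dxy(gm, pm, "P1", "P2")),
                 oracle_dxy(gm$geno, a, b), tolerance = 1e-12)
    expect_equal(as.numeric(nuc_div(gm, pm, "P2")),
                 oracle_pi(gm$geno, b), tolerance = 1e-12)
  }
})

test_that("d_XY is symmetric and non-negative; identical groups give zero", {
  gm <- random_role_gm(99, n_sites = 40, n_per = 2, miss_rate = 0.2)
  pm <- make_pm(gm)
  d12 <- as.numeric(dxy(gm, pm, "P1", "P2"))
  d21 <- as.numeric(dxy(gm, pm, "P2", "P1"))
  expect_identical(d12, d21)
  expect_gte(d12, 0)
})

test_that("pi closed forms: monomorphic zero, one differing pair gives one", {
  gm <- make_gm(matrix(0L, 10, 4), samples = c("p2_1", "p2_2"))
  pm0 <- population_map(c(p2_1 = "p2", p2_2 = "p2", x = "a", y = "b",
                          z = "c"),
                        roles = list(P1 = "a", P2 = "p2", P3 = "b", O = "c"))
  expect_equal(as.numeric(nuc_div(gm, list(assignment = c(p2_1 = "p2",
                                                          p2_2 = "p2"),
                                           roles = pm0$roles), "p2")), 0)
  # two called haplotypes differing at the single usable site: 2*0.25*2 = 1
  gm1 <- make_gm(matrix(c(0L, 1L, NA, NA), 1, 4),
                 samples = c("p2_1", "p2_2"))
  expect_equal(as.numeric(nuc_div(gm1, list(assignment = c(p2_1 = "p2",
                                                           p2_2 = "p2"),
                                            roles = pm0$roles), "p2")), 1)
})

test_that("site_frequencies polarizes on the outgroup and handles pools", {
  # outgroup fixed for allele 0 -> derived is allele 1
  geno <- rbind(c(0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L),
                c(NA, NA, 0L, 1L, 1L, 1L, 0L, 0L))
  gm <- make_gm(geno, samples = c("p1_1", "p2_1", "p3_1", "o_1"))
  sf <- site_frequencies(gm, make_pm(gm))
  expect_equal(sf$p[1, ], c(P1 = 0, P2 = 1, P3 = 1, O = 0))
  expect_true(is.na(sf$p[2, "P1"]))  # group fully missing -> flagged
  expect_equal(unname(sf$p[2, "P2"]), 0.5)

  # ploidy-10 pool with 7 ref / 3 derived alleles -> p = 0.3
  gp <- matrix(c(rep(0L, 7), rep(1L, 3), 0L, 0L, 1L, 1L, 0L, 0L), 1)
  gmp <- make_gm(gp, samples = c("p2_1", "p1_1", "p3_1", "o_1"),
                 ploidy = c(10L, 2L, 2L, 2L))
  sfp <- site_frequencies(gmp, make_pm(gmp))
  expect_equal(unname(sfp$p[1, "P2"]), 0.3)
})

test_that("ABBA/BABA sums match per-site re-evaluation", {
  tab <- data.frame(p1 = 0, p2 = 1, p3 = 1, pO = 0)
  s <- abba_baba_sums(tab)
  expect_equal(c(s$abba, s$baba, s$denom), c(1, 0, 1))
  s2 <- abba_baba_sums(data.frame(p1 = 1, p2 = 0, p3 = 1, pO = 0))
  expect_equal(c(s2$abba, s2$baba), c(0, 1))

  set.seed(5)
  tab <- data.frame(p1 = runif(40), p2 = runif(40), p3 = runif(40),
                    pO = runif(40))
  tab[sample(40, 5), "p3"] <- NA  # skipped sites
  s3 <- abba_baba_sums(tab)
  o <- oracle_abba_baba(tab$p1, tab$p2, tab$p3, tab$pO)
  expect_equal(s3$abba, o$abba, tolerance = 1e-12)
  expect_equal(s3$baba, o$baba, tolerance = 1e-12)
  expect_equal(s3$denom, o$denom, tolerance = 1e-12)
})

test_that("f_d limits: complete replacement, negative D, no information", {
  # P2 identical to P3, P1 identical to O, many informative sites -> fd = 1
  n <- 30
  geno <- cbind(matrix(0L, n, 2), matrix(1L, n, 2), matrix(1L, n, 2),
                matrix(0L, n, 2))
  gm <- make_gm(geno, samples = c("p1_1", "p2_1", "p3_1", "o_1"))
  r <- fd_window(gm, make_pm(gm))
  expect_equal(r$fd, 1)
  expect_equal(r$D, 1)

  # pure BABA pattern -> D = -1 -> fd reported as 0, raw D retained
  geno2 <- cbind(matrix(1L, n, 2), matrix(0L, n, 2), matrix(1L, n, 2),
                 matrix(0L, n, 2))
  gm2 <- make_gm(geno2, samples = c("p1_1", "p2_1", "p3_1", "o_1"))
  r2 <- fd_window(gm2, make_pm(gm2))
  expect_equal(r2$fd, 0)
  expect_equal(r2$D, -1)

  # monomorphic window -> undefined with a reason
  gm3 <- make_gm(matrix(0L, 10, 8),
                 samples = c("p1_1", "p2_1", "p3_1", "o_1"))
  r3 <- fd_window(gm3, make_pm(gm3))
  expect_true(is.na(r3$fd))
  expect_match(r3$reason, "no informative sites")
})

test_that("f_d never decreases as more P2 haplotypes are replaced by donor", {
  set.seed(31)
  n <- 200
  base <- cbind(matrix(0L, n, 4), matrix(0L, n, 4), matrix(1L, n, 4),
                matrix(0L, n, 4))
  samples <- c("p1_1", "p1_2", "p2_1", "p2_2", "p3_1", "p3_2", "o_1", "o_2")
  prev <- -1
  for (k in 1:4) {
    geno <- base
    geno[, 4 + seq_len(k)] <- 1L  # replace k P2 haplotypes
    gm <- make_gm(geno, samples = samples)
    fd_k <- fd_window(gm, make_pm(gm))$fd
    expect_gte(fd_k, prev)
    prev <- fd_k
  }
  expect_equal(prev, 1)  # full replacement reaches the limit
})

test_that("scan_genome equals single-window statistics window by window", {
  gm <- random_role_gm(77, n_sites = 120, n_per = 2, miss_rate = 0.1)
  gm$sites$pos <- as.integer(sort(sample(1:1000, 120)))
  pm <- make_pm(gm)
  w <- make_windows(c(chr1 = 1000), 250)
  sc <- scan_genome(gm, pm, w, stats = c("dxy", "pi", "fd"),
                    dxy_pairs = list(c("P1", "P2")), pi_roles = "P2")
  for (i in seq_len(nrow(w))) {
    sl <- window_slice(gm, w[i, ])
    expect_equal(sc$dxy_P1_P2[i], as.numeric(dxy(sl, pm, "P1", "P2")),
                 tolerance = 1e-12)
    expect_equal(sc$pi_P2[i], as.numeric(nuc_div(sl, pm, "P2")),
                 tolerance = 1e-12)
    fdw <- fd_window(sl, pm)
    expect_equal(sc$fd[i], fdw$fd, tolerance = 1e-12)
  }
})

test_that("empty windows yield records with undefined statistics", {
  gm <- make_gm(matrix(rbinom(40, 1, 0.5), 5, 8),
                samples = c("p1_1", "p2_1", "p3_1", "o_1"),
                pos = c(1L, 2L, 3L, 201L, 202L))
  w <- make_windows(c(chr1 = 300), 100)
  sc <- scan_genome(gm, make_pm(gm), w, stats = "dxy",
                    dxy_pairs = list(c("P1", "P2")))
  expect_equal(nrow(sc), 3)
  expect_equal(sc$n_sites, c(3, 0, 2))
  expect_true(is.na(sc$dxy_P1_P2[2]))
})

test_that("scan summaries reproduce sort-based order statistics", {
  gm <- random_role_gm(13, n_sites = 400, n_per = 2, miss_rate = 0)
  gm$sites$pos <- seq_len(400)
  w <- make_windows(c(chr1 = 400), 20)
  sc <- scan_genome(gm, make_pm(gm), w, stats = "dxy",
                    dxy_pairs = list(c("P1", "P3")))
  s <- scan_summary(sc, "dxy_P1_P3")
  x <- sc$dxy_P1_P3
  expect_equal(s$q1, oracle_quartile(x, 0.25))
  expect_equal(s$median, oracle_quartile(x, 0.5))
  expect_equal(s$q3, oracle_quartile(x, 0.75))
  expect_equal(s$n, 20)
})

test_that("statistics are invariant to sample order permutation", {
  gm <- random_role_gm(55, n_sites = 60, n_per = 2, miss_rate = 0.1)
  pm <- make_pm(gm)
  set.seed(1)
  perm <- sample(length(gm$samples))
  col0 <- c(0L, cumsum(gm$ploidy))
  cols <- unlist(lapply(perm, function(j) (col0[j] + 1L):col0[j + 1L]))
  gm2 <- make_gm(gm$geno[, cols], samples = gm$samples[perm],
                 ploidy = unname(gm$ploidy[perm]), pos = gm$sites$pos)
  pm2 <- make_pm(gm2)
  expect_equal(as.numeric(dxy(gm, pm, "P1", "P2")),
               as.numeric(dxy(gm2, pm2, "P1", "P2")))
  expect_equal(fd_window(gm, pm)$fd, fd_window(gm2, pm2)$fd)
  expect_equal(as.numeric(nuc_div(gm, pm, "P3")),
               as.numeric(nuc_div(gm2, pm2, "P3")))
})
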