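test_that("founder fixed differences follow the configured Poisson density", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(chr1 = 1e7),
                    wp_locus = data.frame(chrom = "chr1", pos = 5e6))
  fo <- simulate_founders(cfg)
  n_fixed <- sum(fo$sites$category == "fixed")
  expected <- 1e7 * 0.005
  expect_lt(abs(n_fixed - expected), 4 * sqrt(expected))
  # fixed differences actually separate the lineages
  rec <- which(fo$hap_pop == "recipient")
  don <- which(fo$hap_pop == "donor")
  rows <- which(fo$sites$category == "fixed")[1:50]
  expect_true(all(fo$geno[rows, rec] != fo$geno[rows, don][, 1]))
})

test_that("zero densities leave recipient and donor identical except wp", {
  cfg <- small_sim_config(seed = 3, fixed_diff_density = 0,
                          polymorphism_density = 0,
                          shared_polymorphism_density = 0)
  fo <- simulate_founders(cfg)
  expect_equal(unique(fo$sites$category), "wp_null")
  wp_row <- which(fo$sites$category == "wp_null")
  rec <- which(fo$hap_pop == "recipient")
  don <- which(fo$hap_pop == "donor")
  expect_true(all(fo$geno[wp_row, don] == 1L))
  expect_true(all(fo$geno[wp_row, rec] == 0L))
  other <- setdiff(seq_len(nrow(fo$sites)), wp_row)
  expect_true(all(fo$geno[other, rec] == fo$geno[other, don][, 1]))
})

test_that("the same seed reproduces the site table and emitted files", {
  cfg <- small_sim_config(seed = 77)
  a <- simulate_founders(cfg)
  b <- simulate_founders(cfg)
  expect_identical(a$sites, b$sites)
  expect_identical(a$geno, b$geno)

  d1 <- simulate_introgression_dataset(small_sim_config(seed = 78))
  d2 <- simulate_introgression_dataset(small_sim_config(seed = 78))
  expect_identical(d1$gm$geno, d2$gm$geno)
  p1 <- emit_observations(d1, file.path(tempdir(), "sim_a"))
  p2 <- emit_observations(d2, file.path(tempdir(), "sim_b"))
  expect_identical(unname(tools::md5sum(p1["vcf"])),
                   unname(tools::md5sum(p2["vcf"])))
  expect_identical(readLines(p1["truth_bed"]), readLines(p2["truth_bed"]))
})

test_that("meiosis respects the crossover model", {
  cfg <- sim_config(seed = 2, chrom_lengths = c(chr1 = 1e7),
                    wp_locus = data.frame(chrom = "chr1", pos = 5e6))
  fo <- simulate_founders(cfg, sites = FALSE)
  het <- list(h1 = list(chr1 = list(starts = 0, ids = 1L)),
              h2 = list(chr1 = list(starts = 0, ids = 3L)))
  hom <- list(h1 = list(chr1 = list(starts = 0, ids = 1L)),
              h2 = list(chr1 = list(starts = 0, ids = 1L)))

  # crossover rate 0: the gamete is one parental haplotype, fair coin
  cfg0 <- sim_config(seed = 2, chrom_lengths = c(chr1 = 1e7),
                     wp_locus = data.frame(chrom = "chr1", pos = 5e6),
                     crossover_rate = 0)
  set.seed(1)
  picks <- vapply(1:200, function(i) meiosis(het, cfg0)$chr1$ids[1],
                  integer(1))
  expect_setequal(unique(picks), c(1L, 3L))
  expect_lt(abs(mean(picks == 1L) - 0.5), 3 * sqrt(0.25 / 200))

  # homozygous parent: gamete identical regardless of crossovers
  set.seed(2)
  g <- meiosis(hom, cfg)
  expect_equal(unique(g$chr1$ids), 1L)

  # realized crossover count matches Poisson(1.5) in expectation
  set.seed(3)
  n_seg <- vapply(1:10000, function(i) length(meiosis(het, cfg)$chr1$ids),
                  integer(1))
  # the parents are distinct single-founder haplotypes, so every crossover
  # is a visible segment boundary: segments - 1 ~ Poisson(1.5)
  xo <- n_seg - 1
  expect_lt(abs(mean(xo) - 1.5), 3 * sd(xo) / sqrt(10000))
})

test_that("tract bookkeeping conserves chromosome length", {
  cfg <- small_sim_config(seed = 10)
  fo <- simulate_founders(cfg, sites = FALSE)
  line <- breed_introgression_line(cfg, fo)
  tr <- line$truth$tracts
  for (ind in unique(tr$individual)) for (h in c("h1", "h2")) {
    for (ch in names(cfg$chrom_lengths)) {
      runs <- tr[tr$individual == ind & tr$hap == h & tr$chrom == ch, ]
      expect_equal(sum(runs$end - runs$start),
                   unname(cfg$chrom_lengths[[ch]]))
      expect_true(all(runs$start[-1] == runs$end[-nrow(runs)]))
      # alternating ancestries after compaction
      if (nrow(runs) > 1) {
        expect_true(all(runs$ancestry[-1] != runs$ancestry[-nrow(runs)]))
      }
    }
  }
})

test_that("zero recombination makes the whole wp chromosome donor", {
  cfg <- small_sim_config(seed = 21, crossover_rate = 0)
  fo <- simulate_founders(cfg, sites = FALSE)
  line <- breed_introgression_line(cfg, fo)
  tr <- line$truth$tracts
  wp_tr <- tr[tr$chrom == "chr1", ]
  expect_true(all(wp_tr$ancestry == "donor"))
  # without recombination every haplotype is a single unbroken tract
  other <- tr[tr$chrom == "chr2", ]
  expect_equal(nrow(other), 2 * length(line$individuals))
})

test_that("every final individual is homozygous donor at the wp locus", {
  for (seed in c(4, 9)) {
    cfg <- small_sim_config(seed = seed)
    line <- breed_introgression_line(cfg,
                                     simulate_founders(cfg, sites = FALSE))
    per_ind <- line$truth$wp_tract_individual
    expect_equal(nrow(per_ind), length(line$individuals))
    expect_true(all(per_ind$start < cfg$wp_locus$pos[1] - 0.5))
    expect_true(all(per_ind$end > cfg$wp_locus$pos[1] - 0.5))
  }
})

test_that("donor genome fraction outside the selected chromosome halves per cross", {
  # 60 light replicates: mean within 3 SE of 2^-n_backcross
  fr <- vapply(1:60, function(i) {
    cfg <- small_sim_config(seed = 4000 + i, n_backcross = 4L)
    donor_fraction_outside(
      breed_introgression_line(cfg, simulate_founders(cfg, sites = FALSE)))
  }, numeric(1))
  expect_lt(abs(mean(fr) - 2^-4), 3 * sd(fr) / sqrt(length(fr)))
})

test_that("emitted pools carry their members' haplotypes and depth model", {
  cfg <- small_sim_config(seed = 31)
  ds <- simulate_introgression_dataset(cfg)
  gm <- ds$gm
  expect_equal(unname(gm$ploidy["line_pool1"]), 10L)
  pool_cols <- group_columns(gm, ds$pm, "introgressed")
  expect_equal(length(pool_cols), 2 * 2 + 10)

  # DP lower tail matches Poisson(30)
  p_low <- mean(gm$depth < 5)
  expect_lt(p_low, ppois(4, 30) + 3 * sqrt(ppois(4, 30) / length(gm$depth)) +
              1e-6)

  # VCF round trip reproduces the emitted matrix exactly
  paths <- emit_observations(ds, file.path(tempdir(), "sim_rt"))
  back <- read_vcf(paths["vcf"])
  expect_identical(unname(back$geno), unname(gm$geno))
  expect_identical(back$sites$pos, gm$sites$pos)
})

test_that("selection failure at impossible settings raises an error", {
  cfg <- small_sim_config(seed = 1, brood_size = 1L, max_retries = 1L)
  expect_error(breed_introgression_line(cfg,
                                        simulate_founders(cfg, sites = FALSE)),
               "selection failed")
})
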