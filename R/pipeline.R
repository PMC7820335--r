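# Orchestration of the simulate -> filter -> scan -> map workflow, with
# filter-stage logging and reproducible file output. The numbered scripts
# under analysis/ are thin drivers over these functions.

#' Filter genotypes with the standard rules, with an audit log
#'
#' Applies the depth mask (genotypes with depth below `min_depth` set
#' missing) and the site filter (more than `max_missing` missing haplotype
#' fraction, or indel, dropped), recording counts at each stage.
#'
#' @param gm a [genotype_matrix()]
#' @param min_depth depth mask threshold (default 5)
#' @param max_missing maximum missing fraction (default 0.20)
#' @param drop_indels drop indel sites (default TRUE)
#' @return the filtered matrix with attribute `filter_log` (character)
#' @export
filter_genotypes <- function(gm, min_depth = 5L, max_missing = 0.2,
                             drop_indels = TRUE) {
  n0 <- nrow(gm$sites)
  miss0 <- sum(is.na(gm$geno))
  gm <- apply_depth_mask(gm, min_depth)
  miss1 <- sum(is.na(gm$geno))
  gm2 <- filter_sites(gm, max_missing, drop_indels)
  log <- c(
    sprintf("depth mask (DP < %d): %d genotype calls set missing", min_depth,
            miss1 - miss0),
    sprintf("site filter (> %d%% missing or indel): %d sites retained (from %d)",
            round(100 * max_missing), nrow(gm2$sites), n0))
  attr(gm2, "filter_log") <- log
  gm2
}

#' Map introgressed loci from a filtered genotype matrix
#'
#' The three-test concordance pipeline: a coarse genome scan (d_XY, pi of the
#' introgressed group, f_d, topology weights), candidate windows passing
#' `f_d > fd_min` AND `w_introgression > weight_min` AND the d_XY discordance
#' pattern, merged into regions, refined at fine window scale, and checked
#' for homozygous introgression.
#'
#' @param gm a filtered [genotype_matrix()]
#' @param pm a [population_map()]
#' @param contig_lengths named vector of contig lengths (bp)
#' @param coarse_size,fine_size window sizes in bp (defaults 1e5, 1e4)
#' @param fd_min,weight_min candidate thresholds (defaults 0.75)
#' @param high_mult,low_mult d_XY discordance multiples (defaults 0.75, 0.25)
#' @param pi_max,donor_fix_min homozygosity-check parameters
#' @param max_gap merge gap (default one coarse window)
#' @return list of class `locus_map`: `scan` (coarse `window_stats`),
#'   `selected` (windows passing all three tests), `regions` (merged),
#'   `report` (one row per region with refined bounds and homozygosity
#'   metrics), `fine_scans`, `log`
#' @export
map_introgressed_locus <- function(gm, pm, contig_lengths,
                                   coarse_size = 1e5, fine_size = 1e4,
                                   fd_min = 0.75, weight_min = 0.75,
                                   high_mult = 0.75, low_mult = 0.25,
                                   pi_max = 0.001, donor_fix_min = 0.95,
                                   max_gap = coarse_size) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  windows <- make_windows(contig_lengths, coarse_size, "genome_coarse")
  scan <- scan_genome(gm, pm, windows,
                      stats = c("dxy", "pi", "fd", "weights"),
                      dxy_pairs = list(c("P1", "P2"), c("P1", "P3"),
                                       c("P2", "P3")),
                      pi_roles = "P2")
  note("coarse scan: %d windows of %g bp over %d contigs", nrow(windows),
       coarse_size, length(contig_lengths))
  disc <- dxy_discordance_flag(scan, high_mult, low_mult)
  pass_fw <- !is.na(scan$fd) & scan$fd > fd_min &
    !is.na(scan$w_introgression) & scan$w_introgression > weight_min
  sel <- pass_fw & disc
  note("windows with f_d > %g and introgression weighting > %g: %d",
       fd_min, weight_min, sum(pass_fw))
  note("of those, d_XY-discordant (all three tests): %d", sum(sel))
  selected <- scan[sel, , drop = FALSE]
  if (nrow(selected)) {
    selected$fd_pass <- TRUE
    selected$weighting_pass <- TRUE
    selected$dxy_discordant <- TRUE
  }
  regions <- merge_windows(selected, max_gap)
  note("merged candidate regions: %d", nrow(regions))

  fine_scans <- list()
  report <- NULL
  if (nrow(regions)) {
    rows <- list()
    for (i in seq_len(nrow(regions))) {
      reg <- regions[i, , drop = FALSE]
      refined <- tryCatch(
        refine_locus(gm, pm, reg, fine_size, coarse_size, fd_min, weight_min,
                     contig_length = contig_lengths[[reg$chrom]]),
        introscan_refine_error = function(e) {
          note("region %s:%g-%g: %s (coarse bounds kept)", reg$chrom,
               reg$start, reg$end, conditionMessage(e))
          attr(reg, "fine_scan") <- e$fine_scan
          reg
        })
      fine_scans[[i]] <- attr(refined, "fine_scan")
      # the candidate-threshold envelope is the locus's maximum range; the
      # homozygous core (diversity- and fixation-narrowed) is the locus call
      core <- tryCatch(
        narrow_locus(refined, fd_min = fd_min, weight_min = weight_min,
                     pi_max = pi_max, donor_fix_min = donor_fix_min),
        introscan_narrow_error = function(e) NULL)
      if (is.null(core)) {
        hz <- homozygosity_check(gm, pm, refined, pi_max, donor_fix_min)
        note("region %s:%g-%g: maximum range %g-%g, no homozygous core",
             reg$chrom, reg$start, reg$end, refined$start, refined$end)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = reg$chrom, coarse_start = reg$start, coarse_end = reg$end,
          max_start = refined$start, max_end = refined$end,
          start = NA_real_, end = NA_real_,
          n_windows = reg$n_windows, mean_fd = reg$mean_fd,
          pi_introgressed = hz$pi, donor_fix = hz$donor_fix,
          n_diagnostic = hz$n_diagnostic, homozygous = FALSE,
          stringsAsFactors = FALSE)
      } else {
        # one locus call per contiguous fixed-donor block
        runs <- attr(core, "core_runs")
        for (k in seq_len(nrow(runs))) {
          run <- runs[k, ]
          hz <- homozygosity_check(gm, pm, run, pi_max, donor_fix_min)
          note(paste0("region %s:%g-%g: maximum range %g-%g, homozygous ",
                      "core %g-%g; pi=%.5f donor_fix=%.3f %s"),
               reg$chrom, reg$start, reg$end, refined$start, refined$end,
               run$start, run$end, hz$pi,
               ifelse(is.na(hz$donor_fix), NaN, hz$donor_fix),
               ifelse(isTRUE(hz$pass), "homozygous", "not homozygous"))
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = reg$chrom, coarse_start = reg$start, coarse_end = reg$end,
            max_start = refined$start, max_end = refined$end,
            start = run$start, end = run$end,
            n_windows = reg$n_windows, mean_fd = reg$mean_fd,
            pi_introgressed = hz$pi, donor_fix = hz$donor_fix,
            n_diagnostic = hz$n_diagnostic, homozygous = isTRUE(hz$pass),
            stringsAsFactors = FALSE)
        }
      }
    }
    report <- do.call(rbind, rows)
  } else {
    note("no candidates")
    report <- data.frame(chrom = character(), coarse_start = numeric(),
                         coarse_end = numeric(), max_start = numeric(),
                         max_end = numeric(), start = numeric(),
                         end = numeric(), n_windows = integer(),
                         mean_fd = numeric(), pi_introgressed = numeric(),
                         donor_fix = numeric(), n_diagnostic = integer(),
                         homozygous = logical())
  }
  structure(list(scan = scan, selected = selected, regions = regions,
                 report = report, fine_scans = fine_scans, log = log),
            class = "locus_map")
}

#' @export
print.locus_map <- function(x, ...) {
  cat("<locus_map>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Run the full simulate -> filter -> scan -> map pipeline
#'
#' Simulates a data set under `cfg`, applies the standard filters, maps
#' introgressed regions, and (optionally) writes all outputs plus a
#' reproducibility block to `out_dir`. Outputs are bit-identical given the
#' same configuration.
#'
#' @param cfg a [sim_config()]
#' @param out_dir optional output directory
#' @param min_depth,max_missing filter parameters
#' @param ... passed to [map_introgressed_locus()]
#' @return list: `dataset`, `gm_filtered`, `map` (a `locus_map`), `log`
#' @export
run_introgression_pipeline <- function(cfg, out_dir = NULL, min_depth = 5L,
                                       max_missing = 0.2, ...) {
  dataset <- simulate_introgression_dataset(cfg)
  gm <- filter_genotypes(dataset$gm, min_depth, max_missing)
  log <- c(sprintf("simulated %d sites, %d haplotypes (seed %d)",
                   nrow(dataset$gm$sites), ncol(dataset$gm$geno), cfg$seed),
           attr(gm, "filter_log"))
  res <- map_introgressed_locus(gm, dataset$pm, cfg$chrom_lengths, ...)
  log <- c(log, res$log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_window_stats(res$scan, file.path(out_dir, "window_stats.tsv"))
    if (nrow(res$regions)) {
      write_regions_bed(res$regions, file.path(out_dir, "candidate_regions.bed"))
    }
    data.table::fwrite(res$report, file.path(out_dir, "locus_report.tsv"),
                       sep = "\t", na = "NA", quote = FALSE)
    writeLines(c("# introscan run log", paste0("seed = ", cfg$seed),
                 paste0("package_version = ",
                        as.character(utils::packageVersion("introscan"))),
                 log),
               file.path(out_dir, "run_log.txt"))
  }
  list(dataset = dataset, gm_filtered = gm, map = res, log = log)
}
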