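# Candidate-region extraction, merging, fine-scale refinement and
# homozygosity verification.

#' Windows passing the introgression candidate thresholds
#'
#' Selects windows with `f_d > fd_min` AND `w_introgression > weight_min`
#' (both strictly greater, matching the extraction rule "greater than 0.75").
#' Undefined statistics never pass.
#'
#' @param stats a `window_stats` data.frame carrying `fd` and
#'   `w_introgression`
#' @param fd_min,weight_min thresholds (defaults 0.75)
#' @return the passing rows of `stats`, with logical columns `fd_pass` and
#'   `weighting_pass` (all TRUE) appended
#' @export
candidate_windows <- function(stats, fd_min = 0.75, weight_min = 0.75) {
  sel <- !is.na(stats$fd) & stats$fd > fd_min &
    !is.na(stats$w_introgression) & stats$w_introgression > weight_min
  out <- stats[sel, , drop = FALSE]
  out$fd_pass <- rep(TRUE, nrow(out))
  out$weighting_pass <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Flag windows with the introgression d_XY discordance pattern
#'
#' A window is discordant when the recipient/introgressed-line divergence
#' approaches the recipient/donor level while the introgressed-line/donor
#' divergence collapses: `dxy(P1,P2) >= high_mult * median(dxy(P1,P3))` AND
#' `dxy(P2,P3) <= low_mult * median(dxy(P2,P3))`, medians taken genome-wide.
#'
#' @param stats a `window_stats` data.frame with `dxy_P1_P2`, `dxy_P1_P3`
#'   and `dxy_P2_P3`
#' @param high_mult,low_mult multiples of the genome medians (defaults 0.75
#'   and 0.25)
#' @return logical vector, one flag per window (NA-safe: undefined d_XY never
#'   flags)
#' @export
dxy_discordance_flag <- function(stats, high_mult = 0.75, low_mult = 0.25) {
  need <- c("dxy_P1_P2", "dxy_P1_P3", "dxy_P2_P3")
  miss <- setdiff(need, names(stats))
  if (length(miss)) stop("stats lacks columns: ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(stats[, need])
  if (sum(ok) < 10) {
    stop("fewer than 10 windows with defined d_XY; genome medians unreliable")
  }
  med_13 <- stats::median(stats$dxy_P1_P3, na.rm = TRUE)
  med_23 <- stats::median(stats$dxy_P2_P3, na.rm = TRUE)
  flag <- !is.na(stats$dxy_P1_P2) & !is.na(stats$dxy_P2_P3) &
    stats$dxy_P1_P2 >= high_mult * med_13 &
    stats$dxy_P2_P3 <= low_mult * med_23
  flag
}

#' Merge selected windows into candidate regions
#'
#' Same-chromosome windows whose gaps are at most `max_gap` merge into one
#' region; evidence flags (any logical columns of the input) are OR-combined
#' and the mean f_d is carried as a score. Idempotent; output regions are
#' disjoint and sorted.
#'
#' @param selected data.frame of windows (chrom, start, end, optionally
#'   `fd` and logical evidence columns), any order
#' @param max_gap maximum gap in bp between merged windows (default 1e5,
#'   one coarse window)
#' @return data.frame of regions: chrom, start, end, n_windows, mean_fd and
#'   OR-combined evidence columns; class `candidate_regions`
#' @export
merge_windows <- function(selected, max_gap = 1e5) {
  flag_cols <- names(selected)[vapply(selected, is.logical, logical(1))]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      mean_fd = numeric())
  if (!nrow(selected)) {
    class(empty) <- c("candidate_regions", "data.frame")
    return(empty)
  }
  sel <- selected[order(selected$chrom, selected$start), , drop = FALSE]
  regions <- list()
  cur <- NULL
  flush <- function(cur) {
    base <- data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
                       n_windows = cur$n, mean_fd = mean(cur$fd),
                       stringsAsFactors = FALSE)
    if (length(cur$flags)) base <- cbind(base, as.data.frame(as.list(cur$flags)))
    base
  }
  for (i in seq_len(nrow(sel))) {
    w <- sel[i, ]
    fd_i <- if ("fd" %in% names(sel)) w$fd else NA_real_
    fl_i <- if (length(flag_cols)) unlist(w[flag_cols]) else logical(0)
    if (is.null(cur) || w$chrom != cur$chrom || w$start - cur$end > max_gap) {
      if (!is.null(cur)) regions[[length(regions) + 1L]] <- flush(cur)
      cur <- list(chrom = w$chrom, start = w$start, end = w$end, n = 1L,
                  fd = fd_i, flags = fl_i)
    } else {
      cur$end <- max(cur$end, w$end)
      cur$n <- cur$n + 1L
      cur$fd <- c(cur$fd, fd_i)
      if (length(flag_cols)) cur$flags <- cur$flags | fl_i
    }
  }
  regions[[length(regions) + 1L]] <- flush(cur)
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  class(out) <- c("candidate_regions", "data.frame")
  out
}

#' Refine a candidate region at fine window scale
#'
#' Rescans the region extended by one coarse window on each side using
#' `fine_size` tiled windows and the same statistics and thresholds as
#' [candidate_windows()]; the refined bounds are the outermost passing fine
#' windows. This is the algorithmic stand-in for visual inspection of a
#' locus-scale scan: deterministic and auditable via the attached fine-scan
#' table.
#'
#' @param gm a [genotype_matrix()]
#' @param pm a [population_map()]
#' @param region one-row region (chrom, start, end)
#' @param fine_size fine window size in bp (default 1e4)
#' @param coarse_size coarse window size used for the flanking extension
#'   (default 1e5)
#' @param fd_min,weight_min candidate thresholds (defaults 0.75)
#' @param contig_length length of the region's chromosome; defaults to the
#'   largest observed site position on it
#' @return the region with refined start/end and attributes `fine_scan`
#'   (the fine `window_stats` table) and `n_pass`
#' @export
refine_locus <- function(gm, pm, region, fine_size = 1e4, coarse_size = 1e5,
                         fd_min = 0.75, weight_min = 0.75,
                         contig_length = NULL) {
  stopifnot(fine_size < region$end - region$start)
  if (is.null(contig_length)) {
    contig_length <- max(gm$sites$pos[gm$sites$chrom == region$chrom])
  }
  lo <- max(0, region$start - coarse_size)
  hi <- min(contig_length, region$end + coarse_size)
  sub <- window_slice(gm, list(chrom = region$chrom, start = lo, end = hi))
  fine <- make_windows(stats::setNames(hi - lo, region$chrom), fine_size,
                       scheme = "locus_fine")
  fine$start <- fine$start + lo
  fine$end <- fine$end + lo
  fs <- scan_genome(sub, pm, fine, stats = c("dxy", "pi", "fd", "weights"),
                    dxy_pairs = list(c("P1", "P2"), c("P2", "P3")),
                    pi_roles = "P2")
  fs$donor_fix <- window_donor_fix(sub, pm, fine)
  pass <- !is.na(fs$fd) & fs$fd > fd_min &
    !is.na(fs$w_introgression) & fs$w_introgression > weight_min
  if (!any(pass)) {
    cond <- simpleError(paste0("no fine window passes in region ",
                               region$chrom, ":", region$start, "-",
                               region$end))
    cond$fine_scan <- fs
    class(cond) <- c("introscan_refine_error", class(cond))
    stop(cond)
  }
  region$start <- min(fs$start[pass])
  region$end <- max(fs$end[pass])
  attr(region, "fine_scan") <- fs
  attr(region, "n_pass") <- sum(pass)
  region
}

# per-site donor-diagnostic table: diagnostic sites are fixed differences
# between P1 and P3 among called haplotypes; all_donor marks sites where
# every called P2 haplotype carries the donor allele
donor_diagnostic_sites <- function(gm, pm) {
  rc <- role_columns(gm, pm)
  g1 <- gm$geno[, rc$P1, drop = FALSE]
  g3 <- gm$geno[, rc$P3, drop = FALSE]
  g2 <- gm$geno[, rc$P2, drop = FALSE]
  n1 <- rowSums(!is.na(g1)); n3 <- rowSums(!is.na(g3))
  first_called <- function(g) {
    out <- rep(NA_integer_, nrow(g))
    for (j in seq_len(ncol(g))) {
      fill <- is.na(out) & !is.na(g[, j])
      out[fill] <- g[fill, j]
    }
    out
  }
  a1 <- first_called(g1)
  a3 <- first_called(g3)
  mono1 <- rowSums(g1 != a1, na.rm = TRUE) == 0 & n1 >= 1
  mono3 <- rowSums(g3 != a3, na.rm = TRUE) == 0 & n3 >= 1
  diagn <- mono1 & mono3 & !is.na(a1) & !is.na(a3) & a1 != a3
  n2 <- rowSums(!is.na(g2))
  all_donor <- rowSums(g2 != a3, na.rm = TRUE) == 0 & n2 >= 1
  list(diagnostic = diagn & n2 >= 1, all_donor = all_donor)
}

#' Per-window donor-fixation fraction
#'
#' For each window, the fraction of donor-diagnostic sites (fixed differences
#' between P1 and P3) at which every called introgressed (P2) haplotype
#' carries the donor allele. `NA` for windows without diagnostic sites.
#'
#' @param gm a [genotype_matrix()]
#' @param pm a [population_map()]
#' @param windows data.frame of windows
#' @return numeric vector, one value per window
#' @export
window_donor_fix <- function(gm, pm, windows) {
  dd <- donor_diagnostic_sites(gm, pm)
  wid <- site_window_index(gm$sites, windows)
  num <- win_accum(as.numeric(dd$all_donor), dd$diagnostic, wid, nrow(windows))
  den <- win_accum(rep(1, nrow(gm$sites)), dd$diagnostic, wid, nrow(windows))
  ifelse(den > 0, num / den, NA_real_)
}

#' Narrow a refined region to its homozygous core
#'
#' The candidate-threshold envelope of [refine_locus()] gives the maximum
#' range of the introgressed locus; partially introgressed shoulders (donor
#' haplotype frequency above the candidate threshold but below fixation)
#' still inflate it. This step reproduces the diversity-based narrowing of
#' the locus: within the fine scan it keeps the outermost fine windows that
#' pass the candidate thresholds AND are donor-fixed (window donor-fixation
#' >= `donor_fix_min`) AND have introgressed-group diversity <= `pi_max`.
#'
#' @param region a refined region from [refine_locus()] (carrying the
#'   `fine_scan` attribute), or pass `fine_scan` explicitly
#' @param fine_scan fine `window_stats` table with `donor_fix` and `pi_P2`
#' @param fd_min,weight_min candidate thresholds (defaults 0.75)
#' @param pi_max,donor_fix_min homozygosity thresholds (defaults 0.001, 0.95)
#' @return the region with narrowed start/end and attribute `n_core_windows`;
#'   an error of class `introscan_narrow_error` when no window qualifies
#' @export
narrow_locus <- function(region, fine_scan = attr(region, "fine_scan"),
                         fd_min = 0.75, weight_min = 0.75,
                         pi_max = 0.001, donor_fix_min = 0.95) {
  if (is.null(fine_scan)) stop("fine_scan required (run refine_locus first)")
  fs <- fine_scan
  pass <- !is.na(fs$fd) & fs$fd > fd_min &
    !is.na(fs$w_introgression) & fs$w_introgression > weight_min &
    !is.na(fs$donor_fix) & fs$donor_fix >= donor_fix_min &
    !is.na(fs$pi_P2) & fs$pi_P2 <= pi_max
  if (!any(pass)) {
    cond <- simpleError("no fine window passes the homozygous-core criteria")
    cond$fine_scan <- fs
    class(cond) <- c("introscan_narrow_error", class(cond))
    stop(cond)
  }
  region$start <- min(fs$start[pass])
  region$end <- max(fs$end[pass])
  # contiguous runs of core windows: disjoint fixed-donor blocks (linked
  # drag that reached fixation appears as its own block, as in real lines)
  idx <- which(pass)
  brk <- c(TRUE, fs$start[idx[-1]] != fs$end[idx[-length(idx)]] |
             fs$chrom[idx[-1]] != fs$chrom[idx[-length(idx)]])
  run_id <- cumsum(brk)
  runs <- data.frame(
    chrom = tapply(fs$chrom[idx], run_id, `[`, 1),
    start = as.numeric(tapply(fs$start[idx], run_id, min)),
    end = as.numeric(tapply(fs$end[idx], run_id, max)),
    n_windows = as.integer(table(run_id)), stringsAsFactors = FALSE)
  attr(region, "fine_scan") <- fs
  attr(region, "core_runs") <- runs
  attr(region, "n_core_windows") <- sum(pass)
  region
}

#' Homozygous-introgression check for a region
#'
#' A region is consistent with a fixed recessive introgressed allele when
#' (a) nucleotide diversity of the introgressed group (P2) within the region
#' is at most `pi_max` and (b) at least `donor_fix_min` of the region's
#' donor-diagnostic sites have every called P2 haplotype carrying the donor
#' allele. Diagnostic sites are fixed differences between P1 and P3 among
#' called haplotypes.
#'
#' @inheritParams refine_locus
#' @param pi_max per-site diversity ceiling (default 0.001)
#' @param donor_fix_min minimum fixed-donor fraction of diagnostic sites
#'   (default 0.95)
#' @return list(pass, pi, donor_fix, n_diagnostic, n_sites); `pass` is NA
#'   when the region has no diagnostic sites
#' @export
homozygosity_check <- function(gm, pm, region, pi_max = 0.001,
                               donor_fix_min = 0.95) {
  sub <- window_slice(gm, region)
  pi2 <- as.numeric(nuc_div(sub, pm, "P2"))
  dd <- donor_diagnostic_sites(sub, pm)
  usable <- dd$diagnostic
  donor_fix <- if (any(usable)) mean(dd$all_donor[usable]) else NA_real_
  pass <- if (!any(usable)) {
    NA
  } else {
    !is.na(pi2) && pi2 <= pi_max && donor_fix >= donor_fix_min
  }
  list(pass = pass, pi = pi2, donor_fix = donor_fix,
       n_diagnostic = sum(usable), n_sites = nrow(sub$sites))
}

#' Write candidate regions as BED6
#'
#' Name field encodes the evidence flags, score is 1000 * mean f_d (capped).
#' @param regions a `candidate_regions` data.frame
#' @param path output path
#' @export
write_regions_bed <- function(regions, path) {
  flag_cols <- names(regions)[vapply(regions, is.logical, logical(1))]
  name <- if (length(flag_cols) && nrow(regions)) {
    apply(regions[, flag_cols, drop = FALSE], 1, function(fl) {
      paste(flag_cols[which(fl)], collapse = ",")
    })
  } else rep(".", nrow(regions))
  name[!nzchar(name)] <- "."
  score <- round(pmin(pmax(regions$mean_fd, 0), 1) * 1000)
  score[is.na(score)] <- 0
  bed <- data.frame(regions$chrom, sprintf("%.0f", regions$start),
                    sprintf("%.0f", regions$end), name, score,
                    strand = ".")
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
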