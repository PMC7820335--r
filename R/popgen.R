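# Windowed population-genetic statistics: allele frequencies, Nei's d_XY,
# nucleotide diversity pi, Patterson's D and the f_d introgression estimator.
#
# Conventions (documented in the methods vignette):
#  * Monomorphic usable sites count in the d_XY and pi denominators: both are
#    per-site averages over all sites where the groups involved have enough
#    called haplotypes, not over variant sites only (`variant_only` switches).
#  * Polarization for the four-taxon statistics: the derived allele at a site
#    is the minor allele in the outgroup O (ancestral = O's major allele),
#    ties broken toward the reference allele. Other alleles at multiallelic
#    sites are pooled with the ancestral state; d_XY and pi use the full
#    allele-frequency vectors instead.

# allele count matrix: n_sites x (n_alleles) for one set of haplotype columns
allele_counts <- function(geno, cols, n_alleles) {
  sub <- geno[, cols, drop = FALSE]
  vapply(seq_len(n_alleles) - 1L,
         function(k) rowSums(sub == k, na.rm = TRUE),
         numeric(nrow(geno)))
}

# list(n = called haplotypes per site, f = frequency matrix) for a column set
group_freqs <- function(geno, cols, n_alleles) {
  cnt <- allele_counts(geno, cols, n_alleles)
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1)
  n <- rowSums(cnt)
  f <- cnt / ifelse(n > 0, n, NA_real_)
  list(n = n, f = f)
}

n_alleles_of <- function(gm) {
  mx <- suppressWarnings(max(gm$geno, na.rm = TRUE))
  if (!is.finite(mx)) mx <- 0L
  as.integer(mx) + 1L
}

#' Per-site derived-allele frequencies for the four test roles
#'
#' Polarizes each site using the outgroup (derived = minor allele in O, ties
#' toward the reference allele) and returns the derived-allele frequency among
#' called haplotypes for each role. Sites where the outgroup has no called
#' haplotype cannot be polarized and carry `NA` frequencies for all roles;
#' roles with zero called haplotypes at a site carry `NA` there.
#'
#' @param gm a [genotype_matrix()] (typically a window slice)
#' @param pm a [population_map()]
#' @return list with `p` (sites x 4 matrix, columns P1,P2,P3,O), `n_called`
#'   (same shape), `derived`/`ancestral` allele codes per site, and
#'   `n_reduced`, the count of multiallelic sites whose extra alleles were
#'   pooled with the ancestral state.
#' @export
site_frequencies <- function(gm, pm) {
  A <- n_alleles_of(gm)
  rc <- role_columns(gm, pm)
  ns <- nrow(gm$sites)
  cntO <- allele_counts(gm$geno, rc$O, A)
  if (is.null(dim(cntO))) cntO <- matrix(cntO, nrow = 1)
  nO <- rowSums(cntO)
  # ancestral = O's most frequent allele; ties.method="first" with allele 0
  # (REF) in column 1 breaks ties toward the reference allele
  ancestral <- ifelse(nO > 0, max.col(cntO, ties.method = "first") - 1L,
                      NA_integer_)
  # derived = most frequent non-ancestral allele over all haplotypes
  cnt_all <- allele_counts(gm$geno, seq_len(ncol(gm$geno)), A)
  if (is.null(dim(cnt_all))) cnt_all <- matrix(cnt_all, nrow = 1)
  cnt_masked <- cnt_all
  cnt_masked[cbind(seq_len(ns), ancestral + 1L)] <- -1L
  derived <- max.col(cnt_masked, ties.method = "first") - 1L
  derived[is.na(ancestral)] <- NA_integer_
  third_count <- rowSums(cnt_all) -
    cnt_all[cbind(seq_len(ns), ifelse(is.na(ancestral), 1L, ancestral + 1L))] -
    cnt_all[cbind(seq_len(ns), ifelse(is.na(derived), 1L, derived + 1L))]
  n_reduced <- sum(third_count > 0 & !is.na(ancestral))

  p <- matrix(NA_real_, ns, 4, dimnames = list(NULL, c("P1", "P2", "P3", "O")))
  n_called <- matrix(0, ns, 4, dimnames = dimnames(p))
  for (r in c("P1", "P2", "P3", "O")) {
    sub <- gm$geno[, rc[[r]], drop = FALSE]
    der <- rowSums(sub == derived, na.rm = TRUE)
    n <- rowSums(!is.na(sub))
    n_called[, r] <- n
    p[, r] <- ifelse(n > 0 & !is.na(derived), der / n, NA_real_)
  }
  list(p = p, n_called = n_called, derived = derived, ancestral = ancestral,
       n_reduced = n_reduced)
}

# per-site dxy between two column sets; returns list(value = per-site vector,
# usable = logical). Multiallelic form: 1 - sum_k x_k y_k.
dxy_per_site <- function(geno, colsA, colsB, n_alleles) {
  fa <- group_freqs(geno, colsA, n_alleles)
  fb <- group_freqs(geno, colsB, n_alleles)
  same <- rowSums(fa$f * fb$f)
  usable <- fa$n >= 1 & fb$n >= 1
  list(value = 1 - same, usable = usable)
}

# per-site pi for one column set: unbiased pairwise form
# n/(n-1) * (1 - sum_k x_k^2); usable where n >= 2
pi_per_site <- function(geno, cols, n_alleles) {
  fr <- group_freqs(geno, cols, n_alleles)
  n <- fr$n
  hom <- rowSums(fr$f^2)
  list(value = ifelse(n >= 2, n / (n - 1) * (1 - hom), NA_real_),
       usable = n >= 2)
}

#' Nei's absolute divergence d_XY between two groups
#'
#' Mean over usable sites (both groups with at least one called haplotype) of
#' the per-site probability that haplotypes drawn from each group differ,
#' `1 - sum_k x_k y_k` over allele frequency vectors. Equivalent to the mean
#' pairwise difference over all inter-group haplotype pairs with per-site
#' pairwise deletion.
#'
#' @param gm a [genotype_matrix()] (typically a window slice)
#' @param pm a [population_map()]
#' @param group_a,group_b group labels or role names
#' @param variant_only if TRUE, average over variant usable sites only;
#'   default FALSE counts monomorphic usable sites in the denominator.
#' @return numeric; `NA` (with attribute `n_sites` 0) when no usable site.
#' @export
dxy <- function(gm, pm, group_a, group_b, variant_only = FALSE) {
  A <- n_alleles_of(gm)
  ca <- group_columns(gm, pm, group_a)
  cb <- group_columns(gm, pm, group_b)
  ds <- dxy_per_site(gm$geno, ca, cb, A)
  use <- ds$usable
  if (variant_only) use <- use & ds$value > 0
  val <- if (any(use)) mean(ds$value[use]) else NA_real_
  attr(val, "n_sites") <- sum(use)
  val
}

#' Nucleotide diversity pi within one group
#'
#' Mean over usable sites (>= 2 called haplotypes) of the unbiased per-site
#' pairwise difference `2p(1-p) * n/(n-1)` (multiallelic generalization
#' `n/(n-1) * (1 - sum x_k^2)`). Pool columns are treated as haplotypes.
#'
#' @inheritParams dxy
#' @param group group label or role name
#' @export
nuc_div <- function(gm, pm, group, variant_only = FALSE) {
  A <- n_alleles_of(gm)
  cols <- group_columns(gm, pm, group)
  ps <- pi_per_site(gm$geno, cols, A)
  use <- ps$usable
  if (variant_only) use <- use & !is.na(ps$value) & ps$value > 0
  val <- if (any(use)) mean(ps$value[use]) else NA_real_
  attr(val, "n_sites") <- sum(use)
  val
}

#' ABBA/BABA site-pattern sums and the f_d denominator
#'
#' Given per-site derived-allele frequencies for P1, P2, P3 and O, computes
#' `ABBA_i = (1-p1) p2 p3 (1-pO)`, `BABA_i = p1 (1-p2) p3 (1-pO)` and the
#' dynamic-donor f_d denominator in which `pD = max(p2, p3)` replaces both p2
#' and p3: `denom_i = (1-p1) pD pD (1-pO) - p1 (1-pD) pD (1-pO)`. Sites with
#' any undefined role frequency are skipped.
#'
#' @param freqs output of [site_frequencies()], or a data.frame/matrix with
#'   columns p1, p2, p3, pO (case-insensitive).
#' @return list(abba, baba, denom, n_sites)
#' @export
abba_baba_sums <- function(freqs) {
  p <- if (is.list(freqs) && !is.null(freqs$p)) freqs$p else as.matrix(freqs)
  cn <- tolower(colnames(p))
  idx <- match(c("p1", "p2", "p3", "po"), cn)
  if (anyNA(idx)) idx <- 1:4
  p1 <- p[, idx[1]]; p2 <- p[, idx[2]]; p3 <- p[, idx[3]]; pO <- p[, idx[4]]
  ok <- !(is.na(p1) | is.na(p2) | is.na(p3) | is.na(pO))
  p1 <- p1[ok]; p2 <- p2[ok]; p3 <- p3[ok]; pO <- pO[ok]
  abba <- (1 - p1) * p2 * p3 * (1 - pO)
  baba <- p1 * (1 - p2) * p3 * (1 - pO)
  pD <- pmax(p2, p3)
  denom <- (1 - p1) * pD * pD * (1 - pO) - p1 * (1 - pD) * pD * (1 - pO)
  list(abba = sum(abba), baba = sum(baba), denom = sum(denom),
       n_sites = sum(ok))
}

#' Patterson's D and the f_d introgression estimator for one window
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`; `f_d = (ABBA - BABA) / denom` when
#' `D >= 0` and 0 otherwise (the statistic's published convention for
#' negative-D windows; raw D is returned alongside so the choice is
#' auditable). Undefined (`NA`) when there are no informative sites, with a
#' `reason` field.
#'
#' @inheritParams dxy
#' @return list(fd, D, abba, baba, denom, n_informative, reason)
#' @export
fd_window <- function(gm, pm) {
  sf <- site_frequencies(gm, pm)
  s <- abba_baba_sums(sf)
  tot <- s$abba + s$baba
  if (s$n_sites == 0) {
    return(list(fd = NA_real_, D = NA_real_, abba = 0, baba = 0, denom = 0,
                n_informative = 0L, reason = "missing role frequencies"))
  }
  if (tot == 0) {
    return(list(fd = NA_real_, D = NA_real_, abba = s$abba, baba = s$baba,
                denom = s$denom, n_informative = s$n_sites,
                reason = "no informative sites"))
  }
  D <- (s$abba - s$baba) / tot
  fd <- if (D < 0) 0 else (s$abba - s$baba) / s$denom
  fd <- min(max(fd, 0), 1)
  list(fd = fd, D = D, abba = s$abba, baba = s$baba, denom = s$denom,
       n_informative = s$n_sites, reason = NA_character_)
}

# window index per site: NA where a site falls in no window.
# Windows must be non-overlapping within each chrom.
site_window_index <- function(sites, windows) {
  wid <- rep(NA_integer_, nrow(sites))
  p0 <- sites$pos - 1L
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    wi <- wi[order(windows$start[wi])]
    si <- which(sites$chrom == ch)
    if (!length(si)) next
    fi <- findInterval(p0[si], windows$start[wi])
    ok <- fi >= 1L
    ok[ok] <- p0[si][ok] < windows$end[wi][fi[ok]]
    wid[si[ok]] <- wi[fi[ok]]
  }
  wid
}

# sum of x over usable sites per window -> length nrow(windows) vector
win_accum <- function(x, usable, wid, n_windows) {
  sel <- usable & !is.na(wid) & !is.na(x)
  out <- numeric(n_windows)
  if (any(sel)) {
    s <- rowsum(x[sel], wid[sel])
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Windowed genome scan of d_XY, pi, D/f_d and topology weights
#'
#' Computes the requested statistics independently for every window. Results
#' are identical to calling the single-window functions on each
#' [window_slice()] (the vectorized paths share the same per-site formulas).
#'
#' @param gm a [genotype_matrix()]
#' @param pm a [population_map()]
#' @param windows data.frame from [make_windows()]
#' @param stats subset of c("dxy","pi","fd","weights")
#' @param dxy_pairs list of role pairs for d_XY, e.g.
#'   `list(c("P1","P2"), c("P2","P3"))`; default all six role pairs.
#' @param pi_roles roles for which pi is computed (default all four).
#' @param tree_min_sites minimum sites in a window before a local tree is
#'   attempted for topology weighting (default 1).
#' @return data.frame of class `window_stats`: one row per window with the
#'   window coordinates, `n_sites` (sites present), `n_sites_used` (sites
#'   with all four roles called, the substrate of the polarized statistics),
#'   the requested statistic columns, and for weights `w_species`,
#'   `w_introgression`, `w_control`, `n_combinations`, `n_unresolved`.
#'   Undefined statistics are `NA`.
#' @export
scan_genome <- function(gm, pm, windows,
                        stats = c("dxy", "pi", "fd", "weights"),
                        dxy_pairs = NULL,
                        pi_roles = c("P1", "P2", "P3", "O"),
                        tree_min_sites = 1L) {
  stats <- match.arg(stats, several.ok = TRUE)
  nw <- nrow(windows)
  A <- n_alleles_of(gm)
  rc <- role_columns(gm, pm)
  wid <- site_window_index(gm$sites, windows)
  out <- windows[, c("chrom", "start", "end",
                     intersect("scheme", names(windows)))]
  inwin <- !is.na(wid)
  out$n_sites <- win_accum(rep(1, nrow(gm$sites)), rep(TRUE, nrow(gm$sites)),
                           wid, nw)

  # n_sites_used: all four roles have >= 1 called haplotype
  called_all <- Reduce(`&`, lapply(rc, function(cols) {
    rowSums(!is.na(gm$geno[, cols, drop = FALSE])) >= 1
  }))
  out$n_sites_used <- win_accum(rep(1, nrow(gm$sites)), called_all, wid, nw)

  if ("dxy" %in% stats) {
    if (is.null(dxy_pairs)) {
      dxy_pairs <- utils::combn(c("P1", "P2", "P3", "O"), 2, simplify = FALSE)
    }
    for (pr in dxy_pairs) {
      ds <- dxy_per_site(gm$geno, rc[[pr[1]]], rc[[pr[2]]], A)
      num <- win_accum(ds$value, ds$usable, wid, nw)
      den <- win_accum(rep(1, length(ds$value)), ds$usable, wid, nw)
      out[[paste0("dxy_", pr[1], "_", pr[2])]] <-
        ifelse(den > 0, num / den, NA_real_)
    }
  }
  if ("pi" %in% stats) {
    for (r in pi_roles) {
      ps <- pi_per_site(gm$geno, rc[[r]], A)
      num <- win_accum(ps$value, ps$usable, wid, nw)
      den <- win_accum(rep(1, length(ps$value)), ps$usable, wid, nw)
      out[[paste0("pi_", r)]] <- ifelse(den > 0, num / den, NA_real_)
    }
  }
  if ("fd" %in% stats) {
    sf <- site_frequencies(gm, pm)
    p1 <- sf$p[, "P1"]; p2 <- sf$p[, "P2"]; p3 <- sf$p[, "P3"]
    pO <- sf$p[, "O"]
    ok <- !(is.na(p1) | is.na(p2) | is.na(p3) | is.na(pO))
    abba <- (1 - p1) * p2 * p3 * (1 - pO)
    baba <- p1 * (1 - p2) * p3 * (1 - pO)
    pD <- pmax(p2, p3)
    denom <- (1 - p1) * pD * pD * (1 - pO) - p1 * (1 - pD) * pD * (1 - pO)
    sa <- win_accum(abba, ok, wid, nw)
    sb <- win_accum(baba, ok, wid, nw)
    sd <- win_accum(denom, ok, wid, nw)
    tot <- sa + sb
    D <- ifelse(tot > 0, (sa - sb) / tot, NA_real_)
    fd <- ifelse(is.na(D), NA_real_,
                 ifelse(D < 0, 0, pmin(pmax((sa - sb) / sd, 0), 1)))
    out$D <- D
    out$fd <- fd
  }
  if ("weights" %in% stats) {
    cols <- unlist(rc, use.names = FALSE)
    labels <- colnames(gm$geno)[cols]
    groups <- lapply(rc, function(ci) colnames(gm$geno)[ci])
    out$w_species <- out$w_introgression <- out$w_control <- NA_real_
    out$n_combinations <- out$n_unresolved <- NA_integer_
    rows_by_win <- split(seq_len(nrow(gm$sites))[inwin], wid[inwin])
    for (key in names(rows_by_win)) {
      wi <- as.integer(key)
      rows <- rows_by_win[[key]]
      if (length(rows) < tree_min_sites) next
      w <- tryCatch({
        sub <- gm_subset_sites(gm, rows)
        dm <- pairwise_distances(sub, model = "raw", cols = cols)
        tr <- nj_tree(dm)
        topology_weights(tr, groups, method = "exact")
      }, error = function(e) NULL)
      if (is.null(w)) next
      out$w_species[wi] <- w$w["species"]
      out$w_introgression[wi] <- w$w["introgression"]
      out$w_control[wi] <- w$w["control"]
      out$n_combinations[wi] <- w$n_combinations
      out$n_unresolved[wi] <- w$n_unresolved
    }
  }
  rownames(out) <- NULL
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Box-plot style summary of one scan column
#'
#' Quartiles, IQR and 1.5*IQR whisker bounds over defined window values, as
#' used to summarize genome-wide window distributions.
#'
#' @param stats a `window_stats` data.frame
#' @param column column name, e.g. "dxy_P1_P2"
#' @export
scan_summary <- function(stats, column) {
  x <- stats[[column]]
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  list(n = length(x), q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
       whisker_low = max(min(x), q[1] - 1.5 * iqr),
       whisker_high = min(max(x), q[3] + 1.5 * iqr))
}

#' Write per-window statistics as TSV
#'
#' Deterministic column order; undefined values serialized as "NA".
#' @param stats a `window_stats` data.frame
#' @param path output path
#' @export
write_window_stats <- function(stats, path) {
  data.table::fwrite(as.data.frame(stats), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}
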