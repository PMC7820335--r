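# Genotype container and site/window bookkeeping.
#
# Coordinates: VCF positions are stored 1-based as given; all windowing is
# half-open 0-based (BED convention), so a site at 1-based position p falls in
# window [start, end) iff start <= p - 1 < end.

MISSING <- NA_integer_

#' Construct a genotype matrix
#'
#' Sites-by-haplotypes container for allele codes with per-sample depth and
#' ploidy. Haplotype columns are contiguous per sample, ordered by sample then
#' allele slot, so a diploid contributes two adjacent columns and a ploidy-10
#' pool ten.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated alternate alleles, "" if none) and `is_indel`.
#'   Sites must be sorted by chrom block and strictly increasing position
#'   within each chrom.
#' @param geno integer matrix, `nrow(sites)` x total haplotypes; allele codes
#'   index REF = 0, first ALT = 1, ...; `NA` = missing.
#' @param samples character vector of sample ids.
#' @param ploidy integer vector of per-sample haplotype counts (recycled if
#'   length 1).
#' @param depth optional integer matrix, `nrow(sites)` x `length(samples)`,
#'   per-sample read depth; `NA` where depth was not reported.
#' @return An object of class `geno_mat`.
#' @export
genotype_matrix <- function(sites, geno, samples, ploidy = 2L, depth = NULL) {
  stopifnot(is.data.frame(sites), is.matrix(geno))
  ploidy <- as.integer(rep(ploidy, length.out = length(samples)))
  names(ploidy) <- samples
  if (ncol(geno) != sum(ploidy)) {
    stop("geno has ", ncol(geno), " columns but sum(ploidy) is ", sum(ploidy))
  }
  if (nrow(geno) != nrow(sites)) stop("geno rows must match sites")
  need <- c("chrom", "pos", "ref", "alt", "is_indel")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites lacks columns: ", paste(miss, collapse = ", "))
  if (!is.null(depth)) {
    stopifnot(is.matrix(depth), nrow(depth) == nrow(sites),
              ncol(depth) == length(samples))
    colnames(depth) <- samples
  }
  # strict ordering within each chrom
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      stop("sites not strictly sorted on ", ch)
    }
  }
  hap_sample <- rep(seq_along(samples), ploidy)
  colnames(geno) <- unlist(lapply(seq_along(samples), function(i) {
    paste0(samples[i], "_", seq_len(ploidy[i]))
  }), use.names = FALSE)
  storage.mode(geno) <- "integer"
  rownames(sites) <- NULL
  structure(
    list(sites = sites, geno = geno, samples = samples, ploidy = ploidy,
         hap_sample = hap_sample, depth = depth),
    class = "geno_mat")
}

#' @export
print.geno_mat <- function(x, ...) {
  cat("<geno_mat> ", nrow(x$sites), " sites x ", ncol(x$geno),
      " haplotypes (", length(x$samples), " samples)\n", sep = "")
  cat("  chroms:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cat("  depth:", if (is.null(x$depth)) "absent" else "present", "\n")
  invisible(x)
}

#' Number of haplotype columns
#' @param gm a `geno_mat`
#' @export
n_haplotypes <- function(gm) ncol(gm$geno)

# Row subset preserving all sample structure.
gm_subset_sites <- function(gm, idx) {
  gm$sites <- gm$sites[idx, , drop = FALSE]
  rownames(gm$sites) <- NULL
  gm$geno <- gm$geno[idx, , drop = FALSE]
  if (!is.null(gm$depth)) gm$depth <- gm$depth[idx, , drop = FALSE]
  gm
}

#' Population map: sample groups and the four test roles
#'
#' @param assignment named character vector mapping sample id -> group label.
#' @param roles named list or character vector mapping the roles `P1`
#'   (recipient), `P2` (introgressed line), `P3` (donor) and `O` (outgroup)
#'   to group labels. The four roles must name four distinct groups.
#' @return An object of class `pop_map`.
#' @export
population_map <- function(assignment, roles) {
  roles <- as.list(roles)
  need <- c("P1", "P2", "P3", "O")
  if (!setequal(intersect(names(roles), need), need)) {
    stop("roles must name P1, P2, P3 and O")
  }
  roles <- roles[need]
  grp <- unlist(roles, use.names = FALSE)
  if (anyDuplicated(grp)) stop("the four roles must map to distinct groups")
  for (g in grp) {
    if (!any(assignment == g)) stop("role group '", g, "' has no samples")
  }
  structure(list(assignment = assignment, roles = roles), class = "pop_map")
}

#' Read a two-column sample map TSV (sample, group)
#' @param path TSV file, no header required (header auto-detected by names
#'   `sample`/`group`).
#' @param roles passed to [population_map()].
#' @export
read_population_map <- function(path, roles) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample", "group"),
                          stringsAsFactors = FALSE)
  if (identical(tolower(df$sample[1]), "sample")) df <- df[-1, , drop = FALSE]
  population_map(stats::setNames(df$group, df$sample), roles)
}

#' Haplotype columns belonging to a group
#' @param gm a `geno_mat`
#' @param pm a `pop_map`
#' @param group a group label, or a role name (`P1`, `P2`, `P3`, `O`)
#' @export
group_columns <- function(gm, pm, group) {
  if (group %in% names(pm$roles)) group <- pm$roles[[group]]
  smp <- names(pm$assignment)[pm$assignment == group]
  if (!length(smp)) stop("no samples in group '", group, "'")
  bad <- setdiff(smp, gm$samples)
  if (length(bad)) stop("samples absent from genotype matrix: ",
                        paste(bad, collapse = ", "))
  which(gm$hap_sample %in% match(smp, gm$samples))
}

# role -> haplotype column index list
role_columns <- function(gm, pm) {
  lapply(stats::setNames(nm = names(pm$roles)),
         function(r) group_columns(gm, pm, r))
}

#' Leaf (haplotype) labels belonging to a role
#' @inheritParams group_columns
#' @param role one of "P1","P2","P3","O"
#' @export
role_leaves <- function(gm, pm, role) colnames(gm$geno)[group_columns(gm, pm, role)]

#' Read genotypes from a VCF
#'
#' Reads GT (required) and DP (honored when present) for all samples. Phased
#' and unphased genotypes are both accepted; per-sample ploidy is taken from
#' the GT field itself (number of allele slots), so diploid individuals and
#' higher-ploidy pooled libraries can coexist in one file.
#'
#' @param path VCF file, plain or gzipped.
#' @param pm optional [population_map()]; every sample it names must be
#'   present in the VCF (configuration error otherwise).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, pm = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1]
  if (!is.null(pm)) {
    bad <- setdiff(names(pm$assignment), samples)
    if (length(bad)) {
      stop("configuration error: samples named in population map absent ",
           "from VCF: ", paste(bad, collapse = ", "))
    }
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- ""
  ref <- fix[, "REF"]
  is_indel <- vapply(seq_along(ref), function(i) {
    alleles <- c(ref[i], if (nzchar(alt[i])) strsplit(alt[i], ",", fixed = TRUE)[[1]])
    any(nchar(alleles) != 1L)
  }, logical(1))
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = ref, alt = alt, is_indel = is_indel,
                      stringsAsFactors = FALSE)

  # per-sample ploidy from the first non-missing GT
  split_gt <- function(x) strsplit(x, "[/|]")
  ploidy <- integer(length(samples))
  parsed <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    toks <- split_gt(ifelse(is.na(gt[, j]), ".", gt[, j]))
    nall <- lengths(toks)
    known <- which(vapply(toks, function(t) !all(t %in% c(".", "")), logical(1)))
    ploidy[j] <- if (length(known)) nall[known[1]] else max(nall)
    parsed[[j]] <- toks
  }
  n_hap <- sum(ploidy)
  geno <- matrix(MISSING, nrow = nrow(sites), ncol = n_hap)
  col0 <- c(0L, cumsum(ploidy))
  for (j in seq_along(samples)) {
    toks <- parsed[[j]]
    for (i in seq_len(nrow(sites))) {
      t <- toks[[i]]
      if (all(t %in% c(".", ""))) next  # fully missing, keep NA row
      if (length(t) != ploidy[j]) {
        stop("parse error: record ", i, " (", sites$chrom[i], ":",
             sites$pos[i], ") sample ", samples[j], " has ", length(t),
             " alleles, expected ", ploidy[j])
      }
      codes <- suppressWarnings(as.integer(t))
      bad <- is.na(codes) & !(t %in% c(".", ""))
      if (any(bad)) {
        stop("parse error: record ", i, " (", sites$chrom[i], ":",
             sites$pos[i], ") sample ", samples[j],
             " has malformed GT '", gt[i, j], "'")
      }
      n_alt <- if (nzchar(sites$alt[i])) {
        length(strsplit(sites$alt[i], ",", fixed = TRUE)[[1]])
      } else 0L
      if (any(codes > n_alt, na.rm = TRUE)) {
        stop("parse error: record ", i, " genotype code exceeds declared alleles")
      }
      geno[i, (col0[j] + 1L):col0[j + 1L]] <- codes
    }
  }
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  depth <- if (!is.null(dp)) {
    m <- matrix(as.integer(round(dp)), nrow = nrow(sites))
    colnames(m) <- samples
    m
  } else NULL
  genotype_matrix(sites, geno, samples, ploidy, depth)
}

#' Write a genotype matrix back to VCF (GT + DP)
#'
#' Minimal VCF 4.2 writer covering the fields this package consumes; it
#' round-trips genotype codes and missingness exactly through [read_vcf()].
#'
#' @param gm a `geno_mat`
#' @param path output path (".gz" suffix writes gzipped text)
#' @export
write_vcf <- function(gm, path) {
  has_dp <- !is.null(gm$depth)
  fmt <- if (has_dp) "GT:DP" else "GT"
  col0 <- c(0L, cumsum(gm$ploidy))
  sample_fields <- matrix("", nrow = nrow(gm$sites), ncol = length(gm$samples))
  for (j in seq_along(gm$samples)) {
    cols <- (col0[j] + 1L):col0[j + 1L]
    g <- gm$geno[, cols, drop = FALSE]
    gs <- matrix(as.character(g), nrow = nrow(g))
    gs[is.na(gs)] <- "."
    gt <- do.call(paste, c(split(gs, col(gs)), sep = "/"))
    if (has_dp) {
      d <- gm$depth[, j]
      gt <- paste0(gt, ":", ifelse(is.na(d), ".", as.character(d)))
    }
    sample_fields[, j] <- gt
  }
  alt <- gm$sites$alt
  alt[!nzchar(alt)] <- "."
  body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, alt, ".",
                "PASS", ".", fmt,
                do.call(paste, c(split(sample_fields, col(sample_fields)),
                                 sep = "\t")),
                sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=introscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Mask genotypes below a depth threshold
#'
#' Sets all haplotype codes of a sample-site to missing wherever that sample's
#' depth is below `min_depth`. Sites or samples without reported depth are
#' left untouched: the rule is a depth mask, not a requirement that depth
#' exist.
#'
#' @param gm a `geno_mat`
#' @param min_depth genotypes with depth strictly less than this are masked
#'   (default 5).
#' @export
apply_depth_mask <- function(gm, min_depth = 5L) {
  stopifnot(min_depth >= 0)
  if (is.null(gm$depth) || min_depth == 0L) return(gm)
  low <- gm$depth < min_depth
  low[is.na(low)] <- FALSE
  gm$geno[low[, gm$hap_sample, drop = FALSE]] <- MISSING
  gm
}

#' Filter sites on missingness and indel status
#'
#' Removes sites where the missing fraction of haplotype columns exceeds
#' `max_missing_frac` (strictly greater), and indel sites when `drop_indels`.
#' The missingness denominator is haplotype columns, not samples, so pooled
#' higher-ploidy libraries are weighted by their haplotypes.
#'
#' @param gm a `geno_mat`
#' @param max_missing_frac maximum tolerated missing fraction (default 0.20).
#' @param drop_indels drop sites whose alleles are not all single bases
#'   (default TRUE).
#' @export
filter_sites <- function(gm, max_missing_frac = 0.2, drop_indels = TRUE) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  miss <- rowMeans(is.na(gm$geno))
  keep <- miss <= max_missing_frac
  if (drop_indels) keep <- keep & !gm$sites$is_indel
  gm_subset_sites(gm, which(keep))
}

#' Tile contigs with half-open windows
#'
#' @param contig_lengths named numeric vector chrom -> length (bp).
#' @param size window size in bp.
#' @param scheme label recorded in the `scheme` column
#'   (e.g. "genome_100kb", "locus_10kb", "tree_1kb", "custom").
#' @param step start-to-start distance; defaults to `size` (adjacent
#'   non-overlapping tiling, the interpretation of "tiled" used throughout).
#' @return data.frame chrom, start (0-based incl.), end (excl.), scheme.
#' @export
make_windows <- function(contig_lengths, size, scheme = "custom", step = size) {
  stopifnot(size >= 1, step >= 1, all(contig_lengths >= 1))
  out <- lapply(names(contig_lengths), function(ch) {
    len <- contig_lengths[[ch]]
    starts <- seq(0, len - 1, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size, len),
               scheme = scheme, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write windows as BED3 + scheme column
#' @param windows data.frame from [make_windows()]
#' @param path output path
#' @export
write_windows_bed <- function(windows, path) {
  bed <- data.frame(windows$chrom, sprintf("%.0f", windows$start),
                    sprintf("%.0f", windows$end), windows$scheme)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sites falling in one window
#'
#' Keeps exactly the sites whose 0-based position lies in `[start, end)`.
#'
#' @param gm a `geno_mat`
#' @param window one-row data.frame (or list) with chrom, start, end.
#' @export
window_slice <- function(gm, window) {
  p0 <- gm$sites$pos - 1L
  keep <- gm$sites$chrom == window$chrom & p0 >= window$start & p0 < window$end
  gm_subset_sites(gm, which(keep))
}
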