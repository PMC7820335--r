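# Independent oracles: brute-force pair counting, explicit quartet pruning,
# least-squares topology fits, and a hand-rolled translator. These stay
# deliberately naive (loops, enumeration) and share no code with the package
# internals they check.

# mean pairwise difference between two column sets, per-site pair counting
# with pairwise deletion, averaged over sites where both sets have >= 1
# called haplotype
oracle_dxy <- function(geno, cols_a, cols_b) {
  vals <- c()
  for (i in seq_len(nrow(geno))) {
    a <- geno[i, cols_a]; a <- a[!is.na(a)]
    b <- geno[i, cols_b]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) next
    diff <- 0
    for (x in a) for (y in b) diff <- diff + (x != y)
    vals <- c(vals, diff / (length(a) * length(b)))
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

# mean pairwise difference within one column set over unordered pairs,
# averaged over sites with >= 2 called haplotypes
oracle_pi <- function(geno, cols) {
  vals <- c()
  for (i in seq_len(nrow(geno))) {
    a <- geno[i, cols]; a <- a[!is.na(a)]
    n <- length(a)
    if (n < 2) next
    diff <- 0
    for (j in 1:(n - 1)) for (k in (j + 1):n) diff <- diff + (a[j] != a[k])
    vals <- c(vals, diff / (n * (n - 1) / 2))
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

# spreadsheet-style re-evaluation of the ABBA/BABA/f_d-denominator sums
oracle_abba_baba <- function(p1, p2, p3, pO) {
  abba <- baba <- denom <- 0
  for (i in seq_along(p1)) {
    if (anyNA(c(p1[i], p2[i], p3[i], pO[i]))) next
    abba <- abba + (1 - p1[i]) * p2[i] * p3[i] * (1 - pO[i])
    baba <- baba + p1[i] * (1 - p2[i]) * p3[i] * (1 - pO[i])
    pd <- max(p2[i], p3[i])
    denom <- denom + (1 - p1[i]) * pd * pd * (1 - pO[i]) -
      p1[i] * (1 - pd) * pd * (1 - pO[i])
  }
  list(abba = abba, baba = baba, denom = denom)
}

# quartet classification by explicit pruning and cherry inspection
# (structural; assumes resolved trees with positive internal branches)
oracle_quartet <- function(tree, leaves) {
  pt <- ape::unroot(ape::keep.tip(tree, unname(leaves)))
  tip_parent <- pt$edge[match(seq_len(4), pt$edge[, 2]), 1]
  tab <- table(tip_parent)
  cherries <- as.integer(names(tab)[tab == 2])
  if (!length(cherries)) return(NA_integer_)
  cherry_tips <- pt$tip.label[which(tip_parent == cherries[1])]
  pair <- names(leaves)[match(cherry_tips, leaves)]
  key <- paste(sort(pair), collapse = "")
  switch(key,
         "P1P2" = 1L, "OP3" = 1L,
         "P2P3" = 2L, "OP1" = 2L,
         "OP2" = 3L, "P1P3" = 3L,
         NA_integer_)
}

# exact topology weights by enumeration over the pruning oracle
oracle_weights <- function(tree, groups) {
  combos <- expand.grid(groups$P1, groups$P2, groups$P3, groups$O,
                        stringsAsFactors = FALSE)
  cls <- integer(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    lv <- c(P1 = combos[i, 1], P2 = combos[i, 2], P3 = combos[i, 3],
            O = combos[i, 4])
    cls[i] <- oracle_quartet(tree, lv)
  }
  dec <- sum(!is.na(cls))
  list(w = tabulate(cls, 3) / dec, n = nrow(combos),
       unresolved = sum(is.na(cls)))
}

# least-squares fit of each of the 3 quartet topologies to a 4x4 distance
# matrix (rows/cols ordered P1, P2, P3, O); returns argmin topology index
oracle_ls_quartet <- function(dm) {
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  y <- apply(pairs, 1, function(pr) dm[pr[1], pr[2]])
  design <- function(split) {
    # split: the sibling pair of tips (other two are siblings too);
    # columns: 4 terminal branches + internal branch
    A <- matrix(0, 6, 5)
    for (r in 1:6) {
      A[r, pairs[r, 1]] <- 1
      A[r, pairs[r, 2]] <- 1
      same_side <- all(pairs[r, ] %in% split) || all(!(pairs[r, ] %in% split))
      if (!same_side) A[r, 5] <- 1
    }
    A
  }
  rss <- vapply(list(c(1, 2), c(2, 3), c(2, 4)), function(split) {
    fit <- stats::lm.fit(design(split), y)
    sum(fit$residuals^2)
  }, numeric(1))
  which.min(rss)
}

# codon-table translation and first-stop scan, independent of Biostrings
oracle_codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(64)
  i <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    i <- i + 1
    codons[i] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

oracle_translate <- function(dna) {
  n <- nchar(dna) %/% 3
  aa <- character(n)
  for (i in seq_len(n)) {
    aa[i] <- oracle_codon_table[[substr(dna, 3 * i - 2, 3 * i)]]
  }
  paste(aa, collapse = "")
}

# offset (bp from CDS start to the stop codon's last base) of the first stop
# in a mutated CDS, by linear codon scan; NA if none before the last codon
oracle_stop_offset <- function(mut) {
  prot <- oracle_translate(mut)
  idx <- regexpr("*", prot, fixed = TRUE)
  if (idx < 1 || idx == nchar(prot)) return(NA_integer_)
  3L * as.integer(idx)
}

# type-7 quartiles by explicit order statistics (independent of quantile())
oracle_quartile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}
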