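# Local trees per window: pairwise-deletion distances, neighbor joining,
# quartet topology classification and topology weighting.
#
# The three quartet topologies of interest, indexed 1..3 throughout:
#   1 "species"       {P1,P2} | {P3,O}   expected across most of the genome
#   2 "introgression" {P2,P3} | {P1,O}   expected at the introgressed locus
#   3 "control"       {P2,O}  | {P1,P3}  negative control

TOPOLOGY_NAMES <- c("species", "introgression", "control")

#' Pairwise haplotype distances with pairwise deletion
#'
#' Proportion of differing alleles over sites where both haplotypes are
#' called; optional Jukes-Cantor correction `-(3/4) log(1 - (4/3) p)`.
#' Saturated pairs (p >= 0.75) under JC map to `max_dist` with a warning
#' rather than infinity.
#'
#' @param gm a [genotype_matrix()] (typically a window slice)
#' @param model "raw" (proportion) or "jc" (Jukes-Cantor)
#' @param cols haplotype columns to include (default all)
#' @param max_dist distance assigned to JC-saturated pairs (default 5)
#' @return symmetric numeric matrix with haplotype labels; attribute `model`.
#' @export
pairwise_distances <- function(gm, model = c("raw", "jc"), cols = NULL,
                               max_dist = 5) {
  model <- match.arg(model)
  if (is.null(cols)) cols <- seq_len(ncol(gm$geno))
  g <- gm$geno[, cols, drop = FALSE]
  if (ncol(g) < 2) stop("need at least 2 haplotypes")
  labs <- colnames(g)
  A <- n_alleles_of(gm)
  C <- (!is.na(g)) * 1
  N <- crossprod(C)
  M <- matrix(0, ncol(g), ncol(g))
  for (k in seq_len(A) - 1L) {
    Xk <- (!is.na(g) & g == k) * 1
    M <- M + crossprod(Xk, C - Xk)
  }
  off <- N == 0 & !diag(TRUE, ncol(g))
  if (any(off)) {
    ij <- which(off, arr.ind = TRUE)[1, ]
    stop("haplotype pair ", labs[ij[1]], " / ", labs[ij[2]],
         " has zero co-called sites")
  }
  p <- M / N
  diag(p) <- 0
  if (model == "jc") {
    sat <- p >= 0.75
    if (any(sat)) {
      warning(sum(sat) / 2, " saturated pair(s) set to max_dist = ", max_dist)
    }
    p <- ifelse(sat, max_dist, -0.75 * log(1 - 4 * p / 3))
    diag(p) <- 0
  }
  dimnames(p) <- list(labs, labs)
  attr(p, "model") <- model
  p
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via \pkg{ape}); negative branch
#' lengths are clamped to zero. Deterministic given the input label order.
#'
#' @param dm symmetric distance matrix with labels
#' @return an unrooted `phylo` tree
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3) stop("need at least 3 labels")
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# leaf-to-leaf patristic distance matrix
cophenetic_dist <- function(tree) {
  d <- ape::dist.nodes(tree)
  n <- length(tree$tip.label)
  d <- d[seq_len(n), seq_len(n)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# classify quartets by the four-point condition on patristic distances.
# a,b,c,d: leaf index vectors (P1,P2,P3,O). Returns integer 1..3 or NA
# (unresolved: the two smallest sums tie, i.e. zero-length internal branch).
classify_quartets <- function(dmat, a, b, c, d, tol = NULL) {
  s1 <- dmat[cbind(a, b)] + dmat[cbind(c, d)]  # {P1,P2}|{P3,O}
  s2 <- dmat[cbind(b, c)] + dmat[cbind(a, d)]  # {P2,P3}|{P1,O}
  s3 <- dmat[cbind(b, d)] + dmat[cbind(a, c)]  # {P2,O}|{P1,P3}
  S <- cbind(s1, s2, s3)
  if (is.null(tol)) tol <- 1e-10 * (1 + apply(S, 1, max))
  top <- max.col(-S, ties.method = "first")
  smin <- S[cbind(seq_len(nrow(S)), top)]
  nties <- rowSums(S <= smin + tol)
  ifelse(nties > 1L, NA_integer_, top)
}

#' Induced quartet topology for one haplotype per role
#'
#' Prunes the tree to the four chosen leaves and reports which of the three
#' unrooted quartet topologies is induced; a zero-length internal branch
#' yields `NA` (unresolved).
#'
#' @param tree a `phylo` tree
#' @param one_per_group named character vector with entries P1, P2, P3, O
#'   giving one leaf label each
#' @return integer 1 (species), 2 (introgression), 3 (control) or NA;
#'   names in `TOPOLOGY_NAMES` order.
#' @export
quartet_topology <- function(tree, one_per_group) {
  stopifnot(all(c("P1", "P2", "P3", "O") %in% names(one_per_group)))
  idx <- match(one_per_group[c("P1", "P2", "P3", "O")], tree$tip.label)
  if (anyNA(idx)) stop("chosen haplotypes are not all leaves of the tree")
  dmat <- cophenetic_dist(tree)
  classify_quartets(dmat, idx[1], idx[2], idx[3], idx[4])
}

#' Topology weighting of a local tree
#'
#' Decomposes a tree with multiple haplotypes per group into the fraction of
#' single-haplotype-per-group quartets inducing each of the three topologies.
#' The exact method enumerates all `prod(group sizes)` combinations;
#' `monte_carlo` samples combinations with replacement under `seed`. Weights
#' are normalized over decisive combinations; the unresolved count is
#' reported separately.
#'
#' @param tree a `phylo` tree
#' @param groups named list (`P1`, `P2`, `P3`, `O`) of leaf label vectors
#' @param method "exact" or "monte_carlo"
#' @param draws number of Monte-Carlo draws
#' @param seed RNG seed for Monte-Carlo (ambient RNG state is restored)
#' @return list of class `topology_weights`: `w` (named weights summing to 1
#'   over decisive combinations, NA if none decisive), `n_combinations`,
#'   `n_unresolved`, `method`.
#' @export
topology_weights <- function(tree, groups, method = c("exact", "monte_carlo"),
                             draws = 10000L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("P1", "P2", "P3", "O") %in% names(groups)))
  idx <- lapply(groups[c("P1", "P2", "P3", "O")], function(g) {
    i <- match(g, tree$tip.label)
    if (anyNA(i)) stop("group leaves missing from tree: ",
                       paste(g[is.na(i)], collapse = ", "))
    i
  })
  dmat <- cophenetic_dist(tree)
  if (method == "exact") {
    combos <- expand.grid(a = idx[[1]], b = idx[[2]], c = idx[[3]],
                          d = idx[[4]], KEEP.OUT.ATTRS = FALSE)
  } else {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      }
      set.seed(seed)
    }
    combos <- data.frame(a = sample(idx[[1]], draws, replace = TRUE),
                         b = sample(idx[[2]], draws, replace = TRUE),
                         c = sample(idx[[3]], draws, replace = TRUE),
                         d = sample(idx[[4]], draws, replace = TRUE))
  }
  cls <- classify_quartets(dmat, combos$a, combos$b, combos$c, combos$d)
  decisive <- sum(!is.na(cls))
  counts <- tabulate(cls, nbins = 3)
  w <- if (decisive > 0) counts / decisive else rep(NA_real_, 3)
  names(w) <- TOPOLOGY_NAMES
  structure(list(w = w, n_combinations = nrow(combos),
                 n_unresolved = sum(is.na(cls)), method = method),
            class = "topology_weights")
}

#' @export
print.topology_weights <- function(x, ...) {
  cat("<topology_weights> method:", x$method, "\n")
  print(round(x$w, 4))
  cat("combinations:", x$n_combinations, " unresolved:", x$n_unresolved, "\n")
  invisible(x)
}

#' Fraction of trees in which a leaf set is monophyletic
#'
#' A leaf union forms a clade when some bipartition of the unrooted tree
#' separates exactly that union from the rest; tested by rooting each tree at
#' a leaf outside the union.
#'
#' @param trees a list of `phylo` trees (or `multiPhylo`)
#' @param leaves character vector: the leaf union to test
#' @return fraction in [0, 1]
#' @export
monophyly_fraction <- function(trees, leaves) {
  hits <- vapply(trees, function(tr) {
    out <- setdiff(tr$tip.label, leaves)
    if (!length(out)) return(TRUE)
    rooted <- ape::root(tr, outgroup = out[1], resolve.root = TRUE)
    ape::is.monophyletic(rooted, leaves)
  }, logical(1))
  mean(hits)
}

#' Modal topology over windows and per-topology window fractions
#'
#' Per window, the argmax topology of its weights (ties or undefined weights
#' count as unresolved); fractions are over resolved windows. A majority
#' topology over windows is exact species-tree inference for the 4-group
#' case this pipeline targets.
#'
#' @param stats a `window_stats` data.frame carrying `w_species`,
#'   `w_introgression`, `w_control` (or a list of `topology_weights`)
#' @return list(topology = modal topology name, fractions = named fractions,
#'   n_windows, n_unresolved)
#' @export
majority_species_topology <- function(stats) {
  if (is.data.frame(stats)) {
    W <- as.matrix(stats[, c("w_species", "w_introgression", "w_control")])
  } else {
    W <- do.call(rbind, lapply(stats, function(x) x$w))
  }
  pick <- rep(NA_integer_, nrow(W))
  ok <- stats::complete.cases(W)
  if (any(ok)) {
    mx <- apply(W[ok, , drop = FALSE], 1, max)
    tie <- rowSums(W[ok, , drop = FALSE] == mx) > 1
    p <- max.col(W[ok, , drop = FALSE], ties.method = "first")
    p[tie] <- NA_integer_
    pick[ok] <- p
  }
  n_res <- sum(!is.na(pick))
  if (n_res == 0) stop("no window with decisive weights")
  frac <- tabulate(pick, nbins = 3) / n_res
  names(frac) <- TOPOLOGY_NAMES
  list(topology = TOPOLOGY_NAMES[which.max(frac)], fractions = frac,
       n_windows = nrow(W), n_unresolved = sum(is.na(pick)))
}

#' Write trees as Newick
#' @param trees list of `phylo` trees
#' @param path output path
#' @export
write_trees_newick <- function(trees, path) {
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Read Newick trees
#' @param path Newick file (one or more trees)
#' @return list of `phylo` trees
#' @export
read_trees_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- list(tr)
  tr
}
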