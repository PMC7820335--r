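# Programmatic fixtures: small genotype matrices, toy VCF text, and trees
# with known structure.

# genotype matrix from a raw allele-code matrix (rows = sites)
make_gm <- function(geno, samples = NULL, ploidy = 2L, chrom = "chr1",
                    pos = NULL, depth = NULL, is_indel = FALSE) {
  geno <- as.matrix(geno)
  if (is.null(samples)) {
    samples <- paste0("s", seq_len(ncol(geno) / ploidy))
    ploidy <- rep(ploidy, length(samples))
  }
  if (is.null(pos)) pos <- seq_len(nrow(geno))
  sites <- data.frame(chrom = chrom, pos = as.integer(pos), ref = "A",
                      alt = "T", is_indel = rep(is_indel, length.out = nrow(geno)),
                      stringsAsFactors = FALSE)
  genotype_matrix(sites, geno, samples, ploidy, depth)
}

# standard four-role map over sample prefixes p1_*, p2_*, p3_*, o_*
make_pm <- function(gm) {
  grp <- sub("_[0-9]+$", "", gm$samples)
  population_map(stats::setNames(grp, gm$samples),
                 roles = list(P1 = "p1", P2 = "p2", P3 = "p3", O = "o"))
}

# random four-group matrix: n_per = diploid individuals per group
random_role_gm <- function(seed, n_sites = 50, n_per = 1, miss_rate = 0.1) {
  set.seed(seed)
  samples <- as.vector(vapply(c("p1", "p2", "p3", "o"),
                              function(g) paste0(g, "_", seq_len(n_per)),
                              character(n_per)))
  n_hap <- 2L * length(samples)
  geno <- matrix(rbinom(n_sites * n_hap, 1L, runif(n_sites, 0.05, 0.95)),
                 nrow = n_sites)
  geno[matrix(runif(length(geno)) < miss_rate, nrow = n_sites)] <- NA_integer_
  make_gm(geno, samples = samples, ploidy = rep(2L, length(samples)))
}

write_toy_vcf <- function(records, samples, format = "GT") {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, vapply(records, function(r) {
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", format,
            r$gt), collapse = "\t")
  }, character(1))), path)
  path
}

# balanced species-arrangement tree: ((P1),(P2)) | ((P3),(O)), two
# haplotypes per group, all groups reciprocally monophyletic
sorted_tree <- function() {
  ape::read.tree(text = paste0(
    "(((p1a:0.1,p1b:0.1):0.4,(p2a:0.1,p2b:0.1):0.4):0.5,",
    "((p3a:0.1,p3b:0.1):0.6,(oa:0.1,ob:0.1):0.6):0.5);"))
}

sorted_groups <- list(P1 = c("p1a", "p1b"), P2 = c("p2a", "p2b"),
                      P3 = c("p3a", "p3b"), O = c("oa", "ob"))

# one P2 haplotype nests inside the P3 clade, everything else sorted
one_nested_tree <- function() {
  ape::read.tree(text = paste0(
    "(((p1a:0.1,p1b:0.1):0.4,p2a:0.5):0.5,",
    "((p2b:0.2,(p3a:0.1,p3b:0.1):0.1):0.5,(oa:0.1,ob:0.1):0.6):0.5);"))
}

# small CDS with a terminal stop, no internal stop, random interior
random_cds <- function(seed, n_codons = 60) {
  set.seed(seed)
  codons <- names(oracle_codon_table)
  interior <- codons[!(oracle_codon_table %in% "*") & codons != "ATG"]
  paste0("ATG", paste(sample(interior, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

# tiny default-design config scaled down for unit tests
small_sim_config <- function(seed, ...) {
  sim_config(seed = seed,
             chrom_lengths = stats::setNames(rep(2e6, 2), c("chr1", "chr2")),
             wp_locus = data.frame(chrom = "chr1", pos = 1e6), ...)
}
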