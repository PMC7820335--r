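# Forward simulation of the backcross-introgression breeding design over
# mosaic genomes with tracked ancestry.
#
# Model: lineage identity per site plus within-population frequency noise (a
# mosaic fixed-difference model, not a coalescent). Founder haplotypes carry
# the site alleles; bred haplotypes are piecewise references to founder
# haplotypes, recombined by Poisson crossovers without interference, so every
# emitted genotype and every ancestry tract is exact by construction.
#
# Crossing scheme (fully penetrant recessive null at the wp locus, phenotype
# = genotype): round 1 is the interspecific cross donor female x recipient
# male; each later round intercrosses two carrier siblings, selects a
# null-homozygous female, and backcrosses her to a fresh recipient male.
# `n_backcross` counts the crosses to the recurrent parent including the
# interspecific one, so the expected donor fraction of unlinked genome after
# breeding is 2^-n_backcross. The scheme is run as `n_lineages` parallel
# mother lineages descending from the same F1 brood; the final intercross
# pairs carriers from different lineages, which recovers a null-homozygous
# founding pair (the introgressed tract is homozygous by selection) while
# residual donor fragments elsewhere -- which serial sib intercrosses drive
# to homozygosity within a lineage -- are almost never shared between
# lineages and therefore stay heterozygous in the line. Sampled individuals
# are offspring of the founding pair; an optional `n_establish` phase of
# single-pair sib mating can be added to model post-founding drift.

#' Simulation configuration
#'
#' Defaults are the emulated study conditions; see the methods vignette for
#' the reasoning behind every value.
#'
#' @param seed RNG seed (mandatory; all stages derive their streams from it)
#' @param chrom_lengths named vector of chromosome lengths in bp
#' @param wp_locus data.frame (chrom, pos) of selected donor loci; one row in
#'   the standard design
#' @param fixed_diff_density per-bp density of fixed differences between
#'   recipient and donor lineages
#' @param outgroup_div_multiplier outgroup private fixed differences arise at
#'   `multiplier * fixed_diff_density`
#' @param polymorphism_density per-bp density of within-population
#'   polymorphic sites in the recipient and outgroup lineages
#' @param donor_polymorphism_density within-population polymorphism density
#'   of the donor strain; 0 by default (the donor is modelled as an isogenic
#'   long-inbred mutant laboratory strain, so the introgressed haplotype is
#'   unique)
#' @param shared_polymorphism_density per-bp density of ancestral
#'   polymorphisms segregating in all three ingroup lineages
#' @param freq_range range of the uniform allele-frequency distribution for
#'   polymorphic sites
#' @param crossover_rate Poisson mean crossovers per chromosome per meiosis
#' @param n_backcross crosses to the recurrent parent (including the
#'   interspecific cross); the classic design is 1 + five additional rounds
#' @param selection "homozygote": backcross mothers are selected wp null
#'   homozygotes from an intercross each round (the phenotype-selected
#'   scheme); "carrier": heterozygous carrier mothers
#' @param n_lineages parallel mother lineages bred from the F1 brood and
#'   merged at the final intercross (default 2)
#' @param brood_size offspring examined per cross before a retry
#' @param max_retries retries before a selection failure becomes an error
#' @param n_establish generations of single-pair sib mating after the final
#'   intercross; 0 by default (line maintenance at adequate population size,
#'   no post-founding drift)
#' @param n_seq_individuals sequenced diploid individuals per lineage
#' @param pool_specs list of pooled libraries, each `c(n = individuals,
#'   ploidy = haplotypes)`; ploidy must equal 2n
#' @param depth_mean Poisson mean sequencing depth per sample
#' @param genotype_error per-haplotype-call allele flip probability
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed,
                       chrom_lengths = stats::setNames(rep(1e7, 5),
                                                       paste0("chr", 1:5)),
                       wp_locus = data.frame(chrom = "chr1", pos = 5e6),
                       fixed_diff_density = 0.005,
                       outgroup_div_multiplier = 3,
                       polymorphism_density = 0.001,
                       donor_polymorphism_density = 0,
                       shared_polymorphism_density = 5e-4,
                       freq_range = c(0.1, 0.9),
                       crossover_rate = 1.5,
                       n_backcross = 6L,
                       selection = c("homozygote", "carrier"),
                       n_lineages = 2L,
                       brood_size = 50L,
                       max_retries = 20L,
                       n_establish = 0L,
                       n_seq_individuals = 2L,
                       pool_specs = list(c(n = 5, ploidy = 10)),
                       depth_mean = 30,
                       genotype_error = 0) {
  if (missing(seed)) stop("seed is mandatory")
  selection <- match.arg(selection)
  stopifnot(all(wp_locus$chrom %in% names(chrom_lengths)),
            all(wp_locus$pos >= 1),
            all(wp_locus$pos <= chrom_lengths[wp_locus$chrom]),
            fixed_diff_density >= 0, fixed_diff_density <= 1,
            polymorphism_density >= 0, polymorphism_density <= 1,
            shared_polymorphism_density >= 0,
            crossover_rate >= 0, n_backcross >= 1)
  for (ps in pool_specs) {
    if (ps[["ploidy"]] != 2 * ps[["n"]]) {
      stop("pool ploidy must be twice the number of pooled individuals")
    }
  }
  structure(list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths,
    wp_locus = wp_locus, fixed_diff_density = fixed_diff_density,
    outgroup_div_multiplier = outgroup_div_multiplier,
    polymorphism_density = polymorphism_density,
    donor_polymorphism_density = donor_polymorphism_density,
    shared_polymorphism_density = shared_polymorphism_density,
    freq_range = freq_range, crossover_rate = crossover_rate,
    n_backcross = as.integer(n_backcross), selection = selection,
    n_lineages = as.integer(n_lineages),
    brood_size = as.integer(brood_size), max_retries = as.integer(max_retries),
    n_establish = as.integer(n_establish),
    n_seq_individuals = as.integer(n_seq_individuals),
    pool_specs = pool_specs, depth_mean = depth_mean,
    genotype_error = genotype_error), class = "sim_config")
}

# ---------------------------------------------------------------- founders

#' Simulate founder haplotypes and the site table
#'
#' Places fixed recipient/donor differences by a Poisson process at the
#' configured density (derived on the donor or the recipient branch with
#' equal probability; the outgroup carries the ancestral state), outgroup
#' private fixed differences at `multiplier * density`, within-population
#' polymorphisms per lineage, and shared ancestral polymorphisms. The donor
#' lineage is fixed for the wp null allele at each configured wp locus.
#'
#' @param cfg a [sim_config()]
#' @param sites if FALSE, skip the site table and founder genotypes and
#'   return only the pedigree scaffolding (enough to run
#'   [breed_introgression_line()] and score ancestry tracts; much faster for
#'   large breeding batches)
#' @return list of class `sim_founders`: `sites` (site table with category
#'   and lineage frequencies), `geno` (sites x founder haplotypes), `hap_pop`
#'   (lineage of each founder haplotype), `individuals` (founder diploids and
#'   their roles), `cfg`
#' @export
simulate_founders <- function(cfg, sites = TRUE) {
  set.seed(cfg$seed)
  nb <- cfg$n_backcross
  # cross males (round 1 + one per later round per lineage) + sequenced + spare
  n_rec <- 1L + (nb - 1L) * cfg$n_lineages + cfg$n_seq_individuals + 2L
  n_don <- 1L + cfg$n_seq_individuals        # cross female + sequenced
  n_out <- cfg$n_seq_individuals
  ind <- data.frame(
    id = c(paste0("rec", seq_len(n_rec)), paste0("don", seq_len(n_don)),
           paste0("out", seq_len(n_out))),
    pop = c(rep("recipient", n_rec), rep("donor", n_don),
            rep("outgroup", n_out)),
    stringsAsFactors = FALSE)
  ind$hap1 <- seq_len(nrow(ind)) * 2L - 1L
  ind$hap2 <- seq_len(nrow(ind)) * 2L
  hap_pop <- rep(ind$pop, each = 2L)
  n_hap <- length(hap_pop)
  cols_of <- function(pop) which(hap_pop == pop)
  if (!sites) {
    return(structure(list(sites = NULL, geno = NULL, hap_pop = hap_pop,
                          individuals = ind, cfg = cfg),
                     class = "sim_founders"))
  }

  site_list <- list()
  for (ch in names(cfg$chrom_lengths)) {
    L <- cfg$chrom_lengths[[ch]]
    counts <- c(fixed = stats::rpois(1, L * cfg$fixed_diff_density),
                og = stats::rpois(1, L * cfg$fixed_diff_density *
                                    cfg$outgroup_div_multiplier),
                poly_recipient = stats::rpois(1, L * cfg$polymorphism_density),
                poly_donor = stats::rpois(1, L * cfg$donor_polymorphism_density),
                poly_outgroup = stats::rpois(1, L * cfg$polymorphism_density),
                shared = stats::rpois(1, L * cfg$shared_polymorphism_density))
    n_tot <- sum(counts)
    if (n_tot > L) stop("site densities exceed chromosome length")
    pos <- sample.int(L, n_tot)
    cat_vec <- rep(names(counts), counts)
    df <- data.frame(chrom = rep(ch, n_tot), pos = pos, category = cat_vec,
                     stringsAsFactors = FALSE)
    wp_here <- cfg$wp_locus[cfg$wp_locus$chrom == ch, , drop = FALSE]
    if (nrow(wp_here)) {
      df <- df[!(df$pos %in% wp_here$pos), , drop = FALSE]
      df <- rbind(df, data.frame(chrom = rep(ch, nrow(wp_here)),
                                 pos = as.integer(wp_here$pos),
                                 category = "wp_null",
                                 stringsAsFactors = FALSE))
    }
    df <- df[order(df$pos), , drop = FALSE]
    site_list[[ch]] <- df
  }
  sites <- do.call(rbind, site_list)
  rownames(sites) <- NULL
  ns <- nrow(sites)
  sites$donor_derived <- NA
  is_fixed <- sites$category == "fixed"
  sites$donor_derived[is_fixed] <- stats::runif(sum(is_fixed)) < 0.5
  sites$donor_derived[sites$category == "wp_null"] <- TRUE
  rfreq <- function(n) stats::runif(n, cfg$freq_range[1], cfg$freq_range[2])
  sites$p_recipient <- sites$p_donor <- sites$p_outgroup <- NA_real_
  for (pop in c("recipient", "donor", "outgroup")) {
    rows <- sites$category == paste0("poly_", pop) | sites$category == "shared"
    sites[[paste0("p_", pop)]][rows] <- rfreq(sum(rows))
  }

  geno <- matrix(0L, ns, n_hap)
  fill_bern <- function(rows, pop) {
    cols <- cols_of(pop)
    p <- sites[[paste0("p_", pop)]][rows]
    geno[rows, cols] <<- matrix(
      stats::rbinom(length(rows) * length(cols), 1L, rep(p, length(cols))),
      nrow = length(rows))
  }
  rows <- which(is_fixed & sites$donor_derived)
  geno[rows, cols_of("donor")] <- 1L
  rows <- which(is_fixed & !sites$donor_derived)
  geno[rows, cols_of("recipient")] <- 1L
  geno[which(sites$category == "wp_null"), cols_of("donor")] <- 1L
  geno[which(sites$category == "og"), cols_of("outgroup")] <- 1L
  for (pop in c("recipient", "donor", "outgroup")) {
    fill_bern(which(sites$category == paste0("poly_", pop)), pop)
  }
  sh <- which(sites$category == "shared")
  if (length(sh)) for (pop in c("recipient", "donor", "outgroup")) {
    if (pop == "donor" && cfg$donor_polymorphism_density == 0) {
      # isogenic donor strain: one draw per site, identical across haplotypes
      g1 <- stats::rbinom(length(sh), 1L, sites$p_donor[sh])
      geno[sh, cols_of("donor")] <- g1
    } else {
      fill_bern(sh, pop)
    }
  }
  structure(list(sites = sites, geno = geno, hap_pop = hap_pop,
                 individuals = ind, cfg = cfg),
            class = "sim_founders")
}

# ------------------------------------------------------------ tract algebra
# A haplotype is, per chromosome, list(starts = c(0, ...), ids = founder
# haplotype column per segment); segment i covers [starts[i], starts[i+1]).

founder_diplotype <- function(founders, ind_row) {
  mk <- function(hid) {
    lapply(founders$cfg$chrom_lengths, function(L) {
      list(starts = 0, ids = hid)
    })
  }
  list(h1 = mk(founders$individuals$hap1[ind_row]),
       h2 = mk(founders$individuals$hap2[ind_row]))
}

recombine_chrom <- function(hA, hB, L, rate) {
  k <- stats::rpois(1, rate)
  first <- if (stats::runif(1) < 0.5) 1L else 2L
  if (k == 0L) return(if (first == 1L) hA else hB)
  breaks <- sort(stats::runif(k, 0, L))
  B <- c(0, breaks, L)
  src <- list(hA, hB)
  cur <- first
  starts_out <- vector("list", length(B) - 1L)
  ids_out <- vector("list", length(B) - 1L)
  for (i in seq_len(length(B) - 1L)) {
    s <- B[i]; e <- B[i + 1L]
    h <- src[[cur]]
    j0 <- findInterval(s, h$starts)
    j1 <- findInterval(e, h$starts)
    if (h$starts[j1] == e) j1 <- j1 - 1L
    st <- h$starts[j0:j1]
    st[1] <- s
    starts_out[[i]] <- st
    ids_out[[i]] <- h$ids[j0:j1]
    cur <- 3L - cur
  }
  starts <- unlist(starts_out, use.names = FALSE)
  ids <- unlist(ids_out, use.names = FALSE)
  keep <- c(TRUE, ids[-1L] != ids[-length(ids)])
  list(starts = starts[keep], ids = ids[keep])
}

#' One meiosis: recombined gamete haplotype
#'
#' Per chromosome, draws `k ~ Poisson(crossover_rate)` breakpoints uniformly
#' and alternates the parental haplotypes starting from a fair-coin choice
#' (no crossover interference). Uses the ambient RNG stream.
#'
#' @param parent a diplotype `list(h1, h2)` of tract haplotypes
#' @param cfg a [sim_config()]
#' @return a gamete haplotype (per-chromosome tract list)
#' @export
meiosis <- function(parent, cfg) {
  out <- lapply(names(cfg$chrom_lengths), function(ch) {
    recombine_chrom(parent$h1[[ch]], parent$h2[[ch]],
                    cfg$chrom_lengths[[ch]], cfg$crossover_rate)
  })
  names(out) <- names(cfg$chrom_lengths)
  out
}

offspring_of <- function(mom, dad, cfg) {
  list(h1 = meiosis(mom, cfg), h2 = meiosis(dad, cfg))
}

hap_founder_at <- function(hap, chrom, x) {
  h <- hap[[chrom]]
  h$ids[findInterval(x, h$starts)]
}

# donor-allele dose (0/1/2) at every wp locus
wp_dose <- function(ind, cfg, hap_pop) {
  vapply(seq_len(nrow(cfg$wp_locus)), function(i) {
    ch <- cfg$wp_locus$chrom[i]
    x <- cfg$wp_locus$pos[i] - 0.5
    sum(hap_pop[hap_founder_at(ind$h1, ch, x)] == "donor",
        hap_pop[hap_founder_at(ind$h2, ch, x)] == "donor")
  }, numeric(1))
}

draw_selected <- function(mom, dad, cfg, hap_pop, predicate, need = 1L,
                          what = "selected offspring") {
  found <- list()
  for (r in seq_len(cfg$max_retries)) {
    for (i in seq_len(cfg$brood_size)) {
      o <- offspring_of(mom, dad, cfg)
      if (predicate(o)) {
        found[[length(found) + 1L]] <- o
        if (length(found) == need) return(found)
      }
    }
  }
  stop("selection failed: no ", what, " after ", cfg$max_retries,
       " broods of ", cfg$brood_size)
}

# ------------------------------------------------------------------ breeding

#' Breed the introgressed line
#'
#' Runs the recessive-selected backcross design and the line-establishment
#' phase, returning the final individuals with full ancestry tracts and the
#' truth set used to score locus recovery.
#'
#' @param cfg a [sim_config()]
#' @param founders a [simulate_founders()] result (generated from `cfg` if
#'   omitted)
#' @return list of class `sim_line`: `individuals` (final diplotypes),
#'   `truth` (ancestry tract table, per-individual and line-level homozygous
#'   wp tracts, donor genome fraction outside the selected chromosomes),
#'   `founders`, `cfg`
#' @export
breed_introgression_line <- function(cfg, founders = NULL) {
  if (is.null(founders)) founders <- simulate_founders(cfg)
  set.seed(cfg$seed + 1L)
  hp <- founders$hap_pop
  ind <- founders$individuals
  rec_rows <- which(ind$pop == "recipient")
  don_rows <- which(ind$pop == "donor")
  n_loci <- nrow(cfg$wp_locus)
  is_hom <- function(o) all(wp_dose(o, cfg, hp) == 2)
  is_carrier <- function(o) all(wp_dose(o, cfg, hp) >= 1)

  donor_female <- founder_diplotype(founders, don_rows[1])
  # round 1: interspecific cross to the first recipient male; the F1 brood
  # seeds every lineage, so all introgressed material funnels through it
  rec_male <- founder_diplotype(founders, rec_rows[1])
  lineages <- lapply(seq_len(cfg$n_lineages), function(k) {
    list(offspring_of(donor_female, rec_male, cfg),
         offspring_of(donor_female, rec_male, cfg))
  })
  next_male <- 2L
  if (cfg$n_backcross > 1L) for (r in 2:cfg$n_backcross) {
    for (k in seq_len(cfg$n_lineages)) {
      pair <- lineages[[k]]
      mother <- if (cfg$selection == "homozygote") {
        draw_selected(pair[[1]], pair[[2]], cfg, hp, is_hom,
                      what = "null-homozygous female")[[1]]
      } else {
        pair[[1]]  # carrier mother, no intercross
      }
      rec_male <- founder_diplotype(founders, rec_rows[next_male])
      next_male <- next_male + 1L
      lineages[[k]] <- draw_selected(mother, rec_male, cfg, hp, is_carrier,
                                     need = 2L, what = "carrier offspring")
    }
  }
  # final intercross across lineages: null-homozygous founding pair
  dam <- lineages[[1]][[1]]
  sire <- if (cfg$n_lineages > 1L) lineages[[2]][[1]] else lineages[[1]][[2]]
  pair <- draw_selected(dam, sire, cfg, hp, is_hom, need = 2L,
                        what = "null-homozygous founding pair")
  # line establishment: single-pair sib mating (all offspring homozygous)
  if (cfg$n_establish > 0L) for (g in seq_len(cfg$n_establish)) {
    pair <- list(offspring_of(pair[[1]], pair[[2]], cfg),
                 offspring_of(pair[[1]], pair[[2]], cfg))
  }
  n_final <- cfg$n_seq_individuals +
    sum(vapply(cfg$pool_specs, function(p) p[["n"]], numeric(1)))
  finals <- lapply(seq_len(n_final), function(i) {
    offspring_of(pair[[1]], pair[[2]], cfg)
  })
  truth <- line_truth(finals, cfg, hp)
  structure(list(individuals = finals, truth = truth, founders = founders,
                 cfg = cfg), class = "sim_line")
}

# ancestry projection of one haplotype on one chromosome
ancestry_runs <- function(h, L, hap_pop) {
  anc <- ifelse(hap_pop[h$ids] == "donor", "donor", "recurrent")
  keep <- c(TRUE, anc[-1L] != anc[-length(anc)])
  starts <- h$starts[keep]
  data.frame(start = starts, end = c(starts[-1L], L),
             ancestry = anc[keep], stringsAsFactors = FALSE)
}

# donor run containing x on one haplotype, or NULL
donor_run_at <- function(h, L, hap_pop, x) {
  runs <- ancestry_runs(h, L, hap_pop)
  hit <- runs$start <= x & x < runs$end & runs$ancestry == "donor"
  if (!any(hit)) return(NULL)
  runs[which(hit)[1], c("start", "end")]
}

line_truth <- function(finals, cfg, hap_pop) {
  tracts <- list()
  for (i in seq_along(finals)) {
    for (hname in c("h1", "h2")) {
      for (ch in names(cfg$chrom_lengths)) {
        runs <- ancestry_runs(finals[[i]][[hname]][[ch]],
                              cfg$chrom_lengths[[ch]], hap_pop)
        runs$individual <- i
        runs$hap <- hname
        runs$chrom <- ch
        tracts[[length(tracts) + 1L]] <- runs
      }
    }
  }
  tracts <- do.call(rbind, tracts)
  tracts <- tracts[, c("individual", "hap", "chrom", "start", "end",
                       "ancestry")]

  per_ind <- list()
  line_tract <- list()
  for (li in seq_len(nrow(cfg$wp_locus))) {
    ch <- cfg$wp_locus$chrom[li]
    L <- cfg$chrom_lengths[[ch]]
    x <- cfg$wp_locus$pos[li] - 0.5
    rows <- lapply(seq_along(finals), function(i) {
      r1 <- donor_run_at(finals[[i]]$h1[[ch]], L, hap_pop, x)
      r2 <- donor_run_at(finals[[i]]$h2[[ch]], L, hap_pop, x)
      if (is.null(r1) || is.null(r2)) return(NULL)
      data.frame(locus = li, individual = i, chrom = ch,
                 start = max(r1$start, r2$start),
                 end = min(r1$end, r2$end), stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    per_ind[[li]] <- rows
    if (!is.null(rows) && nrow(rows) == length(finals)) {
      line_tract[[li]] <- data.frame(
        locus = li, chrom = ch, start = max(rows$start), end = min(rows$end),
        stringsAsFactors = FALSE)
    }
  }
  per_ind <- do.call(rbind, per_ind)
  line_tract <- do.call(rbind, line_tract)

  wp_chroms <- unique(cfg$wp_locus$chrom)
  other <- setdiff(names(cfg$chrom_lengths), wp_chroms)
  tot_other <- sum(unlist(cfg$chrom_lengths[other]))
  frac <- vapply(seq_along(finals), function(i) {
    d <- 0
    for (hname in c("h1", "h2")) for (ch in other) {
      runs <- ancestry_runs(finals[[i]][[hname]][[ch]],
                            cfg$chrom_lengths[[ch]], hap_pop)
      d <- d + sum(runs$end[runs$ancestry == "donor"] -
                     runs$start[runs$ancestry == "donor"])
    }
    d / (2 * tot_other)
  }, numeric(1))

  list(tracts = tracts, wp_tract_individual = per_ind,
       wp_tract_line = line_tract, donor_fraction_outside = mean(frac),
       donor_fraction_outside_by_individual = frac)
}

# ------------------------------------------------------------- observations

#' Simulate a complete introgression data set
#'
#' Founders, breeding, and the observed genotype matrix (sequenced recipient,
#' introgressed-line, donor and outgroup individuals plus pooled libraries,
#' with Poisson depth) in one call.
#'
#' @param cfg a [sim_config()]
#' @return list of class `sim_dataset`: `gm` ([genotype_matrix()]), `pm`
#'   ([population_map()]), `truth`, `line`, `cfg`
#' @export
simulate_introgression_dataset <- function(cfg) {
  founders <- simulate_founders(cfg)
  line <- breed_introgression_line(cfg, founders)
  set.seed(cfg$seed + 2L)
  ns <- nrow(founders$sites)
  ind <- founders$individuals
  rec_rows <- which(ind$pop == "recipient")
  don_rows <- which(ind$pop == "donor")
  out_rows <- which(ind$pop == "outgroup")
  nseq <- cfg$n_seq_individuals
  # sequenced founder individuals: spare recipients (never crossed), the
  # donor individuals beyond the cross female, and the outgroup individuals
  rec_seq <- utils::tail(rec_rows, nseq)
  don_seq <- utils::tail(don_rows, nseq)
  out_seq <- utils::tail(out_rows, nseq)

  hap_geno <- function(hap) {
    out <- integer(ns)
    for (ch in names(cfg$chrom_lengths)) {
      rows <- which(founders$sites$chrom == ch)
      if (!length(rows)) next
      h <- hap[[ch]]
      fid <- h$ids[findInterval(founders$sites$pos[rows] - 0.5, h$starts)]
      out[rows] <- founders$geno[cbind(rows, fid)]
    }
    out
  }

  samples <- character(0); ploidy <- integer(0); group <- character(0)
  cols <- list()
  add_founder <- function(prefix, rows, grp) {
    for (k in seq_along(rows)) {
      samples <<- c(samples, paste0(prefix, k))
      ploidy <<- c(ploidy, 2L)
      group <<- c(group, grp)
      cols[[length(cols) + 1L]] <<-
        founders$geno[, c(ind$hap1[rows[k]], ind$hap2[rows[k]]),
                      drop = FALSE]
    }
  }
  add_founder("rec_", rec_seq, "recipient")
  for (k in seq_len(nseq)) {
    samples <- c(samples, paste0("line_", k))
    ploidy <- c(ploidy, 2L)
    group <- c(group, "introgressed")
    f <- line$individuals[[k]]
    cols[[length(cols) + 1L]] <- cbind(hap_geno(f$h1), hap_geno(f$h2))
  }
  next_ind <- nseq
  for (pi in seq_along(cfg$pool_specs)) {
    ps <- cfg$pool_specs[[pi]]
    members <- line$individuals[(next_ind + 1L):(next_ind + ps[["n"]])]
    next_ind <- next_ind + ps[["n"]]
    samples <- c(samples, paste0("line_pool", pi))
    ploidy <- c(ploidy, as.integer(ps[["ploidy"]]))
    group <- c(group, "introgressed")
    cols[[length(cols) + 1L]] <- do.call(cbind, lapply(members, function(f) {
      cbind(hap_geno(f$h1), hap_geno(f$h2))
    }))
  }
  add_founder("don_", don_seq, "donor")
  add_founder("out_", out_seq, "outgroup")

  geno <- do.call(cbind, cols)
  if (cfg$genotype_error > 0) {
    flip <- matrix(stats::runif(length(geno)) < cfg$genotype_error,
                   nrow = nrow(geno))
    geno[flip] <- 1L - geno[flip]
  }
  depth <- matrix(stats::rpois(ns * length(samples), cfg$depth_mean),
                  nrow = ns)
  sites <- data.frame(chrom = founders$sites$chrom,
                      pos = as.integer(founders$sites$pos),
                      ref = "A", alt = "T", is_indel = FALSE,
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(sites, geno, samples, ploidy, depth)
  pm <- population_map(stats::setNames(group, samples),
                       roles = list(P1 = "recipient", P2 = "introgressed",
                                    P3 = "donor", O = "outgroup"))
  structure(list(gm = gm, pm = pm, truth = line$truth, line = line,
                 cfg = cfg), class = "sim_dataset")
}

#' Write a simulated data set to disk
#'
#' VCF (GT + DP), sample map TSV, truth ancestry tracts BED (name field
#' `individual_hap_ancestry`; the line-level homozygous wp tract is included
#' with name `wp_homozygous_tract`), a config echo, and a manifest.
#' Deterministic given the dataset (byte-identical on rerun).
#'
#' @param dataset a [simulate_introgression_dataset()] result
#' @param dir output directory (created if needed)
#' @return the manifest as a named character vector of paths
#' @export
emit_observations <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             sample_map = file.path(dir, "sample_map.tsv"),
             truth_bed = file.path(dir, "truth_tracts.bed"),
             config = file.path(dir, "sim_config.txt"),
             manifest = file.path(dir, "manifest.txt"))
  write_vcf(dataset$gm, paths["vcf"])
  pm <- dataset$pm
  data.table::fwrite(data.frame(sample = names(pm$assignment),
                                group = unname(pm$assignment)),
                     paths["sample_map"], sep = "\t", col.names = FALSE)
  tr <- dataset$truth$tracts
  bed <- data.frame(chrom = tr$chrom, start = sprintf("%.0f", floor(tr$start)),
                    end = sprintf("%.0f", ceiling(tr$end)),
                    name = paste0("ind", tr$individual, "_", tr$hap, "_",
                                  tr$ancestry))
  wt <- dataset$truth$wp_tract_line
  if (!is.null(wt) && nrow(wt)) {
    bed <- rbind(bed, data.frame(chrom = wt$chrom,
                                 start = sprintf("%.0f", floor(wt$start)),
                                 end = sprintf("%.0f", ceiling(wt$end)),
                                 name = "wp_homozygous_tract"))
  }
  data.table::fwrite(bed, paths["truth_bed"], sep = "\t", col.names = FALSE,
                     quote = FALSE)
  cfg <- dataset$cfg
  cfg_lines <- vapply(names(cfg), function(nm) {
    paste0(nm, " = ", paste(utils::capture.output(dput(cfg[[nm]])),
                            collapse = " "))
  }, character(1))
  writeLines(c("# introscan simulation configuration", cfg_lines),
             paths["config"])
  writeLines(basename(paths[c("vcf", "sample_map", "truth_bed", "config")]),
             paths["manifest"])
  invisible(paths)
}

#' Donor-genome fraction outside the selected chromosomes
#'
#' Mean over a line's final individuals of the fraction of non-selected
#' chromosome genome that is donor-derived; the quantity whose expectation
#' under n halving crosses is `2^-n`.
#'
#' @param line a `sim_line` (or `sim_dataset`)
#' @export
donor_fraction_outside <- function(line) {
  if (inherits(line, "sim_dataset")) return(line$truth$donor_fraction_outside)
  line$truth$donor_fraction_outside
}
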