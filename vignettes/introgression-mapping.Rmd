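---
title: "Mapping an introgressed recessive locus with windowed divergence, f_d and topology weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping an introgressed recessive locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(introscan)
```

## The problem

A recessive visible mutation (here called *wp*, for the white-pupae
phenotype of tephritid fruit flies) is moved from a donor species into a
recipient species by repeated phenotype-selected backcrossing. After enough
rounds, the resulting introgressed line is genetically the recipient except
for a donor-derived chromosomal tract that must contain the causal gene.
Locating that tract with whole-genome resequencing of four lineages —
recipient (P1), introgressed line (P2), donor (P3) and an outgroup (O) —
turns a classical mapping cross into a comparative-genomics exercise:
wherever the line is "donor-like" while the rest of its genome is
"recipient-like", the causal locus must sit.

`introscan` implements that exercise end to end: windowed statistics,
local-tree topology weighting, concordance-based candidate extraction with
fine-scale refinement and homozygosity verification, coding-sequence
consequence annotation of candidate null mutations, and a forward simulator
of the breeding design that provides exact planted ground truth.

## Statistics

All statistics work on a sites-by-haplotypes genotype matrix
(`genotype_matrix()`), where a diploid contributes two columns and a pooled
library of five individuals genotyped at ploidy 10 contributes ten. Values
are averages per *genotyped site* (the VCF's sites), not per base pair;
every windowed quantity therefore shares a common scale within one data
set.

* **d_XY** (`dxy()`): Nei's absolute divergence, the mean probability that
  haplotypes drawn from two groups differ, `1 - sum_k x_k y_k` over allele
  frequency vectors, averaged over usable sites (both groups with at least
  one called haplotype). Monomorphic usable sites count in the denominator
  (`variant_only = TRUE` switches to variant sites only). This equals
  brute-force inter-group pair counting with per-site pairwise deletion.
* **pi** (`nuc_div()`): within-group diversity in the unbiased pairwise
  form `n/(n-1) * (1 - sum x_k^2)`, sites with >= 2 called haplotypes.
* **Patterson's D and f_d** (`fd_window()`): four-taxon site-pattern
  statistics on derived-allele frequencies. Polarization takes the
  ancestral allele as the outgroup's major allele (ties broken toward the
  reference allele); at multiallelic sites the remaining alleles are pooled
  with the ancestral state and the reduction is counted. The f_d
  denominator substitutes `pD = max(p2, p3)` for both P2 and P3 per site
  (the dynamic-donor form). Windows with negative D report `f_d = 0`, with
  the raw D kept alongside so the convention is auditable; windows with no
  informative site are undefined, never zero.
* **Topology weighting** (`topology_weights()`): each window's
  neighbor-joining tree (pairwise-deletion distances, optional
  Jukes-Cantor correction) is decomposed over all single-haplotype-per-group
  quartets into the fractions supporting
  species `{P1,P2}|{P3,O}`, introgression `{P2,P3}|{P1,O}` and the negative
  control `{P2,O}|{P1,P3}`. Classification uses the four-point condition on
  patristic distances; quartets whose two smallest sums tie (zero-length
  internal branch) are unresolved and are excluded from the weight
  denominator, with the unresolved count reported. Exact enumeration is the
  default; Monte-Carlo subsampling (`draws`, `seed`) is available for large
  trees.

Local trees are deliberately built by neighbor joining rather than by
likelihood tree search: the downstream consumer is the induced quartet
topology, for which NJ on short windows is deterministic, fast and
dependency-free. Externally built trees can be supplied as Newick
(`read_trees_newick()`) wherever a tree is consumed.

## From scans to a locus call

The mapping pipeline (`map_introgressed_locus()`) mirrors a three-test
concordance design:

1. **Coarse scan** of 100 kb tiled windows: d_XY for the pairs
   recipient/line, recipient/donor and line/donor, pi of the line, D/f_d,
   and topology weights.
2. **Candidate windows** pass `f_d > 0.75` *and* introgression weighting
   `> 0.75` (`candidate_windows()`), *and* show the d_XY discordance
   pattern (`dxy_discordance_flag()`): recipient/line divergence at
   interspecies level (`>= 0.75 x` the genome median of recipient/donor
   d_XY) while line/donor divergence collapses (`<= 0.25 x` its own genome
   median). The multiples operationalize a qualitative pattern and are
   configurable.
3. **Merging and refinement**: candidate windows merge across gaps of at
   most one coarse window (`merge_windows()`); each region is rescanned at
   10 kb (`refine_locus()`), and the envelope of fine windows passing the
   candidate thresholds is the locus's **maximum range** — the
   reproducible, algorithmic replacement for eyeballing a locus-scale scan.
4. **Narrowing to the homozygous core** (`narrow_locus()`): within the fine
   scan, windows must additionally be donor-fixed (fraction of
   donor-diagnostic sites — fixed differences between P1 and P3 — at which
   *every* called P2 haplotype carries the donor allele `>= 0.95`) and show
   line diversity `pi <= 0.001` per site. Partially introgressed shoulders,
   where the donor haplotype segregates above the 0.75 candidate threshold
   but below fixation, are thereby trimmed; disjoint fixed-donor blocks are
   reported as separate regions. This is the diversity-based narrowing
   step: the maximum range answers "how far could introgression reach", the
   core answers "what is fixed homozygous, as a recessive causal tract must
   be".
5. **Homozygosity verification** (`homozygosity_check()`) on each core
   block: `pi(P2) <= pi_max` and donor fixation `>= donor_fix_min`. The
   defaults (0.001 per site, 0.95) are calibrations chosen on simulated
   data, not empirical constants; 0.95 tolerates window-quantized edges,
   and 0.001 allows residual genotype noise while rejecting any region
   where even one sampled haplotype segregates.

Filtering before any of this follows fixed rules (`filter_genotypes()`):
genotypes with depth below 5 are set missing (sites without depth are not
penalized — the rule is a mask, not a requirement that depth exist), then
sites with more than 20% missing *haplotype columns* or any non-SNP allele
are dropped. Counting missingness over haplotype columns rather than
samples weights a ploidy-10 pool by its ten haplotypes; this is a choice
the package surfaces (see Limitations).

## The simulator

`sim_config()` / `simulate_introgression_dataset()` emulate the breeding
design forward in time, with exact tract bookkeeping instead of sequences:

* **Sites** arise by Poisson processes: fixed recipient/donor differences
  at density 5e-3 per bp (derived on either branch with equal probability;
  the outgroup carries the ancestral state), outgroup-private fixed
  differences at 3x that density, within-population polymorphism at 1e-3
  per bp for recipient and outgroup with allele frequencies uniform on
  [0.1, 0.9], and shared ancestral polymorphism at 5e-4 per bp segregating
  in all three ingroups (frequencies drawn per lineage). The shared class
  exists so that D and f_d are defined — and concentrate near zero —
  outside the donor tract; without it, windows outside the tract have no
  informative sites at all, which real data never show.
* **The donor strain is isogenic** (`donor_polymorphism_density = 0`): it
  stands for a long-inbred mutant laboratory stock, so the introgressed
  haplotype is unique and the fixed tract has exactly zero internal
  diversity. Setting the density above zero restores donor polymorphism if
  wanted.
* **Meiosis** draws Poisson(1.5) crossovers per chromosome (10 Mb default,
  i.e. 1.5 Morgans), placed uniformly, without interference. Haplotypes are
  piecewise references to founder haplotypes, so genotypes and ancestry
  tracts are exact at every generation.
* **The crossing scheme**: round 1 is the interspecific cross donor female
  x recipient male; each later round intercrosses two carrier siblings,
  selects a null-homozygous female (phenotype equals genotype for a fully
  penetrant recessive), and backcrosses her to a fresh recipient male.
  `n_backcross = 6` counts the crosses to the recurrent parent including
  the interspecific one, so unlinked donor ancestry is halved six times:
  the expected residual donor fraction outside the selected chromosome is
  `2^-6 ~ 1.6%`, which the test suite verifies over hundreds of simulated
  lines.
* **Two parallel mother lineages** (`n_lineages = 2`) run the scheme
  independently from the same F1 brood and merge at the final intercross.
  This matters: serial sib intercrosses drive residual donor fragments to
  homozygosity *within* a lineage, but the same fragment is almost never
  retained in both lineages, so in the founded line residual donor
  segregates heterozygously — it shows up in the scans (correctly) as
  discordant but fails the homozygosity tests, exactly the behavior that
  lets homozygosity single out the causal tract. A single-lineage run
  (`n_lineages = 1`) instead fixes residual fragments and produces
  additional genuinely-homozygous donor blocks.
* **Line establishment**: the final intercross yields a null-homozygous
  founding pair whose offspring are sampled (2 sequenced individuals and a
  pool of 5 at ploidy 10, with Poisson(30) depth). By default no
  post-founding drift is modelled (`n_establish = 0`), representing
  maintenance at a population size large enough that frequencies at
  sampling match founding frequencies; `n_establish > 0` adds generations
  of single-pair sib mating, which progressively fixes residual donor
  fragments and is useful to study that regime.
* Brood size 50 and up to 20 retries per selection step are practical
  defaults for the selection searches; they do not affect expectations.

The simulated truth (`$truth`) records every ancestry tract, the
per-individual and line-level homozygous donor tract around the selected
locus (the intersection over final individuals), and the realized donor
fraction outside the selected chromosomes.

### What the simulator does and does not emulate

It reproduces the statistical structure the pipeline consumes: interspecies
divergence contrasts, a fixed donor tract with sharp frequency boundaries,
segregating residual donor, pooled genotypes, depth-dependent missingness.
It does **not** model coalescent genealogies (no incomplete lineage sorting
beyond the crude shared-polymorphism class), mutation after the cross,
genotyping error (available as an optional flip probability, default 0),
crossover interference, sex chromosomes, or reference/alignment artifacts.
Passing tests on simulated data therefore demonstrate correctness of the
statistics and of the locus logic under the breeding design's genetics; they
do not certify robustness to misalignment, repeat content or callable-site
heterogeneity in real resequencing data.

## Numerical and procedural choices

* Coordinates: VCF positions are stored 1-based; all windows are half-open
  0-based (BED convention). "Tiled" windows are adjacent and
  non-overlapping; a `step` argument exists for overlapping schemes.
* Jukes-Cantor saturation (`p >= 0.75`) maps to a configurable large
  distance (default 5) with a warning, never infinity.
* NJ negative branch lengths are clamped to zero; quartets are classified
  with a relative tolerance of `1e-10` on the four-point sums, so
  clamped-to-zero internal branches register as unresolved.
* Undefined statistics are `NA` with a reason where the cause is
  informative ("no informative sites" vs "missing role frequencies");
  undefined values never pass a threshold.
* The d_XY discordance medians require at least 10 windows genome-wide;
  fewer is an error rather than a silent unreliable baseline.
* All simulator stages derive their RNG streams from one mandatory seed
  (`seed`, `seed + 1`, `seed + 2` for founders, breeding and observation
  noise), so a configuration is a complete recipe for a bit-identical data
  set.
* Test and acceptance problem sizes: unit tests run on reduced genomes
  (two 2-3 Mb chromosomes, 50/5 kb windows); the acceptance suite runs the
  full 5 x 10 Mb design at 100/10 kb windows over 20 replicates, 500
  light-weight breeding replicates for the backcross expectation, 200
  random matrices against the brute-force oracles, and 1000 random
  CDS/deletion cases against an independent translator. These sizes are the
  package's own choices for a thorough yet routine check.

## Limitations and open choices

* Missingness is counted over haplotype columns; whether a pooled library
  should instead count as one sample is unresolved in the field, so the
  choice is documented and easily changed (`filter_sites()` operates on the
  matrix, not on samples).
* Pool columns are treated as called haplotypes throughout; no
  allele-frequency-from-read-counts model is implemented.
* d_XY/pi averages are per genotyped site. Comparisons against per-bp
  values from other tools require rescaling by the genotyped-site density.
* No block-jackknife significance testing for D/f_d: the design thresholds
  f_d rather than testing it.
* The boundary precision of the locus call is one fine window by
  construction; sub-window precision would require haplotype-level
  breakpoint inference, which is out of scope.
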