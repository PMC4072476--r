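# mhclineage

Tools for studying the long-term evolution of allelic lineages at
classical MHC loci (such as *HLA-DRB1*) from aligned complete coding
sequences.

MHC genes are the most polymorphic loci in vertebrate genomes. Balancing
selection on the peptide-binding region (PBR) keeps dozens of allelic
lineages segregating so long that their splits predate speciation events
— the hallmark of trans-species polymorphism. Two questions drive the
analyses in this package: **how old** is a group of allelic lineages,
and **how many ancestral lineages** does a present-day sample trace back
to?

## What the package computes

For an aligned, in-frame allele set (multi-FASTA, IMGT-style names such
as `HLA-DRB1*03:01`):

* **Recombinant screening** — for each allele pair, sliding windows at
  geometrically growing sizes are tested for an excess of the pair's
  nucleotide differences with the exact binomial tail
  `P = Σ_{i=m}^{n} C(n,i) p^i (1−p)^{n−i}`, `p = l/L`; alleles flagged
  against ≥ 2 partners are removed.
* **Codon-level distances** — pairwise *d*<sub>S</sub> and
  *d*<sub>N</sub> by the modified Nei–Gojobori method (transition bias
  κ weighting in site counting, pathway-averaged difference counting)
  with the Jukes–Cantor correction `d = −(3/4) ln(1 − 4p/3)`.
* **Divergence dating** — the neutral synonymous clock
  `T = d_S / (2μ)` with μ = 10⁻⁹ substitutions/site/year by default:
  mean within-group *d*<sub>S</sub> dates the average allelic split,
  *d*<sub>Smax</sub> dates the group's TMRCA.
* **Synonymous-site compatibility** — segregating synonymous sites are
  classified (singleton vs parsimony-informative) and every informative
  pair is run through the four-gamete test; incompatible pairs reveal
  recurrent mutation or recombination.
* **Parsimony recount** — synonymous substitutions are placed on a
  supplied tree by Fitch parsimony and re-counted along tree paths
  (*K*<sub>S</sub>); `TMRCA = (K_Smax / L_S) / (2μ)` recovers multiple
  hits independently of the Jukes–Cantor correction.
* **Ancestral lineage probabilities** — the coalescent ancestral
  process g<sub>nk</sub>(t), the probability that *n* sampled lineages
  descend from exactly *k* ancestors at scaled time *t*.
* **Synthetic data** — a codon simulator with transition bias,
  region-specific selection (elevated ω in a PBR mask), optional
  infinite-sites mode and splice recombinants, with full ground truth
  recorded for every branch.

All results are tibbles or carry `tidy()` / `glance()` methods, and the
main result types have `autoplot()` methods.

## Worked example

Simulate a 31-allele set under the package's default study conditions
(257 codons, 27-codon PBR mask with ω ≈ 10, background ω = 0.5,
κ = 2, deepest synonymous divergence ≈ 0.08), label the two clades
descending from the root as groups, and run the full pipeline:

```r
library(mhclineage)

sim     <- simulate_alleles(sim_config(seed = 20))
tr      <- sim$truth$tree
kids    <- tr$edge[tr$edge[, 1] == length(tr$tip.label) + 1, 2]
tips_of <- function(node) {
  if (node <= length(tr$tip.label)) tr$tip.label[node]
  else ape::extract.clade(tr, node)$tip.label
}
groups <- c(setNames(rep("A", length(tips_of(kids[1]))), tips_of(kids[1])),
            setNames(rep("B", length(tips_of(kids[2]))), tips_of(kids[2])))

run <- run_pipeline(sim$alleles, tree = tr, groups = groups,
                    mask = default_pbr_mask(offset = 29), kappa = 2)
run
#> <lineage_run>
#>   screen: 0 allele(s) removed
#>   alleles analysed: 31 x 690 nt
#>   group A: mean dS 0.0138 (T ~ 7 MYA), dS max 0.03395 (TMRCA ~ 17 MYA)
#>   group B: mean dS 0.02686 (T ~ 13 MYA), dS max 0.05138 (TMRCA ~ 26 MYA)
#>   synonymous-site compatibility: 20 informative, 190 pairs, 0 incompatible
#>   parsimony recount: KSmax 15, TMRCA ~ 41 MYA
```

Reading the report: the PBR mask leaves a 690-nt background alignment;
no allele pair shows the clustered-difference signature of
recombination; each group's mean synonymous divergence and its maximum
convert to an average allelic age and a TMRCA under the 10⁻⁹ clock; the
20 informative synonymous sites are mutually compatible with a single
tree (the simulation used one); and re-counting synonymous changes along
the tree paths gives the path-based TMRCA, which exceeds the pairwise
estimates exactly when parallel/back substitutions hide divergence from
direct comparison.

The dating table itself:

```r
tidy(run)[, c("group", "n_alleles", "dS_mean", "T_mya", "dS_max", "TMRCA_mya")]
#> # A tibble: 2 × 6
#>   group n_alleles dS_mean T_mya dS_max TMRCA_mya
#>   <chr>     <int>   <dbl> <dbl>  <dbl>     <dbl>
#> 1 A            15  0.0138     7 0.0340        17
#> 2 B            16  0.0269    13 0.0514        26
```

How plausible is it that at least 7 ancestral lineages persist in a
sample of 31 alleles at scaled time 0.25?

```r
ld <- lineage_distribution(31, 0.25)
ld[ld$k %in% 6:8, ]
#> # A tibble: 3 × 5
#>       n     t     k probability p_at_least
#>   <int> <dbl> <int>       <dbl>      <dbl>
#> 1    31  0.25     6       0.251      0.797
#> 2    31  0.25     7       0.264      0.546
#> 3    31  0.25     8       0.177      0.283
```

`p_at_least` for k = 7 answers the persistence question directly
(here ≈ 0.55).

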