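---
title: "Dating and dissecting MHC allelic-lineage divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating and dissecting MHC allelic-lineage divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhclineage)
```

## The scientific problem

Classical MHC loci such as *HLA-DRB1* are the most polymorphic genes in
vertebrate genomes. Balancing selection on the peptide-binding region
(PBR) keeps many allelic lineages segregating for tens of millions of
years, long enough that lineages are shared across species boundaries
(trans-species polymorphism). Asking *how old* a group of allelic
lineages is, and *how many* ancestral lineages a present-day sample
traces back to, therefore probes the history of host–pathogen
coevolution directly.

`mhclineage` implements the full analysis chain for such questions on
aligned complete coding sequences:

1. **Recombinant screening.** Alleles assembled by recombination or gene
   conversion violate the tree assumptions of everything downstream and
   are removed first.
2. **Region masking.** The PBR evolves under balancing selection with a
   roughly ten-fold elevated nonsynonymous rate; it is excluded before
   any clock-based inference so that dating reads only neutrally
   evolving sequence.
3. **Codon-level distances.** Pairwise synonymous (dS) and
   nonsynonymous (dN) distances by the modified Nei–Gojobori method with
   a Jukes–Cantor correction.
4. **Divergence dating.** Mean within-group dS dates the average
   allelic split, the maximum pairwise dS (dSmax) dates the group's
   most recent common ancestor: `T = dS / (2 mu)` with `mu` the neutral
   rate per site per year (default `1e-9` for MHC loci).
5. **Synonymous-site compatibility.** Segregating synonymous sites are
   classified (singleton / parsimony-informative) and all informative
   pairs are run through the four-gamete test; incompatible pairs
   betray recurrent mutation or recombination, both of which bias naive
   distance-based dating.
6. **Parsimony recount.** Synonymous substitutions are placed on a
   supplied tree by Fitch parsimony; re-counting substitutions along
   tree paths (KS) recovers parallel and back changes that pairwise
   comparison conflates, giving a second, correction-free TMRCA
   estimate `(KSmax / LS) / (2 mu)` to cross-check the Jukes–Cantor
   one.
7. **Ancestral lineage counts.** The coalescent probability g_nk(t)
   that n sampled lineages descend from exactly k ancestors at scaled
   time t, for lineage-persistence arguments.

A codon-level simulator with recorded ground truth backs every stage,
so the whole chain is testable without any database download.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `mu` | `1e-9` | substitutions/site/year | commonly used neutral rate at MHC loci; all times scale as `1/mu` |
| `kappa` | 1 | rate ratio | transition/transversion bias in site counting; 1 recovers classic Nei–Gojobori, `estimate_kappa()` provides a third-position moment estimate when no ML estimate is at hand |
| PBR mask | 27 codons | mature-protein codon numbers | 24 commonly cited DR beta-chain contact residues plus 57/67/90; shipped as an editable text file because contact-residue definitions vary |
| mask `offset` | 29 | codons | DRB1 precursors carry a 29-residue signal peptide; mask coordinates are mature-protein numbers |
| screen `window`, `step` | 30, 5 | codons | base scan scale (about one exon-2 length); the scan also runs at doubled sizes, see below |
| screen `alpha` | 0.01 | — | per-pair significance after Šidák correction |

## Design choices made where the method family is genuinely open

**Window scheme of the recombinant screen.** The regional clustering
test assumes that, under uniform scatter, the share of a pair's
differences inside a region of length `l` is binomial with `p = l/L`;
the exact upper tail is the test statistic. A spliced segment can be
anything from a short conversion tract to half the gene, so a single
window size has essentially no power against splices much longer than
itself. The scan therefore runs at geometrically growing sizes
(`window`, `2*window`, ... while smaller than the alignment), each
sliding with a proportionally scaled step and always including the
final 3'-placement.

**Multiple-testing correction.** Overlapping windows are strongly
dependent, so a Šidák correction over the raw window count is badly
conservative, while correcting only over disjoint windows is
anti-conservative. Windows sharing more than half their span carry
largely redundant information, so the correction counts windows at
half-overlap spacing per size (`2C/size`, capped at the actual count)
and sums over sizes. Null simulations (uniformly scattered differences,
1,000 pairs) put the realized per-pair false-positive rate close to the
nominal `alpha`; the test suite re-runs that calibration.

**Per-allele removal rule.** A window flag names a *pair*, not a
culprit. A true recombinant clusters differences against **both**
parental lineages, so an allele is removed only when flagged against at
least two distinct partners. This avoids discarding both members of
every flagged pair.

**Mask before screen.** The pipeline applies the PBR mask before
screening. The balancing-selection hotspot concentrates perfectly
ordinary substitutions into a 27-codon span — exactly the spatial
signature the clustering test hunts for — and screening unmasked MHC
sequence flags most allele pairs. On the masked (neutral) alignment the
screen retains its calibrated behaviour.

**Stop codons in the Nei–Gojobori machinery.** Potential changes that
would create a stop are counted as nonsynonymous in site counting;
mutational pathways through a stop are excluded from pathway averaging;
if every ordering is blocked, the differing positions are classified
independently in the first codon's context. This matches common NG
implementations.

**Site denominators and missing data.** Potential-site totals use the
average of the two sequences (per the original method); codons
containing `-` or `N` in either sequence of a pair are deleted
pairwise, maximizing usable pairs in ragged allele sets. Saturated
pairs (`p >= 3/4`) are reported as errors, never silently clipped.

**Segregating-site effect calls.** A column is called synonymous only
if every observed state leaves the amino acid unchanged in *every*
sequence's own codon context; columns synonymous in some backgrounds
only are labelled `mixed` and kept out of the synonymous tally — a
conservative rule for exactly the sites that feed the compatibility
test and the parsimony recount. Columns with more than two states are
excluded from the four-gamete test (which is defined for biallelic
sites) and reported separately.

**Fitch tie handling.** The top-down pass keeps the parent's state
whenever it lies in the child's first-pass state set and otherwise
takes a fixed (alphabetical) choice, charging the change to that
branch. Branch-level attribution differs among equally parsimonious
reconstructions, but per-site change totals — the only quantity the KS
recount consumes — are invariant, and the tests assert exactly those
invariants (including against an exhaustive-labeling oracle and an
independent parsimony engine).

**Rounding of reported times.** Human-readable tables round to whole
million years, half away from zero (so 28.5 prints as 29 MYA and 20.5
as 21 MYA); machine outputs always carry raw years.

**g_nk numerics.** The ancestral-process probability is an alternating
series whose terms grow combinatorially with `n`. It is evaluated
through log-gamma with compensated (Kahan) summation; when the largest
term exceeds `1e3`, cancellation would cap absolute accuracy below the
`1e-9` normalization contract, and the implementation switches to
uniformization of the coalescent death chain (a Poisson mixture of
powers of a substochastic operator — all-nonnegative arithmetic, stable
at any `t`). Above `n = 64` an error is raised rather than returning
unstable values. Because the effective size of a balanced allelic
subpopulation is generally unknown, time is exposed in scaled
coalescent units with a single user-supplied `scale` conversion rather
than asserting any `Ne`.

## What the simulator does and does not emulate

`simulate_alleles()` evolves a random in-frame ancestral sequence down
a tree. Proposals arrive at rate `3 x codons` per unit branch length
with a transition bias `kappa`; synonymous proposals are always
accepted, which calibrates branch lengths in expected synonymous
substitutions per synonymous site (a two-leaf tree with branch lengths
0.01 yields dS near 0.02, and the tests verify recovery within 10%).
Selection is a deliberately simple stand-in: nonsynonymous proposals
are thinned with probability `min(1, omega)`, and `omega > 1` regions
receive a second, nonsynonymous-only proposal stream at rate
`omega - 1`, leaving the synonymous clock untouched. Stop-creating
changes are rejected; `infinite_sites = TRUE` forbids repeat hits per
column, producing homoplasy-free data on which the parsimony map must
recover the recorded truth exactly. Splice recombinants are constructed
from simulated tips post hoc.

Defaults mirror the data regime the analyses target: 31 alleles of 257
codons, a 27-codon PBR mask (so the unmasked background spans 690 nt),
maximum synonymous divergence near 0.08, `kappa = 2`, background
`omega = 0.5` and PBR `omega = 10`.

The simulator is **not** a full codon model: no codon-frequency or
dN/dS covariance structure, no rate heterogeneity beyond the mask, no
coalescent-with-selection genealogy (tree shape is an input), and no
indels. Passing tests demonstrate the algorithms' correctness on data
satisfying their assumptions; they do not certify behaviour on real
alignments with alignment error, intron-phase artifacts or partial
sequences.

## Problem sizes used by the test suite

The suite exercises every operation at sizes chosen to make the
statistics sharp but cheap: all 3,721 sense-codon pairs against a
pathway-enumeration oracle; 1,000 random trees of up to six leaves
against exhaustive internal labelings; a 100,000-replicate Monte-Carlo
coalescent for g_nk at `n = 10, t = 0.5`; 1,000 uniform-scatter null
pairs for screen calibration; and 10,000-codon two-leaf simulations for
distance recovery. The complete run takes well under a minute per
suite on a single core.

## Known limitations

* The screen names windows and pairs, not breakpoints; tract-length
  inference and quartet-based recombination detection are out of scope.
* Dating carries no confidence intervals and assumes a strict clock;
  `mu` enters linearly, so alternative rates rescale all times.
* The compatibility test reduces multi-allelic sites to their two major
  states rather than modelling them.
* Trees are consumed, never inferred; group labels are user-supplied
  (an ML tree's clade structure is the natural source).
* Results on IMGT/IPD data depend on the database release; the package
  makes the computation reproducible, not the archive.
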