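---
title: "Classifying germline and somatic variation in multigene-family amplicon clones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying germline and somatic variation in multigene-family amplicon clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliclone)
```

## The problem

Antimicrobial-peptide gene families in bivalves — the motivating case is
myticin-C in the Mediterranean mussel — can show extreme sequence
variability in cloned amplicons: tens of distinct sequences per
individual, far more than a diploid with one or two gene copies could
carry in its germline. ampliclone implements the inference chain needed
to decompose that variability into three layers:

1. **Germline ("basic") sequences** — the 1–3 heritable variants an
   individual actually carries across two tandemly duplicated loci.
2. **Somatic point mutations** — single-nucleotide differences between a
   cloned sequence and its basic sequence, presumed to arise in somatic
   cells.
3. **Somatic recombinants** — chimeric clones stitched together from two
   (occasionally three) basic sequences.

Separating the layers matters because evolutionary statistics computed
on raw clone samples conflate somatic noise with heritable
polymorphism. The package therefore computes every diversity table twice
— for the whole clone sample and for the basic sequences only — and the
two views are first-class throughout.

## Classification model and its assumptions

For one individual with clones aligned over the coding region, the
procedure (`infer_basic_sequences()`) is greedy-iterative:

1. Collapse clones into exact haplotypes (gap columns ignored; `N` is
   missing data with a 5% per-clone cap).
2. Seed the basic set with the most frequent haplotype.
3. Repeatedly promote the haplotype farthest (Hamming distance) from all
   current basics, provided its distance is at least `tau`, its clone
   support at least `min_support`, and it is not explainable as a
   chimera of the current basics.
4. Assign every clone to its nearest basic; residual differences become
   somatic variant candidates. Clones tied between basics, or farther
   than `max_residual` from every basic, are flagged ambiguous and
   excluded from every rate denominator — ambiguity is reported, never
   auto-resolved.

Recombinant detection (`detect_recombinants()`) labels the clone's state
at each informative site (a site where the individual's basics differ)
by donor basic and asks whether the labels segment into 2 or 3 runs,
each supported by at least `min_run` sites, attributed to different
donors, with at most `max_mismatch` leftover sites — which become
somatic variant candidates on the recombinant — and strictly fewer
leftovers than the best single-donor explanation. The search over cuts
and ordered donor tuples is exhaustive, so the reported segmentation is
the minimal-mismatch one with the fewest segments.

Key assumptions: clones are high-quality double-strand consensus reads
(sequencing error is not modelled separately from somatic mutation);
within-individual germline variants are far more divergent than the
somatic layer; and a chimera is rarer than a point mutation, so a
single-site donor switch is always read as a mutation.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `tau` | 3 | nt | a haplotype 1–2 sites from a basic is more parsimoniously 1–2 somatic mutations, since clones carry 1–3 substitutions |
| `min_support` | 2 | clones | a singleton haplotype cannot be distinguished from a mutated clone; corroboration by the individual's gDNA can justify lowering it to 1 |
| `min_run` | 2 | informative sites | a one-site switch is indistinguishable from a point mutation at an informative site |
| `max_breakpoints` | 2 | breakpoints | observed chimeras involve two, at most three, donors |
| `max_mismatch` | 2 | sites | a chimera explanation requiring more discounted sites than a plausible mutation load is rejected; at 3 a genuinely divergent third germline sequence can still admit a spurious two-segment explanation in the two-clade geometry, so 2 is the default |
| `max_residual` | 3 | nt | clones farther than this from every basic (e.g. clones of an under-sampled germline variant) are ambiguous, not force-assigned |

`somatic_mutation_rate()` divides total variant candidates by clones ×
coding sites. By default recombinant clones contribute their residual
variants and their share of the denominator; `include_recombinants =
FALSE` removes them from both, since whether a published substitution
count includes variants carried on recombinants is often unstated. On
the benchmark dataset the two conventions give 30/27900 and 30/26100 —
both round to 1.1e-3.

`recombination_rate()` reports the mean per-individual recombinant
fraction with its standard error. The optional detectability correction
divides each individual's rate by the probability that a recombinant
with a uniformly placed breakpoint is callable: the breakpoint must
leave at least `min_run` informative sites on both sides and at least
one donor-differing site on each side, averaged over donor pairs
weighted by basic support (support tracks gene-copy multiplicity in
expectation), with the ambiguous-clone count standing in for the mass
of germline copies that were never recovered (a recombinant sourced
from or donated by such a copy is uncallable). The raw fraction is the
default report; the corrected one is the right comparator when the
underlying per-clone recombination probability itself is of interest,
and it is what the simulation-recovery tests check.

## Diversity and neutrality statistics

`popgen` functions are deliberately formula-level implementations:
segregating sites with singleton/parsimony-informative classification,
per-site pi (complete deletion by default, pairwise optional),
Watterson's theta as S/(a1·L), haplotype diversity with the n/(n−1)
correction, Tajima's D from (S, n, mean pairwise differences), Fu and
Li's D in the star (D*, default — samples of clones contain no
outgroup) and outgroup-polarized variants, the Hudson–Kaplan
four-gamete Rm with interval disjointing, and a Nei–Gojobori (1986)
pathway-counting Ka/Ks with Jukes–Cantor correction. The counting omega
is a descriptive companion, not a site-model estimate; values from
likelihood site models are not comparable and are out of scope.

Numerical choices: sites with gaps are handled per-site for S and by the
deletion policy for pi; statistics are undefined (flagged, not errored)
at S = 0; Rm uses only biallelic sites; ties in haplotype ordering
resolve by descending count then lexicographic sequence. Every D
statistic is cross-checked in the tests against an independent literal
transcription of the published formulas, and Rm against exhaustive
minimization for up to 10 segregating sites.

## Fragment-analysis and family modules

Intron size peaks are counted with the peak-counting convention (each
distinct peak in an individual contributes one count), the convention
forced on any study that cannot assign alleles to loci; it slightly
underestimates common-allele frequencies, which the tests verify by
simulation. Gene diversity uses the Nei unbiased estimator. The minimum
locus number is ceil(max peaks / 2). The expected proportion of
four-allele individuals under two duplicated loci drawing from one
shared pool is He²: this single-pool independence model reproduces all
four printed expectations in the motivating study from its printed gene
diversities, which is why it was adopted; whether the He inside the
square should itself be bias-corrected is not decidable from such data.

Family analysis partitions each parent's peaks into two gamete blocks —
possibly sharing a hidden duplicated allele, inferred only when
offspring set patterns require it, since peak sets alone cannot reveal a
duplicate that peak heights could — such that every offspring is the
union of one father block and one mother block. Segregation is tested
with a plain Pearson chi-square (no continuity correction) against
1:1:1:1 over the father-block × mother-block classes; intron–intron
linkage is read off the block contingency with phase set by majority.
With fewer than 8 offspring a power warning is issued: an
always-co-transmitted pair arises by chance with probability 2·(1/2)^n
under independence.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions the package targets:
10 individuals × 10 clones, two tandem gene copies per haplotype drawn
from a pool of 3 clades separated by 15 fixed differences, a 300-nt
coding region partitioned 60/120/120 (signal/mature/C-terminal), somatic
mutation at 1.1e-3 per site with domain weights 0.083/0.058/0.150
(matching the observed per-domain mutation proportions), per-clone
recombination probability 0.06 with a uniform breakpoint and a
different-sequence donor copy, and intron size alleles on the major
fragment modes (intron 1: 184/221/376; intron 2: 199/200/210/211, with
mode frequencies chosen as round values in the observed proportions).
Families transmit whole two-gene haplotypes with recombination fraction
0 between the tandem copies by default.

Not emulated: cell-lineage structure in somatic events (mutations are
independent per clone, consistent with the observation that gDNA and
cDNA mutations rarely coincide), PCR-chimera artifacts, gene-conversion
double breakpoints (single crossover only — the data cannot distinguish
the two mechanisms), coalescent ancestry of the germline pool, and
selection. Passing recovery tests on this generator therefore shows the
procedure is calibrated under its own assumptions, not that real
amplicon libraries meet them.

A separate deterministic benchmark, `synthetic_study_dataset()`, encodes
in fixed design (no RNG) a dataset with the headline structure of the
motivating study — 93 cDNA clones + reference with 21 basics in three
clades, 30 somatic substitutions (86.7% singletons), six recombinants
giving a mean per-individual fraction of 0.064, coding-region S = 72
(25 singletons, 47 informative), Rm = 5 among the basics, and a gDNA
intron-2 haplotype spectrum with Hd = 0.987 — so the whole chain can be
scored against known truth end to end.

## Problem sizes used in the checks

The test suite runs the neutral-coalescent calibration of Tajima's D on
500 replicates at n = 20, theta = 5; parameter recovery on 100 replicate
datasets at the 10 × 10 design; locus-model recovery on 500 simulated
crosses of 20 offspring; and brute-force cross-checks (Rm, minimal-event
classification, rank-sum permutation) on small instances where
enumeration is exact. These sizes were chosen so each property is tested
at the scale the package targets while the full suite stays comfortably
interactive.

## Known limitations

- Somatic mutation cannot be separated from residual sequencing error;
  the rates are upper bounds under the high-quality-read assumption.
- Recombinants whose breakpoint falls outside the informative-site span
  are undetectable in principle; the detectability correction accounts
  for this on average but individual calls are conservative.
- The family module needs both parents genotyped; peaks absent from both
  parents are flagged, not modelled (null alleles and scoring error are
  out of scope).
- p-values for the D statistics are not provided beyond the undefined/
  defined flag; coalescent-simulation significance is out of scope.
- With `min_support = 2`, a germline variant supported by a single
  unmutated clone is (correctly) not promoted; its clones surface as
  ambiguous rather than distorting the mutation rate.
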