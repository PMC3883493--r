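---
title: "Fragment-sharing phylogenies from in-silico 2b-RAD digestion"
author: "rad2b"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-sharing phylogenies from in-silico 2b-RAD digestion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rad2b)
```

## The method

Type IIB restriction endonucleases cleave double-stranded DNA on *both*
sides of their recognition site, excising a blunt fragment of fixed length
(21–33 bp depending on the enzyme). Because the recognition sites are
scattered across the whole genome, the resulting fragment collection — the
2b-RAD reduced representation — is a large, arbitrary, genome-wide sample
of loci. Two genomes that diverged recently still carry most of these
short loci in recognizable form; as divergence grows, substitutions both
destroy recognition sites and mutate the excised fragments, so the
fraction of fragments two genomes share decays with evolutionary distance.
`rad2b` turns that decay into a distance and the distance into trees:

1. **Digestion.** Each genome is scanned on both strands for each enzyme's
   degenerate (IUPAC) recognition pattern and the blunt windows are
   excised (`digestGenome()`).
2. **Representative sets.** Per genome and enzyme, identical copies
   collapse to one representative and *divergent fragment families* —
   distinct fragments within a small Hamming radius of one another inside
   the same genome — are removed (`buildRepresentativeSet()`). These
   families are typically repeat-derived and would otherwise produce
   spurious cross-genome matches.
3. **Sharing.** For each genome pair, every representative fragment is
   classified against the other genome's set as *identical*, *similar*
   (nearest counterpart within `maxMismatch` mismatches, default 5), or
   unmatched, in both directions (`countShared()`).
4. **Distance.** The pair's distance is
   $d = -\ln\left(\frac{\mathrm{identical} + \mathrm{similar}}{n_A + n_B}\right)$,
   the negative log of the sharing ratio (`pairDistance()`), which is 0
   for identical genomes and grows as sharing decays.
5. **Trees.** One neighbor-joining tree per enzyme
   (`neighborJoining()`), then a strict majority-rule consensus across
   enzymes whose branches carry the number (and percentage) of supporting
   enzymes (`majorityConsensus()`). The enzymes act as quasi-independent
   genome-wide samples, so per-branch enzyme counts play the role
   bootstrap proportions play elsewhere.

## Enzyme model

An enzyme is its recognition pattern plus fragment geometry
(`TypeIIBEnzyme`): `leftFlank + patternLength + rightFlank =
bluntLength`. The shipped table contains 13 characterized Type IIB
enzymes. Two analytic quantities anchor the model:

* **Site probability.** On uniform random sequence, a pattern matches a
  position of one strand with probability
  $p = \prod_i \mathrm{deg}(i)/4$, where $\mathrm{deg}(i)$ is the size of
  the base set the IUPAC code at position $i$ denotes (N positions
  contribute a factor of 1).
* **Cut-site spacing.** A *palindromic* (self-reverse-complementary)
  pattern sees each double-stranded site once, so sites recur every
  $1/p$ bp; a non-palindromic pattern is recognized in either
  orientation, halving the spacing to $1/(2p)$. This single rule
  reproduces the expected spacing of all 13 shipped enzymes, e.g. AlfI
  (GCANNNNNN TGC, palindromic) at 4096 bp and BslFI (GGGAC) at 512 bp.

```{r spacing}
sapply(typeIIBEnzymes(), expectedSiteSpacing)
```

The chance that one particular 21-mer occurs at all in an unrelated
150 Mb genome is `fragmentOccurrenceProbability(21, 1.5e8)` ≈ 3.4e-5
(0.0034 %), which is why exact 21–33 bp matches between genomes are
overwhelmingly homologous rather than coincidental.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `maxMismatch` | 5 | mismatches allowed for a "similar" match; 5 on a ~27 bp fragment keeps matched pairs above roughly 80 % identity. Larger values admit more remote homologs but also more noise. |
| `familyRadius` | 2 | within-genome Hamming radius defining a divergent fragment family; members of any family are removed entirely. |
| `cap` | 30 | distance assigned to a pair sharing nothing (≈ −ln 1e−13); keeps matrices finite so NJ stays computable. Never reached in realistic comparisons. |
| flank split | symmetric | the paper-facing enzyme tables give pattern and blunt length but not the cut offsets; the spare bases are split symmetrically (left flank gets the odd base), overridable per enzyme in the TSV config. Fragment *content* depends on this choice; fragment *counts* and downstream distances on homologous genomes do not. |

Fragments are compared in **canonical form** (the lexicographic minimum
of the sequence and its reverse complement), so results cannot depend on
the assembly strand of either genome: digesting a genome and its
reverse complement yields identical multisets. During similarity search
both strand alignments of each pair are examined and the smaller Hamming
distance is used.

## Design choices at genuinely open points

* **Family removal is whole-family.** "Divergent families" are taken as
  connected components of the ≤ `familyRadius` relation and removed
  entirely (equivalently: any fragment with at least one within-radius
  neighbor is dropped). Removing only the duplicates would leave one
  ambiguous witness per repeat family; removing all is the conservative
  choice and makes the operation idempotent.
* **Bidirectional counting.** Shared fragments are counted from both
  genomes' perspectives and summed; with the $n_A + n_B$ denominator this
  makes two identical fragment sets give a distance of exactly 0.
* **Denominator.** "Total fragments of both species" is the sum of the
  two representative-set sizes (after family filtering), i.e. the same
  collections the numerator is counted over.
* **NJ determinism.** Ties in the Q-criterion are broken by the
  lexicographic order of the joined clusters' smallest leaf labels.
  Negative branch lengths, which only arise on non-additive input, are
  clamped to zero with the deficit moved to the sibling branch (at the
  final trifurcation, to the next branch cyclically); a message reports
  when clamping fires.
* **Strict majority consensus.** A split is retained iff it occurs in
  more than half of the enzyme trees; retained splits are mutually
  compatible by construction, and consensus branches carry counts, not
  lengths (per-enzyme trees carry the lengths).
* **Zero-sharing cap.** −ln of 0 is infinite; the cap (30) substitutes a
  finite "effectively unrelated" distance rather than dropping the pair.

## The synthetic-genome generator

`simulateGenomes()` draws an i.i.d. root genome (default GC 0.42, in the
range of the fly genomes that motivated the method) and evolves it along
a user-supplied tree under Jukes–Cantor (JC69): on a branch of length $b$
expected substitutions per site, each site changes with probability
$\tfrac{3}{4}(1 - e^{-4b/3})$, the replacement uniform over the three
alternatives. No indels are introduced — fragment matching is
Hamming-based, and indel handling is outside the method's scope — and no
repeats, isochores or chromosome structure are modeled. Passing
topology-recovery tests on these genomes therefore demonstrates that the
pipeline converts substitution divergence into correct tree structure; it
does not exercise repeat-induced family filtering at realistic rates, nor
assembly artifacts of real genomes.

Two calibration notes. The analytic spacing assumes uniform base
composition, so yield-versus-spacing checks use GC 0.5; at GC 0.42 the
GC-rich recognition sites fire measurably less often, exactly the
GC-dependence seen on real genomes. And because a 2 Mb genome at spacing
512 yields only ≈ 2 300 BslFI fragments (against ≈ 300 000 on a real
150 Mb genome), simulated distances are noisier than real ones; the
recovery tests compensate with a modest tree depth (≤ 0.2
substitutions/site).

## Problem sizes used by the test suite

The packaged tests run the full pipeline on simulated data at sizes
chosen to exercise every stage meaningfully on a single CPU: an 8-taxon
balanced tree (internal branches 0.02–0.03, leaf depth 0.07
substitutions/site) on 2 Mb genomes, over the five most frequent-cutting
enzymes (BslFI, HaeIV, BcgI, BsaXI, Bsp24I), repeated for ten seeds with
the consensus compared to the generating topology; plus brute-force
oracle equivalence for the matching kernel on random 200–1 000-fragment
sets and exact recovery of 100 random additive matrices by the NJ
implementation. Smaller deterministic fixtures cover each operation's
edge cases (boundary windows, ambiguity codes, strand symmetry,
serialization round-trips).

## Known limitations

* Distances are raw −ln sharing ratios: monotone in divergence but not
  calibrated to time or substitutions/site; no model-based correction is
  applied.
* Very distant genomes (sharing → 0) saturate at the cap and carry no
  signal; the method presumes a set of genomes close enough to share
  fragments.
* Fragment families are defined by Hamming distance only; a repeat family
  whose members differ by an indel is not detected as such.
* The consensus annotates support but deliberately computes no branch
  lengths.
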