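# rad2b

Whole-genome phylogenies from predicted Type IIB restriction fragments
(2b-RAD), for comparative genomicists who have assemblies (or deep reads)
but no alignments.

Type IIB restriction endonucleases cut both strands of double-stranded DNA
upstream *and* downstream of their recognition site, releasing blunt
fragments of uniform length (21–33 bp per enzyme). Predicted in silico,
these fragments form a genome-wide reduced representation: a large,
arbitrary sample of short loci. Closely related genomes share many of
them; divergence erodes both the recognition sites and the fragment
sequences. `rad2b` quantifies that erosion and builds trees from it.

For genomes *A* and *B* digested with one enzyme, let n_A and n_B be the
sizes of their representative fragment sets (identical copies collapsed,
divergent within-genome fragment families removed), and count each
fragment's best match in the other genome — *identical*, or *similar*
(nearest counterpart within `maxMismatch` mismatches, default 5, both
strand alignments considered). The pairwise distance is the negative log
sharing ratio

    d(A, B) = -ln( (identical + similar) / (n_A + n_B) )

which is 0 for identical genomes and grows as sharing decays. Per enzyme,
the pairwise matrix feeds neighbor joining; across enzymes, a strict
majority-rule consensus annotates each branch with the number of
supporting enzymes — 13 characterized Type IIB enzymes ship with the
package.

A Jukes–Cantor simulator (`simulateGenomes()`) evolves genomes along any
Newick tree so the whole pipeline's topology recovery can be verified
against a known truth.

## Worked example

Five genomes simulated on a known tree, analyzed with three enzymes:

```r
library(rad2b)

sim <- simulateGenomes("((a:0.03,b:0.03):0.04,(c:0.03,d:0.03):0.04,e:0.07);",
                       rootLength = 3e5, gc = 0.5, seed = 17)
res <- radPhylogeny(sim$genomes, typeIIBEnzymes(c("BslFI", "HaeIV", "BcgI")),
                    verbose = TRUE)
#> BslFI: 577/586/545/547/579 representative fragments
#> HaeIV: 258/261/269/278/273 representative fragments
#> BcgI: 170/164/174/182/151 representative fragments

print(distanceMatrix(res$matrices$BslFI), digits = 3)
#>       a     b     c     d     e
#> a 0.000 0.271 0.568 0.574 0.539
#> b 0.271 0.000 0.563 0.573 0.558
#> c 0.568 0.563 0.000 0.256 0.581
#> d 0.574 0.573 0.256 0.000 0.579
#> e 0.539 0.558 0.581 0.579 0.000

res$consensus
#> ConsensusTree: majority-rule over 3 trees, 5 taxa, 2 supported splits
supportTable(res$consensus)
#>   clade count percent
#> 1   a,b     3     100
#> 2   c,d     3     100

robinsonFoulds(res$consensus@tree, sim$tree)
#> [1] 0
```

Reading the numbers: at ~0.06–0.14 substitutions/site of divergence, the
sister pairs (a,b) and (c,d) still share roughly three quarters of their
BslFI fragments (d ≈ 0.26–0.27 = −ln 0.76) while cross-clade pairs share
about 57 % (d ≈ 0.56); all three enzyme trees contain both true splits,
so the consensus carries them at 3/3 = 100 % and matches the generating
topology exactly (Robinson–Foulds 0).

The same workflow runs from the shell via the thin CLI in
`inst/scripts/rad2b.R` (`digest`, `repset`, `compare`, `nj`, `consensus`,
`simulate`, `run-all`).

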