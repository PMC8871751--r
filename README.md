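# patrilineR

Y-chromosomal lineage tracing for sire-line genealogies.

The male-specific region of the Y chromosome (MSY) is inherited from father
to son as a single non-recombining linkage block, so the concatenated
allelic states of all MSY variants in one male — his **haplotype (HT)** —
records his paternal ancestry. Under the infinite-sites assumption each
variant arises once, mutations accumulate strictly hierarchically, and the
HTs of a set of males admit a unique rooted **perfect phylogeny** in which
every variant maps to exactly one branch. `patrilineR` implements the full
analysis chain that turns haploid sequencing calls into named haplotype
trees and pedigree-checked sire lines:

* **Variant ascertainment** — haploid VCF / delimited matrices with
  per-call read depth (DP) and genotype quality (GQ); a site is excluded
  when calls with DP < 3 or GQ < 5 exceed 10% of samples, when its call
  rate falls below 75%, or when it is heterozygous-only, multi-allelic, or
  a reference error. Alleles are polarized ancestral/derived against an
  outgroup (in horses, the Przewalski's Horse).
* **Haplogroup-consensus imputation** — samples are clustered by
  diagnostic variants; missing calls are filled by within-group consensus
  (unanimity by default, strict majority optional), never touching an
  observed call.
* **Tree reconstruction** — the rooted perfect phylogeny with variants on
  branches, explicit polytomies, four-gamete conflict reporting, and
  greedy conflict resolution when requested; Newick/DOT/GraphML/table
  export with HT frequencies.
* **Hierarchical nomenclature** — legacy stems (e.g. `Ta-b`, `Ao-aA1a`)
  anchor subtrees; every further node appends one character, alternating
  letters and digits; a terminal `*` marks a placement at an internal node
  that sequencing has not yet resolved.
* **Backbone panel genotyping** — a complexity-reduced marker panel (one
  assayable marker per backbone branch) and the consecutive testing
  procedure: key variants first (crown membership), then clade tests, then
  HT-determining markers, with ancestral auto-imputation in the clades the
  sample does not carry and `*HT` placement when markers below a node are
  untested.
* **Pedigree congruence** — tail-male lines (`sample`, ancestor chain to
  the foundation sire) are checked against the molecular HTs: one
  nested-label chain per line means the written pedigree is consistent (possibly
  with de novo *subline-HTs* private to one subline); two or more disjoint
  chains mean more than one stallion founded the recorded line.
* **Forward simulator** — male genealogies with zero-truncated-Poisson
  offspring numbers (optional "popular sire"), Poisson mutations under
  infinite sites, genotyping noise (missingness, heterozygous artifacts
  with threshold-violating DP/GQ), and recorded-pedigree paternity errors,
  with full ground truth for every stage.

The package also ships a machine-encoded panel of the 145 genotyped males
from 26 occidental Arabian foundation-sire lines
(`occidental_lines()`), which reproduces the reference summary statistics
(16 HTs, three Arabian haplogroups, two incongruent lines).

## Worked example

```r
library(patrilineR)

## a simulated male genealogy with ground truth
cfg   <- sim_config(generations = 5, founders = 2, mu = 0.5, sites = 250, seed = 42)
truth <- simulate_patrilines(cfg)
truth
#> msy_sim: 5 generations, 2 founders, 51 sampled males, 43 segregating sites

## rooted perfect phylogeny from the polarized call matrix
res <- build_tree(truth$true_matrix)
nrow(res$conflicts$conflicting_pairs)   # infinite sites: no four-gamete conflicts
#> [1] 0
tree <- assign_names(res$tree, name_registry(1L, "T"))
tree
#> haplotype_tree: 34 nodes, 51 samples, 43 sites on edges
head(tree$nodes[, c("node_id", "parent", "label", "n_members")], 5)
#>   node_id parent label n_members
#> 1       1     NA     T         5
#> 2       2      1    T1         1
#> 3       3      1    T2         2
#> 4       4      1    T3         1
#> 5       5      1    T4         2
```

The root carries the outgroup-ancestral haplotype; each child label appends
one character to its parent's label, so `T1` is nested in `T` and tree
ancestry can be read off the names alone (`is_ancestor_name("T", "T1")`).

Marker-panel genotyping against the bundled crown backbone: a sample
derived for the crown keys, the T-clade test, and the six `Ta`-branch
markers, but ancestral for the `Ta-s`/`Ta-b` markers, sits at the internal
`Ta` node — reported as `Ta*` because an un-ascertained private branch
below `Ta` cannot be excluded by panel markers:

```r
panel <- select_backbone(crown_backbone(), focus = c("Ta-s", "Ta-bA"))
a <- assign_sample(c(rAX = "D", rW = "D", fRL = "D", sPY = "A", qGB = "A"),
                   crown_backbone(), panel)
a$node_label
#> [1] "Ta*"
a$resolved
#> [1] FALSE
```

Sire-line congruence on the bundled panel of occidental Arabian lines:

```r
s <- summarize_panel(occidental_lines())
s$total_samples; s$n_lines; s$n_distinct_hts
#> [1] 145
#> [1] 26
#> [1] 16
s$incongruent_lines
#> [1] "Ilderim db" "Siglavy db"
```

145 males from 26 foundation sires carry 16 haplotypes; 137 of them fall
into the three Arabian haplogroups (`Ao-aA`, `Ta`, `Ao-aD2`). Two lines mix
haplotypes that cannot descend from a single founder: the Siglavy line
(`Ao-aA1a2`/`Ao-aA1a2a` vs `Ao-aA1b`, two homonymous founders) and the
Ilderim line (`Ao-aA1a*`/`Ao-aA1a4` vs `Ta-b`, a mis-recorded paternity).
Three labels (`Ta-bA`, `Ao-aA1a2a`, `Ao-aA1a4`) are de novo subline-HTs
that arose within the documented pedigree timeframe and act as private
markers for their sublines.

`run_pipeline()` chains the stages (filter → polarize → cluster → impute →
haplotypes → tree → names → panel → congruence), writing every artifact
plus a manifest of parameters and md5 checksums; identical inputs
reproduce identical checksums.

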