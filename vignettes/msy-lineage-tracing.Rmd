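---
title: "MSY lineage tracing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSY lineage tracing: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patrilineR)
```

## The inheritance model

The male-specific region of the Y chromosome (MSY) passes from father to
son as one non-recombining block. Writing the allelic state of every
variant as ancestral (0) or derived (1) relative to an outgroup, each male
carries a binary vector — his haplotype — and a mutation event flips a
single previously unmutated site in one transmission (the infinite-sites
assumption). Two consequences carry the whole package:

1. **Perfect phylogeny.** The derived-carrier sets of all sites form a
   laminar family (any two sets are nested or disjoint) relative to the
   all-ancestral root, so a unique rooted tree exists in which every
   polymorphic site mutates on exactly one branch. `build_tree()`
   constructs it by containment sorting of the distinct carrier sets;
   sites with identical carrier sets share one branch, and nodes with more
   than two children are kept as polytomies because a multifurcation is a
   finding (simultaneous expansion), not an artifact to be resolved
   arbitrarily.
2. **Four-gamete test.** A pair of sites contradicts a single tree exactly
   when all four combinations 00, 01, 10, 11 occur. `four_gamete_check()`
   applies the literal definition to the sample rows; *inside*
   `build_tree()` the implicit all-ancestral root row is included, which
   turns the test into the rooted laminarity criterion the construction
   requires. The distinction matters for small matrices in which every
   sample is derived somewhere.

When conflicts exist (recurrent mutation, genotyping error),
`on_conflict = "greedy_drop"` removes conflicting sites in increasing
derived-carrier-count order, ties broken by `site_id`. Dropping the rarer
site first minimizes the number of carriers whose placement changes, and
the tie-break makes runs reproducible.

## Ascertainment filters

`filter_config()` encodes the depth/quality regime of haploid MSY calling:

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 3 reads | calls below are low-confidence |
| `min_quality` | 5 (GQ) | likewise |
| `max_low_quality_fraction` | 0.10 | site dropped when low-confidence calls exceed this fraction of samples |
| `min_call_rate` | 0.75 | site dropped when called in fewer samples |

A call failing *either* the depth or the quality threshold counts as
low-quality; the 10% rule is applied to that union. Additional rules drop
heterozygous-only sites (impossible on a haploid locus, hence artifacts),
multi-allelic SNV/indels, and *reference errors*, operationalized as sites
where every non-missing ingroup call carries the alternative allele — on
an outgroup-rooted haploid panel the only consistent reading is that the
reference assembly itself carries the singleton. Heterozygous artifacts
surviving at retained sites are demoted to missing, which makes filtering
idempotent. STR sites keep all observed length alleles and are binarized
at polarization as outgroup length vs any other length; multistep STR
evolution is deliberately not modeled (a warning says so).

Plain matrix dialects without DP/GQ metadata treat every call as passing
the thresholds, so curated summary tables can flow through the same code
path. Missing calls are written `"."`, coordinates are 1-based.

## Imputation

Missing calls are filled by within-haplogroup consensus
(`impute_by_group()`), mirroring the practice of introducing the allelic
state observed in samples of the same clade. Because the source procedure
was manual and states no explicit consensus rule, both readings are
exposed: `"unanimity"` (default — fill only when every non-missing group
member agrees) and `"majority"` (strict majority, ties left missing,
announced loudly because it can fabricate minority states). Observed calls
are never altered, every filled cell is logged, and sites that still
contain missing calls after imputation are excluded from haplotype
construction — the site is sacrificed, not the sample, matching the
variant-centric accounting of the rest of the pipeline.

This exclusion rule has a consequence worth stating plainly: a private
variant whose only carrier is masked is unrecoverable *by any method*, and
the site leaves the analysis. The simulation suite therefore scores
degraded-data runs against the *recoverable* truth — the true tree
restricted to sites that retain evidence after the mask, an oracle
computed directly from the mask — and against the full truth on clean
data. Passing those tests shows the pipeline loses nothing the data still
contain; it cannot show recovery of information the noise destroyed.

## Nomenclature

Labels are hierarchical: registered legacy stems (`T`, `Ta`, `Tb-oB`,
`Ao-a`, ...) anchor subtrees, every unanchored child appends exactly one
character to its parent's label, alternating character class — after a
terminal letter a digit starting at "1", after a digit a lowercase letter
starting at "a" (overflow continues into the other class, 36 symbols per
level; a 37-way polytomy is an error). Children are named in order of
their smallest member sample (matrix input order), so naming is
deterministic and renaming an already-named tree is a no-op. Hyphens are
ordinary characters owned by the legacy stems, which keeps externally
published labels (`Tb-dW1`) parseable as opaque stems; case is
significant. A terminal `*` flags a placement at an internal node. Nesting
of names is a pure string property: `a` names an ancestor of `b` iff
`strip_asterisk(a)` is a prefix of `strip_asterisk(b)` — the test suite
verifies on simulated trees that this agrees exactly with tree ancestry.

## Backbone panels and consecutive genotyping

`select_backbone()` reduces the tree to one genotypable marker per branch:
full traceability (every edge on every root-to-focus path) for lineages of
interest, one subtending marker only for coarse clades. Where an edge
carries several variants the lexicographically smallest `site_id` is
chosen, again for reproducibility. Stage roles mirror the bench workflow —
`key` markers on edges leaving the root (crown membership), `clade` on the
next split, `ht` below.

`assign_sample()` evaluates the final call set declaratively rather than
simulating assay order; the result is identical because the consecutive
procedure only determines *which* markers get tested, and untested markers
are handled explicitly. The sample is placed on the deepest node whose
root path is fully supported by derived calls with no tested-derived
marker off the path; markers confined to clades the sample does not carry
are auto-imputed ancestral (and never count as evidence). Derived markers
on two disjoint branches — or an ancestral call contradicting a derived
call below it — yield the reportable outcome `"conflict"`, never an
exception. Assay dropout (`F`) is treated as untested (`U`); nothing in
the procedure distinguishes them.

Any placement at an internal node carries `*` and `resolved = FALSE`,
*even when every marker below was tested ancestral*: panel markers are
ascertained from previously sequenced lineages, so they can never exclude
a private, un-ascertained branch below the node (ascertainment bias). Only
a leaf placement without conflicts is resolved. The bundled
`crown_backbone()` tree encodes the published marker-to-branch relations
(keys rAY/rAX; clade tests rA/rW/fYR; the six Ta-path markers; sPY/qGB/qGC
below Ta; the four recent de novo variants); relations that are not
published — which clade each of rA/rW/fYR tags, and the A-side internal
chain — are synthetic stand-ins, and users genotyping real panels should
supply their own tree table.

## Pedigree congruence

A tail-male line is the ancestor chain from a sampled male to his
foundation sire. `classify_line()` merges the haplotype labels observed in
one line into chains in which every pair is nested (with `X*` compatible
with any descendant of X): one chain with one label is `consistent`; one
chain with several labels is `subline_consistent`, the deeper labels being
candidate de novo subline-HTs attributed to their carrier sublines; two or
more disjoint chains mean at least two paternally unrelated stallions
founded the recorded line (`incongruent`) — de novo mutation cannot
explain sibling haplotypes whose divergence predates the pedigree.

The bundled `occidental_lines()` records encode, one row per subline, the
145-male panel of 26 occidental Arabian foundation lines with haplotype
labels and curated remarks. Where the published table does not pin the
allocation of samples to sublines within a row, the allocation was fixed
so that every row and panel total is preserved; all summary statistics are
invariant to that choice. `summarize_panel()` recomputes the headline
counts (145 samples, 26 lines, 20 with more than one descendant, 16
distinct HTs, 137 samples in the Arabian haplogroups `Ao-aA`/`Ta`/`Ao-aD2`,
92 samples and 12 lines in `Ao-aA`, 88 in `Ao-aA1a`, 6 lines on the basal
`Ao-aA1a*` node, 3 subline-HT labels, and the 2 incongruent lines) from
the records alone; haplogroup membership is name-nesting, never a lookup.

## The synthetic-data generator

`sim_config()` fixes the study conditions; the defaults are the regime the
rest of the package assumes:

* `offspring_lambda = 1.2` under a zero-truncated Poisson — every male
  leaves at least one son, reflecting that only retained sire lines are
  observed; the optional `popular_sire` multiplier (default 3) concentrates
  reproduction in one male per generation and reproduces star-like
  expansions.
* `mu = 0.3` mutations per transmission, of the order expected for ~5 Mb
  of single-copy MSY sequence per generation; pedigree-window experiments
  that model only panel-visible markers use `mu = 0.002`, matching the
  handful of de novo marker mutations observed across roughly a thousand
  documented transmissions.
* `founder_mutations = 0` by default (founders start on the ancestral
  haplotype); positive values give each founder private derived sites,
  emulating foundation sires whose lineages diverged long before the
  recorded pedigree — required for cross-haplogroup paternity errors to
  exist at all on pedigree timescales.
* `missing_rate = 0.05`, `het_artifact_rate = 0.01` per call; degraded
  calls receive DP/GQ values that violate the default filter thresholds,
  clean calls values that pass, so the filter and the noise model agree by
  construction. The outgroup is never degraded.
* `paternity_error_rate` replaces a recorded father by a different male of
  the same generation; `generation_interval_years = 8` converts
  transmissions to calendar time.

Time is counted in transmissions. The infinite-sites pool is enforced by
rejection: mutations are drawn from never-mutated sites and the simulator
stops with advice to enlarge `sites` when the pool is exhausted.
Everything is deterministic given `seed`, and the caller's RNG state is
restored afterwards.

What the generator does *not* emulate: recurrent or back mutation,
STR-specific stepwise evolution, sequence-level error correlation along
reads, female-line information, selection beyond the popular-sire
multiplier, and coalescent-scale deep history. Tests passing on this
generator therefore certify the algorithmic chain under the model's own
assumptions, not robustness to model violations in real data (recurrent
mutations, for instance, appear only through the explicit conflict-path
tests).

The simulator's truth tree is built directly from the transmission
genealogy (pruning unsampled lineages, merging zero-mutation transmissions,
contracting unary unsampled chains) — an independent construction path
from the carrier-set algorithm in `build_tree()`, which is what makes
recovery tests meaningful. For the same reason the exhaustive
small-parsimony check in the test suite scores candidate topologies with
`phangorn`, an implementation the package does not share code with.

## Problem sizes and determinism

The shipped experiments run at deliberately desk-scale sizes: trees of a
few dozen nodes, matrices of a few hundred sites, 10–100 seeded replicates
per property, and exhaustive topology enumeration up to 8 tips (10,395
unrooted trees). These sizes were chosen so each property is measured with
clear margins (e.g. >10,000 imputed cells behind the 99% recovery bound)
while the whole suite remains quick to run; the algorithms themselves are
polynomial and handle larger panels. Sequencing-scale quantities that
depend on raw archived reads (variant counts in the thousands, coverage
distributions) are out of desk-scale reach by construction and are covered
by the property suites instead.

All orderings are fixed (sites by position, samples by input order,
children by smallest member), so every artifact — including the pipeline
manifest checksums of `run_pipeline()` — is a pure function of inputs,
configuration, and seed.

## Known limitations

* Binarized STRs lose multistep information; fast markers deserve a
  stepwise model.
* Unanimity imputation cannot rescue sites where an entire group is
  masked; such sites leave the analysis (see above), which on sparse
  panels with many singleton haplotypes can prune real terminal branches.
* Greedy conflict resolution is heuristic; a minimal-cost site-removal set
  is NP-hard in general and not attempted.
* The name grammar caps fan-out at 36 children per node.
* Congruence classification sees only label nesting: a recorded line fully
  replaced by a single foreign lineage is haplotype-homogeneous and
  therefore undetectable — only mixtures can be flagged.
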