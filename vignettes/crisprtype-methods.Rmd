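---
title: "Models and methods behind crisprtype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crisprtype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprtype)
```

`crisprtype` types strains of an uncultured bacterial population by the
ordered content of their CRISPR arrays and quantifies how those strains are
partitioned across a nested sampling hierarchy. This vignette documents the
models, the parameters that matter, the numerical choices, and what the
synthetic-data validation does and does not demonstrate.

## The ordered independent spacer-loss (OISL) model

A CRISPR array is an ordered sequence of spacer identities, leader (5′) end
first. The model has two processes:

* every spacer, anywhere in the array, is lost independently at rate 1
  (time is therefore measured in expected deletions per spacer);
* new spacers are inserted at the leader end at relative rate ρ, each a
  sequence never seen before.

Two haplotypes that diverged from their most recent common ancestor a time
*t* ago each retain a given ancestral spacer with probability
p = e^(−t). Aligning a pair by its shared spacers (which must be collinear:
order-discordant pairs violate the model and raise a typed error rather
than being silently accommodated) partitions spacers into

* `shared` — present in both (probability p²),
* `internal unique` — present in one, at or trailer-ward of the leader-most
  shared spacer, i.e. ancestral but lost in the other lineage
  (probability p(1−p) each way),
* `leader unique` — leader-ward of all shared spacers: surviving
  post-divergence insertions, Poisson with mean λ = ρ(1−p) per lineage.

### Conditioning on observability

A fourth class exists — ancestral spacers lost in *both* lineages, with
probability (1−p)² — but it is unobservable: nothing in the data reveals
how many there were. The class likelihood must therefore condition on a
spacer having survived in at least one lineage:

$$\log L = 2s\log p + i\,[\log p + \log(1-p)] - (s+i)\log[1-(1-p)^2]
  + \sum_{X\in\{A,B\}} \log \mathrm{Pois}(k_X;\, \rho(1-p))$$

with *s* shared and *i* internal-unique counts. Omitting the conditioning
term looks harmless but makes the estimator inconsistent: its maximiser
converges to p* = 1/(2−p) instead of p, an overestimate of retention and
hence a systematic underestimate of divergence (for t = 0.3, the
unconditioned estimator converges to t ≈ 0.233). The package's
parameter-recovery test (500 simulated pairs from a 200-spacer ancestor at
t = 0.3) checks exactly this: the conditioned estimator's mean t̂ falls
within three standard errors of the truth.

With the conditioning term the deletion-only maximum has closed form

$$\hat p = \frac{2s}{2s+i},\qquad \hat t = -\log\hat p,\qquad \hat\rho = 0,$$

used whenever neither array carries leader-unique spacers. Otherwise the
Poisson mean is profiled analytically (λ̂ = (k_A+k_B)/2, attainable for any
t > 0), so the profile likelihood over *t* is one-dimensional and is
maximised with bounded `optimize()` at tolerance 1e−6 on *t*.

Numerical edge cases, all deliberate:

* identical arrays: t̂ = 0, distance 0, log L = 0;
* no shared spacers: the pair carries no information about *t*; the
  distance is capped at 2·`t_max` (default `t_max` = 10, i.e. retention
  probability ≈ 4.5e−5) with a typed warning rather than a failure, so a
  single aberrant haplotype cannot abort a distance matrix;
* shared spacers with leader-unique but no internal-unique spacers: the
  class terms are maximised on the boundary t → 0 while the Poisson terms
  need λ > 0; the supremum is approached, not attained, and the estimate is
  reported at the optimizer tolerance. This configuration does not arise in
  deletion-only data.

The reported pairwise distance is 2·t̂, the tip-to-tip divergence under the
model's equal-branch-length (clock) assumption — one divergence-time
parameter per pair, matching the definition of the distance as twice the
time to the pair's most recent common ancestor.

## Haplotype calling from long amplicon reads

The caller mirrors a long-read amplicon workflow in which circular
consensus reads have modest, indel-rich errors:

* **Spacer discovery.** Approximate occurrences of the conserved repeat
  (edit distance ≤ `max_repeat_edits`, default 3) are located on both
  strands; inter-repeat segments of plausible spacer length (20–60 nt by
  default) are clustered greedily at 85% identity, seeded by the most
  abundant exact sequences; each cluster's consensus is its modal member.
  Cluster order — which becomes catalog id order — is a topological sort of
  the within-read precedence counts, so the catalog order reproduces the
  leader-to-trailer order of the underlying array even when no single read
  spans it.
* **Mapping and QC.** Both primers and every catalog spacer are matched by
  Levenshtein distance, at most `max_edits` = 5 (the 85%-identity
  convention for ~35 nt spacers; substitutions and indels count equally
  because the error process is indel-rich). Overlapping candidate hits are
  resolved greedily by ascending edit distance, then leftmost position — a
  deterministic tie-break. Each read gets exactly one category by the fixed
  precedence `MISSING_PRIMER > TOO_SHORT > MIXED_ORIENTATION > MISORDERED >
  IRREGULAR_SPACING > PASS`; the categories partition every library. The
  length filter (33 nt, roughly one spacer) applies to the primer-trimmed
  interior. "Regularly interspaced" means consecutive spacer hits separated
  by one repeat length ± `spacing_tol` (5 nt, absorbing indel errors in the
  repeat). Reads whose gaps are irregular are flagged as putatively
  carrying new spacers; the gap regions (with bordering repeats) can be
  re-fed to the discoverer, which discards clusters resembling a known
  spacer (identity ≥ 0.5 to the catalog) as low-quality rediscoveries
  rather than adding near-duplicates that fuzzy matching could never
  distinguish.
* **Orientation.** The read is reverse-complemented when the primer layout
  indicates the reverse strand, so downstream arrays are always stored
  leader-first; spacer hits on the wrong strand after normalisation are an
  orientation inconsistency (`MIXED_ORIENTATION`).

## Phylogeny: clamped rooted neighbour joining

Standard NJ can emit negative branch lengths, which are meaningless as
deletion counts. During agglomeration every negative branch estimate is set
to zero and the deficit added to its sister branch, preserving the joined
pair's tip-to-tip distance; reduced distances are floored at zero. Join
ties in the Q-criterion are broken lexicographically by node label, so the
topology is deterministic. After the final two-way join the tree is rooted
at the midpoint of the longest tip-to-tip path: under the clock assumption
already baked into the pairwise distances the true tree is ultrametric and
the midpoint *is* the root (the package verifies that ultrametric inputs
yield tips equidistant from the root to 1e−9). An equal split of the final
joined edge — the more obvious choice — fails that property whenever the
final two subtrees have unequal heights, which is why midpoint placement
was chosen. Patristic distances are path sums over the rooted tree and are
invariant to the rooting position.

## Population structure

**AMOVA.** Every read is one individual (one symbiont cell). Reads carrying
the same haplotype are at distance zero, so all sums of squares reduce to
quadratic forms of per-group haplotype count vectors with the haplotype
squared-distance matrix — this is what makes 1000-permutation tests cheap
even with thousands of reads. Variance components solve the
expected-mean-square equations of the unbalanced nested random-effects
design (coefficients from the classical group-size sums); negative
components are reported as-is, since truncation would silently bias the
percentages. Φ for a level is its component over the sum of itself and all
nested components; the within row carries the cumulative (total) Φ.
Permutation tests follow the standard nested scheme: whole lowest-level
units (host samples) are permuted among the groups of the tested level
within the enclosing stratum; the innermost level and the within/total row
permute individual reads. Permuting the immediately-lower stratum instead
(e.g. two habitats per region) was rejected: with so few subunits the
permutation space is too coarse for small p-values regardless of effect
size. One-level AMOVA Φ and pairwise FST/ΦST coincide by construction, and
the test suite checks the permutation p-values are uniform under an
exchangeable null (Kolmogorov–Smirnov over 200 simulated datasets).

**Lingoes correction.** Tree-derived distances need not be
Euclidean-embeddable, but AMOVA's variance decomposition assumes they are;
the smallest constant c with d′² = d² + 2c (off-diagonal) restores
embeddability, with c read off the smallest eigenvalue of the
Gower-centred −d²/2 matrix (tolerance 1e−9, relative).

**FST/ΦST and Mantel.** `pairwise_fst` runs a two-level AMOVA per
population pair — 0/1 distances for classical haplotype-frequency FST,
supplied (patristic) distances for ΦST — with p-values from permuting
reads between the pair. Mantel correlations between differentiation
matrices enumerate all label permutations exactly for ≤ 6 populations
(n! ≤ 720) and use seeded random permutations above that; non-significant
differentiation entries (permutation p > 0.05) can be zeroed (negatives
clamped to zero in this mode only) or excluded pairwise.

**Minimum spanning network.** Kruskal's algorithm with edges ordered by
weight then lexicographic endpoints — fully deterministic under ties —
with per-population read counts attached to nodes; infinite (capped)
distances are absent edges, and a disconnected graph is a typed error.

## The synthetic-data generator

The generator emulates the statistical structure of a regional symbiont
survey: one long ancestral array eroded by deletions into a nested
haplotype set (insertions optional via ρ); three regions with nested
habitats and hosts in which differentiation is strong at the outer level
and negligible at the habitat level; and long amplicon reads with primer
flanks, ~30 nt interleaved repeats, i.i.d. substitution and indel errors
(0.5% + 0.5% by default, CCS-like), random strand, and configurable
corruption (primer dropout, truncation) to exercise every QC category.
Defaults mirror the emulated study's shape: 3 regions × up to 3 habitats ×
a few hosts, a few dozen haplotypes, read depths in the low hundreds per
sample. Per-level differentiation weights act on haplotype pools: weight 1
partitions the parent pool disjointly (maximal differentiation), weight 0
inherits the parent frequencies, intermediate weights mix in a
group-specific Dirichlet draw. All stages take a mandatory seed and are
byte-reproducible.

What passing on synthetic data does **not** show: the error model is
i.i.d. per base, so systematic homopolymer errors, PCR chimeras, context-
dependent error hotspots and host-DNA contamination are not represented;
quality strings are constant (QC is sequence-based except for the gene-
amplicon SNP counter); the generator has no recombination, duplication or
spacer re-acquisition, matching the model's assumptions exactly — real
arrays that violate those assumptions (order-discordant pairs) surface as
collinearity errors rather than biased estimates.

## Gene-amplicon haplotypes

For short gene markers the package counts two-locus haplotypes: bases
below Phred 28 are conservatively masked to N, each aligned read is
truncated to the two SNP columns (1-based), reads with a masked or
non-ACGT base at either column are dropped, and the ≤ 4 observed two-base
haplotypes are tallied. These frequency tables feed the
haplotype-frequency FST mode.

## Validation sizes and runtime

The test suite validates each component against an independent oracle at
fixed seeds: 1000 random alignments against a 1e−4-resolution grid search
(t̂ agreement to 1e−3); a 100,000-trial Monte-Carlo of the loss process
against the class probabilities p², p(1−p), (1−p)²; 500-pair divergence
recovery at t = 0.3; patristic round-trips on additive 4–8-taxon matrices
to 1e−9 and non-negativity on 1000 random matrices; exhaustive
spanning-tree enumeration (Prüfer sequences) for n ≤ 7 and full Mantel
enumeration for n ≤ 5; a hand-solved balanced AMOVA toy, the Φ/FST
identity, and 200-dataset null calibration; exact zero-error caller
round-trips and sub-5-point frequency recovery at 0.5% + 0.5% error, depth
200; and 50 end-to-end replicates in which region-only differentiation
must be detected as a significant region component with a null habitat
component. These sizes were chosen so the whole suite completes in a few
minutes on one CPU while keeping every binomial/KS bound meaningful.

## Known limitations

* The likelihood treats each pair independently; no joint multi-taxon
  likelihood on the tree is attempted (the pairwise reduction is the
  method's design), and ρ is estimated per pair rather than shared.
* Arrays with duplicated spacer ids are rejected at construction: the
  model has no duplication process, and alignment by shared spacers would
  be ill-defined.
* `t_max` caps no-shared-spacer pairs at a finite distance; such pairs
  dominate MSTs and AMOVA only through that cap, which is a modelling
  convention, not an estimate.
* The AMOVA permutation scheme treats lowest-level units as exchangeable
  under the null at every among-group level; designs whose units differ
  systematically in size remain valid but conservative.
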