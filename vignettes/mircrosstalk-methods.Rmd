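---
title: "Inferring miRNA-miRNA crosstalk from population variant data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring miRNA-miRNA crosstalk from population variant data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircrosstalk)
```

## The idea

A microRNA silences a transcript only while the two sequences are
complementary enough at the binding site. A single nucleotide change —
in the mature miRNA or inside the site — can therefore create or destroy a
regulation. Across a panel of naturally inbred ecotypes genotyped
genome-wide, every miRNA–transcript regulation has a *fate* in each ecotype
relative to the reference genome: kept, lost, gained, or absent. If two
miRNAs truly cooperate on a shared target, selection should keep their two
regulations together: wherever one is lost or gained, so is the other. The
package turns that co-inheritance signal into a miRNA–miRNA crosstalk
network and provides the statistical machinery to evaluate it.

## From variants to per-ecotype fates

**Materialization.** Each ecotype's variant genotypes are applied to the
reference miRNA and transcript sequences. Sequences carrying any short
indel in an ecotype are *discarded* there (frameshift semantics: an indel
inside a transcript or mature miRNA is assumed disruptive and the sequence
is excluded from comparison rather than rescored); sequences carrying only
SNPs become *mutant type*; untouched sequences are *wild type*. Biallelic
variants carried by exactly one ecotype (singletons) are removed before
any analysis — a standing-variation filter that also removes most
genotyping artifacts. Heterozygous calls count the ecotype as a carrier:
the panel species are selfing and near-homozygous, so presence of the
alternate allele is the relevant signal.

**Two-scorer agreement.** Target sites are predicted independently by two
complementarity scorers and a pair counts as detected in a genome only
when *both* scorers find it. The built-in scorers are gapless antiparallel
duplex penalty sums (0 per Watson–Crick pair, `gu_wobble` per G:U,
`mismatch` otherwise, core-region penalties multiplied):

* scheme A — mismatch 1, G:U 0.5, core at miRNA positions 2–13 with
  multiplier 2, cutoff 4 (an Allen-style plant scorer);
* scheme B — mismatch 1, G:U 0.5, core 2–17 with multiplier 1.5, cutoff
  2.5 (a stricter 5'-weighted variant).

Ties at the cutoff are accepted. The schemes deliberately trade
thermodynamic realism for an exactly checkable primitive: every window is
scored by table lookup, so a brute-force enumeration oracle can verify the
scanner bit-for-bit, and bulged duplexes are out of scope. Users with
predictions from external plant target-prediction tools can substitute
them through `as_prediction_set()`; the downstream pipeline only consumes
pair-level presence.

**Fate symbols.** With `R` the number of scorers detecting the pair in the
reference and `E` in the ecotype, the per-ecotype fate is

| `R` \ `E` | 0 | 1 | 2 |
|---|---|---|---|
| **0** | `n` | `o` | `g` |
| **1** | `o` | `o` | `o` |
| **2** | `l` | `o` | `k` |

`k`/`l`/`g` are the kept/lost/gained calls; `n` marks a pair absent
everywhere relevant. The `o` symbol (single-scorer ambiguity) is our
explicit design choice for every combination where scorer agreement fails
in either genome: such ecotypes are informative neither for loss nor for
gain, and `o` never counts as fate agreement downstream. The `n` symbol is
likewise an explicit extension — without it, the denominator of the
co-regulation score would be undefined for regulations gained in a small
ecotype subset.

**General fates.** A regulation present in the reference intersection is
`K` (kept, never lost), `KL` (lost in at least one ecotype), or `L` (lost
in all — a legal output we have not observed on realistic panels); one
absent from the reference but gained somewhere is `G`. `K` regulations are
*static*; `KL` and `G` are *dynamic*.

## The co-regulation score

For two regulations toward the same target, over the shared ecotype
universe `Eco(i,j,t)` (ecotypes where both miRNAs and the target are wild
or mutant type, none discarded):

$$coreg(i,j,t) = \frac{|EcoK| + |EcoL| + |EcoG| + |EcoN|}{|Eco(i,j,t)|}$$

where `EcoK`, `EcoL`, `EcoG` count ecotypes with joint fate (k,k), (l,l),
(g,g), and `EcoN` joint absence (n,n). Two guards reject coincidental
agreement: a `KL`/`KL` motif must be lost *together* at least once
(`EcoL` nonempty), and a `G`/`G` motif gained together at least once
(`EcoG` nonempty); otherwise the score is 0. Joint `o` never counts.

The inclusion of `EcoN` and the `G`/`G` guard are the package's
`"extended"` mode (the default). The alternative `"literal"` mode counts
only `EcoK + EcoL + EcoG` with the `KL` guard. The two modes differ
materially for gained regulations: a pair of regulations co-gained in,
say, 22 of 1,100 ecotypes scores 1.0 in extended mode but ~0.02 in
literal mode and would be filtered from the network. Extended mode treats
joint absence as agreement — the profile-similarity reading of
co-occurrence — and is the mode under which family-wide gain events
survive filtering; both are exposed because the choice is genuinely open.

Motifs whose general fates can never agree per ecotype (`K`/`G`,
`KL`/`G`, anything with `L`) are structurally 0 and excluded from typing.
The surviving combinations give the motif's co-regulation type: `ss`
(K/K), `sd` (K/KL), `dd` (KL/KL or G/G).

**Network assembly.** Motifs with `coreg < threshold` are removed (ties at
the threshold survive, matching the strictly-smaller removal rule); miRNA
pairs retaining at least one target become edges. The default threshold
0.85 is a configuration value, not an estimate — `threshold_sweep()`
exists precisely so users can pick it from the expression-support curve of
their own data. An edge's crosstalk type is the co-regulation type held by
strictly more than half of its surviving motifs (`SS`, `SD`, `DD`),
otherwise `unclassified`. Exactly half is not a majority.

## Statistical evaluation

* **Enrichment matrices** (`enrichment_matrix()`): observed
  category-pair edge counts against randomized networks, using Z-scores
  `(x_obs - mean)/sd` and normal p-values. Three randomizations: fate
  shuffling over a fixed topology, node-identifier permutation (preserves
  the degree sequence and the category multiset), and per-stratum edge
  resampling. P-values are two-sided by default — enrichment and depletion
  are both of interest — with a one-sided option; cells with zero
  randomization spread report p = 1 rather than an infinite Z. BH
  adjustment is applied across all cells of one matrix, which is the
  multiple-testing family.
* **Topology** (`topology()`): degree and unnormalized shortest-path
  betweenness (fractional counting across equally short paths — the
  standard convention, stated explicitly because graphical tools differ).
  Hubs / bottlenecks / bridges are the top `ceiling(0.15·N)` nodes or
  edges by rank, extended through value ties so that tied elements are
  treated alike; the hub and bottleneck flags partition nodes into four
  classes.
* **Expression support** (`preprocess_expression()`,
  `threshold_sweep()`): replicates are averaged, then log2; zero
  abundances are treated as missing rather than pseudocounted, because the
  downstream filter (a miRNA must have values in ≥ 6 samples) is a
  presence/absence criterion. Pairwise Pearson correlations require ≥ 3
  common samples.
* **Stress sharing** (`stress_share_test()`): fraction of edges whose
  endpoints share a stress annotation versus same-size uniform draws of
  miRNA pairs. The null pair universe is not fully determined by the
  method description; we default to the union of annotated miRNAs and
  network endpoints, overridable via `universe=`.
* **Climate similarity** (`climate_sd_test()`): the SD of a bioclimatic
  variable over an ecotype group versus uniform same-size permutations;
  the empirical p is the fraction of permutations *strictly* smaller, so
  p = 0 is attainable by construction and no pseudocount is added.

## What the synthetic generator emulates

`generate_panel()` builds panels in which the statistical structure the
method assumes is planted and known: cooperative miRNA pairs whose site
gains/losses hit identical ecotype clusters, discordant pairs whose loss
clusters barely overlap (agreement tuned analytically via cluster sizes
and overlap), singleton and indel variants at stated rates, plus a
correlated expression compendium and a geographically clustered climate
table.

Planted sites use a *marginal* duplex design: a perfect complement
degraded by two 3'-tail mismatches and one G:U wobble (miRNA positions
18–20). Such a site is present under both schemes (score 2.5 vs cutoffs
4 and 2.5) yet a single core substitution (position 10) pushes it past
both cutoffs at once (4.5 and 4.0) — so every planted gain or loss event
is one SNP, as in the single-SNP case studies the method is meant to
detect. Static-dynamic pairs get their loss SNP in the dynamic miRNA's
own sequence instead of the site; planted miRNAs carry G or U at position
20 so the wobble is always constructible.

Default conditions, chosen once as a realistic desk-scale population:
100 ecotypes, 30 miRNAs (cooperative pairs disjoint), 60 transcripts of
300 nt, 10 cooperative pairs (3 ss, 3 dd-loss, 2 dd-gain, 2 sd), 10
discordant pairs at agreement 0.3 (two 40-ecotype loss clusters
overlapping in 5), dd clusters of 20 ecotypes, sd clusters of 10 (true
agreement 0.9), 5% singleton and background-SNP rates, 10% transcript
indel rate, 30 expression samples at pair correlation 0.9. Two packaged
fixtures freeze specific configurations: `fixture_fig1e()` (one pair, 18
shared targets, 2 ss + 16 dd motifs, crosstalk DD) and `fixture_fig7a()`
(a 7-member homologous family gaining one target through a single shared
site SNP in the same 22 ecotypes).

What the generator does **not** emulate: linkage disequilibrium and
population structure among ecotypes, recombination, realistic
transcript length/UTR structure, bulged or thermodynamically scored
duplexes, and expression measurement noise beyond log-normal replicates.
Passing the planted-recovery tests therefore shows the pipeline is
correct and well-calibrated under its own model — not that the two
built-in scorers reproduce any external tool's site calls on real
genomes.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive within each sequence; multi-allelic
  VCF rows are split into biallelic records before the singleton filter.
* Substitution re-validates the reference allele, so re-applying variants
  to an already-mutated sequence errors instead of silently compounding.
* An empty shared ecotype universe makes a motif's score undefined; the
  motif is dropped with a warning rather than scored 0.
* `sd = 0` randomization cells, all-zero Fisher tables, and
  zero-annotation stress tests all degrade to p = 1.
* Pipeline problem sizes in the test suite (40–100 ecotypes, 200
  simulated matrices at 300 randomizations, 200 climate fixtures at 400
  permutations) were fixed as desk-scale study conditions; the
  calibration checks — fate-shuffle rejection within [0.03, 0.07] at
  α = 0.05, uniform climate p-values — run at exactly these sizes.

## Worked example

```{r example, eval = FALSE}
panel <- fixture_fig1e()
profiles <- population_fate_profiles(panel)
network <- build_network(profiles, threshold = 0.85)
glance(network)
tidy(network)
autoplot(network)
```

## Limitations

Pair-level semantics only: multiple sites for one pair collapse to
existence, and binding-affinity changes that do not cross the cutoffs are
invisible. The fate alphabet is tied to two-scorer agreement; with only
one prediction source every disagreement symbol `o` disappears and the
dynamics are overstated. The crosstalk network is undirected and pairwise;
higher-order cooperation is only seen through its pairwise shadow. The
`"extended"`/`"literal"` coreg ambiguity is inherent to the score's
definition for gained regulations — results for `G`/`G` motifs should be
reported with the mode stated.
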