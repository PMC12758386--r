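---
title: "Methods: dissecting subterminal heterochromatic caps with stcap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting subterminal heterochromatic caps with stcap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

African great ape chromosomes (chimpanzee, bonobo, gorilla) carry large
subterminal heterochromatic caps that humans lack. A cap is built from
megabase-scale tandem arrays of a 32 bp satellite unit (pCht, also
called StSat), interrupted ("interdigitated") by 32–34 kbp segmental
duplication (SD) copies — the *spacers*. The caps are of interest for
three reasons: their satellite variant composition records the expansion
history of each chromosome arm; the spacers are long, nearly identical,
hypomethylated sequences that are candidate substrates for ectopic
(nonallelic) recombination between chromosome ends; and the
heterochromatin–euchromatin transition at the cap boundary is enriched
for structural variation and young duplicated genes.

`stcap` implements the complete analysis chain for such regions:

1. **Satellite annotation** — detect unit occurrences against the
   consensus, type each occurrence by its variant signature, and derive
   arrays and spacers by subtraction.
2. **Composition clustering** — build the arm × variant matrix, cluster
   arms hierarchically with bootstrap support, and classify fixed-width
   cap blocks into higher-order types by two-step k-means.
3. **Spacer phylogeny** — align spacer copies, build a bootstrap
   neighbor-joining tree on JC69 distances, and convert node heights to
   ages with a strict molecular clock calibrated on fixed ape
   divergence times (6.4, 8.6, 15.2, 19.5 MYA for human versus
   chimpanzee, gorilla, orangutan, siamang).
4. **Exchange tests** — find >99.5%-identity nonallelic blocks
   (exchange candidates) with refined breakpoints, test breakpoint
   proximity to spacers by permutation, and test for within-spacer
   recombination with the half-alignment Robinson–Foulds (RF) shift
   procedure.
5. **Boundary epigenomics** — merge strand-symmetric CpG calls, profile
   methylation by compartment and along the boundary, call insertions
   from syntenic alignment gaps, and run the boundary enrichment
   permutation test.
6. **Synthetic data** — a simulator that generates cap-like genomes
   with complete ground truth, so every stage above has a
   parameter-recovery test.

Because the real T2T ape assemblies are external data, the package's
validation runs end-to-end on the simulator. Everything below states
what is emulated, what is not, and which numerical choices were open.

## The simulator and its defaults

`sim_config()` / `simulate_cap_genome()` build each arm as

```
[ euchromatic flank | array – spacer – array – … – array (telomere) ]
```

Defaults are desk-scale stand-ins for the real dimensions, chosen once:
2 kbp spacers for the real 32–34 kbp copies, 2 kbp higher-order blocks
for the real 20 kbp ones, 20 kbp boundary windows for the real 2 Mbp
ones, 60–120 kbp flanks. All are parameters; nothing is hard-coded.

**Satellite variation.** Units are drawn i.i.d. within each array from
the array's *block type*, a frequency vector over a small alphabet of
unit variants (default 8: the consensus plus substitution/deletion
signatures). The four default block types each load 0.42 on a dedicated
pair of variants; each arm favours one type (weight 0.55). This paired
design gives the two-step k-means a well-posed planted truth: variant
columns cluster into four groups and blocks into four types. Real caps
have thousands of variant types with much flatter profiles; passing the
recovery tests shows the procedure is implemented correctly, not that
real caps contain four types.

**Spacer evolution.** Spacer copies evolve from a random root along a
coalescent tree (default root-to-tip depth 0.05 substitutions/site,
matching the few-percent divergence of real spacer copies) by per-site
Poisson substitution events, each replacing a base with one of the
other three (Jukes–Cantor events, multiple hits allowed). Indels are
deliberately excluded so the true multiple alignment is the identity
and tree/RF ground truth is exact. Consequence: the center-star
aligner's gap handling is exercised only by dedicated small fixtures,
not by the simulator.

**Methylation.** Each CpG draws a per-site probability from a beta
distribution — mean 0.80 in satellite arrays, 0.35 in spacers, 0.70 in
the flank (concentration 30) — then both cytosines emit binomial
counts at Poisson(20) coverage per strand. The paper-scale contrast
(hypermethylated satellite, hypomethylated spacers, ~70% euchromatin)
is preserved; read-level autocorrelation and sequence-context effects
are not modelled. The beta-binomial form is this package's choice; no
generative model is claimed by the source analyses.

**Boundary features.** SD and gene intervals are placed over the flank
with Poisson counts, `fold` (default 5) times denser inside the
boundary window. Lengths are uniform (0.5–2 kbp SDs, 0.3–1.5 kbp
genes).

**Ectopic exchange.** `plant_exchange()` supports two modes. The
reciprocal `swap` trades distal tails between two arms — the textbook
event. On a single-haplotype simulation, however, a pure swap leaves
*no* identical nonallelic pair behind: each arm now carries the other's
tail, and the two tails were never homologous. In real assemblies a
recent exchange is visible because the donor haplotype retains the
original copy. The non-reciprocal `copy` mode reproduces that
detectable configuration (recipient takes a copy of the donor's tail;
donor unchanged), and is what the detection tests plant. Breakpoints
with `placement = "in_spacer"` land strictly inside a spacer copy;
`spacer_index` selects which (1 = most proximal, giving the longest
detectable tail).

Determinism: the whole simulation is a pure function of the config,
including its seed; all stochastic package functions take explicit
seeds and restore the caller's RNG state.

## Satellite detection: thresholds and canonical windows

Detection is seeded approximate matching (`Biostrings::matchPattern`
with indels) against the consensus on both strands, followed by global
re-alignment of each candidate under unit edit costs. The acceptance
rule follows the ">90% of the consensus" convention: strictly more
than `floor(0.9 × 32) = 28` consensus positions must be matched, i.e.
at least 29 of 32, which caps the edit budget at 3. Ties at exactly
90% are rejected. `N` never matches, and candidates over 10% `N` are
discarded.

Two canonicalization layers make output deterministic and comparable
to an exhaustive oracle:

* **Signature normalization.** Indels inside homopolymer runs are
  ambiguous (deleting either C of a CC gives the same string);
  signatures are left-normalized, so `9delC` and `8delC` collapse.
* **Canonical windows.** The seeded matcher reports narrowest ranges,
  which represent terminal variation as truncation. Every imperfect
  hit is re-windowed over all extensions within the edit budget and
  the best window kept — identity first, then leftmost start, then
  fewest edits, then longest window. Tandem context repeats heavily,
  so re-windowing is cached per local context string.

Overlapping hits are resolved greedily (identity desc, leftmost,
longest, "+" before "−"). The test suite checks exact set equality
against a sliding-window `adist` oracle on dozens of planted genomes.

Arrays merge consecutive units with gaps ≤ 5 bp (the merging distance
is not dictated by any published convention; 5 bp keeps single-indel
junctions inside one array while never bridging a real spacer), and
spacers are the cap minus the arrays, so the two classes tile the cap
exactly.

## Composition clustering choices

The arm × variant matrix normalizes by each arm's total unit count
*before* column filtering, keeps arms with ≥ 2000 units and variants
with genome-wide count > 100 (both strict in the directions stated).
Arm clustering uses 1 − Pearson correlation with average linkage.
Support values come from a plain nonparametric bootstrap over matrix
columns (100 replicates): the multiscale bootstrap of pvclust
(approximately-unbiased p-values) is intentionally replaced by the
simpler estimator with the same "fraction of replicates containing the
group" semantics; values are therefore plain bootstrap percentages,
not AU p-values.

Two-step k-means: step 1 clusters variant signatures by their
across-arm frequency vectors (the composition-matrix columns, taken as
is — re-normalizing per variant was the open alternative; the raw
columns keep abundant and rare variants on the arm-frequency scale the
matrix already defines); step 2 represents each block by its
composition over step-1 clusters and clusters blocks. Both steps pick
k by maximal mean silhouette (Euclidean distance — no metric is
prescribed anywhere, and Euclidean on composition vectors is the
k-means-consistent choice), k-means++-style multiple random starts
(`n_init = 10`, fixed seed, so results are reproducible). Blocks are
tiled over the *annotated satellite arrays* rather than whole cap
spans, so blocks never straddle a spacer; terminal partial blocks of
at least half width stand alone, shorter ones merge into their left
neighbour. Degenerate inputs (fewer variants than the smallest k, or
identical frequency vectors, for which the silhouette is undefined at
k > 1) raise informative errors rather than returning arbitrary
labels.

## Spacer phylogeny: distance trees and a strict clock

Copies shorter than 90% of the modal length are dropped. The MSA is
center-star: the center is the copy with maximal mean pairwise
identity, all others are globally aligned to it (match 1, mismatch −1,
gap open 4, extend 1) and gap patterns merged. For the ≥90%-identical
spacer regime this is effectively exact; the classical sum-of-pairs
bound (within 2(1 − 1/k) of optimal) is verified against an exhaustive
three-sequence alignment in the tests. Substitution-only input
round-trips without gaps.

Trees are neighbor-joining on JC69-corrected p-distances (raw
p-distance available); saturated pairs (p ≥ 0.75) abort with the pair
named. Negative NJ branches are clamped to zero with the deficit moved
to the sibling, preserving paths through the parent. Support comes
from site-resampled bootstrap replicates.

Dating is a strict clock: node height = mean substitutions/site to
descendant tips; one global rate is fitted by least squares through
the calibrated nodes (`rate = Σ h·a / Σ a²`), and ages are heights
over rate, forced monotone root→tip. Rooting is on the outgroup of
the oldest calibration, with one subtlety: `ape::root()` leaves the
root *at* the outgroup's attachment node, which under a clock biases
the root height low (the outgroup terminal edge absorbs the whole
basal path). The root is therefore slid along the outgroup edge to the
point where outgroup depth equals mean ingroup depth. Without this
correction the fitted rate absorbs a systematic error from the
heaviest calibration. Confidence intervals re-date site-resampled
bootstrap trees and match nodes across replicates by their descendant
tip sets. This strict-clock NJ pipeline deliberately replaces
maximum-likelihood inference with tip-dating software; consistency of
NJ with ML topologies on these data is the premise, and the simulated
recovery tests (topology exactly recovered in ≥ 9/10 clock
simulations; ~99% of node ages within 10% at 20 kbp alignments) bound
what it can do under clock-like evolution. It is *not* expected to
reproduce published age estimates that depend on external genomes and
ML model fits.

## Exchange detection and the two tests

`pairwise_identity()` anchors on k-mers unique within each sequence
(k = 21), groups anchors into near-constant diagonal bands, chains
left-to-right with bounded gaps, and rescores exactly: same-diagonal
gaps bytewise, small shifted gaps by global alignment. Chains split at
weak gaps (identity < 0.99 over ≥ 100 bp) so a 100%-identity exchanged
tail is not diluted by an adjacent merely-homologous spacer. Tandem
satellite interiors contain no unique k-mers; chains bridge them via
the `window` parameter (default 50 kbp ≥ the longest anchor desert).
Consequences worth knowing: breakpoint resolution is bounded by
residual homology — when the recipient's own spacer is closely related
to the donor copy, the block legitimately extends proximally (hundreds
of bp at 2 kbp spacer scale); and block ends inside terminal satellite
arrays stop at the last unique anchor.

`detect_candidates()` keeps nonallelic blocks with identity > 0.995
over a minimum span (10–20 kbp at synthetic scale, standing in for the
megabase filter used on full assemblies), merges them per arm pair,
and reports the proximal edge per arm as the refined breakpoint, with
a ">99.8%" recency class.

**Breakpoint permutation test.** Statistic: mean distance from each
breakpoint to the nearest spacer base (0 inside). Null: each
breakpoint re-placed uniformly *within its own cap* (the shuffle
universe is not specified by any convention we inherit; per-cap
placement conditions on the observed chromosome assignment), 1000
shuffles, one-sided toward proximity, add-one corrected so p is never
zero. A one-sided Wilcoxon rank-sum comparison of observed distances
versus pooled null distances is reported alongside, mirroring the
alternative test statistic that appears in published analyses of this
kind; the permutation p is primary.

**RF shift test.** Full-alignment NJ tree T, half-alignment trees T1,
T2 (first ⌈L/2⌉ columns / rest); observed statistics RF(T, Ti) in
unrooted symmetric-difference form. Null: RF between each of n_boot
full-alignment bootstrap trees and their majority-rule consensus;
p_i = (1 + #{null ≥ RF(T,Ti)}) / (1 + n_boot). Calibration was
characterized by simulation at the spacer regime (8 copies, 2 kbp,
0.05 subs/site): type-I error ≈ 0.03–0.04 at α = 0.05 on coalescent
trees, which include the weak-signal near-identical-copy situation the
test actually faces. Power is reported against *resolvable* chimeras —
both planted topologies with every internal branch ≥ 0.005 subs/site
(≈10 substitutions over a 2 kbp spacer) and maximal RF between them —
because no method can detect a shift between topologies the data
cannot resolve; there it exceeds 90% at p < 0.01.

## Boundary epigenomics

`merge_cpg()` keys both cytosines of a CpG to the + strand C, sums
counts, validates dinucleotide context when sequences are supplied
(non-CpG calls are skipped with a warning and counted), applies the
≥ 5-read filter *after* merging, and is idempotent. Count conservation
before the filter is asserted in the tests.

`call_insertions()` emits query intervals uncovered by any alignment
chain and ≥ 50 bp (the minimum structural event size) as insertions,
then re-aligns each against a panel of candidate source arms; the best
hit with ≥ 50% coverage and ≥ 90% identity assigns the source,
otherwise "unplaced".

`boundary_enrichment_test()` measures feature bp density inside
boundary windows, counted with multiplicity (a coverage-style reduce
saturates when features overlap, biasing the fold toward 1). The null
re-places each feature uniformly within its chromosome's allowed spans
(lengths preserved, overlaps allowed; cap spans excluded from the
universe — features shuffled, not windows, since the windows are fixed
by the cap anatomy). Two folds are reported: window density over
genome-wide density (the conventional headline number — note it is
diluted when windows are a large fraction of the genome, as at
synthetic scale where a 5× planted enrichment reads ≈ 3.4 genome-wide)
and window density over *outside-window* density, which is the
generator's own parameter and recovers the planted 5× within 20% (in
expectation over seeds).

Boundary windows anchor at the cap-proximal edge of the last satellite
unit; capless arms use the terminal tip.

## Problem sizes and runtime

The shipped tests and the acceptance script run everything at
desk scale, chosen as the package's own study conditions: the
end-to-end genome is 6 arms ≈ 2 Mbp (≈28,000 units, one planted copy
exchange), clustering recovery uses 10 six-arm genomes, phylogeny
recovery 10 clock simulations at 20 kbp, test calibration 100–200 null
runs and 40–50 power runs. The complete suite finishes in roughly a
quarter hour on one CPU.

## Known limitations

* The simulator omits indels within spacers, unit-order
  autocorrelation, higher-order repeat turnover and assembly error;
  recovery on it validates implementation, not robustness to real-cap
  messiness.
* The aligner is for high-identity comparisons (caps, haplotypes,
  syntenic arms); it is not a general-purpose aligner and will
  fragment below ~90% identity where unique 21-mer anchors thin out.
* Strict-clock dating inherits all strict-clock caveats; rate
  variation across spacer lineages will distort ages even when the
  topology is right.
* Bootstrap supports are plain bootstrap proportions, not
  approximately-unbiased p-values.
* The RF shift test's null conditions on the full-alignment bootstrap;
  with very few informative sites both observed and null collapse to
  zero and the test is conservative rather than anticonservative.
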