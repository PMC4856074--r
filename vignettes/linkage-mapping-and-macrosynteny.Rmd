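---
title: "Haploid linkage mapping and macrosynteny: models and methods"
author: "haplomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haploid linkage mapping and macrosynteny: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomap)
```

haplomap fits genetic linkage maps to haploid progenies of dikaryotic
fungal hybrids (the mapping design used for mushroom crops such as
*Agaricus subrufescens*) and assesses chromosome-scale synteny of the
resulting map against a congeneric reference genome (*A. bisporus* in the
motivating application). This vignette records the statistical model, the
staged mapping procedure, every tunable parameter, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## The genetic model

Progeny are single-spore isolates carrying one haploid nucleus, so each
marker call is simply the parental origin of the allele: `P1`, `P2` or
missing. Along one chromosome, the origins of an individual form a
two-state Markov chain: the origin at the first locus is a fair coin, and
between adjacent loci the origin switches with probability equal to the
interval's recombination fraction $r$. This "no interference beyond the
map function" assumption makes adjacent-interval recombination fractions
exactly recoverable and keeps the multipoint likelihood correctly
specified; crossover interference enters only through the map function
used to convert $r$ to distance.

**Two-point estimation.** For markers $a, b$ with $N$ doubly-scored
individuals of which $R$ are recombinant, $\hat r = R/N$ and the LOD score
is the log10 likelihood ratio against free recombination,
$$\mathrm{LOD} = R \log_{10}\hat r + (N - R)\log_{10}(1 - \hat r) +
N \log_{10} 2,$$
with $0\log 0 = 0$; estimates at or above $0.5$ are reported as
$r = 0.5$, LOD $= 0$.

**Map distances.** Recombination fractions convert to centimorgans with
the Kosambi function $d = 25\ln\{(1+2r)/(1-2r)\}$, which admits partial
interference; the Haldane function is available for the simulator. Both
inverses are closed-form and round-trip to near machine precision.

**Multipoint likelihood.** For a fixed order with interval fractions
$r_1,\dots,r_{m-1}$, each individual's likelihood is computed by the
forward algorithm on the two-state chain, so missing calls are
marginalised exactly; the reported value is conditional on each
individual's first observed state (an all-missing individual contributes
nothing). Interval fractions for a fixed order are re-estimated by EM
(Baum-Welch): the E-step computes each individual's posterior switch
probability per interval by forward-backward, the M-step averages over the
individuals actually informative for that interval (observed on both
sides). Convergence is declared at $\max|\Delta r| < 10^{-6}$ (at most 100
iterations; ordering searches use a looser $10^{-4}$/30-iteration setting
and the winning order is always refit at full tolerance). With complete
data the first iteration already lands on the observed adjacent
recombinant fractions.

## The staged mapping procedure

`linkage_map()` reproduces the classical staged workflow:

1. **Segregation QC.** Every marker is tested against the Mendelian 1:1
   ratio with a plain chi-square (1 df, no continuity correction — progeny
   sizes here are ~70-80, where the correction is conventionally omitted).
   Flags use the raw $p < \alpha$ with $\alpha = 0.05$ and no
   multiple-testing correction, matching standard practice where the flag
   feeds a filtering rule rather than an inference.
2. **Round-one selection.** The framework round admits codominant markers
   with missing fraction $\le 0.30$ and no distortion flag. Dominant AFLP
   markers are held out; distorted AFLPs are removed for good, distorted
   or gappy codominant markers are deferred to stage two.
3. **Grouping.** Linkage groups are connected components of the graph
   whose edges are marker pairs with LOD $\ge 4.0$ and Kosambi distance
   $\le 30$ cM (single-linkage transitive closure).
4. **Ordering.** Groups of $\le 7$ markers are ordered exactly by
   enumerating all orders up to reversal and maximising the multipoint
   likelihood. Larger groups are seeded with an exhaustively ordered
   five-marker core chosen by maximin two-point distance (so the core
   spans the group), extended by best-position insertion, and polished by
   `ripple()`: a sliding window (default 5) whose internal permutations
   are accepted only on strict likelihood improvement, iterated to a fixed
   point. A sum-of-adjacent-rf criterion is available as a fast screen.
5. **Assignment and placement.** Each deferred marker joins the group
   holding its best two-point LOD if that LOD exceeds 6, at the insertion
   position maximising the multipoint likelihood. If the best and
   second-best placements at *genuinely different map positions* are
   separated by less than 2.0 log10-likelihood units the marker is dropped
   as ambiguous. Two positions that tie because they are the same map
   point — either side of a co-segregating marker — do not count as
   ambiguity, so zero-recombination clusters place cleanly. A deferred
   marker linked at grouping thresholds to two framework groups merges
   them. Markers that remain unassigned are re-grouped among themselves,
   so a cluster of (for example) jointly distorted markers can still form
   its own linkage group; orders are confirmed with a final ripple pass.
6. **Numbering.** Groups are renumbered by descending map length, ties
   broken by marker count then by the first marker id; each group is
   reported in its reversal-canonical orientation (lexicographically
   smaller endpoint first). All tie-breaks are deterministic, so the whole
   pipeline is reproducible from the input alone.

Parameters, all exposed as arguments with these defaults: `lod_group`
(4.0), `dmax_cM` (30 cM), `lod_assign` (6.0), `ripple_window` (5 markers),
`ambiguity_delta` (2.0 log10 units), `missing_max` (0.30), `alpha` (0.05),
`exhaustive_max` (7 markers). The missing-data bound is inclusive
(`missing_frac <= 0.30` passes); the ambiguity threshold quantifies the
qualitative notion of a marker "difficult to place".

**Genome length and coverage.** Two method-of-moments estimators are
provided. `hulbert_mom` counts the $K$ marker pairs at LOD $\ge Z$
(default $Z = 4$) and takes $L_e = N(N-1)X/K$ with $X$ the largest
distance among those pairs; under random marker placement
$N(N-1)X/L_e$ pairs are expected within $X$, and the estimator simply
inverts that moment. On simulated 150-marker genomes of known 2000 cM
length this recovers the truth within 15%. `per_group_inflation` expands
each group for the chromosome tails beyond its terminal markers,
$L_e = \sum_i \ell_i (m_i+1)/(m_i-1)$. Applied to the published
*A. subrufescens* per-group table this gives $\approx 1997$ cM — notably
*not* the 2458 cM reported alongside that table, and no estimator variant
we examined reproduces that figure from the printed numbers; both
estimators are therefore exposed and the discrepancy is left on record
rather than resolved. Expected map coverage uses
$P = 1 - (1 - 2c/L_e)^m$; with $c = 10$, $L_e = 2458$ and $m = 202$ the
formula yields $P = 0.808$, which likewise differs from the 79% printed
next to it (and implies a ~1.8-fold, not 2.3-fold, marker increase for
95% saturation) — the package exposes the formula and records the
mismatch.

## Macrosynteny assessment

Mapped sequence-based markers are joined to reference genes via a
blast-like hit table: a hit qualifies below e-value $10^{-10}$, each
marker keeps its best (smallest e-value) qualifying hit, and a marker
whose two best qualifying hits on different scaffolds lie within a factor
10 in e-value is flagged multi-hit — the signature of a multigene family —
and excluded from collinearity scoring. A gene's physical position is the
midpoint of its model's span: interval sign tests need one representative
coordinate per gene, and the midpoint avoids orientation artefacts.

The Oxford grid cross-tabulates homolog pairs by linkage group and
chromosome; each group is assigned its modal chromosome (ties remain
unassigned), off-modal pairs counted discordant. Collinearity orders each
group's pairs by map position, picks the block orientation ($\pm 1$)
maximising agreement — the published analyses do not state how
orientation was fixed, so majority-sign orientation is our explicit
choice — and calls an adjacent interval collinear iff
$\mathrm{sign}(\Delta \mathrm{bp})\cdot\mathrm{orientation} =
\mathrm{sign}(\Delta \mathrm{cM})$. Zero-length intervals (co-located
markers or genes) are skipped rather than counted against. The fraction
is invariant under whole-group reversal and coordinate mirroring.

When two linkage groups share one chromosome, their homolog spans are
classified: disjoint spans with the outer span within 10% of a chromosome
end give `"terminal"` (the karyotype signature of a chromosome fission in
the mapped lineage, or a terminal translocation), overlapping spans give
`"interleaved"`, and disjoint interior spans `"disjoint"`. The 10% end
tolerance is configurable.

## Homolog density along the reference genome

EST-to-genome hits (PSL or a simplified TSV dialect) are filtered on the
composite score coverage × identity with threshold 0.60 — coverage is
defined on the query side, and the boundary keeps a (coverage 0.75,
identity 0.80) hit exactly. One best hit per query survives (score, then
match count, then smallest (scaffold, start)). Gene-model overlap is at
least one shared base under 0-based half-open coordinates.

Per scaffold, genes are binned by midpoint into 50-kb windows (midpoint
binning gives each gene exactly one window, so spanning genes are not
double-counted); the expected overlapped count per window is the scaffold
total scaled by the window's share of gene models. Windows with expected
count below 1 are merged into their nearest neighbour before the
chi-square test — the published analysis is silent on sparse windows, and
without merging the test statistic is invalid there. A scaffold is
declared nonuniform at $p < 0.01$, and only then are windows flagged hot
or cold at Pearson residuals beyond $\pm 2.576$, aligning the window-level
flags with the scaffold-level 1% test.

## The synthetic-data generator

`sim_config()` defaults describe the study conditions the package
targets: 79 haploid progeny; 202 markers over 13 chromosomes whose
genetic lengths descend 202..65 cM (the published major-group lengths);
40% dominant AFLP markers (90 of 224 in the motivating panel); 9% missing
calls (an average of 72 of 79 individuals scored per locus); a
380-isolate spore pool with 79% heterokaryons (301 of 380); a 21-locus
microsatellite ploidy panel; and viability-driven segregation distortion
at distal loci (two loci with $s = 0.5$, i.e. carriers of one parental
allele survive with probability 0.5, applied by rejection sampling of
whole individuals — reproducing the distal clustering of distorted
markers). The reference side lays 150 genes per chromosome at 3-kb
spacing (so a 50-kb window holds ~16 genes, adequate for the chi-square
defaults) and derives the reference gene order by applying inversions,
translocations, fissions and fusions to the mapped genome's order. EST
hits draw coverage and identity high for reliable alignments, force a
configured fraction below the 0.60 score, and add paralogous secondary
hits with a configured probability.

What the generator does *not* emulate: genotyping error and scoring
conflicts between experimenters (calls are correct or missing), crossover
interference beyond the map function, heterogeneous gene spacing and
repeat-rich regions, sequence-level similarity (no nucleotides exist),
and real multigene-family structure (paralogous hits land on random
genes). Tests passing on these simulations therefore validate the
estimators and the pipeline logic under the stated model, not robustness
to miscalled genotypes or annotation artefacts.

## Problem sizes used by the tests and the acceptance script

Stochastic checks fix their seeds and state their sizes explicitly, all
chosen as the smallest sizes at which the quantity under test is sharply
identified. Recombination-fraction recovery uses 1000 independent marker
pairs at true $r = 0.10$ with 79 progeny. The heuristic-vs-exhaustive
ordering check runs 50 simulated groups of 4-7 markers at 15-cM spacing,
79 progeny. Type-I calibrations use 2000 effectively unlinked balanced
markers (pairs 200 cM apart) and 2000 multinomial window replicates. The
end-to-end closure check (13 chromosomes, rearrangement-free, bijective
Oxford grid and collinearity 1.0) and the fission-signature check use 200
progeny rather than 79: closure is an algorithmic identity of the
pipeline, and at 79 progeny it fails for a nontrivial fraction of seeds
through chance alone — a spurious LOD $\ge 4$ two-point link merging two
chromosomes, or a whole-chromosome segregation drift deferring an entire
group; the statistical behaviour at the study scale is covered separately
by the rf-recovery, linkage-group-count and calibration checks.

## Known limitations

- The mapping engine targets haploid 1:1 designs only; no F2/outbred
  codings, no segregation models beyond 1:1, no QTL machinery.
- Single-linkage grouping inherits the classical sensitivity to one
  spurious two-point link at ~200-marker scale; the thresholds (LOD 4,
  30 cM) are the conventional mitigation, not a guarantee.
- The multipoint engine assumes the Markov (no-interference) chain;
  Kosambi distances reintroduce interference only in the metric.
- Collinearity is scored at marker resolution; micro-rearrangements
  between adjacent homolog anchors are invisible.
- `estimate_genome_length()` assumes markers approximately uniform on the
  genome; strongly clustered markers bias the pair-count moment.

```{r example, eval = FALSE}
# a complete in-memory run on simulated data
cfg <- sim_config(seed = 1)
cross <- simulate_cross(cfg)
map <- linkage_map(cross$genotypes)
summary(map, genotypes = cross$genotypes)
pair <- simulate_genome_pair(cfg, cross)
hits <- simulate_hits(cfg, pair)
synteny_analysis(map, hits$marker_hits, pair$gene_models)
```
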