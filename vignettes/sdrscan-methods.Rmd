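---
title: "Methods: detecting a sex-determining region and an introgressed Y"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting a sex-determining region and an introgressed Y}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sdrscan)
```

## The problem

In a species with genetic male heterogamety, the sex-determining region
(SDR) is the chromosomal segment where X and Y no longer recombine. Three
signatures localise it from population resequencing data: elevated
male-female F~ST~, sex-limited alleles (present at appreciable frequency in
one sex, absent in the other), and inflated male:female nucleotide
diversity (males carry both gametologs). Once the SDR is found, gene trees
over phased haplotypes reveal its mode of origin: a single-origin Y makes
one haplotype from every male coalesce into a male-only clade
("XY-consistent" topology), and the placement of that Y clade relative to
sister species distinguishes an introgressed Y (Y nested inside the donor
species, with reduced Y-donor divergence) from deep coalescence
(incomplete lineage sorting, with *elevated* divergence).

`sdrscan` implements this programme for a three-species system with
topology ((sinensis, tymensis), pungitius) plus an outgroup that carries
the ancestral allele, and ships a coalescent window simulator with known
truth so that every stage is testable end to end without external data.

## Stage-by-stage model

**Male-female scan.** Windowed haplotype-frequency statistics: Hudson's
F~ST~ as a ratio of sums (per site, numerator
$(p_A-p_B)^2 - p_A(1-p_A)/(n_A-1) - p_B(1-p_B)/(n_B-1)$, denominator
$p_A(1-p_B)+p_B(1-p_A)$), the percentage of SNPs whose minor allele
exceeds frequency 0.1 in one sex while absent in the other, per-site
$\pi = \sum \frac{n}{n-1} 2p(1-p) / L$, and log~2~ male:female ratios of
$\pi$ and normalised read depth. Hudson's estimator was chosen because it
is unambiguous on haplotype frequencies and has a clean small-sample
correction; negative window values are reported as-is so simulation nulls
stay unbiased. The SDR call is the longest run of at least 3 consecutive
focal-chromosome windows whose F~ST~ exceeds the autosomal 99th
percentile (at least 20 autosomal windows are required for the null).

**Gene trees.** Neighbor joining on Jukes-Cantor distances, rooted on the
outgroup (midpoint as a logged fallback), with lexicographic tip ordering
for determinism. Distances within analysis windows are computed per bp
(monomorphic positions count as identical): with a deep outgroup, the
mismatch fraction over SNP columns alone sits close to the 3/4 saturation
point of the Jukes-Cantor correction, where window-to-window noise crosses
the cap and scrambles topologies; per-bp distances keep the outgroup at
its true divergence (about 0.13) and far from saturation. A likelihood
tree builder could be substituted behind the same interface; NJ was chosen
for speed and exact reproducibility at desk scale.

**XY consistency.** A rooted window tree is XY-consistent when some clade
contains exclusively focal-species male haplotypes, at most one per male,
covering at least a fraction *q* of males. The default *q* = 1 is the
strict single-origin-Y reading; a relaxed *q* is exposed because
heterozygote dropout in real data breaks perfect coverage.

**Y phasing by voting.** Gene trees are built in overlapping sliding
windows; in each window with a qualifying exclusively-male clade
(*q*~min~ = 0.5 by default - the clade need not contain every male), the
member haplotypes are scored Y-linked, and every heterozygous site of a
scored male votes for the allele its scored haplotype carries. The Y
allele per (male, site) is the across-window majority; ties stay missing.
Votes are unweighted - the procedure is plain counting. The default step
is window/5, so each site is interrogated by five trees and a single
switch error is outvoted. X haplotypes are rebuilt as the complement at
decided heterozygous sites; outside the SDR the procedure naturally
yields missing assignments.

*Choosing the phasing window.* A haplotype must be switch-free across a
window to be scored, so the window size must track phasing quality. With
clean phasing the default 100-kb windows decide >99% of heterozygous
sites at 100% accuracy in simulation. Under heavy switch error
(per-site switch probability 0.02, i.e. one switch per ~50 SNPs) the
appropriate regime is windows of roughly the error-free segment length
(~200 bp at the default SNP density), dense overlap (step = window/5),
relaxed clade coverage (*q*~min~ = 0.3), and a vote-margin threshold
(`min_margin` = 4): a site is decided only when the winning allele leads
by at least four votes. This trades coverage (about 60% of heterozygous
sites decided) for accuracy (about 97-98% in simulation); the margin
generalises the tie rule into a confidence threshold and is reported with
each assignment.

**Topology weighting.** For four groups (pungitius X, pungitius Y,
sinensis, tymensis), quartets with one tip per group are enumerated
(exhaustively when the product of group sizes is at most 10,000, else by
Monte Carlo) and classified into T1 = (X,Y)|(sin,tym),
T2 = (X,sin)|(Y,tym), T3 = (X,tym)|(Y,sin) by path-disjointness. T3 is
the Y-donor sisterhood signal; T1 is the recombining (PAR) signal.

**Direction of introgression.** `donor_sinensis` requires the clade
spanned by Y and sinensis tips to exclude X and tymensis tips *and* to
equal the MRCA of sinensis alone (sinensis paraphyletic, Y nested).
`donor_pungitius` is the mirror image. Everything else is `ambiguous` -
including the sister arrangement (Y-clade, sinensis-clade), which carries
no directional information.

**Introgression scan.** Site patterns are polarised strictly by the
outgroup haplotype (sites with a missing or polymorphic outgroup are
skipped). Per window, $D = \sum(ABBA-BABA)/\sum(ABBA+BABA)$ and
$\hat f_d = \sum(ABBA-BABA)/\sum(ABBA_d-BABA_d)$ with the dynamic donor
$p_d = \max(p_2, p_3)$ site-wise. $\hat f_d$ estimates an admixture
fraction and is reported only for windows with $D \ge 0$; negative-$D$
windows carry a reason code. Windows with no ABBA/BABA imbalance at all
($D = 0/0$) but a positive $\hat f_d$ denominator report $\hat f_d = 0$:
between well-sorted species most informative sites sit on internal
branches of the donor, which contribute to the denominator only, and the
estimator is then a well-defined zero rather than missing. Two standard
configurations are built in: species (P1 = tymensis, P2 = sinensis,
P3 = pungitius) and sexed (P1 = pungitius females, P2 = pungitius males,
P3 = sinensis); haplotype (not genotype) frequencies are used throughout.

**Divergence.** $d_{xy} = \sum [p_A(1-p_B) + p_B(1-p_A)] / L$. The
ILS-versus-introgression test is a one-sided Wilcoxon rank test of
SDR (Y-versus-donor) windows against autosomal (species-pair) windows:
significantly *greater* SDR divergence is consistent with lineage
sorting, anything else with introgression. Coding-sequence divergence
uses Nei-Gojobori (1986) counting: synonymous site fractions averaged
over the two sequences, multi-hit codons averaged with equal weight over
all minimal mutational pathways (pathways through stop codons excluded;
if every pathway hits a stop, all are used), and Jukes-Cantor correction
of both proportions. Equal pathway weighting keeps exact desk-scale
oracles; no transition/transversion or codon-frequency parameters are
fitted. A substitution is assigned to a group when the derived allele
reaches frequency 0.5 among its genotyped haplotypes, and is *private*
when the derived allele is absent from every other group - explicit
operational choices, with the outgroup used only for polarisation.

## The simulator and what it does (not) emulate

Each analysis window receives an independent genealogy (no recombination
within a window, free recombination between windows - matching the
windowed analyses and giving closed-form expectations), onto which
mutations are dropped as a Poisson process per branch under infinite
sites, with positions drawn uniformly without replacement.

Genealogies follow the species tree ((sinensis, tymensis), pungitius)
with within-population Kingman coalescence. In SDR windows the male Y
lineages always coalesce into a single young clade (single-origin Y);
under `introgression` that clade joins a held-out sinensis lineage at
`t_intro`, which guarantees the Y coalesces *inside* the sinensis clade
- the defining feature of the scenario, made structural rather than left
to chance. `introgression_reverse` mirrors this (sinensis nests inside
pungitius); `ils` realises classic deep coalescence - the Y lineage
joins only after the remaining sample has fully coalesced, so Y-donor
divergence exceeds the genomic average, the lineage-sorting prediction
(a Y joining the ancestral pool exactly at the split would be
indistinguishable from the autosomal background);
`xy_ancestral` holds the Y out to a fixed older time;
`no_sdr` treats every window as autosomal.

Default parameters (coalescent units):

| parameter | default | rationale |
|---|---|---|
| `t_st`, `t_pun` | 0.87, 1.27 | calibrated so autosomal d~xy~ matches the observed synonymous divergences (~0.018 sinensis-tymensis, ~0.025 sinensis-pungitius) after adding expected ancestral coalescence |
| `t_out` | 7 | outgroup divergence ~0.126 per site |
| `mu` | 0.009 /site/unit | sets the above on the d~S~ scale; implies a realistic SNP density (~0.17/bp over all samples) |
| `coal_rate` | 10 | within-species diversity pi ~0.002, a realistic pi/divergence ratio; species monophyly is near-certain by the first split |
| `coal_rate_y` | 100 | the Y is young and of single origin: negligible Y diversity |
| `t_intro` | 0.05 | recent introgression; a free parameter, not an estimate |
| SDR interval | 3.5-18.9 Mb of 21 Mb, rescaled | the inversion breakpoints of the focal chromosome, scaled to the simulated length |
| samples | 15/15, 11/9, 13/10 diploids | the study design (pungitius M/F, sinensis, tymensis) plus one haploid outgroup |

Phase-switch errors are a per-male Markov process along the site axis:
at each site the switch state flips with the given probability, and the
two haplotype columns are exchanged wherever the state is on. Truth
refers to the original chromosomes.

The generator does **not** emulate: within-window recombination,
autosomal gene flow (the species-configuration f~d~ is therefore ~0 on
simulated autosomes, unlike real data with ongoing hybridisation),
heterozygote dropout or genotyping error, selection, repeat elements, or
expression. Passing tests therefore demonstrate correctness of the
statistics and the recovery logic under the stated genealogical
conditions - not robustness to artefacts the generator omits.

## Numerical choices and degenerate inputs

- Sites with >20% missing haplotypes are excluded from every scan
  (configurable); no imputation, and each statistic additionally defines
  its own per-site completeness requirement (F~ST~: 4 haplotypes per
  group; sex-limited fraction: 80% of each sex genotyped; pi: 2
  haplotypes; f~d~: 2 per ingroup population and a monomorphic,
  genotyped outgroup).
- Windows below the SNP minimum report missing statistics, never zeros.
- The pi denominator is window bp by default; a SNP-only mode is
  provided since either convention is found in practice.
- Jukes-Cantor distances at $p \ge 3/4$ are capped at 5 and counted.
- NJ negative branch lengths are clamped to zero; ties in clade choice
  skip the window rather than guess.
- All randomness flows from a single integer seed through fixed
  per-window derivations; the code is single-threaded, so results are
  identical regardless of available cores, and pipeline outputs embed the
  config hash and seed but no timestamps - reruns are byte-identical.

## Problem sizes

The shipped tests and the acceptance script run the default conditions at
a 2-Mb focal chromosome plus a 2-Mb autosome with 100-kb windows (20
windows each, ~16,000 SNPs per window across 74 samples), 100
independent autosomal windows for the false-positive check, and 32
windows per scenario class for the divergence test. These sizes give
stable statistics (Monte-Carlo error well inside the asserted margins)
at desk scale.

## Known limitations

- The voting phaser assumes a single-origin Y young enough to form a
  tight clade; a polyphyletic or old Y would lower clade coverage and
  leave sites undecided.
- Direction classification requires the donor clade to remain
  paraphyletic in the reconstructed tree; with very recent donor
  coalescence the sister arrangement is returned as `ambiguous` rather
  than guessed.
- The ILS test is a rank test on window values; it assumes enough
  windows (>= 5 per set, >= 30 for comfortable power) and exchangeable
  window noise.
- NG86 understates divergence at high saturation; records with
  $p \ge 3/4$ are flagged missing rather than extrapolated.
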