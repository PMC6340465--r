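# sdrscan

Windowed population-genomic detection of a sex-determining region (SDR) and
phylogenetic analysis of a Y chromosome that originated by introgression
from a sister species.

`sdrscan` is aimed at population geneticists working with phased
resequencing data from species with young or cryptic sex chromosomes. It
implements the full analysis chain for a three-species stickleback-like
system — *Pungitius pungitius* (focal, XY), *P. sinensis* (candidate Y
donor), *P. tymensis*, and an outgroup carrying the ancestral allele:

1. **SDR localisation** — per-window male–female Hudson F<sub>ST</sub>
   (ratio of sums of
   (p<sub>A</sub>−p<sub>B</sub>)² − p<sub>A</sub>(1−p<sub>A</sub>)/(n<sub>A</sub>−1) − p<sub>B</sub>(1−p<sub>B</sub>)/(n<sub>B</sub>−1)
   over p<sub>A</sub>(1−p<sub>B</sub>)+p<sub>B</sub>(1−p<sub>A</sub>)),
   sex-limited SNP percentage, π and log₂ M:F ratios of π and coverage,
   with the SDR called as the longest run of windows above the autosomal
   99th percentile.
2. **XY-consistent gene trees** — neighbor-joining window trees in which
   one haplotype from every male forms a male-only clade, the signature of
   a single-origin Y.
3. **Y phasing by gene-tree voting** — overlapping sliding windows score
   male haplotypes Y-linked when they fall in an exclusively male clade;
   each heterozygous site takes the across-window majority vote.
4. **Introgression scans** — ABBA-BABA D and the dynamic-donor admixture
   estimator f̂_d (p_d = max(p₂,p₃) site-wise) in the species and the
   sexed (punF, punM, sin, outgroup) configurations.
5. **Topology weighting and direction** — quartet weights over
   (punX, punY, sin, tym); donor classification from clade nesting
   (Y inside sinensis ⇒ sinensis donated the Y).
6. **Divergence** — d<sub>xy</sub>, a rank test separating introgression
   (reduced Y–donor divergence) from incomplete lineage sorting (elevated),
   Nei–Gojobori dN/dS with exact pathway counting, and private-substitution
   partitioning.
7. **Synthetic data with known truth** — a per-window coalescent generator
   for autosome/PAR/SDR windows under introgression, reverse-donor,
   lineage-sorting and null scenarios, calibrated so autosomal divergences
   match the observed synonymous divergences (≈0.018 sinensis–tymensis,
   ≈0.025 sinensis–pungitius, ≈0.126 to the outgroup).

Standard formats throughout: phased VCF in/out, TSV metadata and tables,
Newick trees.

## Worked example

```r
library(sdrscan)

cfg <- scenario_config(seed = 11)        # 2-Mb sex chromosome + 2-Mb autosome
rep <- run_pipeline(cfg, "run1")         # simulate + all stages (~2.5 min)
str(rep$verdicts)
```

```
List of 12
 $ sdr_detected               : logi TRUE
 $ sdr_overlaps_truth         : logi TRUE
 $ xy_consistent_fraction_sdr : num 1
 $ mean_T1_par                : num 1
 $ mean_T3_sdr                : num 1
 $ direction_majority         : chr "donor_sinensis"
 $ donor_sinensis_fraction_sdr: num 1
 $ mean_fd_sexed_sdr          : num 0.613
 $ mean_fd_sexed_autosome     : num 0.000271
 $ ils_classification         : chr "introgression_consistent"
 $ ils_p_value                : num 1
 $ ils_mean_difference        : num -0.0222
```

Reading the verdicts: the F<sub>ST</sub> scan recovers the simulated SDR
(`sdr_call` lands within one 100-kb window of the true inversion
interval); every SDR gene tree is XY-consistent while PAR trees are not;
topology weights put the rebuilt Y with sinensis (T3 ≈ 1) inside the SDR
and with the X (T1 ≈ 1) in the PAR; the sexed f̂_d mean is strongly
positive in the SDR and ≈0 on the autosome; and Y–sinensis divergence in
the SDR is *below* the autosomal pungitius–sinensis average
(`ils_mean_difference` < 0, p ≈ 1), rejecting the lineage-sorting
alternative — the combined signature of a Y acquired by introgression
from sinensis. `run1/` holds the per-stage tables (`sexdiff.tsv`,
`xy_consistency.tsv`, `y_assignment.tsv`, `topology_weights.tsv`,
`fd_scan.tsv`), Newick trees, the rebuilt X/Y VCF, and `report.json`.

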