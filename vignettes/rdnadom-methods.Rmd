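---
title: "rdnadom: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rdnadom: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnadom)
```

# The inference problem

*Arabidopsis thaliana* carries its ~10 kb 45S rRNA genes in two tandem
arrays, rDNA-2 and rDNA-4, at the distal ends of chromosomes 2 and 4. Each
array behaves genetically as a single non-recombining haplotype ("allele")
inherited together with its flanking region. Within an individual, a
sequence variant present on a subset of copies appears in short-read data as
an intermediate allele frequency at one reference position; that frequency
estimates the *copy fraction* — the fraction of the individual's rRNA gene
copies carrying the variant. Variants private to one cluster haplotype are
reporters: if the haplotype is transcribed, the variant appears in RNA-seq
reads in proportion to its DNA copy fraction; if the haplotype is silenced,
it disappears from RNA while remaining in DNA.

The package chains five stages — variant calling, cluster assignment,
RNA-based F2 genotyping, expression/dominance analysis, and QTL scans —
and ships a ground-truth simulator so each stage can be validated end to
end.

# Variant calling from strand-split counts

Input is a per-site table of forward/reverse read counts per allele,
assumed already base-quality filtered (alignment, duplicate marking and
recalibration are upstream of this package). For each non-reference allele:

* copy fraction = allele reads / total reads spanning the site;
* strand-bias score
  $SB = \left|\frac{b}{a+b}-\frac{d}{c+d}\right| \Big/ \frac{b+d}{a+b+c+d}$
  with $a,c$ the major allele's and $b,d$ the evaluated allele's
  forward/reverse counts.

A call passes when the position lies in the transcribed span
**300–8009** (minimal promoter to the end of the 25S), site depth reaches
the DNA floor (25 reads), the copy fraction reaches **5%**, and
$SB \le 0.8$. Failing calls are kept with a status so downstream absence
checks can distinguish "not seen" from "seen but filtered".

Numerical conventions the source formula does not define:

* $b+d=0$ (no minor reads): SB is 0 — no evidence of bias.
* one strand entirely uncovered: that strand's minor-fraction term is 0,
  with a warning.
* all-zero counts: an error.
* The frequency boundary is inclusive (fraction ≥ 0.05 passes); the
  comparator is exposed (`filter_config(frac_strict = TRUE)`) because the
  source material states the rule both as "less than 5% excluded" and as
  "present in > 5%".
* The DNA depth floor of 25 reads mirrors the RNA-level cutoff; the source
  states no DNA floor, so it is configurable (`min_dna_depth`).
* Multi-allelic sites: each alternative allele is evaluated independently
  against the same site depth; the SB contrast is always against the site's
  most frequent other allele, ordered so the major/minor convention holds.
* Where an alternative allele is more frequent than the reference
  (strictly), the reference allele is additionally emitted as a call named
  `X<pos>.<alt>.<ref>` and passed through the same filters; an exact tie
  emits nothing.
* Deletions are encoded as allele `-`; insertions as left-anchored
  `ins:<seq>` at the anchor position. The latter is a package convention —
  the source nomenclature does not cover insertions.

At the RNA level no strand-bias filter is applied (library protocols differ
in strandedness); only DNA-validated variants are reported, and sites with
fewer than **25** spanning RNA reads are flagged not-quantifiable rather
than zero-filled, because a zero there is indistinguishable from lack of
coverage.

# Cluster assignment by linkage

In a multiparent mosaic population the two rDNA loci are randomized against
each other, so a variant's copy fraction across lines associates with the
founder labels at the locus that carries it. Per marker, a one-way ANOVA of
abundance on founder label gives $-\log_{10} p$; genome-wide significance
uses a permutation null (default 200 permutations at desk scale; the
conventional 1000 is a parameter). Only variants shared by **≤ 7 of 19**
founders enter assignment — more widely shared variants cannot be mapped
unambiguously.

Assignment requires four conditions: the scan maximum lies in the distal
"top" region (first 5% of markers) of exactly one of chromosomes 2/4; it is
genome-wide significant; the other top region is not; and the
founder-of-origin consistency (fraction of lines whose observed carrier
status matches the prediction from the candidate locus's founder) is
≥ 0.95. Anything else falls to *ambiguous* — by design, errors must never
cross to the wrong cluster.

**Peak plateaus.** With sparse abundance (non-carriers exactly 0), the
ANOVA statistic is bit-identical across all markers whose founder-label
column differs only in zero-abundance lines. The scan maximum is therefore
routinely a plateau spanning the non-recombined block around the causal
locus, extending past the top-region boundary. Declaring any tied maximum
ambiguous (the literal reading of the tie-break rule) would discard most
true assignments, so the implemented rule treats the *set of regions
attaining the maximum* as the peak location: ambiguous only if that set
contains both rDNA tops, or neither. Founders or lines with recurrent
discordances in the consistency check are flagged (`flag_discordant()`),
generalizing the exclusion of one irreconcilable founder in the original
analysis.

For biparental crosses, parental-specific markers need ≥ **10%** supporting
reads in one parent and *absence* in the other, where absence means below
the 5% calling floor (sequencing error makes literal zero unattainable).
Markers are then assigned by perfect co-segregation with the rDNA-flanking
genotypes across ≥ 8 informative lines; 15/16 co-segregation is ambiguous —
strictness is deliberate for the same no-wrong-cluster reason.

# Genotyping F2s from RNA-seq

Per SNP, reads are attributed to parent A or B; a position is homozygous
when **> 90%** (strict) of its reads come from one parent, else
heterozygous; zero depth is no-call. SNPs whose homozygous-call rates
across the population are skewed **> 10-fold** toward one parent are
removed (alignment artifacts or allele-specific expression; a zero
denominator counts as exceeding any fold). Non-overlapping windows of
**50** called SNPs are homozygous when **> 85%** (strict) of their SNPs
agree on a parent, else heterozygous. A terminal partial window of ≥ 25
SNPs is classified on its own; a smaller remainder merges into the previous
window.

Adjacent same-state windows merge into segments. The original analysis
refined breakpoints manually; here refinement is deterministic: within the
two windows flanking a transition, the cut maximizing (SNP calls left of
the cut matching the left state) + (calls right matching the right state)
is chosen, first maximum winning ties. Genotypes are then imputed to every
position from its containing segment (nearest segment beyond the ends).

**Resolution limit.** The windowed classifier defines genotype at window
resolution: a true segment that does not contain at least one complete
window cannot produce a window of its own state and is absorbed by its
neighbours. With realistic F2 recombination (Poisson, 1.5
crossovers/chromosome/meiosis, two meioses) a few percent of the genome
lies in such sub-window segments; breakpoint refinement recovers segments
down to roughly one window but not below. Accuracy claims in the acceptance
suite are therefore stated at segment (window) resolution, with the
unrestricted per-SNP number reported alongside. An HMM would remove this
limit but is out of scope (and out of contract) here.

# Expression, dominance, epistasis

For each reporter variant, replicate DNA and RNA proportions are averaged
(unweighted; replicate counts are small and equal-status) and summarized by
the activity ratio $\rho = \bar{RNA}/\bar{DNA}$. The source classifies
expression visually against the one-to-one DNA:RNA line; the package
operationalizes this with exposed thresholds: **silenced** for
$\rho < 0.1$, **expressed** for $\rho \ge 0.5$, else **partial**. The upper
band is anchored at 1 (co-dominant genotypes put reporters on the
one-to-one line) and extends to ~2 because a variant on the only active
cluster doubles its RNA share when half the copies are silent. The
classification is monotone in $\rho$ by construction.

Dominance is read from genotype panels: haplotype H1 dominates H2 when a
genotype containing both shows H1's reporters expressed and H2's silenced;
both expressed records co-dominance. Contradictory evidence is reported as
a cycle, never resolved silently. The two-locus epistasis read-out is a
3×3 class matrix (rDNA-2 genotype × rDNA-4 genotype) of per-cell mean ± SD
DNA and RNA proportions; empty cells report n = 0 with NA summaries.

# QTL scans

Marker regression (no interval pseudo-markers — simulated maps are dense):
at each marker the 2-df model with additive $\{-1,0,1\}$ and dominance
$\{0,1,0\}$ codes is compared with the null by
$LOD = (n/2)\log_{10}(RSS_0/RSS_1)$. The map is first reduced by dropping
duplicate genotype columns (keep leftmost) and optionally by a greedy
minimum-index-distance pass (the source's map unit for subsetting is not
stated, so the index is used). Covariate scans absorb a known QTL —
additive code only, or additive + dominance — before testing each marker;
markers collinear with the covariate (including the covariate itself) get
LOD 0 via an absolute-scale rank check on the residualized design.
Genome-wide thresholds are empirical quantiles of the max-LOD distribution
over phenotype permutations (default 1000, seeded, recorded in the
result). Individuals missing the phenotype (e.g. RNA depth < 25) are
dropped.

# What the simulator does and does not emulate

The generator states the world the tests run in:

* **Cluster haplotypes**: private variants at uniform positions in the
  span, composition fractions uniform on [0.2, 1] (variants are rarely
  homogenized through a whole cluster; the lower bound keeps reporters
  above the calling floor at typical copy-number shares — the source does
  not quantify homogenization, so this is a modelling choice made once).
  Copy numbers uniform on [50, 200] per haplotype (cluster sizes vary
  greatly among accessions).
* **Expected fractions**: DNA fraction of variant v =
  $\sum_i c_i \kappa_i(v) / \sum_i c_i$ over the four haplotype copies
  ($c$ copy number, $\kappa$ composition). RNA fraction weights copies by
  activity *in both numerator and denominator*: reads come only from
  active copies, so fully co-dominant genotypes sit on the one-to-one line
  and a reporter on the only active cluster rises above it. (A total-copy
  denominator would cap RNA at DNA and contradict the observed pattern.)
* **Counts**: site depth Poisson around the configured coverage (DNA 100,
  RNA 500 by default); allele counts beta-binomial with overdispersion
  $\rho_{bb}$ (0 = binomial; the noise model is a package choice, made to
  stress estimators); strands split 50:50; an optional strand artifact
  collapses a variant's minor reads onto one strand to create decoys the
  SB filter must reject.
* **Crosses**: crossovers Poisson (1.5/chromosome/meiosis), uniform
  placement, no interference; F2s combine two F1 gametes; mosaics switch
  to a uniformly drawn founder at each crossover, with the rDNA locus and
  its flanking block forced co-inherited. rDNA loci sit in the first 1% of
  markers of chromosomes 2 and 4.
* **SNP counts for genotyping**: depth truncated-Poisson (mean 6, ≥ 1),
  per-read parent misattribution 1%, heterozygous positions Bernoulli(0.5)
  per read.

Not emulated: sequence-level reads and alignment error structure,
concerted-evolution dynamics, copy-number mutation, crossover
interference, maternal effects, and library-type coverage profiles beyond
an optional per-region RNA depth multiplier. A green test therefore
establishes correctness of the count-level inference chain under this
stated world, not robustness to alignment pathologies upstream of it.

# Known limitations

* Sub-window genotype segments are invisible to the window classifier (see
  above); per-SNP imputed accuracy is correspondingly a few percent below
  the segment-resolution accuracy.
* Cluster assignment localizes to a top *region*; within a haplotype block
  the causal position is unidentifiable in principle.
* Two founders can draw "the same" variant (same position and alleles) on
  different clusters; such cross-cluster shared variants have no single
  true cluster and correctly fall to ambiguous.
* The dominance partial order is only as complete as the genotype panel;
  haplotype pairs never co-present in a genotype yield no relation.
* Marker regression without pseudo-markers slightly underestimates QTL
  positions between sparse markers; with the simulated map densities this
  is immaterial.
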