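# rdnadom

Cluster-specific expression analysis of the 45S ribosomal RNA gene arrays of
*Arabidopsis thaliana*.

## The problem

45S rRNA genes occur in hundreds of nearly identical tandem copies in two
chromosomal clusters — rDNA-2 at the distal end of chromosome 2 and rDNA-4 at
the distal end of chromosome 4. Only a subset of copies is transcribed at any
time: whole clusters can be epigenetically silenced (nucleolar dominance),
and which cluster is silenced varies between natural accessions. Because the
copies are homogenized by concerted evolution, cluster-specific expression
cannot be read from ordinary alignments; it has to be inferred from rare
sequence variants that are private to one cluster haplotype and used as
expression reporters.

`rdnadom` implements that inference chain as a reusable, tested pipeline for
anyone working with multicopy gene families and allele-specific expression:

1. **Within-individual variant calling** (`call_variants()`): from
   strand-split per-site allele counts, the *copy fraction* of a variant at
   position *p* is the alternative-read fraction `alt/(depth)`. Calls require
   a copy fraction ≥ 5%, a position inside the transcribed span 300–8009, and
   a strand-bias score

   `SB = |b/(a+b) − d/(c+d)| / ((b+d)/(a+b+c+d)) ≤ 0.8`

   where `a,c` (`b,d`) are forward/reverse counts of the major (minor)
   allele. Variants are named `X<pos>.<ref>.<alt>`, e.g. `X2882.T.C`.
   Where an alternative allele outnumbers the reference, the reference
   allele itself is tracked as a call (`flip_reference_minority()`).
2. **Cluster assignment** (`linkage_scan()`, `assign_cluster()`,
   `assign_biparental()`): variant abundance is mapped by one-way ANOVA on
   founder labels across a multiparent (MAGIC-like) mosaic population, with
   permutation-based genome-wide thresholds and a founder-of-origin
   consistency check; in biparental crosses, parental-specific markers
   (≥ 10% support in one parent, absent in the other) are assigned by
   perfect co-segregation with the rDNA-flanking genotypes.
3. **RNA-seq F2 genotyping** (`genotype_population()`): per-SNP parental
   allele counts are called homozygous when > 90% of reads come from one
   parent, screened for > 10-fold cross-sample call bias, classified in
   non-overlapping 50-SNP windows (> 85% agreement), segmented with
   deterministic SNP-level breakpoint refinement, and imputed genome-wide.
4. **Expression and dominance** (`quantify_rna()`,
   `build_expression_records()`, `dominance_relations()`,
   `genotype_class_matrix()`): RNA proportions (reported only for
   DNA-validated variants with ≥ 25 spanning RNA reads) are compared with
   DNA proportions; the activity ratio ρ = RNA/DNA classifies a reporter's
   haplotype as silenced (ρ < 0.1), partial, or expressed (ρ ≥ 0.5), feeding
   a dominance partial order over haplotypes and a 3×3 two-locus genotype
   class matrix for epistasis read-out in F2s.
5. **QTL mapping** (`reduce_map()`, `single_scan()`, `covariate_scan()`,
   `permutation_threshold()`): marker regression with additive `{−1,0,1}` +
   dominance `{0,1,0}` encodings, `LOD = (n/2)·log10(RSS0/RSS1)`, second-QTL
   covariate scans, and 1000-permutation genome-wide thresholds.
6. **Synthetic data with ground truth** (`make_founders()`,
   `simulate_cross()`, `apply_dominance()`, `simulate_counts()`,
   `simulate_rnaseq_snp_counts()`): cluster haplotypes with private variant
   compositions, dominance rule tables (hierarchies, two-locus epistasis),
   inbred/F1/F2/19-founder-mosaic designs, and beta-binomial strand-split
   count noise with optional strand-collapse artifacts.

## Worked example

Simulate an F2 between two accessions whose dominant clusters oppose each
other (parent A: rDNA-4 dominant; parent B: rDNA-2 dominant), then call and
quantify one individual:

```r
library(rdnadom)
founders <- make_founders(2, ids = c("Alg", "TDr"), seed = 11)
haps     <- founder_haplotypes(founders)
rules    <- f2_epistasis_rules(founders$Alg, founders$TDr)
pop      <- simulate_cross("f2", founders, 180, n_markers = 40, seed = 12)

g   <- pop[[1]]
act <- apply_dominance(g, rules)
act
#> Alg.rDNA2 TDr.rDNA2 Alg.rDNA4
#>         0         1         1

cts   <- simulate_counts(g, act, haps,
                         sim_config(coverage_dna = 100, coverage_rna = 500),
                         seed = 13)
calls <- call_variants(cts$dna)
calls[, c("name", "copy_fraction", "sb_score", "depth", "status")]
#>        name copy_fraction sb_score depth          status
#> 1 X5532.A.G       0.07619    1.208   105   strand_biased
#> 2 X5968.A.C       0.17822    0.504   101            pass
#> 3 X6876.A.T       0.05357    0.144   112            pass
#> 4 X6921.C.G       0.31532    0.330   111            pass
#> 5 X7442.G.A       0.24242    0.645    99            pass
#> 6 X7757.C.T       0.00926    1.688   108 below_frequency

rq <- quantify_rna(cts$rna, calls)
rq[, c("name", "rna_depth", "proportion", "quantifiable")]
#>        name rna_depth proportion quantifiable
#> 2 X5968.A.C       507     0.0000         TRUE
#> 3 X6876.A.T       513     0.0565         TRUE
#> 4 X6921.C.G       454     0.3921         TRUE
#> 5 X7442.G.A       497     0.2736         TRUE
```

Reading the output: this individual is heterozygous Alg/TDr at rDNA-2 and
homozygous Alg at rDNA-4. `X5968.A.C` sits on the silenced Alg rDNA-2
haplotype — present in ~18% of copies at the DNA level but absent from RNA
(proportion 0.0000, ρ ≈ 0 → "silenced"). The other passing variants sit on
active haplotypes: their RNA proportions track (or exceed) their DNA
proportions, i.e. they lie near or above the one-to-one DNA:RNA line. One
site (`X5532.A.G`) is rejected by the strand-bias filter and one falls below
the 5% copy-fraction floor.

A command-line shell wraps the main stages:

```sh
Rscript -e 'quit(status = rdnadom::run_cli())' simulate --seed 1 --out sim/
Rscript -e 'quit(status = rdnadom::run_cli())' call-variants --counts sim/dna_counts.tsv --out variants.csv
```

## Documentation

See `vignettes/rdnadom-methods.Rmd` for the statistical model, threshold
semantics, simulator assumptions, and known limitations.
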