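Package: rdnadom
Title: rDNA Cluster-Specific Variant Calling, Genotyping and Dominance Analysis
Version: 0.1.0
Authors@R: person("rdnadom", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study expression of the two 45S ribosomal DNA clusters
    (rDNA-2 and rDNA-4) of Arabidopsis thaliana from short-read count data.
    Calls within-individual 45S rRNA gene variants from strand-split pileup
    counts with a strand-bias filter, assigns variants to a particular rDNA
    cluster by linkage in multiparent (MAGIC) or biparental populations,
    genotypes F2 individuals from RNA-seq allele counts with a sliding-window
    homozygosity classifier, contrasts DNA and RNA variant proportions to
    score cluster silencing, characterizes dominance and two-locus epistasis
    between rDNA haplotypes, and maps expression phenotypes by marker
    regression with permutation thresholds. A synthetic-data generator
    provides ground-truth populations (inbred panels, F1, F2 and founder
    mosaics) with beta-binomial count noise for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
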