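Package: invkaryo
Title: Chromosomal Inversion Karyotyping, Diversity Contrasts, Dating and
    Enrichment from Genotype Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize a polymorphic chromosomal inversion from
    population genotype data: localization of the inversion from long-range
    linkage disequilibrium, selection of karyotype-diagnostic loci, per-sample
    karyotype calling and latitudinal frequency summaries, homokaryotype
    diversity contrasts (site frequency spectra, Watterson's theta, nucleotide
    diversity, Tajima's D in sliding windows, per-SNP Weir-Cockerham FST,
    per-sample heterozygosity, Welch t and one-way ANOVA tests), calibrated
    strict-clock dating of the inversion from duplicated ortholog families
    (neighbor-joining topology validation plus Jukes-Cantor TMRCA), and
    Fisher-exact gene-set enrichment with Benjamini-Hochberg FDR control.
    Includes coalescent-based simulators for diploid inversion cohorts,
    ortholog sequence families, and gene-annotation tables with planted
    enrichment, providing truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    phangorn,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
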