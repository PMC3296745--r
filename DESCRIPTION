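Package: cndosage
Title: Integration of SNP-Array Copy Number Alterations with Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to integrate discrete SNP-array copy-number states with
    gene-expression deregulation in small tumour cell-line panels.  Builds
    per-sample copy-number-altered regions (CNAs) from 5-state SNP tracks,
    intersects them into minimal recurrent regions (MRRs) shared by all
    samples, maps genes to dosage, calls deregulated genes with a SAM-style
    moderated statistic and permutation FDR, and provides the regional
    enrichment (chi-square/Fisher and parametric gene-set Z), dosage-
    expression trend (linear-by-linear association, Spearman) and contiguous
    deregulated-gene cluster statistics used to assess gene-dosage effects.
    Includes a coupled synthetic-data generator with planted truth, and
    calculators for qPCR copy number, qRT-PCR normalization and FISH signal
    ratios used for orthogonal validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
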