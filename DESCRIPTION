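Package: tmbcount
Title: Reproducible Tumor Mutation Burden Estimation from Multi-Caller Somatic VCFs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic estimation of tumor mutation burden (TMB) from
    somatic variant calls produced by multiple callers (Strelka2-style,
    Mutect2-style, optional Manta). Variant records are normalized to a
    canonical left-aligned, trimmed, biallelic representation, intersected
    across callers under a configurable membership policy, and counted per
    megabase over four genomic subsets: whole genome (non-N alignable space),
    coding sequence, protein-modifying (SnpEff HIGH/MODERATE impact), and a
    pseudo-panel restricted to cancer-gene CDS with COSMIC and
    tumor-suppressor exclusions. Samples are classified against the clinical
    10 mutations per megabase immunotherapy-eligibility threshold and
    cohort-level threshold concordance is summarized. Includes a fully
    synthetic, seeded fixture generator (toy reference, annotation, caller
    VCFs, gene lists, known-somatic sites) with independently enumerated
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
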