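---
title: "Estimating tumor mutation burden from multi-caller somatic calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumor mutation burden from multi-caller somatic calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbcount)
```

## The estimation problem

Tumor mutation burden is a ratio: somatic mutations counted in some genomic
subset, divided by the megabases of that subset a whole-genome analysis can
interrogate. Both numerator and denominator hide decisions that move the
estimate — which caller's word is trusted, whether `10:100 AAC>AC` and
`10:99 TA>T` are one variant or two, whether a "coding" mutation means any
CDS overlap or a protein-altering consequence, and what exactly the
denominator measures. Because a fixed clinical threshold (10 mutations/Mb,
the immunotherapy-eligibility convention; the boundary value itself counts
as high) is applied to the result, small methodological drift can flip a
patient's eligibility. `tmbcount` fixes one fully specified, deterministic
procedure for the step from caller VCFs to classified estimates.

The pipeline assumes: somatic VCFs from at least two independent callers on
the same reference; site-level allele identity is what matters (genotype
columns are ignored); caller-attached FILTER tiers are respected, so only
`PASS`/`.` records are counted; and functional annotation, when present,
arrives as SnpEff-style `ANN` INFO fields whose first entry is the most
deleterious consequence.

## Canonical alleles and consensus

Callers emit the same allele in different representations. Every record is
therefore reduced to a canonical form before any comparison: the shared
suffix of REF and ALT is trimmed, with the alleles re-anchored one reference
base to the left whenever either would become empty (this is what walks an
indel leftward through homopolymers and other repeats), and finally the
shared prefix is trimmed down to the mandatory anchor base. The output is a
fixed point of the procedure and unique per equivalence class — the test
suite enumerates, for fixture indels, *every* VCF representation in a
window that reproduces the same haplotype, and checks they collapse to one
key. One consequence worth spelling out: a deletion inside a repeat such as
`...TAAC...` written as `pos 12 AAC>AC` normalizes to `pos 11 TA>T`, anchored
on the base before the repeat, matching the behaviour of the standard
normalization tools. Records whose REF disagrees with the reference are
errors, as are REF = ALT records; symbolic alleles (`<DEL>`, breakends, `*`)
are tallied but excluded from small-variant counting.

Multi-nucleotide substitutions are decomposed into their constituent SNVs by
default (`decompose_mnvs = TRUE`), because callers differ in whether they
merge adjacent SNVs, and decomposition maximizes cross-caller matchability.
With decomposition off, MNVs keep their own class and enter neither the SNV
nor the indel tally.

Consensus membership is exact-key intersection of the normalized sets. The
default policy requires Strelka2 ∩ Mutect2 and records Manta membership
without requiring it: Manta's contribution to small-variant calling is indel
candidates and structural variants, so requiring it would empty the SNV set.
`all` and `k-of-n:K` policies are available for callers of equal standing.
Exact-key matching is a deliberate simplification relative to
haplotype-aware comparison (vcfeval-style playout of allele combinations):
after left-alignment and trimming the two agree except for rare complex
multi-variant representations, and exact matching keeps the procedure
deterministic and auditable. When callers disagree on annotation, fields are
taken from the first caller in the fixed order strelka2, mutect2, manta that
carries an impact — determinism requires a total order, and the order is
stated rather than incidental.

## The four subsets and their denominators

* **genome** — all consensus variants on the counting scope (autosomes plus
  X and Y; mitochondrial, unplaced and alt contigs are excluded everywhere),
  over the alignable space: the count of non-N reference bases on those
  contigs. Soft-masked lowercase bases are alignable; only N is not. For
  hg19 this denominator is 2,667,837,836 bases and the Ensembl-75 merged CDS
  total below is 31,990,128 bases; `hg19_denominators()` returns these
  published constants, and both are recomputed from any local FASTA/GTF by
  `count_alignable_bases()` and `build_cds_intervals()`.
* **coding** — variants whose reference span (`pos … pos + |REF| − 1`;
  insertions reduce to their anchor base) overlaps at least one base of the
  merged CDS footprint, over the merged CDS total. "Merged" means the union
  over all transcripts: a per-Mb denominator must count each genomic base
  once, so overlapping CDS of alternative transcripts are collapsed.
  Book-ended intervals merge too; only feature rows of type `CDS` are used,
  and stop codons enter only where the annotation includes them as CDS.
  UCSC-style (`chr1`) and Ensembl-style (`1`) contig names are folded into
  one canonical space so a UCSC reference can meet an Ensembl annotation.
* **protein** — variants annotated HIGH or MODERATE impact, over the same
  CDS denominator. Unannotated variants are never counted here.
* **panel** — an emulation of targeted-panel TMB from whole-genome calls:
  variants overlapping the CDS of a cancer-gene panel, minus (a) variants
  matching a known-somatic (COSMIC-like) site list and (b) nonsense SNVs
  (`stop_gained`) anywhere in the panel together with HIGH/MODERATE/LOW
  variants in tumor suppressor genes — the driver-discounting step panel
  assays apply before reporting TMB. A variant hit by several rules is
  removed once.

Two genuinely open choices here were decided as follows. The panel
denominator is the merged CDS of the panel genes, mirroring the
genome/coding pattern (count and denominator describe the same footprint);
this matters when comparing panel estimates against the 10/Mb threshold and
is reported in every output row. Known-site exclusion defaults to exact
normalized-allele matching (`match_mode = "allele"`), the conservative
reading of "intersecting" a site list; position-only matching is available.
The nonsense-SNV exclusion is applied panel-wide, with the impact-tier
exclusion restricted to tumor suppressor genes.

## Numerical and serialization choices

TMB values are computed and classified unrounded; rounding to 4 decimal
places (round half to even) happens only at serialization. A value of
9.99996/Mb therefore prints as `10.0000` yet classifies low — the reports
carry the classification, so the printed value never has to be re-thresholded.
Zero or negative denominators are errors, not NaNs. All report formats fix
column order, key order and float formatting, and the consensus VCF header
contains no timestamps, so identical inputs yield byte-identical outputs;
ties in output ordering cannot occur because variants are totally ordered by
(contig rank, position, REF, ALT) with contigs ranked 1–22, X, Y, then
others alphabetically. Normalization at position 1 of a contig, where no
left anchor exists, re-anchors on the following reference base instead of
failing.

## What the synthetic fixtures emulate — and what they do not

`fixture_spec()` / `make_fixture()` generate the complete input set with
known ground truth: a toy genome (default two contigs of 20 kb, 5% N in
contiguous runs, implanted homopolymer runs, a soft-masked segment), an
annotation whose transcripts overlap so CDS merging is exercised, three
caller VCFs, gene lists and a known-somatic site file. Truth variants
(default 60 SNVs, 20 indels, about half in CDS) are constructed directly in
canonical form; callers re-emit them with per-caller sensitivity (defaults
0.90 / 0.85 / 0.40 for strelka2 / mutect2 / manta — plausible relative
orderings for WGS somatic calling, with manta restricted to indels), a 10%
non-PASS rate, and a 30% chance of a non-canonical equivalent representation
(padded, anchor-extended, or right-shifted through a homopolymer). Impacts
are drawn HIGH/MODERATE/LOW/MODIFIER at 0.15/0.35/0.30/0.20, with 15% of
coding SNVs forced to `stop_gained`; 20% of truth variants are copied into
the known-site file plus five novel sites. These values were chosen once to
make every counting rule and exclusion path exercised at toy scale with
non-trivial frequency; they are the conditions under which the test suite's
exact-equivalence claims hold. Ground truth — expected consensus under each
policy, per-subset counts, exclusion tallies, denominators, TMB values — is
enumerated from per-base boolean masks and the membership bookkeeping at
generation time, never by running the pipeline, which is what makes a
fixture an end-to-end oracle. Each component draws from its own derived
random stream, so changing one spec field perturbs only that component, and
the same spec yields byte-identical files.

What passing these tests shows is that the implementation agrees exactly
with an independent enumeration of its own rules under realistic input
noise. What it does not show: performance on real tumors. The fixtures
contain no sequencing-error-driven false positives shared across callers, no
germline leakage, no multi-allelic somatic sites beyond simple cases, no
clustered complex events, and toy-scale denominators (kilobases, not
gigabases) that make per-Mb values enormous and every toy sample classify
high at 10/Mb. The test suite and the acceptance script run at these sizes —
100 seeded fixtures for the oracle sweep, 20-sample cohorts — which keeps a
full validation under a few minutes on one CPU while covering every rule.

## Known limitations

* Exact-key intersection can split a complex event that two callers
  represent with different variant decompositions; haplotype-aware
  comparison is out of scope.
* Germline filtering, allele-frequency modelling and tumor-only calling are
  upstream concerns; the package consumes caller-accepted somatic calls.
* Annotation is consumed, not computed: protein and panel subsets are only
  as good as the `ANN` fields supplied.
* Microsatellite instability, mutational signatures and survival modelling
  are outside the package; its output (per-sample reports, cohort
  concordance tables) is designed to feed such analyses.
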