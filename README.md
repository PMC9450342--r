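# tmbcount

Reproducible tumor mutation burden (TMB) estimation from multi-caller
somatic VCFs.

TMB — somatic mutations per megabase of interrogated genome — is a clinical
biomarker: patients whose tumors carry ≥ 10 mutations/Mb are more likely to
respond to immune checkpoint inhibitors, and 10/Mb is the FDA-recognized
eligibility threshold. The estimate, however, depends heavily on *how* it is
measured: which variant callers are trusted, how their differing VCF
representations are reconciled, which genomic subset is counted, and what
the per-Mb denominator is. Two centres analysing the same tumor can disagree
on eligibility purely through pipeline drift. `tmbcount` addresses this for
groups running whole-genome somatic analyses: it takes the caller outputs
(Strelka2-style, Mutect2-style, optionally Manta), reduces every record to a
canonical allele, intersects callers, and produces deterministic,
byte-reproducible TMB reports.

## Method

For a sample with per-caller somatic VCFs the pipeline computes:

1. **Normalization.** Each PASS record is split per ALT allele and reduced
   to its canonical form: shared suffix trimmed with left extension through
   repeat context, then shared prefix trimmed retaining the indel anchor
   base — the standard left-align-and-trim procedure, so every equivalent
   VCF representation maps to one `(contig, pos, ref, alt)` key.
   Multi-nucleotide substitutions are decomposed into SNVs; symbolic SV
   alleles are tallied but never counted.
2. **Consensus.** A variant is kept iff it is reported by both Strelka2 and
   Mutect2 (Manta membership is recorded; policies `all` and `k-of-n:K` are
   available).
3. **Subset counting.** With `n` the consensus count in a subset and `D` the
   subset's denominator in bases, `TMB = n / (D / 10^6)`:

   | subset  | variants counted                          | denominator D |
   |---------|-------------------------------------------|---------------|
   | genome  | all, on chromosomes 1–22, X, Y            | alignable (non-N) bases |
   | coding  | reference span overlaps merged CDS        | merged CDS bases |
   | protein | SnpEff impact HIGH or MODERATE            | merged CDS bases |
   | panel   | in cancer-gene CDS, minus known-somatic (COSMIC) matches, minus nonsense SNVs and HIGH/MODERATE/LOW variants in tumor suppressor genes | panel CDS bases |

   For hg19 with Ensembl 75 annotation the whole-genome denominator is
   2,667,837,836 alignable bases and the CDS denominator 31,990,128 bases
   (`hg19_denominators()`); both are recomputed from local FASTA/GTF by
   `count_alignable_bases()` and `build_cds_intervals()`.
4. **Classification.** Each estimate (SNV-only and SNV+indel, per subset) is
   called `high` iff TMB ≥ 10/Mb, on the unrounded value;
   `summarize_cohort()` tallies cross-subset threshold concordance over many
   samples.

All outputs (consensus VCF with a `CALLERS` tag, TSV and JSON reports) are
byte-identical across reruns on the same inputs.

## Worked example

The package ships a seeded fixture generator that emulates the full input
set — toy reference, CDS annotation, three caller VCFs with representation
and filter noise, gene lists, known-somatic sites — with independently
enumerated ground truth:

```r
library(tmbcount)
fx <- make_fixture(fixture_spec(seed = 7), "fixture7")
report <- run_tmb(
  strelka2 = fx$paths$strelka2, mutect2 = fx$paths$mutect2,
  manta = fx$paths$manta, reference = fx$paths$reference,
  gtf = fx$paths$gtf, panel_genes = fx$paths$panel,
  tsg_genes = fx$paths$tsg, cosmic = fx$paths$cosmic,
  sample_id = "COLO_TOY", out_dir = "out7")
```

`out7/tmb_report.tsv` then contains:

```
sample_id  subset   class  count  denominator_bases  tmb_per_mb  classification  threshold
COLO_TOY   genome   snv       35              38000    921.0526  high            10
COLO_TOY   genome   total     48              38000   1263.1579  high            10
COLO_TOY   coding   snv       15               1557   9633.9114  high            10
COLO_TOY   coding   total     18               1557  11560.6936  high            10
COLO_TOY   protein  snv       10               1557   6422.6076  high            10
COLO_TOY   protein  total     12               1557   7707.1291  high            10
COLO_TOY   panel    snv        4                780   5128.2051  high            10
COLO_TOY   panel    total      5                780   6410.2564  high            10
```

Reading the `genome` rows: 35 consensus SNVs (48 variants including indels)
fell on the in-scope contigs, divided by 38,000 alignable bases → 921.05
SNVs/Mb. Per-Mb values are enormous at toy scale because the denominators
are a few kilobases; on a real genome the same 48 variants would be ≈ 0.02/Mb.
Every count above equals the fixture's enumerated ground truth
(`fixture7/ground_truth.json`) exactly. The same run is available from a
shell:

```sh
tmbcount run --strelka2 strelka2.vcf --mutect2 mutect2.vcf --manta manta.vcf \
  --reference ref.fa --gtf ann.gtf --panel-genes panel.txt --tsg-genes tsg.txt \
  --cosmic cosmic.vcf --out-dir OUT
tmbcount refspace --reference ref.fa --gtf ann.gtf --contigs 1-22,X,Y
tmbcount cohort --reports OUT1/tmb_report.tsv,OUT2/tmb_report.tsv --out cohort.tsv
```

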