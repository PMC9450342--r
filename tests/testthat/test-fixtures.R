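test_that("fixture specs validate their probabilities and capacity", {
  expect_error(fixture_spec(caller_sensitivity = c(strelka2 = 1.2,
                                                   mutect2 = 0.5,
                                                   manta = 0.5)),
               "\\[0, 1\\]")
  expect_error(fixture_spec(fraction_cosmic = -0.1), "\\[0, 1\\]")
  expect_error(fixture_spec(contig_length = 500), "too small")
})

test_that("the toy reference has an exact construction-known N budget", {
  spec <- fixture_spec(seed = 11, contig_length = 8000,
                       n_run_fraction = 0.1, n_genes = 4,
                       n_truth_snvs = 24, n_truth_indels = 10)
  ref <- make_reference(spec)
  for (cn in ref$contig_names) {
    expect_equal(sum(ref$seqs[[cn]] == "N"), 800)
    expect_equal(ref$alignable_by_contig[[cn]], 7200)
  }
  # zero N fraction -> fully alignable
  spec0 <- fixture_spec(seed = 11, contig_length = 8000,
                        n_run_fraction = 0, n_genes = 4,
                        n_truth_snvs = 24, n_truth_indels = 10)
  ref0 <- make_reference(spec0)
  expect_equal(unname(ref0$alignable_by_contig), rep(8000, 2))
  # the written FASTA agrees with the in-memory truth
  fa <- tempfile(fileext = ".fa")
  write_reference_fasta(ref, fa)
  loaded <- read_genome_reference(fa)
  expect_equal(count_alignable_bases(loaded, loaded$contig_names),
               sum(ref$alignable_by_contig))
})

test_that("same seed reproduces byte-identical fixture files", {
  spec <- small_fixture_spec(13)
  d1 <- file.path(tempdir(), "fxa")
  d2 <- file.path(tempdir(), "fxb")
  fx1 <- make_fixture(spec, d1)
  fx2 <- make_fixture(spec, d2)
  for (f in c("ref.fa", "ann.gtf", "strelka2.vcf", "mutect2.vcf",
              "manta.vcf", "panel.txt", "tsg.txt", "cosmic.vcf",
              "ground_truth.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6),
                     label = paste("bytes of", f))
  }
  expect_identical(fx1$ground_truth, fx2$ground_truth)
})

test_that("overlapping transcripts make the merged CDS union strictly smaller", {
  fx <- get_fixture(5, small = TRUE)
  spec <- fx$spec
  ref <- make_reference(spec)
  ann <- make_annotation(spec, ref)
  expect_lt(ann$merged_total, ann$transcript_summed_total)
  # dual route: GTF -> interval machinery equals the construction mask
  expect_equal(total_bases(build_cds_intervals(fx$paths$gtf,
                                               scope_contigs =
                                                 ref$contig_names)),
               ann$merged_total)
  for (g in ann$genes) {
    expect_equal(total_bases(build_cds_intervals(
      fx$paths$gtf, scope_contigs = ref$contig_names, gene_filter = g)),
      unname(ann$merged_by_gene[g]))
  }
})

test_that("perfect and zero caller sensitivity bound the consensus", {
  spec1 <- fixture_spec(seed = 3, contig_length = 8000, n_genes = 4,
                        n_truth_snvs = 12, n_truth_indels = 6,
                        caller_sensitivity = c(strelka2 = 1, mutect2 = 1,
                                               manta = 1),
                        fraction_nonpass = 0)
  fx1 <- make_fixture(spec1, file.path(tempdir(), "fx-perfect"))
  expect_setequal(fx1$ground_truth$consensus_keys$default, fx1$truth$key)
  expect_setequal(fx1$ground_truth$consensus_keys$k2_of_3, fx1$truth$key)
  rep1 <- run_fixture(fx1)
  expect_setequal(attr(rep1, "consensus")$variants$key, fx1$truth$key)

  spec0 <- fixture_spec(seed = 3, contig_length = 8000, n_genes = 4,
                        n_truth_snvs = 12, n_truth_indels = 6,
                        caller_sensitivity = c(strelka2 = 1, mutect2 = 0,
                                               manta = 0))
  fx0 <- make_fixture(spec0, file.path(tempdir(), "fx-zero"))
  expect_length(fx0$ground_truth$consensus_keys$default, 0)
  rep0 <- run_fixture(fx0)
  expect_equal(nrow(attr(rep0, "consensus")$variants), 0)
  expect_equal(as.data.frame(rep0)$count, rep(0L, 8))
})

test_that("known-site fraction zero removes nothing from the panel", {
  spec <- fixture_spec(seed = 9, contig_length = 8000, n_genes = 4,
                       n_truth_snvs = 24, n_truth_indels = 10,
                       fraction_cosmic = 0)
  fx <- make_fixture(spec, file.path(tempdir(), "fx-nocosmic"))
  expect_equal(fx$ground_truth$exclusions$cosmic, 0L)
  rep <- run_fixture(fx)
  expect_equal(unname(attr(rep, "exclusions")["cosmic"]), 0L)
})

test_that("caller VCFs respect PASS filtering and membership bookkeeping", {
  fx <- get_fixture(5, small = TRUE)
  ref <- read_genome_reference(fx$paths$reference)
  s <- read_caller_vcf(fx$paths$strelka2, "strelka2", ref)
  # normalized keys recovered from the VCF equal the membership draws
  expect_setequal(s$variants$key, fx$truth$key[fx$membership[, "strelka2"]])
  m <- read_caller_vcf(fx$paths$mutect2, "mutect2", ref)
  member_keys <- fx$truth$key[fx$membership[, "mutect2"]]
  expect_true(all(member_keys %in% m$variants$key))
  # mutect2 additionally carries at most two private multi-allelic alleles
  expect_lte(length(setdiff(m$variants$key, fx$truth$key)), 2)
  mn <- read_caller_vcf(fx$paths$manta, "manta", ref)
  expect_true(all(mn$variants$vclass %in% c("INS", "DEL")))
  expect_equal(mn$n_symbolic, 2L)
})
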