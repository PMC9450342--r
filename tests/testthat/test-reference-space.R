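test_that("alignable bases are the non-N positions, case-insensitively", {
  fa <- write_mini_fasta(list(`1` = "ACGTNNNA", `2` = "NNNN",
                              `3` = "acgtN"))
  ref <- read_genome_reference(fa)
  expect_equal(count_alignable_bases(ref, "1"), 5)
  expect_equal(count_alignable_bases(ref, "2"), 0)
  expect_equal(count_alignable_bases(ref, "3"), 4)  # soft-masked counts
  expect_equal(count_alignable_bases(ref, c("1", "2", "3")), 9)
  expect_error(count_alignable_bases(ref, "Z"), "not in reference")
  expect_error(count_alignable_bases(ref, character()), "empty")
})

test_that("UCSC and Ensembl contig names meet in one canonical space", {
  expect_equal(normalize_contig(c("chr1", "1", "chrX", "chrMT")),
               c("1", "1", "X", "MT"))
  expect_equal(normalize_contig("chrMT", aliases = c(MT = "M")), "M")
  fa <- write_mini_fasta(list(chr1 = "ACGTN"))
  ref <- read_genome_reference(fa)
  expect_equal(count_alignable_bases(ref, "1"), 4)
  expect_equal(count_alignable_bases(ref, "chr1"), 4)
  # duplicate names after normalization are rejected
  fa2 <- write_mini_fasta(list(chr1 = "ACGT", `1` = "ACGT"))
  expect_error(read_genome_reference(fa2), "duplicate contig")
})

test_that("alignable + N partitions the scoped genome", {
  fx <- get_fixture(2, small = TRUE)
  ref <- read_genome_reference(fx$paths$reference)
  scope <- intersect(default_scope_contigs(), ref$contig_names)
  n_total <- sum(ref$contig_lengths[scope])
  n_n <- sum(Biostrings::letterFrequency(ref$seq[scope], "N"))
  expect_equal(count_alignable_bases(ref, scope) + n_n, n_total)
})

test_that("interval sets merge overlapping and book-ended intervals", {
  iv <- interval_set(c("1", "1"), c(100, 150), c(200, 250))
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 100)
  expect_equal(iv$end, 250)
  expect_equal(total_bases(iv), 150)
  # book-ended halves fuse
  iv2 <- interval_set(c("1", "1"), c(0, 50), c(50, 80))
  expect_equal(nrow(iv2), 1)
  expect_equal(total_bases(iv2), 80)
  expect_equal(total_bases(interval_set()), 0)
  expect_error(interval_set("1", 10, 10), "exceed")
})

test_that("merging is idempotent and total_bases matches a coverage mask", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 50
    start <- sample.int(900, n)
    width <- sample.int(60, n)
    contig <- sample(c("1", "2"), n, replace = TRUE)
    iv <- interval_set(contig, start, start + width)
    expect_equal(total_bases(iv),
                 mask_covered_bases(contig, start, start + width, 1000))
    # merge of merge is the identity
    iv2 <- interval_set(iv$contig, iv$start, iv$end)
    expect_identical(as.data.frame(iv), as.data.frame(iv2))
    # invariants: sorted, strictly separated
    for (cn in unique(iv$contig)) {
      part <- iv[iv$contig == cn, ]
      expect_true(all(part$end > part$start))
      if (nrow(part) > 1) {
        expect_true(all(part$end[-nrow(part)] < part$start[-1]))
      }
    }
  }
})

test_that("CDS intervals are a merged union over transcripts", {
  gtf <- write_mini_gtf(data.frame(
    contig = "1", start = c(101, 151), end = c(200, 250),
    gene = "GENEA", transcript = c("tA.1", "tA.2")))
  iv <- build_cds_intervals(gtf, scope_contigs = "1")
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 100)  # 0-based half-open
  expect_equal(iv$end, 250)
  expect_equal(total_bases(iv), 150)
})

test_that("gene filtering restricts the footprint and warns on misses", {
  rows <- data.frame(contig = "1",
                     start = c(101, 151, 401, 521),
                     end = c(200, 250, 520, 580),
                     gene = c("GENEA", "GENEA", "GENEB", "GENEB"),
                     transcript = c("tA.1", "tA.2", "tB.1", "tB.1"))
  gtf <- write_mini_gtf(rows)
  all_iv <- build_cds_intervals(gtf, scope_contigs = "1")
  a_iv <- build_cds_intervals(gtf, scope_contigs = "1",
                              gene_filter = "GENEA")
  b_iv <- build_cds_intervals(gtf, scope_contigs = "1",
                              gene_filter = "GENEB")
  # per-gene totals from an independent coverage mask
  expect_equal(total_bases(a_iv),
               mask_covered_bases("1", c(100, 150), c(200, 250), 1000))
  expect_equal(total_bases(b_iv),
               mask_covered_bases("1", c(400, 520), c(520, 580), 1000))
  # restricting genes never increases the footprint
  expect_lte(total_bases(a_iv), total_bases(all_iv))
  expect_lte(total_bases(b_iv), total_bases(all_iv))
  expect_warning(build_cds_intervals(gtf, scope_contigs = "1",
                                     gene_filter = c("GENEA", "NOPE")),
                 "NOPE")
  # a GTF with no CDS rows is an error
  no_cds <- tempfile(fileext = ".gtf")
  writeLines(paste0("1\tsrc\texon\t1\t10\t.\t+\t.\tgene_id \"g\"; ",
                    "transcript_id \"t\"; gene_name \"g\";"), no_cds)
  expect_error(build_cds_intervals(no_cds, scope_contigs = "1"), "no CDS")
})

test_that("interval sets round-trip through BED", {
  iv <- interval_set(c("2", "1"), c(10, 5), c(20, 9))
  bed <- tempfile(fileext = ".bed")
  write_bed(iv, bed)
  got <- read.table(bed, sep = "\t", colClasses = c(V1 = "character"))
  expect_equal(got$V1, c("1", "2"))  # canonical contig order
  expect_equal(got$V2, c(5, 10))
  expect_equal(got$V3, c(9, 20))
})
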