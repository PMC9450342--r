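REFSEQ3 <- paste0(strrep("GATTACAGGG", 20), strrep("TAACCCAAAA", 20))

scoped_setup <- function() {
  # contigs "1" (in scope) and "MT" (excluded)
  ref <- read_genome_reference(write_mini_fasta(list(`1` = REFSEQ3,
                                                     MT = REFSEQ3)))
  list(ref = ref, scope = counting_scope(ref))
}

consensus_of <- function(rows, ref, ...) {
  intersect_callers(list(
    read_caller_vcf(write_mini_vcf(rows), "strelka2", ref, ...),
    read_caller_vcf(write_mini_vcf(rows), "mutect2", ref, ...)))
}

snv_at <- function(chrom, pos, seq = REFSEQ3) {
  data.frame(chrom = chrom, pos = pos,
             ref = vapply(pos, function(p) substr(seq, p, p), ""),
             alt = vapply(pos, function(p)
               setdiff(c("A", "C", "G", "T"), substr(seq, p, p))[1], ""))
}

test_that("whole-genome counting drops out-of-scope contigs", {
  su <- scoped_setup()
  rows <- rbind(snv_at("1", c(2, 12, 22, 32, 42)), snv_at("MT", 2))
  cons <- consensus_of(rows, su$ref)
  expect_equal(count_genome(cons, su$scope), c(snv = 5L, indel = 0L))
  empty <- consensus_of(NULL, su$ref)
  expect_equal(count_genome(empty, su$scope), c(snv = 0L, indel = 0L))
})

test_that("footprint counting uses reference-span overlap", {
  su <- scoped_setup()
  fp <- interval_set("1", 100, 200)  # 0-based half-open: bases 101..200
  # SNV inside; SNV on the last covered base (200); SNV one past (201);
  # deletion starting before the footprint end but reaching past it
  rows <- rbind(snv_at("1", c(150, 200, 201)),
                data.frame(chrom = "1", pos = 198,
                           ref = substr(REFSEQ3, 198, 205),
                           alt = substr(REFSEQ3, 198, 198)))
  cons <- consensus_of(rows, su$ref)
  got <- count_in_footprint(cons, fp)
  expect_equal(got, c(snv = 2L, indel = 1L))
  # insertions count via their anchor base only
  ins_in <- data.frame(chrom = "1", pos = 200,
                       ref = substr(REFSEQ3, 200, 200),
                       alt = paste0(substr(REFSEQ3, 200, 200), "T"))
  # the inserted base must differ from the anchor so the record cannot
  # left-align into the footprint
  ins_out <- data.frame(chrom = "1", pos = 201,
                        ref = substr(REFSEQ3, 201, 201),
                        alt = paste0(substr(REFSEQ3, 201, 201), "C"))
  expect_equal(count_in_footprint(consensus_of(ins_in, su$ref), fp),
               c(snv = 0L, indel = 1L))
  expect_equal(count_in_footprint(consensus_of(ins_out, su$ref), fp),
               c(snv = 0L, indel = 0L))
})

test_that("footprint counts match a per-base mask oracle on fixtures", {
  fx <- get_fixture(5, small = TRUE)
  ref <- read_genome_reference(fx$paths$reference)
  cds <- build_cds_intervals(fx$paths$gtf,
                             scope_contigs = ref$contig_names)
  cons <- intersect_callers(list(
    read_caller_vcf(fx$paths$strelka2, "strelka2", ref),
    read_caller_vcf(fx$paths$mutect2, "mutect2", ref)))
  # oracle: scan every variant span against a boolean mask
  masks <- lapply(ref$contig_names, function(cn) {
    m <- rep(FALSE, ref$contig_lengths[[cn]])
    part <- cds[cds$contig == cn, ]
    for (i in seq_len(nrow(part))) m[(part$start[i] + 1):part$end[i]] <- TRUE
    m
  })
  names(masks) <- ref$contig_names
  v <- cons$variants
  hit <- vapply(seq_len(nrow(v)), function(i) {
    any(masks[[v$contig[i]]][v$pos[i]:(v$pos[i] + nchar(v$ref[i]) - 1L)])
  }, logical(1))
  want <- c(snv = sum(v$vclass[hit] == "SNV"),
            indel = sum(v$vclass[hit] %in% c("INS", "DEL")))
  expect_equal(count_in_footprint(cons, cds), want)
})

test_that("protein-modifying counting keeps HIGH and MODERATE only", {
  su <- scoped_setup()
  rows <- snv_at("1", c(2, 12, 22, 32, 42))
  impacts <- c("HIGH", "MODERATE", "LOW", "MODIFIER", NA)
  rows$info <- ifelse(is.na(impacts), ".",
                      paste0("ANN=", rows$alt, "|effect|", impacts,
                             "|GENEA|GENEA|t|t1|||||"))
  cons <- consensus_of(rows, su$ref)
  expect_equal(count_protein_modifying(cons), c(snv = 2L, indel = 0L))
  # all-MODIFIER consensus counts nothing
  rows$info <- paste0("ANN=", rows$alt,
                      "|intron_variant|MODIFIER|GENEA|GENEA|t|t1|||||")
  expect_equal(count_protein_modifying(consensus_of(rows, su$ref)),
               c(snv = 0L, indel = 0L))
})

test_that("panel exclusions remove COSMIC, nonsense and TSG drivers once", {
  su <- scoped_setup()
  fp <- interval_set("1", 0, 300)
  pos <- c(2, 12, 22, 32, 42)
  rows <- snv_at("1", pos)
  effects <- c("missense_variant", "missense_variant", "stop_gained",
               "missense_variant", "missense_variant")
  impacts <- c("MODERATE", "MODERATE", "HIGH", "MODERATE", "MODERATE")
  genes <- c("GENEA", "GENEA", "GENEB", "GENEA", "GENEC")
  rows$info <- paste0("ANN=", rows$alt, "|", effects, "|", impacts, "|",
                      genes, "|", genes, "|t|t1|||||")
  cons <- consensus_of(rows, su$ref)
  cosmic_key <- cons$variants$key[cons$variants$pos == 12]
  cfg <- panel_config(panel_genes = c("GENEA", "GENEB", "GENEC"),
                      tumor_suppressor_genes = "GENEC",
                      cosmic_keys = cosmic_key)
  got <- count_panel(cons, fp, cfg)
  # 5 in footprint - 1 COSMIC - 1 nonsense - 1 TSG MODERATE = 2
  expect_equal(unname(got["snv"]), 2L)
  excl <- attr(got, "exclusions")
  expect_equal(unname(excl[c("cosmic", "nonsense", "tsg", "total")]),
               c(1L, 1L, 1L, 3L))
  # a variant that is both COSMIC and a TSG nonsense is removed once
  cfg2 <- panel_config(panel_genes = c("GENEA", "GENEB", "GENEC"),
                       tumor_suppressor_genes = "GENEB",
                       cosmic_keys = cons$variants$key[cons$variants$pos == 22])
  got2 <- count_panel(cons, fp, cfg2)
  expect_equal(unname(got2["snv"]), 4L)
  expect_equal(unname(attr(got2, "exclusions")[c("cosmic", "nonsense",
                                                 "tsg", "total")]),
               c(1L, 1L, 1L, 1L))
  # exclusions only ever decrease the count
  none <- count_panel(cons, fp,
                      panel_config(panel_genes = "GENEA"))
  expect_gte(unname(none["snv"]), unname(got["snv"]))
  # no overlap with the footprint -> zero
  far <- interval_set("1", 350, 380)
  expect_equal(unname(count_panel(cons, far, cfg)["snv"]), 0L)
  expect_error(panel_config(character()), "empty panel")
})

test_that("per-Mb conversion and threshold classification are exact", {
  expect_equal(compute_tmb(0, 123456), 0)
  expect_equal(round(compute_tmb(38014, 2667837836), 4), 14.2490)
  expect_error(compute_tmb(1, 0), "positive")
  expect_error(compute_tmb(-1, 10), "negative")
  expect_equal(classify_threshold(10), "high")      # boundary is high
  expect_equal(classify_threshold(9.9999), "low")
  expect_equal(classify_threshold(17.12), "high")
  expect_equal(classify_threshold(0), "low")
  expect_error(classify_threshold(5, threshold = -1), "negative")
})

test_that("cohort concordance partitions samples by agreement", {
  r_high <- fake_report("all_high", rep(12, 8))
  r_low <- fake_report("all_low", rep(3, 8))
  r_mix <- fake_report("one_off", c(12, 12, 12, 12, 12, 12, 12, 3))
  cs <- summarize_cohort(list(r_high, r_low, r_mix))
  expect_equal(cs$n_samples, 3)
  expect_equal(cs$n_consistently_high, 1)
  expect_equal(cs$n_consistently_low, 1)
  expect_equal(cs$discordant_by_k, c(`1` = 1L))
  # single sample is trivially consistent
  one <- summarize_cohort(list(r_high))
  expect_equal(one$n_consistently_high + one$n_consistently_low, 1)
  # mixed thresholds are rejected
  r_other <- fake_report("other", rep(12, 8), threshold = 5)
  expect_error(summarize_cohort(list(r_high, r_other)), "thresholds")
})

test_that("cohort tallies match a brute-force per-sample scan", {
  set.seed(99)
  reports <- lapply(1:40, function(i)
    fake_report(paste0("S", i), runif(8, 0, 20)))
  cs <- summarize_cohort(reports)
  calls <- t(vapply(reports, function(r)
    ifelse(r$tmb_per_mb >= 10, "high", "low"), character(8)))
  n_high <- sum(apply(calls, 1, function(x) all(x == "high")))
  n_low <- sum(apply(calls, 1, function(x) all(x == "low")))
  expect_equal(cs$n_consistently_high, n_high)
  expect_equal(cs$n_consistently_low, n_low)
  expect_equal(sum(cs$discordant_by_k), 40 - n_high - n_low)
  expect_equal(cs$n_samples, 40)
})

test_that("report rendering is deterministic and round-trips", {
  fx <- get_fixture(5, small = TRUE)
  rep1 <- run_fixture(fx)
  expect_identical(render_report(rep1, "tsv"), render_report(rep1, "tsv"))
  j <- jsonlite::fromJSON(render_report(rep1, "json"),
                          simplifyVector = FALSE)
  df <- as.data.frame(rep1)
  for (e in j$estimates) {
    row <- df[df$subset == e$subset & df$class == e$class, ]
    expect_equal(e$count, row$count)
    expect_equal(e$tmb_per_mb, round(row$tmb_per_mb, 4))
    expect_equal(e$classification, row$classification)
  }
  expect_error(render_report(rep1, "xml"))
  # empty cohort rendering: header only
  cs <- summarize_cohort(list(fake_report("s", rep(12, 8))))
  tsv <- render_report(cs, "tsv")
  expect_equal(length(strsplit(tsv, "\n")[[1]]), 2)
})
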