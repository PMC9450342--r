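# Independent brute-force oracles and small in-code fixtures shared across
# test files. Nothing here calls the interval/overlap machinery under test.

# ---- tiny file writers -------------------------------------------------

write_mini_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(seqs), function(nm) c(paste0(">", nm),
                                                     seqs[[nm]])))
  writeLines(lines, path)
  path
}

write_mini_gtf <- function(rows, path = tempfile(fileext = ".gtf")) {
  # rows: data.frame contig, start, end, gene, transcript (1-based inclusive)
  writeLines(sprintf(
    "%s\tsrc\tCDS\t%d\t%d\t.\t+\t0\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
    rows$contig, rows$start, rows$end, rows$gene, rows$transcript,
    rows$gene), path)
  path
}

write_mini_vcf <- function(rows, path = tempfile(fileext = ".vcf"),
                           contigs = NULL) {
  # rows: data.frame chrom, pos, ref, alt, filter, info (optional)
  header <- c("##fileformat=VCFv4.2",
              if (!is.null(contigs))
                sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                        unname(contigs)),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (is.null(rows) || nrow(rows) == 0) character() else {
    filt <- if ("filter" %in% names(rows)) rows$filter else "PASS"
    info <- if ("info" %in% names(rows)) rows$info else "."
    sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s", rows$chrom, rows$pos, rows$ref,
            rows$alt, filt, info)
  }
  writeLines(c(header, body), path)
  path
}

# ---- brute-force oracles ----------------------------------------------

# covered-position count by per-base boolean mask
mask_covered_bases <- function(contig, start, end, contig_len) {
  # start/end 0-based half-open
  contig <- rep(contig, length.out = length(start))
  total <- 0
  for (cn in unique(contig)) {
    m <- rep(FALSE, contig_len)
    for (i in which(contig == cn)) m[(start[i] + 1):end[i]] <- TRUE
    total <- total + sum(m)
  }
  total
}

# apply a VCF-style variant to a reference string; the resulting haplotype
# defines allele equivalence
apply_variant <- function(seq_str, pos, ref, alt) {
  stopifnot(substr(seq_str, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq_str, 1, pos - 1L), alt,
         substr(seq_str, pos + nchar(ref), nchar(seq_str)))
}

# exhaustively enumerate every VCF representation (pos, ref, alt) within a
# position window that produces the given haplotype: for each candidate
# (pos, ref-length) the required ALT is uniquely determined by the fixed
# flanks, so checking flank identity enumerates the full equivalence class.
enumerate_equivalent_reps <- function(seq_str, hap_str, center,
                                      radius = 10L, max_ref_len = 8L,
                                      max_alt_len = 12L) {
  len <- nchar(seq_str)
  lh <- nchar(hap_str)
  reps <- list()
  for (p in max(1L, center - radius):min(len, center + radius)) {
    for (rl in 1:max_ref_len) {
      if (p + rl - 1L > len) next
      al <- lh - (p - 1L) - (len - (p + rl - 1L))
      if (al < 1L || al > max_alt_len) next
      if (substr(hap_str, 1L, p - 1L) != substr(seq_str, 1L, p - 1L)) next
      if (substr(hap_str, p + al, lh) != substr(seq_str, p + rl, len)) next
      r <- substr(seq_str, p, p + rl - 1L)
      a <- substr(hap_str, p, p + al - 1L)
      if (r == a) next
      reps[[length(reps) + 1L]] <- list(pos = p, ref = r, alt = a)
    }
  }
  reps
}

# ---- cached fixtures ---------------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

small_fixture_spec <- function(seed) {
  fixture_spec(seed = seed, contig_length = 8000, n_genes = 4,
               n_truth_snvs = 24, n_truth_indels = 10)
}

get_fixture <- function(seed, small = FALSE) {
  key <- paste0(if (small) "small" else "full", seed)
  if (is.null(.fixture_cache[[key]])) {
    spec <- if (small) small_fixture_spec(seed) else fixture_spec(seed = seed)
    dir <- file.path(tempdir(), "tmbcount-fixtures", key)
    .fixture_cache[[key]] <- make_fixture(spec, dir)
  }
  .fixture_cache[[key]]
}

run_fixture <- function(fx, out_dir = NULL, ...) {
  suppressMessages(run_tmb(
    strelka2 = fx$paths$strelka2, mutect2 = fx$paths$mutect2,
    manta = fx$paths$manta, reference = fx$paths$reference,
    gtf = fx$paths$gtf, panel_genes = fx$paths$panel,
    tsg_genes = fx$paths$tsg, cosmic = fx$paths$cosmic,
    sample_id = paste0("S", fx$spec$seed), out_dir = out_dir, ...))
}

# fabricate a tmb_report for cohort-summary unit tests
fake_report <- function(sample_id, tmb_values, threshold = 10) {
  subsets <- c("genome", "coding", "protein", "panel")
  df <- expand.grid(class = c("snv", "total"), subset = subsets,
                    stringsAsFactors = FALSE)[, c(2, 1)]
  df$sample_id <- sample_id
  df$count <- 1L
  df$denominator_bases <- 1e6
  df$tmb_per_mb <- tmb_values
  df$classification <- ifelse(tmb_values >= threshold, "high", "low")
  structure(df[, c("sample_id", "subset", "class", "count",
                   "denominator_bases", "tmb_per_mb", "classification")],
            class = c("tmb_report", "data.frame"), threshold = threshold)
}
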