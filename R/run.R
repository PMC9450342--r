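#' Run the full TMB estimation pipeline for one sample
#'
#' Reads the reference, annotation, panel inputs and per-caller somatic
#' VCFs; normalizes and intersects the caller sets; computes the four-subset
#' TMB report; and writes `consensus.vcf`, `tmb_report.tsv`,
#' `tmb_report.json` and `run_log.txt` into `out_dir`. All outputs are
#' deterministic: two runs on identical inputs are byte-identical.
#'
#' @param strelka2,mutect2 paths to the required caller VCFs.
#' @param manta optional path to a Manta VCF (its non-symbolic indel records
#'   join the intersection; symbolic SV records are tallied only).
#' @param reference path to the reference FASTA.
#' @param gtf path to the gene annotation GTF (CDS features).
#' @param panel_genes,tsg_genes paths to plain-text gene lists (one gene per
#'   line).
#' @param cosmic path to a known-somatic-sites VCF/TSV, or NULL for none.
#' @param sample_id sample identifier used in the report.
#' @param threshold per-Mb high/low threshold (default 10).
#' @param policy consensus membership policy (see [intersect_callers()]).
#' @param scope_contigs counting-scope contigs (default autosomes + X, Y;
#'   contigs absent from the reference are ignored).
#' @param decompose_mnvs decompose multi-nucleotide substitutions (default
#'   TRUE).
#' @param cosmic_match_mode `"allele"` (default) or `"position"`.
#' @param out_dir output directory (created if missing), or NULL to skip
#'   writing files.
#' @param aliases optional contig alias table.
#' @return the `tmb_report`, invisibly, with attribute `consensus` (the
#'   `consensus_set`) and `paths` (written files).
#' @export
run_tmb <- function(strelka2, mutect2, manta = NULL,
                    reference, gtf, panel_genes, tsg_genes = NULL,
                    cosmic = NULL, sample_id = "sample",
                    threshold = 10, policy = "strelka2+mutect2",
                    scope_contigs = default_scope_contigs(),
                    decompose_mnvs = TRUE,
                    cosmic_match_mode = "allele",
                    out_dir = NULL, aliases = NULL) {
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  ref <- read_genome_reference(reference, aliases)
  say("reference: ", length(ref$contig_names), " contig(s), ",
      sum(ref$contig_lengths), " bases")
  scope <- counting_scope(ref, scope_contigs)
  say("scope: ", length(scope$contigs), " contig(s), alignable bases = ",
      format(scope$alignable_bases, scientific = FALSE))

  cds <- build_cds_intervals(gtf, scope_contigs = scope$contigs,
                             aliases = aliases)
  say("CDS footprint: ", nrow(cds), " interval(s), ",
      format(total_bases(cds), scientific = FALSE), " bases")

  panel <- readLines(panel_genes)
  panel <- panel[nzchar(panel)]
  tsg <- if (is.null(tsg_genes)) character() else {
    x <- readLines(tsg_genes)
    x[nzchar(x)]
  }
  panel_fp <- build_cds_intervals(gtf, scope_contigs = scope$contigs,
                                  gene_filter = panel, aliases = aliases)
  say("panel footprint (", length(panel), " gene(s)): ",
      format(total_bases(panel_fp), scientific = FALSE), " bases")

  cosmic_keys <- if (is.null(cosmic)) character() else
    read_cosmic_sites(cosmic, ref, aliases)
  cfg <- panel_config(panel, tsg, cosmic_keys,
                      match_mode = cosmic_match_mode)

  sets <- list(read_caller_vcf(strelka2, "strelka2", ref,
                               decompose_mnvs = decompose_mnvs,
                               aliases = aliases),
               read_caller_vcf(mutect2, "mutect2", ref,
                               decompose_mnvs = decompose_mnvs,
                               aliases = aliases))
  if (!is.null(manta)) {
    sets <- c(sets, list(read_caller_vcf(manta, "manta", ref,
                                         decompose_mnvs = decompose_mnvs,
                                         aliases = aliases)))
  }
  for (s in sets) {
    say(s$caller, ": ", s$n_records_read, " read, ", s$n_records_pass,
        " PASS, ", s$n_after_normalization, " normalized, ",
        s$n_symbolic, " symbolic")
  }

  consensus <- intersect_callers(sets, policy = policy)
  say("consensus (", policy, "): ", nrow(consensus$variants), " variant(s)")

  report <- tmb_report(sample_id, consensus, scope, cds, panel_fp, cfg,
                       threshold = threshold)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      consensus_vcf = file.path(out_dir, "consensus.vcf"),
      report_tsv = file.path(out_dir, "tmb_report.tsv"),
      report_json = file.path(out_dir, "tmb_report.json"),
      run_log = file.path(out_dir, "run_log.txt"))
    write_consensus_vcf(consensus, paths$consensus_vcf, reference = ref)
    write_text(render_report(report, "tsv"), paths$report_tsv)
    write_text(render_report(report, "json"), paths$report_json)
    write_text(paste(log_lines, collapse = "\n"), paths$run_log)
  }
  attr(report, "consensus") <- consensus
  attr(report, "paths") <- paths
  invisible(report)
}

# byte-stable text writer (LF endings, trailing newline)
write_text <- function(text, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(text, con, sep = "\n")
  invisible(path)
}

#' Read a YAML run configuration
#'
#' A configuration file mirrors the arguments of [run_tmb()] (keys named
#' after the function's parameters); command-line flags override file
#' values.
#'
#' @param path YAML file path.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- names(formals(run_tmb))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}

#' Load per-sample TSV reports and summarize cohort concordance
#'
#' Reads `tmb_report.tsv` files written by [run_tmb()] and rebuilds the
#' reports for [summarize_cohort()].
#'
#' @param report_paths character vector of `tmb_report.tsv` paths.
#' @return a `cohort_summary`.
#' @export
load_cohort <- function(report_paths) {
  reports <- lapply(report_paths, function(p) {
    df <- utils::read.table(p, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c(sample_id = "character"))
    thr <- unique(df$threshold)
    if (length(thr) != 1) stop("mixed thresholds in ", p)
    df$threshold <- NULL
    structure(df, class = c("tmb_report", "data.frame"), threshold = thr)
  })
  summarize_cohort(reports)
}
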