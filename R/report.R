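SUBSETS <- c("genome", "coding", "protein", "panel")

#' Build a per-sample TMB report across the four genomic subsets
#'
#' Computes SNV-only and total (SNV + indel) counts, per-Mb TMB and the
#' high/low classification for each genomic subset:
#' \describe{
#'   \item{genome}{all consensus variants on scope contigs / alignable
#'     (non-N) bases.}
#'   \item{coding}{variants overlapping the merged CDS footprint / CDS
#'     bases.}
#'   \item{protein}{variants with HIGH or MODERATE impact / CDS bases.}
#'   \item{panel}{variants in panel-gene CDS after COSMIC and
#'     tumor-suppressor/nonsense exclusions / panel CDS bases.}
#' }
#'
#' @param sample_id sample identifier string.
#' @param consensus a `consensus_set`.
#' @param scope a `counting_scope`.
#' @param cds_footprint [interval_set()] of all merged CDS.
#' @param panel_footprint [interval_set()] of panel-gene merged CDS.
#' @param panel_cfg a [panel_config()].
#' @param threshold per-Mb high/low threshold (default 10).
#' @return a `tmb_report`: data.frame with columns sample_id, subset, class,
#'   count, denominator_bases, tmb_per_mb (unrounded), classification;
#'   attributes `threshold` and `exclusions`.
#' @export
tmb_report <- function(sample_id, consensus, scope, cds_footprint,
                       panel_footprint, panel_cfg, threshold = 10) {
  g <- count_genome(consensus, scope)
  # subsets below the genome one only see in-scope variants
  in_scope <- consensus
  in_scope$variants <- in_scope$variants[
    in_scope$variants$contig %in% scope$contigs, , drop = FALSE]
  cc <- count_in_footprint(in_scope, cds_footprint)
  pp <- count_protein_modifying(in_scope)
  pn <- count_panel(in_scope, panel_footprint, panel_cfg)
  counts <- rbind(genome = g, coding = cc, protein = pp,
                  panel = c(pn["snv"], pn["indel"]))
  denoms <- c(genome = scope$alignable_bases,
              coding = total_bases(cds_footprint),
              protein = total_bases(cds_footprint),
              panel = total_bases(panel_footprint))
  rows <- list()
  for (s in SUBSETS) {
    for (cl in c("snv", "total")) {
      n <- if (cl == "snv") counts[s, "snv"] else sum(counts[s, ])
      tmb <- compute_tmb(n, denoms[[s]])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, subset = s, class = cl,
        count = as.integer(n), denominator_bases = denoms[[s]],
        tmb_per_mb = tmb,
        classification = classify_threshold(tmb, threshold),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("tmb_report", "data.frame"),
            threshold = threshold, exclusions = attr(pn, "exclusions"))
}

#' Summarize high/low threshold concordance across a cohort
#'
#' For each sample, the selected (subset, class) estimates are compared
#' against the shared threshold; the cohort is partitioned into samples
#' consistently high, consistently low, and discordant in exactly k
#' estimates (k counted against the sample's majority call).
#'
#' @param reports list of `tmb_report` objects sharing one threshold.
#' @param subsets genomic subsets to compare (default all four).
#' @param classes variant classes to compare (default `"snv"` and
#'   `"total"`).
#' @return a `cohort_summary`: list with `n_samples`,
#'   `n_consistently_high`, `n_consistently_low`, `discordant_by_k` (named
#'   integer vector), and `classifications` (samples x estimates character
#'   matrix).
#' @export
summarize_cohort <- function(reports, subsets = SUBSETS,
                             classes = c("snv", "total")) {
  stopifnot(length(reports) > 0,
            all(vapply(reports, inherits, logical(1), "tmb_report")))
  thresholds <- vapply(reports, attr, numeric(1), "threshold")
  if (length(unique(thresholds)) != 1) {
    stop("reports use different thresholds: ",
         paste(unique(thresholds), collapse = ", "))
  }
  est_names <- as.vector(outer(subsets, classes, paste, sep = "_"))
  cls <- t(vapply(reports, function(r) {
    sel <- r[r$subset %in% subsets & r$class %in% classes, , drop = FALSE]
    key <- paste(sel$subset, sel$class, sep = "_")
    stats::setNames(sel$classification, key)[est_names]
  }, character(length(est_names))))
  rownames(cls) <- vapply(reports, function(r) r$sample_id[1], character(1))
  n_high <- sum(apply(cls, 1, function(x) all(x == "high")))
  n_low <- sum(apply(cls, 1, function(x) all(x == "low")))
  n_disagree <- apply(cls, 1, function(x) min(sum(x == "high"),
                                              sum(x == "low")))
  disc <- n_disagree[n_disagree > 0]
  discordant_by_k <- if (length(disc)) table(factor(disc)) else
    table(factor(integer()))
  structure(
    list(n_samples = nrow(cls),
         n_consistently_high = n_high,
         n_consistently_low = n_low,
         discordant_by_k = stats::setNames(as.integer(discordant_by_k),
                                           names(discordant_by_k)),
         classifications = cls,
         threshold = thresholds[1]),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort_summary: %d sample(s); %d consistently high, %d consistently low, %d discordant\n",
              x$n_samples, x$n_consistently_high, x$n_consistently_low,
              x$n_samples - x$n_consistently_high - x$n_consistently_low))
  invisible(x)
}

# fixed 4-decimal formatting (round half to even, as in R's round())
format_tmb <- function(x) {
  formatC(round(x, 4), format = "f", digits = 4)
}

#' Render a report deterministically as TSV or JSON
#'
#' Fixed column/key order and fixed 4-decimal float formatting make the
#' output byte-stable: identical inputs always render to identical bytes.
#' Classification in the report was computed from unrounded values before
#' rendering.
#'
#' @param report a `tmb_report` or `cohort_summary`.
#' @param format `"tsv"` or `"json"`.
#' @return a character scalar containing the rendered text.
#' @export
render_report <- function(report, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(report, "tmb_report")) {
    df <- as.data.frame(report)
    df$threshold <- attr(report, "threshold")
    if (format == "tsv") {
      header <- paste(names(df), collapse = "\t")
      body <- sprintf("%s\t%s\t%s\t%d\t%.0f\t%s\t%s\t%s",
                      df$sample_id, df$subset, df$class, df$count,
                      df$denominator_bases, format_tmb(df$tmb_per_mb),
                      df$classification, format(df$threshold))
      return(paste(c(header, body), collapse = "\n"))
    }
    x <- list(sample_id = df$sample_id[1],
              threshold = attr(report, "threshold"),
              estimates = lapply(seq_len(nrow(df)), function(i) {
                list(subset = df$subset[i], class = df$class[i],
                     count = df$count[i],
                     denominator_bases = df$denominator_bases[i],
                     tmb_per_mb = round(df$tmb_per_mb[i], 4),
                     classification = df$classification[i])
              }),
              exclusions = as.list(attr(report, "exclusions")))
    return(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                         digits = NA, pretty = TRUE)))
  }
  if (inherits(report, "cohort_summary")) {
    if (format == "tsv") {
      cls <- report$classifications
      header <- paste(c("sample_id", colnames(cls)), collapse = "\t")
      body <- if (nrow(cls) == 0) character() else
        paste(rownames(cls), apply(cls, 1, paste, collapse = "\t"),
              sep = "\t")
      return(paste(c(header, body), collapse = "\n"))
    }
    x <- list(n_samples = report$n_samples,
              n_consistently_high = report$n_consistently_high,
              n_consistently_low = report$n_consistently_low,
              discordant_by_k = as.list(report$discordant_by_k),
              threshold = report$threshold)
    return(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                         digits = NA, pretty = TRUE)))
  }
  stop("unsupported report type: ", paste(class(report), collapse = "/"))
}
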