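#' Load a genome reference from FASTA
#'
#' Reads a (optionally gzipped) FASTA into memory and normalizes contig
#' names to the canonical space (see [normalize_contig()]). Sequences are
#' stored uppercase; soft-masked (lowercase) bases are therefore treated
#' like their uppercase counterparts and only N marks non-alignable
#' positions.
#'
#' @param fasta_path path to a FASTA file.
#' @param aliases optional contig alias table, see [normalize_contig()].
#' @return a `genome_ref` object: list with `seq` (a
#'   [Biostrings::DNAStringSet] keyed by canonical contig name),
#'   `contig_names` and `contig_lengths`.
#' @export
read_genome_reference <- function(fasta_path, aliases = NULL) {
  if (!file.exists(fasta_path)) {
    stop("reference FASTA not found: ", fasta_path)
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  # FASTA headers may carry descriptions after the identifier
  nm <- sub("\\s.*$", "", names(seqs))
  nm <- normalize_contig(nm, aliases)
  if (anyDuplicated(nm)) {
    stop("duplicate contig names after alias normalization: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(seqs) <- nm
  structure(
    list(seq = seqs, contig_names = nm,
         contig_lengths = stats::setNames(Biostrings::width(seqs), nm)),
    class = "genome_ref"
  )
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("genome_ref:", length(x$contig_names), "contig(s),",
      sum(x$contig_lengths), "bases\n")
  invisible(x)
}

# Fetch reference bases [start, end] (1-based inclusive) on a contig.
ref_bases <- function(reference, contig, start, end) {
  stopifnot(inherits(reference, "genome_ref"))
  if (!contig %in% reference$contig_names) {
    stop("contig not in reference: ", contig)
  }
  len <- reference$contig_lengths[[contig]]
  if (start < 1L || end > len || end < start) {
    stop(sprintf("coordinates [%d,%d] out of range for contig %s (length %d)",
                 start, end, contig, len))
  }
  as.character(Biostrings::subseq(reference$seq[[contig]], start, end))
}

#' Count alignable (non-N) bases over a contig scope
#'
#' The whole-genome TMB denominator is the alignable space: the number of
#' reference positions that are not N, case-insensitively, over the allowed
#' contigs. For hg19 chromosomes 1-22, X, Y this is 2,667,837,836 bases.
#'
#' @param reference a `genome_ref` from [read_genome_reference()].
#' @param scope_contigs canonical contig names to count over; defaults to
#'   autosomes plus X and Y.
#' @return integer-valued numeric count of non-N bases.
#' @export
count_alignable_bases <- function(reference,
                                  scope_contigs = default_scope_contigs()) {
  stopifnot(inherits(reference, "genome_ref"))
  scope_contigs <- normalize_contig(scope_contigs)
  if (length(scope_contigs) == 0) stop("empty contig scope")
  missing <- setdiff(scope_contigs, reference$contig_names)
  if (length(missing) > 0) {
    stop("contig(s) not in reference: ", paste(missing, collapse = ", "))
  }
  seqs <- reference$seq[scope_contigs]
  n_count <- sum(Biostrings::letterFrequency(seqs, letters = "N"))
  sum(as.numeric(Biostrings::width(seqs))) - n_count
}

#' Describe a counting scope
#'
#' Bundles the allowed contigs with their alignable-base total, the fixed
#' denominator of whole-genome TMB.
#'
#' @param reference a `genome_ref`.
#' @param scope_contigs canonical contig names (default autosomes + X, Y);
#'   contigs absent from the reference are dropped, so the default works for
#'   toy genomes with fewer chromosomes.
#' @return a `counting_scope` object: list with `contigs`, `alignable_bases`.
#' @export
counting_scope <- function(reference,
                           scope_contigs = default_scope_contigs()) {
  scope_contigs <- normalize_contig(scope_contigs)
  present <- intersect(scope_contigs, reference$contig_names)
  if (length(present) == 0) {
    stop("no scope contig present in the reference")
  }
  structure(
    list(contigs = present,
         alignable_bases = count_alignable_bases(reference, present)),
    class = "counting_scope"
  )
}

#' Build the merged CDS footprint from a GTF annotation
#'
#' Collects all `CDS` feature rows on the scope contigs, optionally
#' restricted to a gene set, and merges them into a union of non-overlapping
#' intervals so each genomic base is counted once regardless of how many
#' transcripts cover it. Coordinates are converted from GTF 1-based
#' inclusive to the package's 0-based half-open convention. For the Ensembl
#' 75 annotation on hg19 chromosomes 1-22, X, Y the merged total is
#' 31,990,128 bases.
#'
#' @param gtf_path path to a GTF file with CDS features carrying a
#'   `gene_name` attribute.
#' @param scope_contigs canonical contig names to keep (contigs absent from
#'   the annotation simply contribute nothing).
#' @param gene_filter optional character vector of gene names; only CDS of
#'   these genes are kept. Names absent from the annotation raise a warning.
#' @param aliases optional contig alias table.
#' @return an [interval_set()].
#' @export
build_cds_intervals <- function(gtf_path,
                                scope_contigs = default_scope_contigs(),
                                gene_filter = NULL,
                                aliases = NULL) {
  if (!file.exists(gtf_path)) stop("GTF not found: ", gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  if (length(gr) == 0) stop("no CDS features found in ", gtf_path)
  contig <- normalize_contig(as.character(GenomicRanges::seqnames(gr)), aliases)
  keep <- contig %in% normalize_contig(scope_contigs)
  gr <- gr[keep]
  contig <- contig[keep]
  if (!is.null(gene_filter)) {
    gene <- as.character(gr$gene_name)
    missing <- setdiff(gene_filter, unique(gene))
    if (length(missing) > 0) {
      warning("gene(s) not found in annotation: ",
              paste(missing, collapse = ", "))
    }
    keep <- !is.na(gene) & gene %in% gene_filter
    gr <- gr[keep]
    contig <- contig[keep]
  }
  interval_set(contig = contig,
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr))
}
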