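#' Canonical contig names
#'
#' Human references mix two naming dialects for the same chromosomes:
#' UCSC-style ("chr1", "chrX") and Ensembl-style ("1", "X"). All coordinates
#' in this package are expressed in a canonical space obtained by stripping a
#' leading "chr" and applying an optional alias table, so a UCSC-named FASTA
#' can be combined with an Ensembl-named GTF.
#'
#' @param x character vector of contig names.
#' @param aliases optional named character vector mapping raw names to
#'   canonical names (applied after "chr" stripping), e.g.
#'   `c(MT = "M")`.
#' @return character vector of canonical contig names.
#' @examples
#' normalize_contig(c("chr1", "1", "chrX"))
#' @export
normalize_contig <- function(x, aliases = NULL) {
  stopifnot(is.character(x))
  out <- sub("^chr", "", x)
  if (!is.null(aliases)) {
    stopifnot(!is.null(names(aliases)))
    hit <- out %in% names(aliases)
    out[hit] <- unname(aliases[out[hit]])
  }
  out
}

#' Default counting scope: the nuclear chromosomes 1-22, X and Y
#'
#' Mitochondrial, unplaced and alt contigs are excluded from all TMB
#' counting by default.
#'
#' @return character vector of canonical contig names.
#' @export
default_scope_contigs <- function() {
  c(as.character(1:22), "X", "Y")
}

# Total order on canonical contig names: 1..22, X, Y first, then everything
# else alphabetically. Used wherever deterministic output order matters.
contig_rank <- function(x) {
  canon <- default_scope_contigs()
  r <- match(x, canon)
  extra <- sort(unique(x[is.na(r)]))
  r[is.na(r)] <- length(canon) + match(x[is.na(r)], extra)
  r
}

#' Published hg19 TMB denominators
#'
#' Reference-space constants for the hg19 assembly with Ensembl 75
#' annotation, as used for whole-genome TMB reporting: the alignable
#' (non-N) base count of chromosomes 1-22, X, Y and the merged CDS base
#' total on the same chromosomes. These are published constants for use as
#' denominators when the full reference files are not at hand;
#' [count_alignable_bases()] and [build_cds_intervals()] recompute them from
#' a local FASTA/GTF.
#'
#' @return named list with `alignable_bases` and `cds_bases`.
#' @export
hg19_denominators <- function() {
  list(alignable_bases = 2667837836, cds_bases = 31990128)
}
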