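IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

# (snv, indel) tally of a variant data.frame. Undecomposed MNVs belong to
# neither bucket (the default pipeline decomposes them into SNVs upstream).
tally_classes <- function(v) {
  c(snv = sum(v$vclass == "SNV"),
    indel = sum(v$vclass %in% c("INS", "DEL")))
}

#' Count consensus variants in the whole-genome subset
#'
#' Keeps variants whose contig belongs to the counting scope (autosomes plus
#' X and Y by default); variants on excluded contigs (mitochondrial,
#' unplaced) are dropped from all subsets.
#'
#' @param consensus a `consensus_set`.
#' @param scope a `counting_scope` from [counting_scope()].
#' @return named integer vector `c(snv=, indel=)`.
#' @export
count_genome <- function(consensus, scope) {
  stopifnot(inherits(consensus, "consensus_set"),
            inherits(scope, "counting_scope"))
  v <- consensus$variants
  tally_classes(v[v$contig %in% scope$contigs, , drop = FALSE])
}

# Restrict a variant data.frame to records whose reference span overlaps a
# footprint. The span of a variant is pos .. pos+|ref|-1 (1-based inclusive);
# for insertions this is just the anchor base.
filter_in_footprint <- function(v, footprint) {
  if (nrow(v) == 0 || nrow(footprint) == 0) return(v[0, , drop = FALSE])
  vg <- GenomicRanges::GRanges(
    seqnames = v$contig,
    ranges = IRanges::IRanges(start = v$pos, end = v$pos + nchar(v$ref) - 1L))
  hits <- GenomicRanges::findOverlaps(vg, as_granges(footprint))
  v[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Count consensus variants overlapping an interval footprint
#'
#' A variant is counted when its reference span (position through position +
#' reference-allele length - 1) overlaps at least one footprint base; an
#' insertion is counted when its anchor base lies in the footprint. Used for
#' the coding subset (CDS footprint) and as the first step of the
#' pseudo-panel subset.
#'
#' @param consensus a `consensus_set`.
#' @param footprint an [interval_set()].
#' @return named integer vector `c(snv=, indel=)`.
#' @export
count_in_footprint <- function(consensus, footprint) {
  stopifnot(inherits(consensus, "consensus_set"),
            inherits(footprint, "interval_set"))
  tally_classes(filter_in_footprint(consensus$variants, footprint))
}

#' Count protein-modifying consensus variants
#'
#' Keeps variants whose annotation impact is HIGH or MODERATE; unannotated
#' variants are never counted. The subset's denominator is the same merged
#' CDS total used by the coding subset.
#'
#' @param consensus a `consensus_set`.
#' @return named integer vector `c(snv=, indel=)`.
#' @export
count_protein_modifying <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_set"))
  v <- consensus$variants
  tally_classes(v[!is.na(v$impact) & v$impact %in% c("HIGH", "MODERATE"), ,
                  drop = FALSE])
}

#' Pseudo-panel configuration
#'
#' Bundles the inputs of the pseudo-panel subset: the cancer-gene panel, the
#' tumor-suppressor gene (TSG) list, and known-somatic (COSMIC-like) sites
#' used for exclusion. Known sites are matched either by full normalized
#' allele (`"allele"`, default, conservative) or by position only
#' (`"position"`).
#'
#' @param panel_genes character vector of panel gene names (non-empty).
#' @param tumor_suppressor_genes character vector of TSG names (need not be
#'   a subset of the panel).
#' @param cosmic_keys character vector of normalized variant keys
#'   (`contig:pos:ref:alt`) for allele mode; positions are derived from them
#'   for position mode. See [read_cosmic_sites()].
#' @param match_mode `"allele"` or `"position"`.
#' @return a `panel_config` object.
#' @export
panel_config <- function(panel_genes, tumor_suppressor_genes = character(),
                         cosmic_keys = character(),
                         match_mode = c("allele", "position")) {
  match_mode <- match.arg(match_mode)
  if (length(panel_genes) == 0) {
    stop("empty panel gene list: the panel denominator is undefined")
  }
  structure(
    list(panel_genes = unique(panel_genes),
         tumor_suppressor_genes = unique(tumor_suppressor_genes),
         cosmic_keys = unique(cosmic_keys),
         match_mode = match_mode),
    class = "panel_config"
  )
}

#' Read known-somatic (COSMIC-like) sites into normalized keys
#'
#' Accepts either a VCF or a tab-separated file with columns contig, pos,
#' ref, alt. Every site is normalized with the same rules as variant records
#' so that exclusion matching is exact.
#'
#' @param path VCF or TSV file.
#' @param reference a `genome_ref`.
#' @param aliases optional contig alias table.
#' @return character vector of normalized keys (`contig:pos:ref:alt`).
#' @export
read_cosmic_sites <- function(path, reference, aliases = NULL) {
  if (!file.exists(path)) stop("known-sites file not found: ", path)
  first <- readLines(path, n = 1)
  if (grepl("^##fileformat=VCF", first)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1,
                                          dimnames = list(NULL, names(fix)))
    if (is.null(fix) || nrow(fix) == 0) return(character())
    df <- data.frame(contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            col.names = c("contig", "pos", "ref", "alt"),
                            colClasses = c("character", "integer",
                                           "character", "character"))
  }
  keys <- character()
  for (i in seq_len(nrow(df))) {
    for (alt in strsplit(df$alt[i], ",", fixed = TRUE)[[1]]) {
      if (is_symbolic_alt(alt)) next
      nv <- normalize_variant(normalize_contig(df$contig[i], aliases),
                              df$pos[i], df$ref[i], alt, reference)
      keys <- c(keys, variant_key(nv$contig, nv$pos, nv$ref, nv$alt))
    }
  }
  unique(keys)
}

#' Count pseudo-panel variants
#'
#' Emulates a targeted-panel TMB from whole-genome calls: variants are first
#' restricted to the panel genes' CDS footprint, then two exclusion rules
#' remove likely drivers that a clinical panel assay would discount:
#' (a) variants matching known somatic (COSMIC-like) sites, and
#' (b) nonsense SNVs (effect `stop_gained`) anywhere in the panel, together
#' with any HIGH/MODERATE/LOW-impact variant in a tumor suppressor gene.
#' A variant hit by several rules is removed once (set semantics).
#'
#' @param consensus a `consensus_set`.
#' @param panel_footprint [interval_set()] of the panel genes' merged CDS.
#' @param config a [panel_config()].
#' @return named integer vector `c(snv=, indel=)` with attribute
#'   `exclusions`, a named vector of per-rule and total removal tallies.
#' @export
count_panel <- function(consensus, panel_footprint, config) {
  stopifnot(inherits(consensus, "consensus_set"),
            inherits(panel_footprint, "interval_set"),
            inherits(config, "panel_config"))
  v <- filter_in_footprint(consensus$variants, panel_footprint)
  if (nrow(v) == 0) {
    out <- c(snv = 0L, indel = 0L)
    attr(out, "exclusions") <- c(cosmic = 0L, nonsense = 0L, tsg = 0L,
                                 total = 0L)
    return(out)
  }
  cosmic_hit <- if (config$match_mode == "allele") {
    v$key %in% config$cosmic_keys
  } else {
    pos_keys <- unique(sub("^([^:]+:[0-9]+):.*$", "\\1", config$cosmic_keys))
    paste(v$contig, v$pos, sep = ":") %in% pos_keys
  }
  nonsense <- !is.na(v$effect) & v$effect == "stop_gained" & v$vclass == "SNV"
  tsg <- !is.na(v$gene) & v$gene %in% config$tumor_suppressor_genes &
    !is.na(v$impact) & v$impact %in% c("HIGH", "MODERATE", "LOW")
  removed <- cosmic_hit | nonsense | tsg
  out <- tally_classes(v[!removed, , drop = FALSE])
  attr(out, "exclusions") <- c(cosmic = sum(cosmic_hit),
                               nonsense = sum(nonsense),
                               tsg = sum(tsg),
                               total = sum(removed))
  out
}

#' Convert a variant count into a per-megabase TMB value
#'
#' @param count non-negative variant count.
#' @param denominator_bases interrogated bases (> 0).
#' @return `count / (denominator_bases / 1e6)`, unrounded. Reports format it
#'   to 4 decimal places (round half to even); classification always uses
#'   the unrounded value.
#' @examples
#' compute_tmb(38014, 2667837836) # 14.249 / Mb
#' @export
compute_tmb <- function(count, denominator_bases) {
  if (any(denominator_bases <= 0)) {
    stop("TMB denominator must be positive")
  }
  if (any(count < 0)) stop("negative variant count")
  count / (denominator_bases / 1e6)
}

#' Classify a TMB value against the clinical threshold
#'
#' The immunotherapy-eligibility convention is high when TMB is at or above
#' 10 mutations/Mb, low below; the boundary value itself is high.
#'
#' @param tmb non-negative per-Mb value(s).
#' @param threshold per-Mb threshold, default 10.
#' @return character vector of `"high"` / `"low"`.
#' @export
classify_threshold <- function(tmb, threshold = 10) {
  if (threshold < 0) stop("negative threshold")
  if (any(tmb < 0)) stop("negative TMB")
  ifelse(tmb >= threshold, "high", "low")
}
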