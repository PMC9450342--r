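#' Normalize a variant to its canonical representation
#'
#' Somatic callers emit the same allele in different but equivalent VCF
#' representations (padded, right-shifted through repeats, redundantly
#' anchored). Cross-caller intersection by exact key is only well defined
#' after each record is reduced to one canonical form. The algorithm is the
#' standard left-align-and-trim procedure:
#'
#' 1. while REF and ALT end in the same base, drop it; whenever either
#'    allele becomes empty, prepend the reference base to the left of the
#'    current position to both alleles and move the position left;
#' 2. then drop any shared leading bases while both alleles are longer than
#'    one (the mandatory indel anchor base is retained).
#'
#' The result is unique: it cannot be shifted one base left and remain the
#' same allele, and shares no trimmable prefix or suffix. Applying the
#' function to its own output is the identity.
#'
#' @param contig canonical contig name.
#' @param pos 1-based position of the first REF base.
#' @param ref,alt allele strings over A,C,G,T (case-insensitive).
#' @param reference a `genome_ref`; REF must match the reference sequence.
#' @return list with `contig`, `pos`, `ref`, `alt`, `vclass` (one of SNV,
#'   INS, DEL, MNV).
#' @examples
#' \dontrun{
#' normalize_variant("1", 100, "AAC", "AC", ref)  # -> pos 100 AA>A, DEL
#' }
#' @export
normalize_variant <- function(contig, pos, ref, alt, reference) {
  stopifnot(inherits(reference, "genome_ref"))
  contig <- normalize_contig(contig)
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (!contig %in% reference$contig_names) {
    stop("contig not in reference: ", contig)
  }
  if (!grepl("^[ACGTN]+$", ref) || !grepl("^[ACGTN]+$", alt)) {
    stop(sprintf("non-sequence allele at %s:%d (%s>%s); symbolic alleles must be filtered upstream",
                 contig, pos, ref, alt))
  }
  if (ref == alt) {
    stop(sprintf("degenerate variant at %s:%d: REF equals ALT (%s)",
                 contig, pos, ref))
  }
  observed <- ref_bases(reference, contig, pos, pos + nchar(ref) - 1L)
  if (observed != ref) {
    stop(sprintf("REF mismatch at %s:%d: expected %s from reference, got %s",
                 contig, pos, observed, ref))
  }
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # suffix trimming with left extension (left-aligns through repeat context)
  repeat {
    changed <- FALSE
    if (length(r) > 0 && length(a) > 0 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
      changed <- TRUE
    }
    if (length(r) == 0 || length(a) == 0) {
      if (pos == 1L) {
        # at the contig edge there is no base to anchor on; re-grow from the
        # right instead (VCF convention for telomeric indels)
        nxt <- pos + max(length(r), length(a))
        b <- ref_bases(reference, contig, nxt, nxt)
        r <- c(r, b)
        a <- c(a, b)
        break
      }
      b <- ref_bases(reference, contig, pos - 1L, pos - 1L)
      r <- c(b, r)
      a <- c(b, a)
      pos <- pos - 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  # prefix trimming, keeping the mandatory anchor base
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  ref <- paste(r, collapse = "")
  alt <- paste(a, collapse = "")
  list(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
       vclass = classify_variant_type(ref, alt))
}

#' Classify a normalized allele pair
#'
#' SNV if both alleles are single bases; INS if the alternate is longer;
#' DEL if the reference is longer; MNV for equal lengths above one.
#'
#' @param ref,alt trimmed, normalized allele strings.
#' @return one of `"SNV"`, `"INS"`, `"DEL"`, `"MNV"`.
#' @export
classify_variant_type <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  if (any(ref == alt)) stop("REF equals ALT")
  out <- character(length(ref))
  out[lr == 1 & la == 1] <- "SNV"
  out[la > lr] <- "INS"
  out[lr > la] <- "DEL"
  out[lr == la & lr > 1] <- "MNV"
  out
}

# Decompose an MNV into its constituent SNVs (positions where REF and ALT
# differ). Returns a data.frame of contig/pos/ref/alt rows.
decompose_mnv <- function(contig, pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  stopifnot(length(r) == length(a))
  i <- which(r != a)
  data.frame(contig = rep(unname(contig), length(i)),
             pos = unname(pos) + i - 1L,
             ref = unname(r[i]), alt = unname(a[i]),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Canonical string key for a normalized variant.
variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}
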