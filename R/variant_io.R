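KNOWN_CALLERS <- c("strelka2", "mutect2", "manta")

# symbolic / non-sequence ALT alleles (<DEL>, breakends, spanning deletions)
is_symbolic_alt <- function(alt) {
  grepl("<", alt, fixed = TRUE) | grepl("[", alt, fixed = TRUE) |
    grepl("]", alt, fixed = TRUE) | alt %in% c("*", ".")
}

#' Read and normalize one caller's somatic VCF
#'
#' Reads a VCF 4.x file (plain or gzipped), keeps records whose FILTER is
#' `PASS` or `.`, splits multi-allelic records into one candidate per ALT,
#' drops symbolic alleles (`<DEL>`, breakends, `*`) from small-variant
#' counting (they are tallied separately), normalizes every candidate with
#' [normalize_variant()], and attaches the gene/impact/effect of the first
#' SnpEff-style `ANN` annotation when present. Multi-nucleotide
#' substitutions are decomposed into their constituent SNVs by default so
#' that callers differing in MNV emission still intersect.
#'
#' @param path VCF file path.
#' @param caller one of `"strelka2"`, `"mutect2"`, `"manta"`.
#' @param reference a `genome_ref`.
#' @param decompose_mnvs decompose multi-nucleotide substitutions into SNVs
#'   (default TRUE). When FALSE, MNVs keep vclass `"MNV"`.
#' @param aliases optional contig alias table.
#' @return a `caller_variant_set`: list with `caller`, `variants`
#'   (data.frame: contig, pos, ref, alt, vclass, gene, impact, effect, key),
#'   `source_path` and tallies `n_records_read`, `n_records_pass`,
#'   `n_after_normalization`, `n_symbolic`.
#' @export
read_caller_vcf <- function(path, caller, reference,
                            decompose_mnvs = TRUE, aliases = NULL) {
  caller <- match.arg(caller, KNOWN_CALLERS)
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF ", path, ": ",
                             conditionMessage(e))
  )
  fix <- vcfR::getFIX(vcf)
  info <- if (nrow(vcf@fix) > 0) vcf@fix[, "INFO"] else character()
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1,
                                        dimnames = list(NULL, names(fix)))
  n_read <- if (is.null(fix)) 0L else nrow(fix)

  rows <- list()
  n_pass <- 0L
  n_symbolic <- 0L
  if (n_read > 0) {
    filt <- fix[, "FILTER"]
    pass <- is.na(filt) | filt %in% c("PASS", ".")
    n_pass <- sum(pass)
    for (i in which(pass)) {
      contig <- normalize_contig(fix[i, "CHROM"], aliases)
      if (!contig %in% reference$contig_names) {
        stop("VCF record ", i, " in ", path,
             ": contig not in reference: ", fix[i, "CHROM"])
      }
      pos <- as.integer(fix[i, "POS"])
      ref <- fix[i, "REF"]
      ann <- parse_impact_annotation(info[i])
      for (alt in strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]) {
        if (is_symbolic_alt(alt)) {
          n_symbolic <- n_symbolic + 1L
          next
        }
        nv <- normalize_variant(contig, pos, ref, alt, reference)
        if (nv$vclass == "MNV" && decompose_mnvs) {
          dec <- decompose_mnv(nv$contig, nv$pos, nv$ref, nv$alt)
          for (j in seq_len(nrow(dec))) {
            rows[[length(rows) + 1L]] <- data.frame(
              contig = dec$contig[j], pos = dec$pos[j],
              ref = dec$ref[j], alt = dec$alt[j], vclass = "SNV",
              gene = ann$gene, impact = ann$impact, effect = ann$effect,
              stringsAsFactors = FALSE)
          }
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            contig = nv$contig, pos = nv$pos, ref = nv$ref, alt = nv$alt,
            vclass = nv$vclass,
            gene = ann$gene, impact = ann$impact, effect = ann$effect,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), vclass = character(), gene = character(),
               impact = character(), effect = character(),
               stringsAsFactors = FALSE)
  if (nrow(variants) > 0) {
    variants$key <- variant_key(variants$contig, variants$pos,
                                variants$ref, variants$alt)
    variants <- variants[!duplicated(variants$key), , drop = FALSE]
    variants <- variants[order(contig_rank(variants$contig), variants$pos,
                               variants$ref, variants$alt), , drop = FALSE]
    rownames(variants) <- NULL
  } else {
    variants$key <- character()
  }
  structure(
    list(caller = caller, variants = variants, source_path = path,
         n_records_read = n_read, n_records_pass = n_pass,
         n_after_normalization = nrow(variants), n_symbolic = n_symbolic),
    class = "caller_variant_set"
  )
}

#' @export
print.caller_variant_set <- function(x, ...) {
  cat(sprintf("caller_variant_set [%s]: %d read, %d PASS, %d normalized, %d symbolic\n",
              x$caller, x$n_records_read, x$n_records_pass,
              x$n_after_normalization, x$n_symbolic))
  invisible(x)
}

#' Extract gene, impact and effect from a SnpEff-style ANN field
#'
#' SnpEff writes `ANN=Allele|Effect|Impact|Gene|...`, one comma-separated
#' entry per affected transcript, ordered most deleterious first. The first
#' entry's gene, impact and effect are returned; a missing ANN yields NA
#' fields, and a malformed entry yields NA fields with a warning (the record
#' itself is retained by callers of this function).
#'
#' @param info a raw VCF INFO string (or NA).
#' @return list with `gene`, `impact`, `effect` (each a length-1 character,
#'   possibly NA).
#' @export
parse_impact_annotation <- function(info) {
  empty <- list(gene = NA_character_, impact = NA_character_,
                effect = NA_character_)
  if (length(info) == 0 || is.na(info) || !grepl("(^|;)ANN=", info)) {
    return(empty)
  }
  m <- regmatches(info, regexpr("(^|;)ANN=[^;]*", info))
  ann <- sub("^;?ANN=", "", m)
  first <- strsplit(ann, ",", fixed = TRUE)[[1]][1]
  f <- strsplit(first, "|", fixed = TRUE)[[1]]
  if (length(f) < 4 || !f[3] %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")) {
    warning("malformed ANN entry: ", first)
    return(empty)
  }
  list(gene = if (nzchar(f[4])) f[4] else NA_character_,
       impact = f[3],
       effect = if (nzchar(f[2])) f[2] else NA_character_)
}

#' Write a consensus variant set as VCF
#'
#' Emits a minimal, deterministic VCF 4.2: fixed header (no timestamps),
#' contig lines in canonical order, and a `CALLERS` INFO tag listing the
#' supporting callers in the fixed order strelka2, mutect2, manta. Identical
#' input always produces byte-identical output.
#'
#' @param consensus a `consensus_set` from [intersect_callers()].
#' @param path output path.
#' @param reference optional `genome_ref` used to emit contig header lines.
#' @return the path, invisibly.
#' @export
write_consensus_vcf <- function(consensus, path, reference = NULL) {
  stopifnot(inherits(consensus, "consensus_set"))
  v <- consensus$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tmbcount",
    sprintf("##consensusPolicy=%s", consensus$policy),
    "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Callers supporting this variant\">"
  )
  if (!is.null(reference)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                reference$contig_names,
                                unname(reference$contig_lengths)))
  }
  header <- c(header,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(v) == 0) character() else {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tCALLERS=%s",
            v$contig, v$pos, v$ref, v$alt, v$callers)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
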