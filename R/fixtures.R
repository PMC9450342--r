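# Synthetic, seeded, ground-truthed fixtures: a toy genome, CDS annotation,
# three caller VCFs with controlled sensitivity / filter / representation
# noise, panel and tumor-suppressor gene lists, and a known-somatic site
# file. The expected consensus, subset counts, exclusion tallies and TMB
# values are enumerated here BY CONSTRUCTION (character masks and membership
# bookkeeping), independently of the interval/overlap machinery the pipeline
# itself uses, so a fixture is an end-to-end oracle.

#' Specify a synthetic fixture
#'
#' All randomness is driven by `seed`; each fixture component (reference,
#' annotation, truth variants, caller membership, representation jitter,
#' panel inputs) consumes its own derived random stream, so changing one
#' spec field perturbs only its component. The same spec always produces
#' byte-identical files.
#'
#' @param seed integer master seed.
#' @param n_contigs number of toy contigs (named "1", "2", ...; at most 22).
#' @param contig_length bases per contig.
#' @param n_run_fraction fraction of each contig set to N, in contiguous
#'   runs; the alignable base count is exact by construction.
#' @param n_genes,transcripts_per_gene,cds_per_transcript annotation shape;
#'   transcripts of one gene overlap so CDS merging is exercised.
#' @param n_truth_snvs,n_truth_indels number of somatic truth variants.
#' @param caller_sensitivity named probabilities (strelka2, mutect2, manta)
#'   that a truth variant is emitted by that caller; manta emits indels only.
#' @param fraction_noncanonical probability an emitted record uses a
#'   non-canonical equivalent representation (padded, anchor-extended, or
#'   right-shifted through a homopolymer).
#' @param fraction_nonpass probability an emitted record carries a non-PASS
#'   filter (and therefore does not count as caller membership).
#' @param fraction_cosmic fraction of truth variants copied into the
#'   known-somatic site file.
#' @param fraction_tsg_nonsense fraction of coding truth SNVs forced to
#'   stop_gained / HIGH before remaining impacts are sampled.
#' @param impact_distribution sampling weights over HIGH, MODERATE, LOW,
#'   MODIFIER for coding variants.
#' @return a `fixture_spec` object (validated list).
#' @export
fixture_spec <- function(seed = 1,
                         n_contigs = 2,
                         contig_length = 20000,
                         n_run_fraction = 0.05,
                         n_genes = 6,
                         transcripts_per_gene = 2,
                         cds_per_transcript = 3,
                         n_truth_snvs = 60,
                         n_truth_indels = 20,
                         caller_sensitivity = c(strelka2 = 0.90,
                                                mutect2 = 0.85,
                                                manta = 0.40),
                         fraction_noncanonical = 0.30,
                         fraction_nonpass = 0.10,
                         fraction_cosmic = 0.20,
                         fraction_tsg_nonsense = 0.15,
                         impact_distribution = c(HIGH = 0.15,
                                                 MODERATE = 0.35,
                                                 LOW = 0.30,
                                                 MODIFIER = 0.20)) {
  probs <- c(caller_sensitivity, fraction_noncanonical, fraction_nonpass,
             fraction_cosmic, fraction_tsg_nonsense, n_run_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities and fractions must lie in [0, 1]")
  }
  stopifnot(all(c("strelka2", "mutect2", "manta") %in%
                  names(caller_sensitivity)),
            setequal(names(impact_distribution), IMPACT_LEVELS),
            abs(sum(impact_distribution) - 1) < 1e-8,
            n_contigs >= 1, n_contigs <= 22,
            n_genes >= 1, transcripts_per_gene >= 1, cds_per_transcript >= 1)
  spec <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
               contig_length = as.integer(contig_length),
               n_run_fraction = n_run_fraction,
               n_genes = as.integer(n_genes),
               transcripts_per_gene = as.integer(transcripts_per_gene),
               cds_per_transcript = as.integer(cds_per_transcript),
               n_truth_snvs = as.integer(n_truth_snvs),
               n_truth_indels = as.integer(n_truth_indels),
               caller_sensitivity = caller_sensitivity,
               fraction_noncanonical = fraction_noncanonical,
               fraction_nonpass = fraction_nonpass,
               fraction_cosmic = fraction_cosmic,
               fraction_tsg_nonsense = fraction_tsg_nonsense,
               impact_distribution = impact_distribution[IMPACT_LEVELS])
  # rough capacity check: gene windows + variant spacing must fit
  genes_per_contig <- ceiling(spec$n_genes / spec$n_contigs)
  need <- 200 + genes_per_contig * (spec$cds_per_transcript * 150 + 400) +
    ceiling((spec$n_truth_snvs + spec$n_truth_indels) / spec$n_contigs) * 12
  if (spec$contig_length * (1 - spec$n_run_fraction) < need) {
    stop("contig_length too small for the requested features (need about ",
         need, " non-N bases per contig)")
  }
  structure(spec, class = "fixture_spec")
}

# derived per-component seeds; master seeds are small ints, keep < 2^31
component_seed <- function(seed, k) {
  (abs(seed) %% 1048576L) * 1024L + k
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Generate the toy reference genome
#'
#' Random A/C/G/T contigs with (i) an exact, construction-known number of N
#' bases placed in contiguous runs, (ii) implanted homopolymer runs so indel
#' left-alignment is exercised, and (iii) a soft-masked (lowercase) segment
#' per contig written to the FASTA to exercise the case-insensitive
#' alignable-base rule.
#'
#' @param spec a [fixture_spec()].
#' @return list with `contig_names`, `seqs` (per-contig character vectors,
#'   uppercase), `is_n` (per-contig logical masks), `alignable_by_contig`,
#'   `homopolymers` (data.frame contig/start/end/base of implanted runs),
#'   `soft_ranges` (written lowercase; display only).
#' @export
make_reference <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(component_seed(spec$seed, 1L), {
    len <- spec$contig_length
    contigs <- as.character(seq_len(spec$n_contigs))
    seqs <- list()
    is_n <- list()
    hp <- list()
    soft <- list()
    for (cn in contigs) {
      s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      # exact N budget, in runs of <= 150
      n_total <- round(spec$n_run_fraction * len)
      mask <- rep(FALSE, len)
      remaining <- n_total
      guard <- 0L
      while (remaining > 0) {
        L <- min(150L, remaining)
        start <- sample.int(len - L - 120L, 1) + 60L
        if (any(mask[max(1, start - 10):min(len, start + L + 9)])) {
          guard <- guard + 1L
          if (guard > 10000L) stop("could not place N runs; contig too small")
          next
        }
        mask[start:(start + L - 1L)] <- TRUE
        remaining <- remaining - L
      }
      s[mask] <- "N"
      # implanted homopolymer runs every ~800 bases (skip any near N)
      runs <- list()
      for (start in seq(400L, len - 60L, by = 800L)) {
        L <- sample(8:12, 1)
        b <- sample(c("A", "C", "G", "T"), 1)
        if (any(mask[(start - 5L):(start + L + 5L)])) next
        s[start:(start + L - 1L)] <- b
        # the base before the run must differ so the run start is unambiguous
        s[start - 1L] <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
        # and the base after, so the run does not silently extend
        s[start + L] <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
        runs[[length(runs) + 1L]] <- data.frame(
          contig = cn, start = start, end = start + L - 1L, base = b,
          stringsAsFactors = FALSE)
      }
      seqs[[cn]] <- s
      is_n[[cn]] <- mask
      hp[[cn]] <- if (length(runs)) do.call(rbind, runs) else NULL
      # one soft-masked display segment clear of N
      repeat {
        st <- sample.int(len - 260L, 1) + 30L
        if (!any(mask[st:(st + 199L)])) break
      }
      soft[[cn]] <- c(start = st, end = st + 199L)
    }
    hp_all <- do.call(rbind, hp[!vapply(hp, is.null, logical(1))])
    list(contig_names = contigs, seqs = seqs, is_n = is_n,
         alignable_by_contig = stats::setNames(
           vapply(is_n, function(m) length(m) - sum(m), numeric(1)),
           contigs),
         homopolymers = hp_all, soft_ranges = soft)
  })
}

#' Write the fixture reference as FASTA
#'
#' @param ref result of [make_reference()].
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  lines <- character()
  for (cn in ref$contig_names) {
    s <- ref$seqs[[cn]]
    sr <- ref$soft_ranges[[cn]]
    s[sr["start"]:sr["end"]] <- tolower(s[sr["start"]:sr["end"]])
    seq_str <- paste(s, collapse = "")
    lines <- c(lines, paste0(">", cn),
               substring(seq_str, seq(1, nchar(seq_str), 60),
                         pmin(seq(60, nchar(seq_str) + 59, 60),
                              nchar(seq_str))))
  }
  write_text(lines, path)
  invisible(path)
}

#' Generate the toy gene annotation
#'
#' Lays out non-overlapping gene windows in N-free sequence; each gene gets
#' overlapping transcripts whose CDS blocks shift against each other, so the
#' merged CDS union is strictly smaller than the transcript-summed total.
#' The merged totals (overall and per gene) are computed from a brute-force
#' per-base coverage mask, independent of the package's interval machinery.
#'
#' @param spec a [fixture_spec()].
#' @param ref result of [make_reference()].
#' @return list with `cds` (data.frame contig/start/end/gene/transcript,
#'   1-based inclusive), `genes`, `cds_mask` (per-contig logical),
#'   `merged_total`, `merged_by_gene`, `transcript_summed_total`.
#' @export
make_annotation <- function(spec, ref) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(component_seed(spec$seed, 2L), {
    len <- spec$contig_length
    window_w <- spec$cds_per_transcript * 150L + 120L
    genes <- paste0("GENE", seq_len(spec$n_genes))
    gene_contig <- ref$contig_names[
      1L + (seq_len(spec$n_genes) - 1L) %% spec$n_contigs]
    rows <- list()
    next_free <- stats::setNames(rep(150L, spec$n_contigs), ref$contig_names)
    for (gi in seq_len(spec$n_genes)) {
      cn <- gene_contig[gi]
      mask <- ref$is_n[[cn]]
      w <- next_free[[cn]]
      repeat {
        if (w + window_w > len - 150L) {
          stop("contig ", cn, " too small to place gene ", genes[gi])
        }
        if (!any(mask[w:(w + window_w)])) break
        w <- w + 50L
      }
      for (t in seq_len(spec$transcripts_per_gene)) {
        shift <- (t - 1L) * sample(15:25, 1)
        for (j in seq_len(spec$cds_per_transcript)) {
          bstart <- w + shift + (j - 1L) * 150L
          blen <- sample(40:90, 1)
          rows[[length(rows) + 1L]] <- data.frame(
            contig = cn, start = bstart, end = bstart + blen - 1L,
            gene = genes[gi], transcript = paste0("G", gi, ".", t),
            stringsAsFactors = FALSE)
        }
      }
      next_free[[cn]] <- w + window_w + 300L
    }
    cds <- do.call(rbind, rows)
    # brute-force coverage masks
    cds_mask <- lapply(ref$contig_names, function(cn) rep(FALSE, len))
    names(cds_mask) <- ref$contig_names
    gene_mask <- lapply(genes, function(g) {
      m <- lapply(ref$contig_names, function(cn) rep(FALSE, len))
      names(m) <- ref$contig_names
      m
    })
    names(gene_mask) <- genes
    for (i in seq_len(nrow(cds))) {
      idx <- cds$start[i]:cds$end[i]
      cds_mask[[cds$contig[i]]][idx] <- TRUE
      gene_mask[[cds$gene[i]]][[cds$contig[i]]][idx] <- TRUE
    }
    merged_by_gene <- vapply(gene_mask, function(m) sum(vapply(m, sum,
                                                               numeric(1))),
                             numeric(1))
    list(cds = cds, genes = genes, cds_mask = cds_mask,
         gene_mask = gene_mask,
         merged_total = sum(vapply(cds_mask, sum, numeric(1))),
         merged_by_gene = merged_by_gene,
         transcript_summed_total = sum(cds$end - cds$start + 1))
  })
}

#' Write the fixture annotation as GTF
#'
#' @param ann result of [make_annotation()].
#' @param path output GTF path.
#' @return the path, invisibly.
#' @export
write_gtf <- function(ann, path) {
  cds <- ann$cds
  gid <- sub("\\..*$", "", cds$transcript)
  lines <- sprintf(
    "%s\tfixture\tCDS\t%d\t%d\t.\t+\t0\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
    cds$contig, cds$start, cds$end, gid, cds$transcript, cds$gene)
  write_text(c("##provider: fixture", lines), path)
  invisible(path)
}
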