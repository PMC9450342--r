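# Truth-variant placement and caller VCF emission for synthetic fixtures.
# Every constructed variant is canonical BY CONSTRUCTION (left-aligned,
# trimmed: the construction rules make each form a fixed point of the
# normalization algorithm), so the expected consensus keys are known without
# running the pipeline.

ACGT <- c("A", "C", "G", "T")

# effect vocabulary per (vclass, impact) for coding variants
effect_for <- function(vclass, impact) {
  if (vclass == "SNV") {
    switch(impact, HIGH = "splice_acceptor_variant",
           MODERATE = "missense_variant", LOW = "synonymous_variant",
           MODIFIER = "intron_variant")
  } else {
    switch(impact, HIGH = "frameshift_variant",
           MODERATE = if (vclass == "INS") "inframe_insertion" else
             "inframe_deletion",
           LOW = "splice_region_variant", MODIFIER = "intron_variant")
  }
}

#' Place ground-truth somatic variants on the fixture genome
#'
#' Positions are sampled on non-N bases with a 12-base minimum spacing
#' (unique normalized keys by construction) and a non-N margin wide enough
#' for representation jitter. About half of SNVs and indels land in CDS.
#' Indels are constructed directly in canonical (left-aligned, trimmed)
#' form; a few insertions duplicate a base of an implanted homopolymer run,
#' whose right-shifted equivalent representation exercises left-alignment.
#' Impact/effect annotations are assigned here and are the protein-subset
#' and panel-exclusion ground truth.
#'
#' @param spec a [fixture_spec()].
#' @param ref result of [make_reference()].
#' @param ann result of [make_annotation()].
#' @return data.frame, one truth variant per row: contig, pos, ref, alt,
#'   vclass, span_end, in_cds, gene, impact, effect, annotated, hp_end, key.
#' @export
make_truth_variants <- function(spec, ref, ann) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(component_seed(spec$seed, 3L), {
    len <- spec$contig_length
    taken <- lapply(ref$contig_names, function(cn) integer())
    names(taken) <- ref$contig_names

    ok_window <- function(cn, pos, span_end) {
      if (pos < 4L || span_end + 3L > len) return(FALSE)
      if (any(ref$is_n[[cn]][(pos - 3L):(span_end + 3L)])) return(FALSE)
      all(abs(taken[[cn]] - pos) >= 12L)
    }
    claim <- function(cn, pos) taken[[cn]] <<- c(taken[[cn]], pos)

    draw_pos <- function(want_cds, span = 0L) {
      # sample a contig, then an anchor; rejection-sample until valid
      for (i in 1:20000) {
        cn <- sample(ref$contig_names, 1)
        cand <- if (want_cds) which(ann$cds_mask[[cn]]) else
          which(!ann$cds_mask[[cn]] & !ref$is_n[[cn]])
        pos <- cand[sample.int(length(cand), 1)]
        if (!ok_window(cn, pos, pos + span)) next
        if (!want_cds && span > 0L &&
            any(ann$cds_mask[[cn]][pos:(pos + span)])) next
        return(list(contig = cn, pos = pos))
      }
      stop("could not place a truth variant; fixture too dense")
    }

    rows <- list()
    add_row <- function(contig, pos, refa, alta, vclass, span_end, hp_end) {
      claim(contig, pos)
      rows[[length(rows) + 1L]] <<- data.frame(
        contig = contig, pos = pos, ref = refa, alt = alta, vclass = vclass,
        span_end = span_end, hp_end = hp_end, stringsAsFactors = FALSE)
    }

    # SNVs, roughly half in CDS
    n_cds_snv <- spec$n_truth_snvs %/% 2L
    for (i in seq_len(spec$n_truth_snvs)) {
      at <- draw_pos(want_cds = i <= n_cds_snv)
      b <- ref$seqs[[at$contig]][at$pos]
      add_row(at$contig, at$pos, b, sample(setdiff(ACGT, b), 1), "SNV",
              at$pos, NA_integer_)
    }

    # homopolymer-duplication insertions (canonical anchor before the run)
    n_hp <- min(3L, spec$n_truth_indels)
    hp_used <- 0L
    if (!is.null(ref$homopolymers)) {
      for (r in seq_len(nrow(ref$homopolymers))) {
        if (hp_used >= n_hp) break
        h <- ref$homopolymers[r, ]
        a <- h$start - 1L
        if (!ok_window(h$contig, a, a)) next
        anchor <- ref$seqs[[h$contig]][a]
        add_row(h$contig, a, anchor, paste0(anchor, h$base), "INS", a,
                h$end)
        hp_used <- hp_used + 1L
      }
    }

    # remaining indels, roughly half in CDS
    n_rest <- spec$n_truth_indels - hp_used
    n_cds_ind <- n_rest %/% 2L
    for (i in seq_len(n_rest)) {
      want_cds <- i <= n_cds_ind
      repeat {
        L <- sample(1:5, 1)
        is_del <- stats::runif(1) < 0.5
        at <- draw_pos(want_cds, span = if (is_del) L else 0L)
        s <- ref$seqs[[at$contig]]
        if (is_del) {
          # canonical deletion: last deleted base differs from the anchor
          if (s[at$pos + L] == s[at$pos]) next
          add_row(at$contig, at$pos,
                  paste(s[at$pos:(at$pos + L)], collapse = ""),
                  s[at$pos], "DEL", at$pos + L, NA_integer_)
        } else {
          ins <- sample(ACGT, L, replace = TRUE)
          # canonical insertion: last inserted base differs from the anchor
          if (ins[L] == s[at$pos]) ins[L] <- sample(setdiff(ACGT, s[at$pos]), 1)
          add_row(at$contig, at$pos, s[at$pos],
                  paste(c(s[at$pos], ins), collapse = ""), "INS", at$pos,
                  NA_integer_)
        }
        break
      }
    }

    truth <- do.call(rbind, rows)
    truth$key <- variant_key(truth$contig, truth$pos, truth$ref, truth$alt)

    # span overlap with CDS / gene assignment (brute-force masks)
    truth$in_cds <- vapply(seq_len(nrow(truth)), function(i) {
      any(ann$cds_mask[[truth$contig[i]]][truth$pos[i]:truth$span_end[i]])
    }, logical(1))
    truth$gene <- vapply(seq_len(nrow(truth)), function(i) {
      span <- truth$pos[i]:truth$span_end[i]
      for (g in ann$genes) {
        if (any(ann$gene_mask[[g]][[truth$contig[i]]][span])) return(g)
      }
      NA_character_
    }, character(1))

    # impact / effect assignment
    truth$impact <- NA_character_
    truth$effect <- NA_character_
    truth$annotated <- FALSE
    for (i in seq_len(nrow(truth))) {
      if (truth$in_cds[i]) {
        truth$annotated[i] <- TRUE
        if (truth$vclass[i] == "SNV" &&
            stats::runif(1) < spec$fraction_tsg_nonsense) {
          truth$impact[i] <- "HIGH"
          truth$effect[i] <- "stop_gained"
        } else {
          imp <- sample(names(spec$impact_distribution), 1,
                        prob = spec$impact_distribution)
          truth$impact[i] <- imp
          truth$effect[i] <- effect_for(truth$vclass[i], imp)
        }
      } else if (stats::runif(1) < 0.85) {
        truth$annotated[i] <- TRUE
        truth$impact[i] <- "MODIFIER"
        truth$effect[i] <- "intergenic_region"
      }
    }
    truth <- truth[order(contig_rank(truth$contig), truth$pos), ,
                   drop = FALSE]
    rownames(truth) <- NULL
    truth
  })
}

# equivalent non-canonical representations (haplotype-preserving)
jitter_representation <- function(v, seqs, jtype) {
  s <- seqs[[v$contig]]
  if (!is.na(v$hp_end)) {
    # right-shifted through the homopolymer run: insert after the last base
    b <- s[v$hp_end]
    return(list(pos = v$hp_end, ref = b, alt = paste0(b, b)))
  }
  if (jtype == 3L) {                       # anchor-extend to the left
    p <- s[v$pos - 1L]
    return(list(pos = v$pos - 1L, ref = paste0(p, v$ref),
                alt = paste0(p, v$alt)))
  }
  k <- jtype                                # pad 1 or 2 reference bases
  pad <- paste(s[(v$span_end + 1L):(v$span_end + k)], collapse = "")
  list(pos = v$pos, ref = paste0(v$ref, pad), alt = paste0(v$alt, pad))
}

ann_info_field <- function(alt, effect, impact, gene, pos) {
  g <- if (is.na(gene)) "" else gene
  first <- sprintf("%s|%s|%s|%s|%s|transcript|%s.1|||||", alt, effect,
                   impact, g, g, g)
  # a deterministic subset carries a second, less deleterious entry to
  # exercise the first-entry rule
  if (pos %% 3L == 0L) {
    paste0("ANN=", first, ",",
           sprintf("%s|downstream_gene_variant|MODIFIER|%s|%s|transcript|%s.2|||||",
                   alt, g, g, g))
  } else {
    paste0("ANN=", first)
  }
}

vcf_fixture_header <- function(caller, ref) {
  c("##fileformat=VCFv4.2",
    "##fileDate=20200101",
    sprintf("##source=%s-fixture", caller),
    "##reference=ref.fa",
    sprintf("##contig=<ID=%s,length=%d>", ref$contig_names,
            vapply(ref$seqs, length, integer(1))),
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
    "##FILTER=<ID=LowEVS,Description=\"Low evidence\">",
    "##FILTER=<ID=weak_evidence,Description=\"Weak evidence\">",
    "##FILTER=<ID=MinQUAL,Description=\"Low quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

#' Emit the three per-caller fixture VCFs
#'
#' Each truth variant appears in a caller's VCF with that caller's
#' sensitivity probability (manta emits indels only, plus two symbolic SV
#' records that small-variant counting must ignore). Emitted records carry a
#' non-PASS filter with probability `fraction_nonpass` (membership then does
#' NOT count), and a non-canonical equivalent representation with
#' probability `fraction_noncanonical`. Membership draws and representation
#' draws use separate seeded streams. Mutect2 additionally emits its first
#' two canonical PASS SNVs as multi-allelic records (second ALT private to
#' mutect2) to exercise allele splitting.
#'
#' @param spec a [fixture_spec()].
#' @param ref result of [make_reference()].
#' @param truth result of [make_truth_variants()].
#' @param out_dir directory for strelka2.vcf, mutect2.vcf, manta.vcf.
#' @return list with `paths`, `membership` (truth x caller logical matrix of
#'   PASS-emission) and `consensus_keys` (expected key sets under the
#'   default, `all`, and 2-of-3 policies).
#' @export
make_caller_vcfs <- function(spec, ref, truth, out_dir) {
  n <- nrow(truth)
  callers <- c("strelka2", "mutect2", "manta")
  member <- with_seed(component_seed(spec$seed, 4L), {
    emit <- vapply(callers, function(cl)
      stats::runif(n) < spec$caller_sensitivity[[cl]], logical(n))
    nonpass <- vapply(callers, function(cl)
      stats::runif(n) < spec$fraction_nonpass, logical(n))
    if (n == 1) {
      emit <- matrix(emit, nrow = 1, dimnames = list(NULL, callers))
      nonpass <- matrix(nonpass, nrow = 1, dimnames = list(NULL, callers))
    }
    emit[, "manta"] <- emit[, "manta"] & truth$vclass %in% c("INS", "DEL")
    list(emit = emit, nonpass = nonpass)
  })
  jit <- with_seed(component_seed(spec$seed, 5L), {
    flag <- matrix(stats::runif(n * 3) < spec$fraction_noncanonical, n, 3,
                   dimnames = list(NULL, callers))
    type <- matrix(sample.int(3L, n * 3, replace = TRUE), n, 3,
                   dimnames = list(NULL, callers))
    list(flag = flag, type = type)
  })

  nonpass_label <- c(strelka2 = "LowEVS", mutect2 = "weak_evidence",
                     manta = "MinQUAL")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  multiallelic_budget <- 2L
  for (cl in callers) {
    recs <- list()
    ma_left <- if (cl == "mutect2") multiallelic_budget else 0L
    for (i in seq_len(n)) {
      if (!member$emit[i, cl]) next
      v <- truth[i, ]
      if (jit$flag[i, cl]) {
        rep_ <- jitter_representation(v, ref$seqs, jit$type[i, cl])
      } else {
        rep_ <- list(pos = v$pos, ref = v$ref, alt = v$alt)
      }
      alt_field <- rep_$alt
      if (ma_left > 0L && v$vclass == "SNV" && !jit$flag[i, cl] &&
          !member$nonpass[i, cl]) {
        extra <- setdiff(ACGT, c(v$ref, v$alt))[1]
        alt_field <- paste(rep_$alt, extra, sep = ",")
        ma_left <- ma_left - 1L
      }
      info <- if (v$annotated) {
        ann_info_field(strsplit(alt_field, ",")[[1]][1], v$effect, v$impact,
                       v$gene, v$pos)
      } else "."
      recs[[length(recs) + 1L]] <- data.frame(
        contig = v$contig, pos = rep_$pos, ref = rep_$ref, alt = alt_field,
        filter = if (member$nonpass[i, cl]) nonpass_label[[cl]] else "PASS",
        info = info, stringsAsFactors = FALSE)
    }
    if (cl == "manta") {
      # symbolic SV records: counted as symbolic tallies, never as variants
      for (sv in list(list(pos = 30L, alt = "<DEL>",
                           info = "SVTYPE=DEL;END=90"),
                      list(pos = 40L, alt = "<DUP:TANDEM>",
                           info = "SVTYPE=DUP;END=140"))) {
        recs[[length(recs) + 1L]] <- data.frame(
          contig = ref$contig_names[1], pos = sv$pos,
          ref = ref$seqs[[1]][sv$pos], alt = sv$alt, filter = "PASS",
          info = sv$info, stringsAsFactors = FALSE)
      }
    }
    body <- character()
    if (length(recs)) {
      df <- do.call(rbind, recs)
      df <- df[order(contig_rank(df$contig), df$pos, df$ref, df$alt), ,
               drop = FALSE]
      body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s", df$contig, df$pos,
                      df$ref, df$alt, df$filter, df$info)
    }
    p <- file.path(out_dir, paste0(cl, ".vcf"))
    write_text(c(vcf_fixture_header(cl, ref), body), p)
    paths[[cl]] <- p
  }

  membership <- member$emit & !member$nonpass
  colnames(membership) <- callers
  keys <- truth$key
  list(paths = paths, membership = membership,
       consensus_keys = list(
         default = keys[membership[, "strelka2"] & membership[, "mutect2"]],
         all = keys[rowSums(membership) == 3L],
         k2_of_3 = keys[rowSums(membership) >= 2L]))
}

#' Write panel, tumor-suppressor and known-somatic-site fixture inputs
#'
#' The panel is the first half of the fixture genes; the tumor-suppressor
#' list holds the last panel gene plus the first non-panel gene. The
#' known-site (COSMIC-like) VCF copies a seeded fraction of truth variants
#' (the first one in a padded, non-canonical representation, which site
#' normalization must undo) plus five novel sites matching no truth variant.
#'
#' @param spec a [fixture_spec()].
#' @param ref result of [make_reference()].
#' @param ann result of [make_annotation()].
#' @param truth result of [make_truth_variants()].
#' @param out_dir directory for panel.txt, tsg.txt, cosmic.vcf.
#' @return list with `paths`, `panel_genes`, `tsg_genes`, `cosmic_keys`
#'   (normalized keys, the exclusion ground truth), `panel_mask`.
#' @export
make_panel_inputs <- function(spec, ref, ann, truth, out_dir) {
  n_cosmic <- round(spec$fraction_cosmic * nrow(truth))
  if (n_cosmic > nrow(truth)) {
    stop("requested known-site overlap exceeds the truth set size")
  }
  panel_genes <- ann$genes[seq_len(ceiling(length(ann$genes) / 2))]
  non_panel <- setdiff(ann$genes, panel_genes)
  tsg_genes <- unique(c(panel_genes[length(panel_genes)],
                        if (length(non_panel)) non_panel[1]))
  with_seed(component_seed(spec$seed, 6L), {
    idx <- sort(sample.int(nrow(truth), n_cosmic))
    cosmic <- truth[idx, c("contig", "pos", "ref", "alt", "span_end"),
                    drop = FALSE]
    # novel sites on positions far from any truth anchor
    novel <- list()
    tries <- 0L
    while (length(novel) < 5L && tries < 20000L) {
      tries <- tries + 1L
      cn <- sample(ref$contig_names, 1)
      pos <- sample.int(spec$contig_length - 8L, 1) + 4L
      if (ref$is_n[[cn]][pos]) next
      if (any(abs(truth$pos[truth$contig == cn] - pos) < 12L)) next
      if (any(vapply(novel, function(x) x$contig == cn &&
                       abs(x$pos - pos) < 12L, logical(1)))) next
      b <- ref$seqs[[cn]][pos]
      novel[[length(novel) + 1L]] <- data.frame(
        contig = cn, pos = pos, ref = b, alt = sample(setdiff(ACGT, b), 1),
        span_end = pos, stringsAsFactors = FALSE)
    }
    novel <- do.call(rbind, novel)

    rows <- rbind(cosmic, novel)
    written <- rows
    if (nrow(written) > 0) {
      # first truth-matched site gets a padded (equivalent) representation
      pad_base <- ref$seqs[[written$contig[1]]][written$span_end[1] + 1L]
      written$ref[1] <- paste0(written$ref[1], pad_base)
      written$alt[1] <- paste0(written$alt[1], pad_base)
    }
    written <- written[order(contig_rank(written$contig), written$pos), ,
                       drop = FALSE]
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(panel = file.path(out_dir, "panel.txt"),
                  tsg = file.path(out_dir, "tsg.txt"),
                  cosmic = file.path(out_dir, "cosmic.vcf"))
    write_text(panel_genes, paths$panel)
    write_text(tsg_genes, paths$tsg)
    write_text(c("##fileformat=VCFv4.2",
                 "##fileDate=20200101",
                 "##source=known-somatic-sites-fixture",
                 sprintf("##contig=<ID=%s,length=%d>", ref$contig_names,
                         vapply(ref$seqs, length, integer(1))),
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                 sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", written$contig,
                         written$pos, written$ref, written$alt)),
               paths$cosmic)

    panel_mask <- lapply(ref$contig_names, function(cn) {
      m <- rep(FALSE, spec$contig_length)
      for (g in panel_genes) m <- m | ann$gene_mask[[g]][[cn]]
      m
    })
    names(panel_mask) <- ref$contig_names
    list(paths = paths, panel_genes = panel_genes, tsg_genes = tsg_genes,
         cosmic_keys = c(truth$key[idx],
                         variant_key(novel$contig, novel$pos, novel$ref,
                                     novel$alt)),
         panel_mask = panel_mask)
  })
}

#' Generate a complete fixture directory with enumerated ground truth
#'
#' Writes ref.fa, ann.gtf, strelka2.vcf, mutect2.vcf, manta.vcf, panel.txt,
#' tsg.txt, cosmic.vcf and ground_truth.json into `out_dir`. The ground
#' truth (consensus keys per policy, per-subset SNV/indel counts, exclusion
#' tallies, denominators, TMB values and high/low classifications) is
#' enumerated from the construction bookkeeping — per-base masks and
#' membership draws — never by running the pipeline under test.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory.
#' @return list with `spec`, `paths`, `truth`, `membership` and
#'   `ground_truth`.
#' @export
make_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- make_reference(spec)
  ann <- make_annotation(spec, ref)
  truth <- make_truth_variants(spec, ref, ann)
  paths <- list(reference = file.path(out_dir, "ref.fa"),
                gtf = file.path(out_dir, "ann.gtf"))
  write_reference_fasta(ref, paths$reference)
  write_gtf(ann, paths$gtf)
  vcfs <- make_caller_vcfs(spec, ref, truth, out_dir)
  panel <- make_panel_inputs(spec, ref, ann, truth, out_dir)
  paths <- c(paths, vcfs$paths, panel$paths)

  # ---- ground-truth enumeration (default policy consensus) ----
  in_consensus <- truth$key %in% vcfs$consensus_keys$default
  cv <- truth[in_consensus, , drop = FALSE]
  tally <- function(v) c(snv = sum(v$vclass == "SNV"),
                         indel = sum(v$vclass %in% c("INS", "DEL")))
  in_panel_fp <- vapply(seq_len(nrow(cv)), function(i) {
    any(panel$panel_mask[[cv$contig[i]]][cv$pos[i]:cv$span_end[i]])
  }, logical(1))
  pv <- cv[in_panel_fp, , drop = FALSE]
  cosmic_hit <- pv$key %in% panel$cosmic_keys
  nonsense <- !is.na(pv$effect) & pv$effect == "stop_gained" &
    pv$vclass == "SNV"
  tsg_hit <- !is.na(pv$gene) & pv$gene %in% panel$tsg_genes &
    !is.na(pv$impact) & pv$impact %in% c("HIGH", "MODERATE", "LOW")
  removed <- cosmic_hit | nonsense | tsg_hit

  counts <- list(
    genome = tally(cv),
    coding = tally(cv[cv$in_cds, , drop = FALSE]),
    protein = tally(cv[!is.na(cv$impact) &
                         cv$impact %in% c("HIGH", "MODERATE"), ,
                       drop = FALSE]),
    panel = tally(pv[!removed, , drop = FALSE]))
  denominators <- list(
    alignable_bases = sum(ref$alignable_by_contig),
    cds_bases = ann$merged_total,
    panel_cds_bases = sum(vapply(panel$panel_mask, sum, numeric(1))))
  denom_of <- c(genome = denominators$alignable_bases,
                coding = denominators$cds_bases,
                protein = denominators$cds_bases,
                panel = denominators$panel_cds_bases)
  tmb <- list()
  classification <- list()
  for (s in names(counts)) {
    for (cl in c("snv", "total")) {
      nm <- paste(s, cl, sep = "_")
      cnt <- if (cl == "snv") counts[[s]]["snv"] else sum(counts[[s]])
      tmb[[nm]] <- unname(cnt / (denom_of[[s]] / 1e6))
      classification[[nm]] <- if (tmb[[nm]] >= 10) "high" else "low"
    }
  }
  ground_truth <- list(
    seed = spec$seed,
    denominators = denominators,
    consensus_size = lapply(vcfs$consensus_keys, length),
    consensus_keys = vcfs$consensus_keys,
    counts = lapply(counts, as.list),
    exclusions = list(cosmic = sum(cosmic_hit), nonsense = sum(nonsense),
                      tsg = sum(tsg_hit), total = sum(removed)),
    tmb = tmb,
    classification = classification,
    threshold = 10)
  paths$ground_truth <- file.path(out_dir, "ground_truth.json")
  write_text(as.character(jsonlite::toJSON(ground_truth, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             paths$ground_truth)
  list(spec = spec, paths = paths, truth = truth,
       membership = vcfs$membership, ground_truth = ground_truth)
}
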