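#' Intersect normalized caller sets into a consensus variant set
#'
#' Multi-caller intersection is the error-control step of TMB estimation:
#' only variants reported by the required combination of independent callers
#' are counted. Variants are matched by exact normalized key
#' (contig, pos, ref, alt), which is well defined because every caller's
#' records were left-aligned and trimmed on the same reference.
#'
#' Membership policies:
#' \describe{
#'   \item{`"strelka2+mutect2"` (default)}{present in both strelka2 and
#'     mutect2; manta membership is recorded but not required (manta
#'     primarily contributes indel candidates and structural variants, so
#'     requiring it would empty the SNV set).}
#'   \item{`"all"`}{present in every supplied caller set.}
#'   \item{`"k-of-n:K"`}{present in at least K of the supplied sets.}
#' }
#'
#' Annotation fields (gene/impact/effect) are taken from the first caller in
#' the fixed precedence order strelka2, mutect2, manta that carries an
#' impact, so ties break deterministically.
#'
#' @param sets list of `caller_variant_set` objects (at least two, unique
#'   caller names).
#' @param policy membership rule string.
#' @return a `consensus_set`: list with `variants` (data.frame with a
#'   `callers` column, comma-joined in fixed order), `policy`, and
#'   `input_tallies`.
#' @export
intersect_callers <- function(sets, policy = "strelka2+mutect2") {
  if (length(sets) == 0) stop("no caller sets supplied")
  stopifnot(all(vapply(sets, inherits, logical(1), "caller_variant_set")))
  callers <- vapply(sets, `[[`, character(1), "caller")
  if (anyDuplicated(callers)) {
    stop("duplicate caller names: ",
         paste(callers[duplicated(callers)], collapse = ", "))
  }
  if (length(sets) < 2) stop("need at least two caller sets to intersect")
  names(sets) <- callers

  required <- parse_policy(policy, callers)

  all_keys <- unique(unlist(lapply(sets, function(s) s$variants$key),
                            use.names = FALSE))
  membership <- vapply(sets, function(s) all_keys %in% s$variants$key,
                       logical(length(all_keys)))
  if (length(all_keys) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, callers))
  keep <- if (is.numeric(required)) {
    rowSums(membership) >= required
  } else {
    rowSums(membership[, required, drop = FALSE]) == length(required)
  }
  keys <- all_keys[keep]

  precedence <- intersect(KNOWN_CALLERS, callers)
  rows <- list()
  for (key in keys) {
    base <- NULL
    annotated <- NULL
    for (cl in precedence) {
      v <- sets[[cl]]$variants
      hit <- v[v$key == key, , drop = FALSE]
      if (nrow(hit) == 1) {
        if (is.null(base)) base <- hit
        if (is.null(annotated) && !is.na(hit$impact)) annotated <- hit
      }
    }
    if (!is.null(annotated)) {
      base$gene <- annotated$gene
      base$impact <- annotated$impact
      base$effect <- annotated$effect
    }
    base$callers <- paste(
      precedence[vapply(precedence,
                        function(cl) key %in% sets[[cl]]$variants$key,
                        logical(1))],
      collapse = ",")
    rows[[length(rows) + 1L]] <- base
  }
  variants <- if (length(rows)) do.call(rbind, rows) else {
    v <- sets[[1]]$variants[0, , drop = FALSE]
    v$callers <- character()
    v
  }
  if (nrow(variants) > 0) {
    variants <- variants[order(contig_rank(variants$contig), variants$pos,
                               variants$ref, variants$alt), , drop = FALSE]
    rownames(variants) <- NULL
  }
  structure(
    list(variants = variants, policy = policy,
         input_tallies = stats::setNames(
           vapply(sets, function(s) nrow(s$variants), integer(1)), callers)),
    class = "consensus_set"
  )
}

# Resolve a policy string against the available caller names. Returns either
# a character vector of required callers or an integer k (k-of-n).
parse_policy <- function(policy, callers) {
  if (identical(policy, "all")) return(callers)
  if (grepl("^k-of-n:[0-9]+$", policy)) {
    k <- as.integer(sub("^k-of-n:", "", policy))
    if (k < 1 || k > length(callers)) {
      stop("k-of-n policy with k=", k, " but ", length(callers), " callers")
    }
    return(k)
  }
  required <- strsplit(policy, "+", fixed = TRUE)[[1]]
  unknown <- setdiff(required, KNOWN_CALLERS)
  if (length(unknown) > 0) {
    stop("unknown caller in policy: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(required, callers)
  if (length(missing) > 0) {
    stop("policy requires caller(s) not supplied: ",
         paste(missing, collapse = ", "))
  }
  required
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus_set: %d variant(s) under policy '%s' (inputs: %s)\n",
              nrow(x$variants), x$policy,
              paste(names(x$input_tallies), x$input_tallies,
                    sep = "=", collapse = ", ")))
  invisible(x)
}
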