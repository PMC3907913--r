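#' Allele-fraction artifact rule
#'
#' Variants supported by strictly less than `min_fraction` of the total reads
#' at the site are artifacts (a fraction of exactly `min_fraction` passes).
#' Sites with zero depth fail and are logged as degenerate.
#'
#' @param variants annotated variant data frame (needs `reads_variant`,
#'   `depth_total`).
#' @param min_fraction threshold fraction, default 0.20.
#' @return logical vector, `TRUE` = pass.
#' @export
vaf_rule <- function(variants, min_fraction = 0.20) {
  depth <- variants$depth_total
  vaf <- ifelse(depth > 0, variants$reads_variant / depth, NA_real_)
  degenerate <- is.na(vaf)
  if (any(degenerate))
    message(sum(degenerate), " call(s) with zero depth fail the VAF rule")
  !degenerate & vaf >= min_fraction
}

#' Strand-disequilibrium artifact rule (indels)
#'
#' An indel supported by strictly more than `min_reads` variant reads fails
#' when the minor strand carries strictly less than `min_strand_fraction` of
#' the evidence. SNVs always pass; indels at or below the read gate pass (the
#' rule is restricted to well-covered evidence); calls with unknown strand
#' counts pass and are logged (absent evidence cannot fail the test).
#'
#' @param variants annotated variant data frame.
#' @param min_reads evidence-depth gate, default 20 (strict `>`).
#' @param min_strand_fraction minor-strand fraction threshold, default 0.10.
#' @param denominator `"variant_reads"` (default): fractions over the
#'   variant-supporting reads; `"total_depth"`: over site depth.
#' @return logical vector, `TRUE` = pass.
#' @export
strand_rule <- function(variants, min_reads = 20L, min_strand_fraction = 0.10,
                        denominator = c("variant_reads", "total_depth")) {
  denominator <- match.arg(denominator)
  indel <- is_indel(variants$vtype)
  unknown <- is.na(variants$reads_fwd) | is.na(variants$reads_rev)
  if (any(indel & unknown))
    message(sum(indel & unknown),
            " indel(s) with unknown strand counts pass the strand rule by default")
  den <- switch(denominator,
                variant_reads = variants$reads_variant,
                total_depth = variants$depth_total)
  minor <- pmin(variants$reads_fwd, variants$reads_rev)
  gated <- indel & !unknown & variants$reads_variant > min_reads & den > 0
  fail <- gated & (minor / den) < min_strand_fraction
  !fail %in% TRUE
}

#' Exon-distance artifact rule (indels)
#'
#' Indels strictly more than `max_distance` bases away from the nearest exon
#' are artifacts. SNVs always pass this rule; deep-intronic SNVs are instead
#' removed at the prioritization stage.
#'
#' @param variants annotated variant data frame (needs `exon_distance`).
#' @param max_distance intronic window, default 20 bp.
#' @return logical vector, `TRUE` = pass.
#' @export
distance_rule <- function(variants, max_distance = 20L) {
  fail <- is_indel(variants$vtype) & variants$exon_distance > max_distance
  !fail %in% TRUE
}

#' Apply the three artifact filters
#'
#' Runs the allele-fraction, strand-disequilibrium and exon-distance rules as
#' independent predicates (order-free) and partitions the input into retained
#' and removed calls. Every removed call carries the set of rules it failed.
#'
#' @param variants annotated variant data frame ([annotate_calls()]).
#' @param config a [panelsift_config()] (or `NULL` for defaults).
#' @return list with `retained`, `removed` (with a `failed_rules` column,
#'   comma-separated subset of vaf/strand/distance), and `verdicts`, a logical
#'   matrix of per-rule passes.
#' @export
apply_artifact_filters <- function(variants, config = NULL) {
  config <- as_panelsift_config(config)
  verdicts <- cbind(
    vaf = vaf_rule(variants, config$min_vaf),
    strand = strand_rule(variants, config$strand_min_reads,
                         config$strand_min_fraction,
                         config$strand_denominator),
    distance = distance_rule(variants, config$max_exon_distance))
  pass <- rowSums(!verdicts) == 0
  removed <- variants[!pass, , drop = FALSE]
  removed$failed_rules <- apply(!verdicts[!pass, , drop = FALSE], 1,
                                function(f) paste(colnames(verdicts)[f],
                                                  collapse = ","))
  retained <- variants[pass, , drop = FALSE]
  rownames(retained) <- rownames(removed) <- NULL
  list(retained = retained, removed = removed, verdicts = verdicts)
}
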