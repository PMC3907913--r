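#' Pipeline configuration
#'
#' All thresholds used by the artifact filters and the prioritization stage
#' live in one configuration object. Defaults are the values used by the
#' diagnostic strategy the package implements: variants supported by less than
#' 20% of total reads at the site are artifacts; indels carried by more than 20
#' variant reads with either strand below 10% of the variant evidence are
#' artifacts; indels more than 20 bp away from the nearest exon are artifacts;
#' a variant of unknown significance seen in five or more DNAs of the cohort
#' is masked; regions averaging below 40x coverage are flagged, with GC
#' fractions above 0.60 annotated.
#'
#' @param min_vaf minimum variant allele fraction (strictly below fails).
#' @param strand_min_reads variant-read depth gate for the strand rule; the
#'   rule only applies to indels with strictly more variant reads than this.
#' @param strand_min_fraction minimum fraction of variant reads on the minor
#'   strand (strictly below fails).
#' @param strand_denominator `"variant_reads"` (default) computes the strand
#'   fraction over variant-supporting reads; `"total_depth"` over site depth.
#' @param max_exon_distance indels further than this many bases from the
#'   nearest exon fail the distance rule; at prioritization the same window
#'   applies to all variant types.
#' @param max_cohort_dna a non-whitelisted variant seen in more than this many
#'   distinct DNAs is masked ("fewer than five DNAs" keeps counts of at most 4).
#' @param depth_threshold regions with average depth of coverage strictly
#'   below this are flagged as low coverage.
#' @param gc_threshold GC fraction strictly above this sets the GC flag on a
#'   low-coverage region.
#' @param low_coverage_stat `"adoc"` flags on the region mean depth;
#'   `"min"` on the region minimum per-base depth.
#' @return a list of class `panelsift_config`.
#' @export
#' @examples
#' cfg <- panelsift_config(min_vaf = 0.25)
#' cfg$min_vaf
panelsift_config <- function(min_vaf = 0.20,
                             strand_min_reads = 20L,
                             strand_min_fraction = 0.10,
                             strand_denominator = c("variant_reads", "total_depth"),
                             max_exon_distance = 20L,
                             max_cohort_dna = 4L,
                             depth_threshold = 40,
                             gc_threshold = 0.60,
                             low_coverage_stat = c("adoc", "min")) {
  strand_denominator <- match.arg(strand_denominator)
  low_coverage_stat <- match.arg(low_coverage_stat)
  stopifnot(min_vaf >= 0, min_vaf <= 1,
            strand_min_reads >= 0,
            strand_min_fraction >= 0, strand_min_fraction <= 1,
            max_exon_distance >= 0, max_cohort_dna >= 0,
            depth_threshold >= 0, gc_threshold >= 0, gc_threshold <= 1)
  structure(list(
    min_vaf = min_vaf,
    strand_min_reads = as.integer(strand_min_reads),
    strand_min_fraction = strand_min_fraction,
    strand_denominator = strand_denominator,
    max_exon_distance = as.integer(max_exon_distance),
    max_cohort_dna = as.integer(max_cohort_dna),
    depth_threshold = depth_threshold,
    gc_threshold = gc_threshold,
    low_coverage_stat = low_coverage_stat
  ), class = "panelsift_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path path to a YAML (or JSON, which YAML subsumes) file whose keys
#'   are arguments of [panelsift_config()].
#' @return a `panelsift_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(panelsift_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(panelsift_config, vals)
}

# internal: accept NULL (-> defaults), a panelsift_config, or a plain list
as_panelsift_config <- function(config) {
  if (is.null(config)) return(panelsift_config())
  if (inherits(config, "panelsift_config")) return(config)
  if (is.list(config)) return(do.call(panelsift_config, config))
  stop("config must be NULL, a panelsift_config, or a named list")
}

# internal: normalized variant identity used for whitelist and cohort keys
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
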