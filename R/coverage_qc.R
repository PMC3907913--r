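#' Coverage profile of one capture unit
#'
#' A capture unit is the contiguous footprint of one targeted exon plus its
#' flanks; `depths` holds one non-negative integer per base of `[start, end)`.
#'
#' @param chrom,start,end unit interval, BED-style 0-based half-open.
#' @param depths integer vector, length `end - start`.
#' @param gene,unit labels.
#' @param gc_fraction GC fraction of the unit or `NA`.
#' @return a list of class `coverage_profile`.
#' @export
coverage_profile <- function(chrom, start, end, depths, gene = NA_character_,
                             unit = NA_character_, gc_fraction = NA_real_) {
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("zero-length region: [", start, ",", end, ")")
  if (length(depths) != end - start)
    stop("depths length ", length(depths), " != region length ", end - start)
  if (any(depths < 0)) stop("negative depth")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 gene = as.character(gene), unit = as.character(unit),
                 gc_fraction = as.numeric(gc_fraction),
                 depths = as.numeric(depths)),
            class = "coverage_profile")
}

#' Average depth of coverage (aDOC) of a region
#'
#' The sum of the per-base depth of coverage across the region divided by the
#' region size in base pairs.
#'
#' @param profile a `coverage_profile`, or a bare numeric vector of per-base
#'   depths.
#' @return non-negative numeric scalar.
#' @export
#' @examples
#' compute_adoc(c(10, 20, 30))  # 20
compute_adoc <- function(profile) {
  depths <- if (inherits(profile, "coverage_profile")) profile$depths else profile
  if (length(depths) == 0) stop("zero-length region has no aDOC")
  sum(depths) / length(depths)
}

#' Per-gene average depth of coverage
#'
#' The length-weighted mean of the per-unit aDOC values of a gene, i.e. total
#' bases sequenced over the gene's total targeted length.
#'
#' @param profiles list of `coverage_profile` objects.
#' @param gene gene symbol to summarize.
#' @return numeric scalar.
#' @export
gene_adoc <- function(profiles, gene) {
  genes <- vapply(profiles, `[[`, "", "gene")
  sel <- which(genes == gene)
  if (!length(sel)) stop("no coverage profile for gene: ", gene)
  tot <- sum(vapply(profiles[sel], function(p) sum(p$depths), numeric(1)))
  len <- sum(vapply(profiles[sel], function(p) length(p$depths), numeric(1)))
  tot / len
}

reads_to_granges <- function(reads) {
  stopifnot(all(c("chrom", "start", "end") %in% names(reads)))
  if (any(reads$end <= reads$start)) stop("malformed read interval(s)")
  cc <- bed_to_1based(reads$start, reads$end)
  GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(cc$start, cc$end))
}

# internal: per-read number of aligned bases falling inside the merged design
read_target_bases <- function(reads, design) {
  gr <- reads_to_granges(reads)
  tg <- regions_to_granges(design$merged_regions)
  covered <- numeric(length(gr))
  # disjoint seqlevels (reads on chromosomes absent from the design) are a
  # legitimate all-off-target case, not a warning condition
  suppressWarnings(ov <- GenomicRanges::findOverlaps(gr, tg))
  if (length(ov)) {
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      gr[S4Vectors::queryHits(ov)], tg[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(agg))] <- as.numeric(agg)
  }
  covered
}

#' Classify reads against the capture design
#'
#' A read is `on_target` when every aligned base lies inside the merged
#' design footprint, `off_target` when none does, and `overlap_target` when
#' it straddles a region edge.
#'
#' @param reads data frame with `chrom`, `start`, `end` (0-based half-open
#'   aligned span of each read).
#' @param design a `panel_design`.
#' @return factor with levels on_target, overlap_target, off_target.
#' @export
classify_read <- function(reads, design) {
  covered <- read_target_bases(reads, design)
  len <- reads$end - reads$start
  cls <- ifelse(covered == len, "on_target",
                ifelse(covered == 0, "off_target", "overlap_target"))
  factor(cls, levels = c("on_target", "overlap_target", "off_target"))
}

#' Base-level on-target fraction
#'
#' The number of aligned bases falling inside targeted regions divided by the
#' number of bases mapped in total. Reads partially overlapping the design
#' contribute only their in-target portion (this is the base-level statistic,
#' distinct from the read-level category counts of [classify_read()]).
#'
#' @inheritParams classify_read
#' @return fraction in `[0, 1]`.
#' @export
on_target_fraction <- function(reads, design) {
  len <- sum(reads$end - reads$start)
  if (length(reads$start) == 0 || len == 0) stop("no mapped bases")
  sum(read_target_bases(reads, design)) / len
}

#' Read a per-base depth track
#'
#' @param path TSV with columns chrom, pos (1-based), depth.
#' @return data.frame(chrom, pos, depth).
#' @export
read_depth_track <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "depth") %in% names(df)))
  if (any(df$depth < 0)) stop("negative depth in track")
  df$chrom <- as.character(df$chrom)
  df
}

#' Build per-unit coverage profiles from a depth track
#'
#' Bases of a unit absent from the track count as depth 0.
#'
#' @param design a `panel_design`.
#' @param track data frame as returned by [read_depth_track()].
#' @return list of `coverage_profile`, one per capture unit.
#' @export
profiles_from_track <- function(design, track) {
  units <- design_units(design)
  lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    pos1 <- (u$start + 1L):u$end
    sel <- track$chrom == u$chrom & track$pos >= u$start + 1L & track$pos <= u$end
    depths <- numeric(length(pos1))
    if (any(sel)) depths[match(track$pos[sel], pos1)] <- track$depth[sel]
    coverage_profile(u$chrom, u$start, u$end, depths,
                     gene = u$gene, unit = u$unit, gc_fraction = u$gc_fraction)
  })
}

#' Capture units of a design
#'
#' Collapses the rows sharing a `unit` label (an exon and its flanks) into one
#' contiguous footprint interval.
#'
#' @param design a `panel_design`.
#' @return data.frame(unit, chrom, start, end, gene, gc_fraction).
#' @export
design_units <- function(design) {
  r <- design$regions
  sp <- split(seq_len(nrow(r)), r$unit)
  out <- do.call(rbind, lapply(sp, function(idx) {
    data.frame(unit = r$unit[idx[1]], chrom = r$chrom[idx[1]],
               start = min(r$start[idx]), end = max(r$end[idx]),
               gene = r$gene[idx[1]],
               gc_fraction = suppressWarnings(max(r$gc_fraction[idx], na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  out$gc_fraction[!is.finite(out$gc_fraction)] <- NA_real_
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize coverage over a panel
#'
#' Computes per-unit and per-gene aDOC, and (when read intervals are given)
#' the on/overlap/off-target read-category fractions.
#'
#' @param profiles list of `coverage_profile`.
#' @param reads optional read-interval data frame for category accounting.
#' @param design required when `reads` is given.
#' @return list of class `coverage_summary`: `adoc_by_region` (data frame:
#'   unit, chrom, start, end, gene, gc_fraction, length, adoc, min_depth),
#'   `adoc_by_gene`, and when reads are supplied `on_target_fraction` plus
#'   read-level `read_fractions` (on/overlap/off, summing to 1).
#' @export
coverage_summary <- function(profiles, reads = NULL, design = NULL) {
  byr <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(unit = p$unit, chrom = p$chrom, start = p$start, end = p$end,
               gene = p$gene, gc_fraction = p$gc_fraction,
               length = length(p$depths),
               adoc = compute_adoc(p),
               min_depth = min(p$depths),
               stringsAsFactors = FALSE)
  }))
  rownames(byr) <- NULL
  bases <- tapply(byr$adoc * byr$length, byr$gene, sum)
  lens <- tapply(byr$length, byr$gene, sum)
  byg <- data.frame(gene = names(bases), adoc = as.numeric(bases / lens),
                    length = as.numeric(lens), stringsAsFactors = FALSE)
  rownames(byg) <- NULL
  out <- list(adoc_by_region = byr, adoc_by_gene = byg,
              overall_adoc = sum(byr$adoc * byr$length) / sum(byr$length))
  if (!is.null(reads)) {
    if (is.null(design)) stop("design required for read accounting")
    cls <- classify_read(reads, design)
    tab <- table(cls) / length(cls)
    out$read_fractions <- c(on_target = unname(tab["on_target"]),
                            overlap_target = unname(tab["overlap_target"]),
                            off_target = unname(tab["off_target"]))
    out$on_target_fraction <- on_target_fraction(reads, design)
  }
  structure(out, class = "coverage_summary")
}

#' Flag poorly covered regions
#'
#' Regions averaging strictly below the depth threshold are flagged; each
#' flagged region carries a GC flag when its GC fraction strictly exceeds the
#' GC threshold (regions lacking a GC fraction get `NA`, not `FALSE`).
#'
#' @param summary a `coverage_summary`, or its `adoc_by_region` data frame.
#' @param depth_threshold flag regions with statistic `< depth_threshold`.
#' @param gc_threshold GC flag when `gc_fraction > gc_threshold`.
#' @param stat `"adoc"` (default) or `"min"` (minimum per-base depth).
#' @return data frame of flagged regions, ascending by the flag statistic,
#'   with a logical `gc_flag` column.
#' @export
flag_low_coverage <- function(summary, depth_threshold = 40,
                              gc_threshold = 0.60,
                              stat = c("adoc", "min")) {
  stat <- match.arg(stat)
  byr <- if (inherits(summary, "coverage_summary")) summary$adoc_by_region
         else summary
  val <- if (stat == "adoc") byr$adoc else byr$min_depth
  flagged <- byr[val < depth_threshold, , drop = FALSE]
  fval <- val[val < depth_threshold]
  flagged$gc_flag <- ifelse(is.na(flagged$gc_fraction), NA,
                            flagged$gc_fraction > gc_threshold)
  flagged <- flagged[order(fval), , drop = FALSE]
  rownames(flagged) <- NULL
  flagged
}

#' Write the per-region / per-gene coverage report
#'
#' @param summary a `coverage_summary`.
#' @param region_path,gene_path output TSV paths (either may be `NULL`).
#' @return invisibly, the summary.
#' @export
write_coverage_report <- function(summary, region_path = NULL, gene_path = NULL) {
  if (!is.null(region_path))
    utils::write.table(summary$adoc_by_region, region_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(gene_path))
    utils::write.table(summary$adoc_by_gene, gene_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(summary)
}
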