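#' @importFrom GenomicRanges GRanges reduce distanceToNearest countOverlaps seqnames start end width findOverlaps pintersect
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

REGION_FEATURES <- c("exon", "utr", "intronic_extension")

# The single owner of the coordinate mapping: BED intervals are 0-based
# half-open, every positional computation runs in 1-based closed space
# (VCF-style). start0/end0 -> [start0 + 1, end0].
bed_to_1based <- function(start0, end0) {
  list(start = as.integer(start0) + 1L, end = as.integer(end0))
}

#' Build a table of capture target regions
#'
#' Validates and normalizes a data frame of targeted intervals (exons plus
#' flanking intronic extensions and UTRs). Coordinates are BED-style: 0-based
#' start, exclusive end.
#'
#' @param chrom chromosome identifiers.
#' @param start,end 0-based half-open interval bounds; `start < end` required.
#' @param gene gene symbols.
#' @param feature one of `"exon"`, `"utr"`, `"intronic_extension"`.
#' @param gc_fraction per-region GC fraction in `[0, 1]`, or `NA`.
#' @param unit optional grouping label tying an exon to its flanks (one
#'   capture unit); defaults to one unit per row.
#' @return a data.frame sorted by (chrom, start) with class `target_regions`.
#' @export
target_regions <- function(chrom, start, end, gene,
                           feature = "exon", gc_fraction = NA_real_,
                           unit = NULL) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   gene = as.character(gene),
                   feature = rep_len(as.character(feature), n),
                   gc_fraction = rep_len(as.numeric(gc_fraction), n),
                   unit = if (is.null(unit)) paste0("r", seq_len(n)) else
                     rep_len(as.character(unit), n),
                   stringsAsFactors = FALSE)
  validate_regions(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("target_regions", "data.frame")
  df
}

validate_regions <- function(df) {
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("invalid region(s): start >= end at row(s) ", paste(bad, collapse = ", "))
  bad <- which(!is.na(df$gc_fraction) & (df$gc_fraction < 0 | df$gc_fraction > 1))
  if (length(bad))
    stop("gc_fraction outside [0,1] at row(s) ", paste(bad, collapse = ", "))
  bad <- which(!df$feature %in% REGION_FEATURES)
  if (length(bad))
    stop("unknown feature at row(s) ", paste(bad, collapse = ", "),
         " (expected one of ", paste(REGION_FEATURES, collapse = ", "), ")")
  invisible(df)
}

regions_to_granges <- function(df) {
  cc <- bed_to_1based(df$start, df$end)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(cc$start, cc$end))
}

#' Merge overlapping or book-ended target regions
#'
#' Collapses the capture footprint into its distinct components: overlapping
#' and touching intervals are united, so the result counts the "different
#' regions" of the design rather than the designed exons. Gene labels are
#' dropped; merged intervals are gene-agnostic.
#'
#' @param regions a `target_regions` data frame (or any data frame with
#'   `chrom`, `start`, `end` BED-style columns).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), pairwise disjoint and sorted by (chrom, start).
#' @export
#' @examples
#' r <- target_regions(c("1", "1"), c(10, 15), c(20, 30), gene = "G")
#' merge_regions(r)  # one interval [10, 30)
merge_regions <- function(regions) {
  if (nrow(regions) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  gr <- GenomicRanges::reduce(regions_to_granges(regions))  # min.gapwidth=1 merges book-ended
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a panel design from its target regions
#'
#' @param regions a `target_regions` data frame.
#' @param homopolymers optional data frame of homopolymer tracts
#'   (chrom, start, end, base), carried through by the simulator.
#' @return an object of class `panel_design` with elements `regions` and
#'   `merged_regions`.
#' @export
panel_design <- function(regions, homopolymers = NULL) {
  if (!inherits(regions, "target_regions"))
    regions <- target_regions(regions$chrom, regions$start, regions$end,
                              regions$gene,
                              feature = if ("feature" %in% names(regions))
                                regions$feature else "exon",
                              gc_fraction = if ("gc_fraction" %in% names(regions))
                                regions$gc_fraction else NA_real_,
                              unit = if ("unit" %in% names(regions))
                                regions$unit else NULL)
  structure(list(regions = regions,
                 merged_regions = merge_regions(regions),
                 homopolymers = homopolymers),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat("panel_design:", nrow(x$regions), "target regions (",
      length(unique(x$regions$gene)), "genes ),",
      nrow(x$merged_regions), "merged regions;",
      sum(x$merged_regions$end - x$merged_regions$start), "bp footprint\n")
  invisible(x)
}

#' Load a panel design from a BED file
#'
#' Reads the BED dialect used for capture designs: columns chrom, start, end,
#' name (gene symbol), score (ignored), strand (read but ignored), plus two
#' optional extra columns `feature` and `gc_fraction`. Merged regions are
#' computed on load.
#'
#' @param path path to the BED file.
#' @param dialect only `"bed"` is supported.
#' @return a `panel_design`.
#' @export
load_design <- function(path, dialect = "bed") {
  dialect <- match.arg(dialect, "bed")
  if (!file.exists(path)) stop("design file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(nf) == 0) stop("design file is empty: ", path)
  bad <- which(nf < 3)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], ": fewer than 3 columns")
  get <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, "")
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], ": non-integer coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("invalid interval at BED line ", lineno[bad[1]], ": start >= end")
  feature <- get(7)
  feature[is.na(feature) | !nzchar(feature)] <- "exon"
  gc <- suppressWarnings(as.numeric(get(8)))
  target_regions(chrom = get(1), start = start, end = end,
                 gene = get(4, default = NA_character_),
                 feature = feature, gc_fraction = gc) |>
    panel_design()
}

#' Write a panel design to a BED file
#'
#' Inverse of [load_design()]: emits the 8-column BED dialect.
#'
#' @param design a `panel_design`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  r <- design$regions
  lines <- paste(r$chrom, r$start, r$end, r$gene, 0L, ".",
                 r$feature,
                 ifelse(is.na(r$gc_fraction), ".", format(r$gc_fraction, digits = 6)),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Distance from a position to the nearest exon of the design
#'
#' Distance 0 means the position lies inside an exon; otherwise the number of
#' base steps to the nearest exon edge on the same chromosome (a position
#' immediately adjacent to an exon is at distance 1). Flanking capture
#' extensions do not count as exon. Chromosomes holding no exon (including
#' unknown chromosomes) yield `Inf`.
#'
#' @param design a `panel_design`.
#' @param chrom chromosome of each query position (recycled).
#' @param pos 1-based positions.
#' @return numeric vector of distances (0 on exon bases, `Inf` off-design
#'   chromosomes).
#' @export
#' @examples
#' d <- panel_design(target_regions("1", 100, 200, "G"))  # exon 1-based [101,200]
#' distance_to_exon(d, "1", c(95, 101, 200, 206))  # 6 0 0 6
distance_to_exon <- function(design, chrom, pos) {
  stopifnot(inherits(design, "panel_design"))
  pos <- as.integer(pos)
  if (any(pos < 1L, na.rm = TRUE)) stop("positions are 1-based; pos >= 1 required")
  chrom <- rep_len(as.character(chrom), length(pos))
  ex <- design$regions[design$regions$feature == "exon", , drop = FALSE]
  out <- rep(Inf, length(pos))
  if (nrow(ex) == 0) return(out)
  exon_gr <- regions_to_granges(ex)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  suppressWarnings({
    hit <- GenomicRanges::distanceToNearest(q, exon_gr)
    inside <- GenomicRanges::countOverlaps(q, exon_gr) > 0
  })
  qi <- S4Vectors::queryHits(hit)
  gap <- S4Vectors::mcols(hit)$distance
  # distance() reports the gap: 0 for both adjacency and overlap, so exon
  # membership must be resolved separately before adding the 1-based step
  out[qi] <- gap + 1
  out[inside] <- 0
  out
}
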