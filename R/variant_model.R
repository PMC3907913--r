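GSDIFF_COLS <- c("chrom", "pos", "ref", "alt", "depth_total",
                 "reads_variant", "reads_fwd", "reads_rev")

#' Infer variant type from the allele pair
#'
#' @param ref,alt allele strings (anchored VCF-style for indels).
#' @return character vector over {snv, ins, del, delins}.
#' @export
infer_vtype <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == 1L & na == 1L, "snv",
    ifelse(na > nr & substr(alt, 1L, nr) == ref, "ins",
      ifelse(nr > na & substr(ref, 1L, na) == alt, "del", "delins")))
}

is_indel <- function(vtype) vtype %in% c("ins", "del", "delins")

#' Validate a table of variant calls
#'
#' Enforces the call invariants record by record: positive position,
#' non-empty alleles, `reads_variant <= depth_total`, and (when both strand
#' counts are known) `reads_fwd + reads_rev == reads_variant`. Violating
#' records are rejected with a reason, not fatal.
#'
#' @param calls data frame with the gsdiff columns (plus optional
#'   `patient_id`); strand counts may be `NA` (unknown, e.g. from VCF input).
#' @return list with elements `calls` (valid rows, `vtype` column added) and
#'   `rejected` (invalid rows with a `reason` column).
#' @export
validate_calls <- function(calls) {
  calls$chrom <- as.character(calls$chrom)
  calls$ref <- toupper(as.character(calls$ref))
  calls$alt <- toupper(as.character(calls$alt))
  for (col in c("pos", "depth_total", "reads_variant", "reads_fwd", "reads_rev"))
    calls[[col]] <- as.integer(calls[[col]])
  reason <- rep(NA_character_, nrow(calls))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  reason <- flag(is.na(calls$pos) | calls$pos < 1L, "pos < 1")
  reason <- flag(!nzchar(calls$ref) | !nzchar(calls$alt) |
                   is.na(calls$ref) | is.na(calls$alt), "empty allele")
  reason <- flag(calls$ref == calls$alt, "ref == alt")
  reason <- flag(is.na(calls$depth_total) | calls$depth_total < 0L,
                 "missing depth")
  reason <- flag(is.na(calls$reads_variant) | calls$reads_variant < 0L,
                 "missing variant reads")
  reason <- flag(!is.na(calls$reads_variant) & !is.na(calls$depth_total) &
                   calls$reads_variant > calls$depth_total,
                 "reads_variant > depth_total")
  known <- !is.na(calls$reads_fwd) & !is.na(calls$reads_rev)
  reason <- flag(known & (calls$reads_fwd < 0L | calls$reads_rev < 0L),
                 "negative strand count")
  reason <- flag(known & !is.na(calls$reads_variant) &
                   calls$reads_fwd + calls$reads_rev != calls$reads_variant,
                 "reads_fwd + reads_rev != reads_variant")
  bad <- !is.na(reason)
  rejected <- calls[bad, , drop = FALSE]
  rejected$reason <- reason[bad]
  valid <- calls[!bad, , drop = FALSE]
  valid$vtype <- infer_vtype(valid$ref, valid$alt)
  rownames(valid) <- rownames(rejected) <- NULL
  list(calls = valid, rejected = rejected)
}

#' Read variant calls
#'
#' Two dialects: `gsdiff_tsv`, a difference-file style TSV with per-strand
#' variant read counts (columns chrom, pos, ref, alt, depth_total,
#' reads_variant, reads_fwd, reads_rev, optional patient_id); and `vcf`, where
#' AD-style allele depths of the first sample populate the count slots and
#' strand counts are recorded as unknown (`NA`).
#'
#' Records violating the call invariants are dropped with a message; the
#' dropped rows are attached as attribute `"rejected"`.
#'
#' @param path input file.
#' @param dialect `"gsdiff_tsv"` or `"vcf"`.
#' @param patient_id patient label to assign when the file carries none.
#' @return data frame of validated calls (a `vtype` column is added).
#' @export
read_calls <- function(path, dialect = c("gsdiff_tsv", "vcf"),
                       patient_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("calls file not found: ", path)
  raw <- switch(dialect, gsdiff_tsv = read_gsdiff(path), vcf = read_vcf_calls(path))
  if (!is.null(patient_id)) raw$patient_id <- patient_id
  if (is.null(raw$patient_id)) raw$patient_id <- NA_character_
  v <- validate_calls(raw)
  if (nrow(v$rejected))
    message(nrow(v$rejected), " record(s) rejected: ",
            paste(unique(v$rejected$reason), collapse = "; "))
  structure(v$calls, rejected = v$rejected)
}

read_gsdiff <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(GSDIFF_COLS, names(df))
  if (length(missing))
    stop("gsdiff_tsv is missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("pos", "depth_total", "reads_variant", "reads_fwd", "reads_rev")) {
    conv <- suppressWarnings(as.integer(df[[col]]))
    if (any(is.na(conv) & !is.na(df[[col]]) & nzchar(df[[col]]) & df[[col]] != "NA"))
      stop("non-integer value in column ", col)
    df[[col]] <- conv
  }
  df
}

read_vcf_calls <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    message(sum(multi), " multi-allelic VCF record(s) skipped")
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD")[, 1],
                 error = function(e) rep(NA_character_, length(alt)))
  dp <- tryCatch(suppressWarnings(
    as.integer(vcfR::extract.gt(vcf, element = "DP")[, 1])),
    error = function(e) rep(NA_integer_, length(alt)))
  ad_ref <- suppressWarnings(as.integer(sub(",.*", "", ad)))
  ad_alt <- suppressWarnings(as.integer(sub("^[^,]*,", "", sub("(,[^,]*),.*", "\\1", ad))))
  depth <- ifelse(!is.na(ad_ref) & !is.na(ad_alt), ad_ref + ad_alt, dp)
  out <- data.frame(chrom = fix[, "CHROM"],
                    pos = suppressWarnings(as.integer(fix[, "POS"])),
                    ref = fix[, "REF"], alt = alt,
                    depth_total = depth,
                    reads_variant = ad_alt,
                    reads_fwd = NA_integer_, reads_rev = NA_integer_,
                    stringsAsFactors = FALSE)
  out[!multi, , drop = FALSE]
}

#' Write calls in the gsdiff TSV dialect
#'
#' @param calls validated call data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  cols <- intersect(c("patient_id", GSDIFF_COLS), names(calls))
  utils::write.table(calls[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Left-normalize an indel against its reference context
#'
#' Shifts an anchored indel to its leftmost equivalent placement in repeat
#' context (the canonical representation; e.g. a one-base deletion inside a
#' homopolymer is anchored at the first base of the run). SNVs are returned
#' unchanged; the operation is idempotent and preserves the implied
#' haplotype.
#'
#' @param pos 1-based position of the (anchored) call.
#' @param ref,alt allele strings.
#' @param context reference sequence covering the locus.
#' @param context_start 1-based genomic position of `context[1]`.
#' @return list with `pos`, `ref`, `alt`, and `normalized` (FALSE when the
#'   context was too short and the call was returned untouched).
#' @export
left_normalize <- function(pos, ref, alt, context, context_start = 1L) {
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  out <- list(pos = as.integer(pos), ref = ref, alt = alt, normalized = TRUE)
  if (nchar(ref) == 1L && nchar(alt) == 1L) return(out)  # SNV
  off <- pos - context_start + 1L
  if (off < 1L || off + nchar(ref) - 1L > nchar(context)) {
    warning("context does not cover the call locus; normalization skipped")
    out$normalized <- FALSE
    return(out)
  }
  if (substr(context, off, off + nchar(ref) - 1L) != ref)
    stop("ref allele disagrees with the supplied context")
  r <- ref; a <- alt; p <- off
  last <- function(s) substr(s, nchar(s), nchar(s))
  repeat {
    if (nchar(r) > 0L && nchar(a) > 0L && last(r) == last(a)) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    } else if (nchar(r) == 0L || nchar(a) == 0L) {
      if (p <= 1L) {  # context exhausted on the left: re-anchor and stop
        warning("context too short to fully left-normalize; skipped")
        out$normalized <- FALSE
        return(out)
      }
      p <- p - 1L
      prev <- substr(context, p, p)
      r <- paste0(prev, r); a <- paste0(prev, a)
    } else break
  }
  while (nchar(r) > 1L && nchar(a) > 1L && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
    r <- substring(r, 2L); a <- substring(a, 2L); p <- p + 1L
  }
  list(pos = context_start + p - 1L, ref = r, alt = a, normalized = TRUE)
}

#' Read a known-pathogenic whitelist
#'
#' @param path TSV with columns chrom, pos, ref, alt, gene, and optionally
#'   cdna_label and class.
#' @return data frame with a normalized `key` column.
#' @export
read_whitelist <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
  df$chrom <- as.character(df$chrom)
  df$key <- variant_key(df$chrom, df$pos, toupper(df$ref), toupper(df$alt))
  df
}

#' Annotate variant calls against a panel design
#'
#' Adds the fields the downstream filters need: containing gene, distance to
#' the nearest exon, location class (`exonic` at distance 0, `near_splice` at
#' 1-20 bp, `deep_intronic` beyond 20 bp, `off_gene` for positions outside
#' every target region), whitelist membership, optional dbSNP id from an
#' offline snapshot, cohort DNA count, and variant allele fraction.
#'
#' @param calls validated call data frame (see [read_calls()]).
#' @param design a `panel_design`.
#' @param whitelist optional data frame from [read_whitelist()].
#' @param cohort_index optional `cohort_index` (see [build_cohort_index()]).
#' @param dbsnp optional offline snapshot data frame with chrom, pos, ref,
#'   alt, rsid.
#' @return the calls with annotation columns appended (class
#'   `annotated_variants`); annotation is deterministic and side-effect free.
#' @export
annotate_calls <- function(calls, design, whitelist = NULL,
                           cohort_index = NULL, dbsnp = NULL) {
  stopifnot(inherits(design, "panel_design"))
  n <- nrow(calls)
  av <- calls
  if (is.null(av$vtype)) av$vtype <- infer_vtype(av$ref, av$alt)
  av$key <- variant_key(av$chrom, av$pos, av$ref, av$alt)

  # containing target region (any feature) -> gene
  av$gene <- NA_character_
  if (n > 0) {
    q <- GenomicRanges::GRanges(av$chrom, IRanges::IRanges(av$pos, av$pos))
    tg <- regions_to_granges(design$regions)
    suppressWarnings(ov <- GenomicRanges::findOverlaps(q, tg))
    first <- !duplicated(S4Vectors::queryHits(ov))
    av$gene[S4Vectors::queryHits(ov)[first]] <-
      design$regions$gene[S4Vectors::subjectHits(ov)[first]]
  }

  av$exon_distance <- if (n > 0) distance_to_exon(design, av$chrom, av$pos)
                      else numeric(0)
  av$location_class <- ifelse(is.na(av$gene), "off_gene",
    ifelse(av$exon_distance == 0, "exonic",
      ifelse(av$exon_distance <= 20, "near_splice", "deep_intronic")))

  av$known_pathogenic <- FALSE
  if (!is.null(whitelist) && nrow(whitelist) > 0) {
    av$known_pathogenic <- av$key %in% whitelist$key
    if ("cdna_label" %in% names(whitelist) && "cdna_label" %in% names(av)) {
      lk <- paste(whitelist$gene, whitelist$cdna_label)
      hit <- !is.na(av$cdna_label) &
        paste(av$gene, av$cdna_label) %in% lk
      av$known_pathogenic <- av$known_pathogenic | hit
    }
  }

  av$dbsnp_id <- NA_character_
  if (!is.null(dbsnp) && nrow(dbsnp) > 0) {
    dk <- variant_key(dbsnp$chrom, dbsnp$pos, toupper(dbsnp$ref), toupper(dbsnp$alt))
    m <- match(av$key, dk)
    av$dbsnp_id <- dbsnp$rsid[m]
  }

  av$cohort_count <- NA_integer_
  if (!is.null(cohort_index)) {
    m <- cohort_index$counts[av$key]
    av$cohort_count <- ifelse(is.na(m), 0L, as.integer(m))
  }

  av$vaf <- ifelse(av$depth_total > 0, av$reads_variant / av$depth_total, NA_real_)
  class(av) <- c("annotated_variants", "data.frame")
  av
}
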