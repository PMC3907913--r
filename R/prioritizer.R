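#' Build a cohort frequency index
#'
#' Counts, for each normalized variant key, the number of distinct DNAs
#' (patients) carrying it. A patient contributes at most one count per key
#' regardless of zygosity or duplicated rows.
#'
#' @param call_tables either a list of per-patient call data frames (each
#'   with a single `patient_id`) or one data frame with a `patient_id`
#'   column.
#' @return list of class `cohort_index` with `counts` (named integer vector
#'   keyed by chrom:pos:ref:alt) and `n_patients`.
#' @export
build_cohort_index <- function(call_tables) {
  if (is.data.frame(call_tables)) {
    df <- call_tables
  } else {
    ids <- vapply(call_tables, function(t) {
      u <- unique(as.character(t$patient_id))
      if (length(u) != 1L) stop("each per-patient table must carry one patient_id")
      u
    }, "")
    if (anyDuplicated(ids))
      stop("duplicate patient_id across call tables: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    df <- do.call(rbind, call_tables)
  }
  if (is.null(df$patient_id) || anyNA(df$patient_id))
    stop("cohort calls must carry patient_id")
  key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  pk <- !duplicated(paste(df$patient_id, key))  # one count per DNA per key
  counts <- table(key[pk])
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 n_patients = length(unique(df$patient_id))),
            class = "cohort_index")
}

#' Write / read a frozen cohort index
#'
#' A frozen index lets a reference cohort serve as the masking background for
#' newly sequenced patients.
#'
#' @param index a `cohort_index`.
#' @param path TSV path (columns key, count, plus a header comment carrying
#'   the cohort size).
#' @return `path` invisibly; `read_cohort_index()` returns a `cohort_index`.
#' @export
write_cohort_index <- function(index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# n_patients=", index$n_patients), con)
  utils::write.table(data.frame(key = names(index$counts),
                                count = unname(index$counts)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_index
#' @export
read_cohort_index <- function(path) {
  first <- readLines(path, n = 1)
  n <- as.integer(sub(".*n_patients=", "", first))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(list(counts = stats::setNames(as.integer(df$count), df$key),
                 n_patients = n),
            class = "cohort_index")
}

#' Prioritize filtered variants
#'
#' Keeps every known pathogenic (whitelisted) variant unconditionally; a
#' variant of unknown clinical significance is kept only when it was found in
#' fewer than five DNAs of the cohort (`cohort_count <= max_cohort_dna`) and
#' lies in an exon or within 20 bp of an intron-exon boundary. Unlike the
#' artifact distance rule, the positional criterion here applies to SNVs too.
#'
#' @param variants annotated variants that passed artifact filtering (need
#'   `known_pathogenic`, `cohort_count`, `exon_distance`).
#' @param index optional `cohort_index`; when given, `cohort_count` is
#'   (re)computed from it before masking.
#' @param config a [panelsift_config()] (`max_cohort_dna`,
#'   `max_exon_distance`) or `NULL` for defaults.
#' @return list with `candidates` and `masked` (the latter with a
#'   `mask_reason` column, comma-separated over cohort_frequent /
#'   deep_intronic).
#' @export
prioritize <- function(variants, index = NULL, config = NULL) {
  config <- as_panelsift_config(config)
  if (!is.null(index)) {
    m <- index$counts[variant_key(variants$chrom, variants$pos,
                                  variants$ref, variants$alt)]
    variants$cohort_count <- ifelse(is.na(m), 0L, as.integer(m))
  }
  if (is.null(variants$cohort_count) || anyNA(variants$cohort_count))
    stop("cohort_count missing; supply a cohort index or annotate with one")
  frequent <- variants$cohort_count > config$max_cohort_dna
  distant <- variants$exon_distance > config$max_exon_distance
  keep <- variants$known_pathogenic | (!frequent & !distant)
  masked <- variants[!keep, , drop = FALSE]
  masked$mask_reason <- paste0(ifelse(frequent[!keep], "cohort_frequent", ""),
                               ifelse(frequent[!keep] & distant[!keep], ",", ""),
                               ifelse(distant[!keep], "deep_intronic", ""))
  candidates <- variants[keep, , drop = FALSE]
  rownames(candidates) <- rownames(masked) <- NULL
  list(candidates = candidates, masked = masked)
}

#' Stage-count accounting for a pipeline run
#'
#' Tallies, per patient and on average, how many calls survive each stage:
#' raw input, after artifact filtering, after cohort/position masking.
#'
#' @param raw,post_filter,post_prioritize call data frames from one run (the
#'   later stages must be subsets of the earlier ones).
#' @return list of class `stage_counts` with `per_patient` (data frame:
#'   patient_id, raw, post_filter, post_prioritize) and `means`.
#' @export
stage_counts <- function(raw, post_filter, post_prioritize) {
  key_of <- function(df) paste(df$patient_id,
                               variant_key(df$chrom, df$pos, df$ref, df$alt))
  if (nrow(post_filter) && !all(key_of(post_filter) %in% key_of(raw)))
    stop("post_filter contains calls absent from raw: inconsistent provenance")
  if (nrow(post_prioritize) && !all(key_of(post_prioritize) %in% key_of(post_filter)))
    stop("post_prioritize contains calls absent from post_filter")
  pats <- unique(c(raw$patient_id, post_filter$patient_id,
                   post_prioritize$patient_id))
  cnt <- function(df) {
    t <- table(factor(df$patient_id, levels = pats))
    as.integer(t)
  }
  per <- data.frame(patient_id = pats, raw = cnt(raw),
                    post_filter = cnt(post_filter),
                    post_prioritize = cnt(post_prioritize),
                    stringsAsFactors = FALSE)
  if (length(pats) == 0)
    return(structure(list(per_patient = per,
                          means = c(raw = 0, post_filter = 0,
                                    post_prioritize = 0)),
                     class = "stage_counts"))
  structure(list(per_patient = per,
                 means = c(raw = mean(per$raw),
                           post_filter = mean(per$post_filter),
                           post_prioritize = mean(per$post_prioritize))),
            class = "stage_counts")
}

#' @export
print.stage_counts <- function(x, ...) {
  cat("stage counts over", nrow(x$per_patient), "patient(s): mean raw",
      round(x$means["raw"], 1), "-> post-filter",
      round(x$means["post_filter"], 1), "-> candidates",
      round(x$means["post_prioritize"], 1), "\n")
  invisible(x)
}
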