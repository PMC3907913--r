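# Independent brute-force oracles. These work per base on explicit boolean
# masks and never call the package's interval machinery.

# union of 0-based half-open intervals on one chromosome -> sorted disjoint
# intervals, via a per-base boolean mask
mask_union_1chrom <- function(start, end) {
  if (length(start) == 0) return(data.frame(start = integer(), end = integer()))
  lo <- min(start); hi <- max(end)
  mask <- logical(hi - lo)
  for (i in seq_along(start))
    mask[(start[i] - lo + 1):(end[i] - lo)] <- TRUE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = lo + starts[keep], end = lo + ends[keep])
}

oracle_merge <- function(regions) {
  out <- lapply(sort(unique(regions$chrom)), function(ch) {
    r <- regions[regions$chrom == ch, ]
    u <- mask_union_1chrom(r$start, r$end)
    cbind(chrom = ch, u)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# stepwise distance from a 1-based position to the nearest exon base
oracle_distance <- function(regions, chrom, pos) {
  ex <- regions[regions$feature == "exon" & regions$chrom == chrom, ]
  if (nrow(ex) == 0) return(Inf)
  exon_bases <- unlist(lapply(seq_len(nrow(ex)),
                              function(i) (ex$start[i] + 1):ex$end[i]))
  min(abs(exon_bases - pos))
}

# base-level on-target fraction by explicit per-base membership
oracle_on_target <- function(reads, merged) {
  in_target <- function(ch, p) {
    any(merged$chrom == ch & merged$start < p & p <= merged$end)
  }
  tot <- 0; hit <- 0
  for (i in seq_len(nrow(reads))) {
    for (p in (reads$start[i] + 1):reads$end[i]) {
      tot <- tot + 1
      if (in_target(reads$chrom[i], p)) hit <- hit + 1
    }
  }
  hit / tot
}

# distinct-DNA counts per variant key via set membership
oracle_cohort_counts <- function(calls) {
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  sapply(unique(key), function(k)
    length(unique(calls$patient_id[key == k])))
}

# all leftmost-equivalent placements of an anchored indel, by exhaustively
# applying candidate edits to the context and comparing haplotypes
oracle_leftmost <- function(pos, ref, alt, context) {
  apply_edit <- function(p, r, a) {
    stopifnot(substr(context, p, p + nchar(r) - 1) == r)
    paste0(substr(context, 1, p - 1), a,
           substr(context, p + nchar(r), nchar(context)))
  }
  target <- apply_edit(pos, ref, alt)
  dl <- nchar(ref) - nchar(alt)
  best <- NULL
  for (p in seq_len(nchar(context))) {
    if (dl >= 0) {  # deletion-like: anchored ref of length dl + 1
      r <- substr(context, p, p + dl)
      if (nchar(r) < dl + 1 || p + dl > nchar(context)) next
      a <- substr(r, 1, 1)
      if (apply_edit(p, r, a) == target) { best <- list(pos = p, ref = r, alt = a); break }
    } else {        # insertion-like: anchored alt of length -dl + 1
      r <- substr(context, p, p)
      for (ins in unique_insertions(-dl)) {
        a <- paste0(r, ins)
        if (apply_edit(p, r, a) == target) { best <- list(pos = p, ref = r, alt = a); break }
      }
      if (!is.null(best)) break
    }
  }
  best
}

unique_insertions <- function(len) {
  if (len > 3) stop("oracle supports insertions up to 3 bp")
  bases <- c("A", "C", "G", "T")
  combos <- do.call(expand.grid, rep(list(bases), len))
  apply(combos, 1, paste, collapse = "")
}

random_regions <- function(n, chroms = c("c1", "c2"), max_pos = 500,
                           max_len = 40) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  target_regions(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + len,
                 gene = sample(c("GA", "GB"), n, replace = TRUE),
                 feature = sample(c("exon", "intronic_extension"), n,
                                  replace = TRUE, prob = c(0.6, 0.4)))
}

small_cfg <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_genes = 4L, n_exons = 30L, n_merged = 26L,
                   n_patients = 6L, rate_low_vaf = 60,
                   rate_strand_indel = 10, rate_deep_intronic_indel = 6,
                   shared_polymorphism_sites = 20L,
                   true_variants_per_patient = 4)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
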