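#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a multi-gene capture
#' design of exons with 100 bp intronic flanks whose footprints partially
#' overlap, GC-dependent overdispersed coverage around a 77x mean, and a
#' 47-patient cohort whose raw call load per patient (about 4674) decomposes
#' into a handful of rare true variants, a few hundred shared cohort
#' polymorphisms, and three artifact classes dominated by low-allele-fraction
#' noise, with strand-biased homopolymer-context indels and deep-intronic
#' indels as the minor classes.
#'
#' @param seed integer seed; mandatory (the generator has no implicit
#'   randomness).
#' @param n_genes number of genes in the design.
#' @param n_exons total targeted exons across genes.
#' @param n_merged number of distinct merged footprint components the design
#'   is constructed to union into (`NULL` for fully random gaps).
#' @param exon_length_meanlog,exon_length_sdlog log-normal exon length
#'   parameters (lengths clipped to `[60, 2000]`).
#' @param flank_bp intronic flank captured on each side of an exon.
#' @param n_patients cohort size.
#' @param true_variants_per_patient Poisson mean of rare true variants per
#'   patient.
#' @param shared_polymorphism_sites number of polymorphic sites shared across
#'   the cohort.
#' @param shared_carrier_prob probability a given patient carries a given
#'   shared site.
#' @param rate_low_vaf,rate_strand_indel,rate_deep_intronic_indel Poisson
#'   means of artifact calls per patient, by class.
#' @param homopolymer_per_kb expected homopolymer tracts per kb of exon.
#' @param mean_depth design-wide mean depth of coverage.
#' @param depth_dispersion negative-binomial size parameter of per-base depth
#'   (smaller = more overdispersed).
#' @param gc_depth_slope depth multiplier lost per unit of GC above 0.5: a
#'   region's designed mean is
#'   `mean_depth * max(0, 1 - gc_depth_slope * max(0, gc - 0.5))`.
#' @param whitelist_fraction fraction of rare true variant sites emitted to
#'   the known-pathogenic whitelist.
#' @param whitelist_shared_sites number of shared polymorphism sites also
#'   placed on the whitelist (frequent known mutations, exercising the
#'   whitelist-overrides-frequency rule).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 19L,
                       n_exons = 634L,
                       n_merged = 535L,
                       exon_length_meanlog = log(170),
                       exon_length_sdlog = 0.55,
                       flank_bp = 100L,
                       n_patients = 47L,
                       true_variants_per_patient = 7,
                       shared_polymorphism_sites = 638L,
                       shared_carrier_prob = 0.55,
                       rate_low_vaf = 4000,
                       rate_strand_indel = 200,
                       rate_deep_intronic_indel = 116,
                       homopolymer_per_kb = 1.5,
                       mean_depth = 77,
                       depth_dispersion = 8,
                       gc_depth_slope = 5.5,
                       whitelist_fraction = 0.25,
                       whitelist_shared_sites = 2L) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("sim_config requires an explicit seed")
  stopifnot(n_genes >= 1, n_exons >= n_genes,
            is.null(n_merged) || (n_merged >= n_genes && n_merged <= n_exons),
            flank_bp >= 0, n_patients >= 1,
            true_variants_per_patient >= 0, shared_polymorphism_sites >= 0,
            shared_carrier_prob >= 0, shared_carrier_prob <= 1,
            rate_low_vaf >= 0, rate_strand_indel >= 0,
            rate_deep_intronic_indel >= 0,
            mean_depth > 0, depth_dispersion > 0, gc_depth_slope >= 0,
            whitelist_fraction >= 0, whitelist_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# internal: draw per-unit GC with a heavy right tail (some exceed 0.60)
draw_gc <- function(n) 0.32 + 0.48 * stats::rbeta(n, 2, 5)

#' Simulate a capture panel design
#'
#' Generates `n_exons` exons over `n_genes` genes (one gene per chromosome),
#' each with `flank_bp` intronic extensions on both sides. Inter-exon gaps
#' are drawn so that, when `n_merged` is set, exactly
#' `n_exons - n_merged` adjacent footprints overlap and the merged design has
#' `n_merged` components. Per-unit GC fractions carry a heavy right tail and
#' homopolymer tracts are laid down inside exons for the error model.
#' Deterministic for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return a `panel_design` whose `homopolymers` element lists the tracts.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  # exons per gene: at least 2, remainder spread at random
  base <- rep(2L, cfg$n_genes)
  extra <- cfg$n_exons - sum(base)
  if (extra < 0) stop("n_exons too small for n_genes")
  add <- table(factor(sample.int(cfg$n_genes, extra, replace = TRUE),
                      levels = seq_len(cfg$n_genes)))
  k_per_gene <- base + as.integer(add)

  n_adj <- cfg$n_exons - cfg$n_genes
  n_close <- if (is.null(cfg$n_merged)) stats::rbinom(1, n_adj, 0.15)
             else cfg$n_exons - cfg$n_merged
  if (n_close > n_adj) stop("n_merged implies more overlaps than adjacencies")
  close <- rep(FALSE, n_adj)
  if (n_close > 0) close[sample.int(n_adj, n_close)] <- TRUE

  rows <- vector("list", cfg$n_exons)
  hp <- list()
  adj_i <- 0L; unit_i <- 0L
  for (g in seq_len(cfg$n_genes)) {
    gene <- sprintf("GENE%02d", g)
    chrom <- sprintf("chr%02d", g)
    pos <- 10000L
    for (e in seq_len(k_per_gene[g])) {
      len <- as.integer(pmin(2000, pmax(60, round(
        stats::rlnorm(1, cfg$exon_length_meanlog, cfg$exon_length_sdlog)))))
      unit_i <- unit_i + 1L
      unit <- sprintf("%s.e%03d", gene, e)
      gc <- draw_gc(1)
      ex_start <- pos
      ex_end <- pos + len
      fl <- cfg$flank_bp
      rows[[unit_i]] <- data.frame(
        chrom = chrom,
        start = c(ex_start - fl, ex_start, ex_end),
        end = c(ex_start, ex_end, ex_end + fl),
        gene = gene,
        feature = c("intronic_extension", "exon", "intronic_extension"),
        gc_fraction = gc, unit = unit, stringsAsFactors = FALSE)
      if (stats::runif(1) < cfg$homopolymer_per_kb * len / 1000) {
        tl <- sample(4:8, 1)
        ts <- ex_start + sample.int(max(1L, len - tl), 1)
        hp[[length(hp) + 1L]] <- data.frame(
          chrom = chrom, start = ts, end = ts + tl,
          base = sample(c("A", "C", "G", "T"), 1), unit = unit,
          stringsAsFactors = FALSE)
      }
      if (e < k_per_gene[g]) {
        adj_i <- adj_i + 1L
        gap <- if (close[adj_i]) sample(40:160, 1) else sample(300:2500, 1)
        pos <- ex_end + as.integer(gap)
      }
    }
  }
  regions <- do.call(rbind, rows)
  hp_df <- if (length(hp)) do.call(rbind, hp) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               base = character(), unit = character())
  panel_design(target_regions(regions$chrom, regions$start, regions$end,
                              regions$gene, regions$feature,
                              regions$gc_fraction, regions$unit),
               homopolymers = hp_df)
}

#' Simulate per-unit coverage profiles
#'
#' Per-base depths are negative-binomial around each unit's designed mean:
#' the GC factor `max(0, 1 - gc_depth_slope * max(0, gc - 0.5))`, rescaled so
#' the length-weighted average over the design equals `mean_depth`. GC-rich
#' units are thus depressed (emulating capture bias) while the design-wide
#' mean stays at the configured depth; the counts are overdispersed.
#' Deterministic for a fixed seed.
#'
#' @param design a `panel_design` from [simulate_panel()].
#' @param cfg the [sim_config()].
#' @return list with `profiles` (list of `coverage_profile`) and `truth`
#'   (data frame unit, designed_mean).
#' @export
simulate_coverage <- function(design, cfg) {
  stopifnot(inherits(design, "panel_design"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  units <- design_units(design)
  gc <- ifelse(is.na(units$gc_fraction), 0.45, units$gc_fraction)
  factor <- pmax(0, 1 - cfg$gc_depth_slope * pmax(0, gc - 0.5))
  # mean_depth is the design-wide average; GC modulates around it, so the
  # factors are renormalized by their length-weighted mean
  len <- units$end - units$start
  mu <- cfg$mean_depth * factor / sum(factor * len) * sum(len)
  profiles <- lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    depths <- if (mu[i] <= 0) rep(0L, u$end - u$start) else
      stats::rnbinom(u$end - u$start, mu = mu[i], size = cfg$depth_dispersion)
    coverage_profile(u$chrom, u$start, u$end, depths, gene = u$gene,
                     unit = u$unit, gc_fraction = u$gc_fraction)
  })
  list(profiles = profiles,
       truth = data.frame(unit = units$unit, designed_mean = mu,
                          gc_fraction = units$gc_fraction,
                          stringsAsFactors = FALSE))
}

# --- internal site/count helpers -------------------------------------------

# sample n exonic 1-based positions; returns data.frame(chrom, pos, unit, gene)
sample_exon_positions <- function(design, n) {
  ex <- design$regions[design$regions$feature == "exon", , drop = FALSE]
  idx <- sample.int(nrow(ex), n, replace = TRUE, prob = ex$end - ex$start)
  pos <- ex$start[idx] + 1L +
    floor(stats::runif(n) * (ex$end[idx] - ex$start[idx]))
  data.frame(chrom = ex$chrom[idx], pos = as.integer(pos),
             unit = ex$unit[idx], gene = ex$gene[idx], stringsAsFactors = FALSE)
}

# depth draws for emitted calls, floored (a call implies minimal coverage)
call_depths <- function(n, cfg, floor_at) {
  pmax(floor_at,
       stats::rnbinom(n, mu = cfg$mean_depth, size = cfg$depth_dispersion))
}

# true-call read support: binomial around the genotype fraction, resampled
# into the detection regime (observed VAF >= 0.25, minor strand >= 0.15 of
# variant reads whenever the strand gate could apply)
true_support <- function(depth, hom) {
  n <- length(depth)
  reads <- integer(n); fwd <- integer(n)
  p <- ifelse(hom, 1, 0.5)
  for (i in seq_len(n)) {
    repeat {
      r <- stats::rbinom(1, depth[i], p[i])
      if (r >= 1 && r / depth[i] >= 0.25) break
    }
    repeat {
      f <- stats::rbinom(1, r, 0.5)
      m <- min(f, r - f)
      if (r <= 20 || (m / r) >= 0.15) break
    }
    reads[i] <- r; fwd[i] <- f
  }
  data.frame(depth_total = depth, reads_variant = reads,
             reads_fwd = fwd, reads_rev = reads - fwd)
}

random_base <- function(n, not = NULL) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (!is.null(not)) {
    clash <- b == not
    while (any(clash)) {
      b[clash] <- sample(c("A", "C", "G", "T"), sum(clash), replace = TRUE)
      clash <- b == not
    }
  }
  b
}

#' Simulate a multi-patient cohort of variant calls with truth labels
#'
#' Emits per-patient call tables in the gsdiff dialect together with a truth
#' table assigning every emitted call exactly one label: `true_variant`
#' (rare, or a shared cohort polymorphism), `artifact:low_vaf` (allele
#' fraction strictly below 0.2), `artifact:strand` (indel in homopolymer
#' context, variant reads above 20, minor strand strictly below 10% of the
#' evidence), or `artifact:deep_intronic` (indel more than 20 bp from any
#' exon). True calls are placed exonic or near-splice with heterozygous or
#' homozygous allele fractions and balanced strands. A subset of rare true
#' sites (plus a few shared sites) is emitted as the known-pathogenic
#' whitelist. Emitted call tables carry no truth columns. Deterministic for a
#' fixed seed.
#'
#' @param design a `panel_design` from [simulate_panel()].
#' @param cfg the [sim_config()].
#' @return list with `calls` (data frame of all patients' calls), `truth`
#'   (patient_id, key, label, homopolymer, shared, whitelisted, detected,
#'   failure_category), and `whitelist` (data frame usable via
#'   [annotate_calls()]).
#' @export
simulate_cohort <- function(design, cfg) {
  stopifnot(inherits(design, "panel_design"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  patients <- sprintf("P%03d", seq_len(cfg$n_patients))
  pieces <- list(); truths <- list()

  ## shared cohort polymorphisms: SNVs at fixed sites, carried independently
  ns <- cfg$shared_polymorphism_sites
  shared_sites <- NULL
  if (ns > 0) {
    shared_sites <- sample_exon_positions(design, ns)
    shared_sites$ref <- random_base(ns)
    shared_sites$alt <- random_base(ns, not = shared_sites$ref)
    carrier <- matrix(stats::runif(ns * cfg$n_patients) < cfg$shared_carrier_prob,
                      nrow = ns)
    idx <- which(carrier, arr.ind = TRUE)
    site <- idx[, 1]
    n <- nrow(idx)
    sup <- true_support(call_depths(n, cfg, 25L),
                        hom = stats::runif(n) < 0.1)
    pieces$shared <- data.frame(
      patient_id = patients[idx[, 2]],
      chrom = shared_sites$chrom[site], pos = shared_sites$pos[site],
      ref = shared_sites$ref[site], alt = shared_sites$alt[site],
      sup, stringsAsFactors = FALSE)
    truths$shared <- data.frame(label = "true_variant", homopolymer = FALSE,
                                shared = TRUE, stringsAsFactors = FALSE)
  }

  ## rare true variants, unique per patient
  n_rare <- stats::rpois(cfg$n_patients, cfg$true_variants_per_patient)
  nr <- sum(n_rare)
  rare_keys <- character(0)
  if (nr > 0) {
    loc <- sample_exon_positions(design, nr)
    near <- stats::runif(nr) < 0.15  # near-splice placement, d in 1..20
    d <- sample(1:20, nr, replace = TRUE)
    ex <- design$regions[design$regions$feature == "exon", , drop = FALSE]
    m <- match(loc$unit, ex$unit)
    left <- stats::runif(nr) < 0.5
    loc$pos[near] <- ifelse(left[near], ex$start[m[near]] + 1L - d[near],
                            ex$end[m[near]] + d[near])
    indel <- stats::runif(nr) < 0.2
    ref <- random_base(nr); alt <- random_base(nr, not = NULL)
    ref[indel] <- paste0(ref[indel], random_base(sum(indel)))
    alt[indel] <- substr(ref[indel], 1, 1)
    snv <- !indel
    fix <- snv & alt == ref
    while (any(fix)) {
      alt[fix] <- random_base(sum(fix))
      fix <- snv & alt == ref
    }
    sup <- true_support(call_depths(nr, cfg, 25L), hom = stats::runif(nr) < 0.1)
    pieces$rare <- data.frame(
      patient_id = rep(patients, n_rare),
      chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
      sup, stringsAsFactors = FALSE)
    truths$rare <- data.frame(label = "true_variant", homopolymer = FALSE,
                              shared = FALSE, stringsAsFactors = FALSE)
    rare_keys <- variant_key(loc$chrom, loc$pos, ref, alt)
  }

  ## low-VAF noise: anywhere on target, observed fraction strictly below 0.2
  n_lv <- sum(stats::rpois(cfg$n_patients, cfg$rate_low_vaf))
  per_lv <- stats::rmultinom(1, n_lv, rep(1, cfg$n_patients))[, 1]
  if (n_lv > 0) {
    loc <- sample_exon_positions(design, n_lv)
    depth <- call_depths(n_lv, cfg, 6L)
    target <- stats::runif(n_lv, 0.02, 0.18)
    cap <- pmax(1L, as.integer(ceiling(depth * 0.2) - 1L))
    reads <- pmin(cap, pmax(1L, stats::rbinom(n_lv, depth, target)))
    fwd <- stats::rbinom(n_lv, reads, 0.5)
    ref <- random_base(n_lv); alt <- random_base(n_lv, not = NULL)
    fix <- alt == ref
    while (any(fix)) { alt[fix] <- random_base(sum(fix)); fix <- alt == ref }
    pieces$low_vaf <- data.frame(
      patient_id = rep(patients, per_lv),
      chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
      depth_total = depth, reads_variant = reads,
      reads_fwd = fwd, reads_rev = reads - fwd, stringsAsFactors = FALSE)
    truths$low_vaf <- data.frame(label = "artifact:low_vaf",
                                 homopolymer = FALSE, shared = FALSE,
                                 stringsAsFactors = FALSE)
  }

  ## strand-biased indels in homopolymer context
  n_sb <- sum(stats::rpois(cfg$n_patients, cfg$rate_strand_indel))
  per_sb <- stats::rmultinom(1, n_sb, rep(1, cfg$n_patients))[, 1]
  if (n_sb > 0) {
    hp <- design$homopolymers
    in_hp <- nrow(hp) > 0
    if (in_hp) {
      ti <- sample.int(nrow(hp), n_sb, replace = TRUE)
      chrom <- hp$chrom[ti]
      # anchor anywhere in the run: un-normalized callers place the miscall
      # at any equivalent position of the homopolymer
      off <- floor(stats::runif(n_sb) * (hp$end[ti] - hp$start[ti]))
      pos <- hp$start[ti] + 1L + as.integer(off)
      base <- hp$base[ti]
    } else {
      loc <- sample_exon_positions(design, n_sb)
      chrom <- loc$chrom; pos <- loc$pos; base <- random_base(n_sb)
    }
    reads <- sample(21:60, n_sb, replace = TRUE)
    minor <- as.integer(floor(stats::runif(n_sb, 0, 0.095) * reads))
    minor_is_fwd <- stats::runif(n_sb) < 0.5
    fwd <- ifelse(minor_is_fwd, minor, reads - minor)
    depth <- as.integer(ceiling(reads / stats::runif(n_sb, 0.3, 0.6)))
    del <- stats::runif(n_sb) < 0.7  # pyrosequencing miscalls run length both ways
    ref <- ifelse(del, paste0(base, base), base)
    alt <- ifelse(del, base, paste0(base, base))
    pieces$strand <- data.frame(
      patient_id = rep(patients, per_sb),
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      depth_total = depth, reads_variant = reads,
      reads_fwd = as.integer(fwd), reads_rev = as.integer(reads - fwd),
      stringsAsFactors = FALSE)
    truths$strand <- data.frame(label = "artifact:strand",
                                homopolymer = in_hp, shared = FALSE,
                                stringsAsFactors = FALSE)
  }

  ## deep-intronic indels: verified > 20 bp from every exon
  n_di <- sum(stats::rpois(cfg$n_patients, cfg$rate_deep_intronic_indel))
  per_di <- stats::rmultinom(1, n_di, rep(1, cfg$n_patients))[, 1]
  if (n_di > 0) {
    fl <- design$regions[design$regions$feature == "intronic_extension", ,
                         drop = FALSE]
    chrom <- character(0); pos <- integer(0)
    while (length(pos) < n_di) {
      need <- n_di - length(pos)
      i <- sample.int(nrow(fl), need, replace = TRUE)
      p <- fl$start[i] + 1L +
        floor(stats::runif(need) * (fl$end[i] - fl$start[i]))
      keep <- distance_to_exon(design, fl$chrom[i], p) > 20
      chrom <- c(chrom, fl$chrom[i][keep]); pos <- c(pos, p[keep])
    }
    base <- random_base(n_di)
    reads <- sample(8:20, n_di, replace = TRUE)  # balanced, below strand gate
    fwd <- stats::rbinom(n_di, reads, 0.5)
    depth <- as.integer(ceiling(reads / stats::runif(n_di, 0.3, 0.6)))
    pieces$deep <- data.frame(
      patient_id = rep(patients, per_di),
      chrom = chrom, pos = pos,
      ref = paste0(base, random_base(n_di)), alt = base,
      depth_total = depth, reads_variant = reads,
      reads_fwd = as.integer(fwd), reads_rev = as.integer(reads - fwd),
      stringsAsFactors = FALSE)
    truths$deep <- data.frame(label = "artifact:deep_intronic",
                              homopolymer = FALSE, shared = FALSE,
                              stringsAsFactors = FALSE)
  }

  calls <- do.call(rbind, unname(pieces))
  labels <- do.call(rbind, unname(Map(function(p, t)
    t[rep(1L, nrow(p)), , drop = FALSE], pieces, truths)))
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  # one row per variant per patient: artifacts drawn onto a site the patient
  # already carries are dropped (true pieces come first, so they win)
  dup <- duplicated(paste(calls$patient_id, key))
  calls <- calls[!dup, , drop = FALSE]
  labels <- labels[!dup, , drop = FALSE]
  key <- key[!dup]

  ## whitelist: a fraction of rare true sites plus a few shared sites
  wl_keys <- character(0)
  if (length(rare_keys)) {
    uk <- unique(rare_keys)
    n_wl <- round(cfg$whitelist_fraction * length(uk))
    if (n_wl > 0) wl_keys <- sample(uk, n_wl)
  }
  if (!is.null(shared_sites) && cfg$whitelist_shared_sites > 0) {
    sk <- variant_key(shared_sites$chrom, shared_sites$pos,
                      shared_sites$ref, shared_sites$alt)
    wl_keys <- c(wl_keys, sample(sk, min(cfg$whitelist_shared_sites, length(sk))))
  }
  wl <- if (length(wl_keys)) {
    parts <- do.call(rbind, strsplit(wl_keys, ":", fixed = TRUE))
    data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
               ref = parts[, 3], alt = parts[, 4], gene = NA_character_,
               class = "Pathogenic", key = wl_keys, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), gene = character(), class = character(),
               key = character())
  }

  truth <- data.frame(patient_id = calls$patient_id, key = key,
                      label = labels$label, homopolymer = labels$homopolymer,
                      shared = labels$shared,
                      whitelisted = key %in% wl$key,
                      detected = TRUE, failure_category = NA_character_,
                      stringsAsFactors = FALSE)
  ord <- order(calls$patient_id, calls$chrom, calls$pos)
  calls <- calls[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  rownames(calls) <- rownames(truth) <- NULL
  list(calls = calls, truth = truth, whitelist = wl)
}

#' Construct a detection-sensitivity validation set
#'
#' Builds a truth table of `n_variants` true variants (all exonic or within
#' 20 bp of an exon, the regime the panel validates against) of which a
#' chosen number are undetected false negatives, split into the three failure
#' categories seen in pyrosequencing validation: homopolymer-context calls the
#' base caller misses, misaligned calls, and calls in poorly covered regions.
#' All detected variants are emitted with retainable characteristics
#' (balanced strands, allele fraction at heterozygous/homozygous levels).
#'
#' @param design a `panel_design`.
#' @param seed integer seed.
#' @param n_variants total true variants in the truth set.
#' @param fn_homopolymer,fn_misaligned,fn_low_coverage undetected counts per
#'   failure category.
#' @param n_patients patients the variants are spread over.
#' @return list with `calls` (detected variants only) and `truth` (every
#'   variant, with `detected` and `failure_category`).
#' @export
simulate_validation_set <- function(design, seed, n_variants = 687L,
                                    fn_homopolymer = 6L, fn_misaligned = 4L,
                                    fn_low_coverage = 3L, n_patients = 24L) {
  set.seed(seed)
  n_fn <- fn_homopolymer + fn_misaligned + fn_low_coverage
  stopifnot(n_fn <= n_variants)
  cfg <- sim_config(seed = seed, n_patients = n_patients)
  loc <- sample_exon_positions(design, n_variants)
  loc$pos <- loc$pos + sample(0:3, n_variants, replace = TRUE)  # decorrelate dup sites
  ref <- random_base(n_variants); alt <- random_base(n_variants)
  fix <- alt == ref
  while (any(fix)) { alt[fix] <- random_base(sum(fix)); fix <- alt == ref }
  patient <- sprintf("V%03d", sample.int(n_patients, n_variants, replace = TRUE))
  key <- variant_key(loc$chrom, loc$pos, ref, alt)
  dup <- duplicated(paste(patient, key))
  while (any(dup)) {  # occurrences must be unique within a patient
    loc$pos[dup] <- loc$pos[dup] + 5L
    key <- variant_key(loc$chrom, loc$pos, ref, alt)
    dup <- duplicated(paste(patient, key))
  }
  undetected <- sample.int(n_variants, n_fn)
  category <- rep(NA_character_, n_variants)
  category[undetected] <- rep(c("homopolymer", "misaligned", "low_coverage"),
                              c(fn_homopolymer, fn_misaligned, fn_low_coverage))
  det <- setdiff(seq_len(n_variants), undetected)
  sup <- true_support(call_depths(length(det), cfg, 25L),
                      hom = stats::runif(length(det)) < 0.1)
  calls <- data.frame(patient_id = patient[det],
                      chrom = loc$chrom[det], pos = loc$pos[det],
                      ref = ref[det], alt = alt[det], sup,
                      stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = patient, key = key, label = "true_variant",
                      homopolymer = category %in% "homopolymer",
                      shared = FALSE, whitelisted = FALSE,
                      detected = is.na(category), failure_category = category,
                      stringsAsFactors = FALSE)
  list(calls = calls, truth = truth)
}

#' Evaluate pipeline output against a truth table
#'
#' Joins the retained pipeline output to the truth labels and reports
#' per-class confusion counts, overall sensitivity (retained true variants
#' over all true variants, detected or not), specificity per artifact class,
#' and a categorization of false negatives (undetected: homopolymer /
#' misaligned / low coverage; detected but lost: filtered_or_masked).
#'
#' @param calls the emitted call table the pipeline consumed.
#' @param truth the matching truth table.
#' @param retained the pipeline's retained calls (e.g. candidates).
#' @return list of class `filter_evaluation`: `sensitivity`, `confusion`
#'   (data frame label, n, retained, removed), `fn_categories` (table),
#'   `artifact_removal_fraction`.
#' @export
evaluate_filters <- function(calls, truth, retained) {
  ckey <- paste(calls$patient_id,
                variant_key(calls$chrom, calls$pos, calls$ref, calls$alt))
  tkey <- paste(truth$patient_id, truth$key)
  det <- if ("detected" %in% names(truth)) truth$detected else
    rep(TRUE, nrow(truth))
  if (!setequal(tkey[det], ckey))
    stop("truth/calls key mismatch: truth does not describe these calls")
  rkey <- paste(retained$patient_id,
                variant_key(retained$chrom, retained$pos, retained$ref,
                            retained$alt))
  kept <- tkey %in% rkey
  conf <- do.call(rbind, lapply(split(kept, truth$label), function(k)
    data.frame(n = length(k), retained = sum(k), removed = sum(!k))))
  conf <- data.frame(label = rownames(conf), conf, row.names = NULL,
                     stringsAsFactors = FALSE)
  is_true <- truth$label == "true_variant"
  sens <- if (any(is_true)) sum(kept & is_true) / sum(is_true) else NA_real_
  fn <- !kept & is_true
  cat_fn <- ifelse(det[fn], "filtered_or_masked",
                   truth$failure_category[fn])
  art <- grepl("^artifact:", truth$label)
  arf <- if (any(art)) sum(!kept & art) / sum(art) else NA_real_
  structure(list(sensitivity = sens,
                 n_true = sum(is_true), n_true_retained = sum(kept & is_true),
                 confusion = conf,
                 fn_categories = table(cat_fn),
                 artifact_removal_fraction = arf),
            class = "filter_evaluation")
}

#' @export
print.filter_evaluation <- function(x, ...) {
  cat("sensitivity:", x$n_true_retained, "/", x$n_true, "=",
      sprintf("%.1f%%", 100 * x$sensitivity), "\n")
  print(x$confusion)
  invisible(x)
}
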