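make_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

ok_calls <- function(n = 5) {
  data.frame(chrom = "c1", pos = 100 + seq_len(n), ref = "A", alt = "T",
             depth_total = 100L, reads_variant = 40L,
             reads_fwd = 22L, reads_rev = 18L)
}

test_that("gsdiff TSV reads, validates, and rejects invariant violations", {
  f <- make_tsv(ok_calls(5))
  calls <- read_calls(f, "gsdiff_tsv", patient_id = "P1")
  expect_equal(nrow(calls), 5)
  expect_equal(unique(calls$vtype), "snv")
  expect_equal(unique(calls$patient_id), "P1")

  bad <- ok_calls(5)
  bad$reads_variant[3] <- 200L  # exceeds depth
  f <- make_tsv(bad)
  expect_message(calls <- read_calls(f, "gsdiff_tsv"), "rejected")
  expect_equal(nrow(calls), 4)
  expect_equal(attr(calls, "rejected")$reason, "reads_variant > depth_total")

  bad <- ok_calls(2)
  bad$reads_fwd[1] <- 10L  # strand counts no longer sum
  v <- validate_calls(bad)
  expect_equal(nrow(v$calls), 1)
  expect_match(v$rejected$reason, "reads_fwd")

  expect_error(read_calls(make_tsv(data.frame(chrom = "c1", pos = 1)),
                          "gsdiff_tsv"), "missing column")
})

test_that("unknown strand counts are preserved as NA, not rejected", {
  x <- ok_calls(2)
  x$reads_fwd <- NA_integer_; x$reads_rev <- NA_integer_
  v <- validate_calls(x)
  expect_equal(nrow(v$calls), 2)
  expect_true(all(is.na(v$calls$reads_fwd)))
})

test_that("VCF ingest maps AD into counts and leaves strands unknown", {
  skip_if_not_installed("vcfR")
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "c1\t101\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:80,20",
    "c1\t202\t.\tT\tTA\t50\tPASS\t.\tGT:AD\t0/1:30,30"), f)
  calls <- read_calls(f, "vcf", patient_id = "P9")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$depth_total[1], 100L)
  expect_equal(calls$reads_variant[1], 20L)
  expect_equal(calls$reads_variant[1] / calls$depth_total[1], 0.20)
  expect_true(all(is.na(calls$reads_fwd)))
  expect_equal(calls$vtype, c("snv", "ins"))
})

test_that("vtype inference distinguishes snv/ins/del/delins", {
  expect_equal(infer_vtype(c("A", "A", "AT", "AT"),
                           c("G", "AT", "A", "GC")),
               c("snv", "ins", "del", "delins"))
})

test_that("left normalization anchors indels at the start of repeat runs", {
  # context ATGGGGC, delete one G called at the last possible anchor
  r <- left_normalize(pos = 5, ref = "GG", alt = "G", context = "ATGGGGC")
  expect_equal(r[c("pos", "ref", "alt")], list(pos = 2L, ref = "TG", alt = "T"))
  # SNVs unchanged
  r <- left_normalize(pos = 4, ref = "G", alt = "T", context = "ATGGGGC")
  expect_equal(r$pos, 4L); expect_equal(r$ref, "G")
  # idempotent
  r2 <- do.call(left_normalize,
                c(r[c("pos", "ref", "alt")], list(context = "ATGGGGC")))
  expect_equal(r2[c("pos", "ref", "alt")], r[c("pos", "ref", "alt")])
  # short context -> skipped with a flag
  expect_warning(r3 <- left_normalize(3, "GG", "G", context = "GGG",
                                      context_start = 2),
                 "skipped|short")
  expect_false(r3$normalized)
})

test_that("normalization agrees with the exhaustive placement oracle", {
  set.seed(11)
  for (i in 1:40) {
    ctx <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE,
                        prob = c(0.4, 0.1, 0.4, 0.1)), collapse = "")
    p <- sample(3:25, 1)
    if (runif(1) < 0.5) {  # deletion of 1-2 bases
      dl <- sample(1:2, 1)
      if (p + dl > nchar(ctx)) next
      ref <- substr(ctx, p, p + dl); alt <- substr(ctx, p, p)
    } else {               # insertion of 1-2 bases
      ref <- substr(ctx, p, p)
      ins <- paste(sample(c("A", "G"), sample(1:2, 1), replace = TRUE),
                   collapse = "")
      alt <- paste0(ref, ins)
    }
    got <- left_normalize(p, ref, alt, ctx)
    want <- oracle_leftmost(p, ref, alt, ctx)
    expect_equal(got$pos, want$pos, info = paste(ctx, p, ref, alt))
    # haplotype preserved
    apply_edit <- function(pp, rr, aa)
      paste0(substr(ctx, 1, pp - 1), aa, substr(ctx, pp + nchar(rr), nchar(ctx)))
    expect_equal(apply_edit(got$pos, got$ref, got$alt),
                 apply_edit(p, ref, alt))
  }
})

test_that("annotation adds gene, distance, location class, and lookups", {
  r <- target_regions(chrom = rep("c1", 3), start = c(0, 100, 200),
                      end = c(100, 200, 300), gene = "GA",
                      feature = c("intronic_extension", "exon",
                                  "intronic_extension"),
                      unit = "u1")
  d <- panel_design(r)
  wl <- data.frame(chrom = "c1", pos = 150L, ref = "A", alt = "T",
                   gene = "GA", key = "c1:150:A:T")
  calls <- data.frame(patient_id = "P1",
                      chrom = c("c1", "c1", "c1", "c9"),
                      pos = c(150L, 225L, 110L, 50L),
                      ref = c("A", "AT", "C", "A"),
                      alt = c("T", "A", "G", "C"),
                      depth_total = 100L, reads_variant = 50L,
                      reads_fwd = 25L, reads_rev = 25L)
  av <- annotate_calls(calls, d, whitelist = wl)
  expect_equal(av$gene, c("GA", "GA", "GA", NA))
  expect_equal(av$exon_distance, c(0, 25, 0, Inf))
  expect_equal(av$location_class,
               c("exonic", "deep_intronic", "exonic", "off_gene"))
  expect_equal(av$known_pathogenic, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(av$vaf, rep(0.5, 4))
  # deterministic and pure: annotating twice is identical
  expect_identical(annotate_calls(calls, d, whitelist = wl), av)
})

test_that("cohort counting in annotation matches a counting oracle", {
  d <- panel_design(target_regions("c1", 0, 1000, "GA"))
  set.seed(3)
  cohort <- do.call(rbind, lapply(1:10, function(i)
    data.frame(patient_id = paste0("P", i), chrom = "c1",
               pos = sample(c(10L, 20L, 30L), 3),
               ref = "A", alt = "T", depth_total = 100L,
               reads_variant = 50L, reads_fwd = 25L, reads_rev = 25L)))
  shared <- cohort[cohort$pos == 10, ][1:6, ]  # 6 distinct patients share pos 10
  idx <- build_cohort_index(rbind(shared, cohort[cohort$pos != 10, ][1:8, ]))
  av <- annotate_calls(shared[1, , drop = FALSE], d, cohort_index = idx)
  expect_equal(av$cohort_count, 6L)
})
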