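# minimal annotated-variant rows for rule testing
av_row <- function(vtype = "snv", depth = 100L, reads = 40L,
                   fwd = NULL, rev = NULL, exon_distance = 0) {
  if (is.null(fwd)) { fwd <- reads %/% 2L; rev <- reads - fwd }
  data.frame(patient_id = "P1", chrom = "c1", pos = 100L,
             ref = if (vtype == "snv") "A" else "AT",
             alt = if (vtype == "snv") "T" else "A",
             vtype = vtype, depth_total = depth, reads_variant = reads,
             reads_fwd = as.integer(fwd), reads_rev = as.integer(rev),
             exon_distance = exon_distance)
}

test_that("the VAF rule is strict below 20% and degenerate at zero depth", {
  expect_false(vaf_rule(av_row(reads = 5L, depth = 100L)))          # 5%
  expect_true(vaf_rule(av_row(reads = 20L, depth = 100L)))          # exactly 20%
  expect_false(vaf_rule(av_row(reads = 19L, depth = 100L)))
  expect_message(res <- vaf_rule(av_row(reads = 0L, depth = 0L)), "zero depth")
  expect_false(res)
  # randomized agreement with the direct ratio
  set.seed(1)
  for (i in 1:50) {
    depth <- sample.int(200, 1)
    reads <- sample.int(depth, 1)
    expect_equal(vaf_rule(av_row(reads = reads, depth = depth)),
                 reads / depth >= 0.20)
  }
})

test_that("the strand rule gates on indels above 20 variant reads", {
  expect_false(strand_rule(av_row("del", reads = 30L, fwd = 2L, rev = 28L)))  # 6.7%
  expect_true(strand_rule(av_row("del", reads = 15L, fwd = 0L, rev = 15L)))   # gate not met
  expect_true(strand_rule(av_row("del", reads = 100L, fwd = 10L, rev = 90L))) # exactly 10%
  expect_false(strand_rule(av_row("del", reads = 100L, fwd = 9L, rev = 91L)))
  expect_true(strand_rule(av_row("snv", reads = 100L, fwd = 0L, rev = 100L))) # SNVs exempt
  expect_true(strand_rule(av_row("del", reads = 20L, fwd = 0L, rev = 20L)))   # exactly 20 exempt
  # unknown strand counts pass by default, with a log line
  x <- av_row("del", reads = 50L); x$reads_fwd <- NA_integer_; x$reads_rev <- NA_integer_
  expect_message(res <- strand_rule(x), "unknown strand")
  expect_true(res)
  # total-depth denominator mode
  y <- av_row("ins", depth = 300L, reads = 60L, fwd = 25L, rev = 35L)
  expect_true(strand_rule(y))                                  # 25/60 = 42%
  expect_false(strand_rule(y, denominator = "total_depth"))    # 25/300 = 8.3%
})

test_that("the distance rule removes only indels beyond 20 bp", {
  expect_false(distance_rule(av_row("del", exon_distance = 21)))
  expect_true(distance_rule(av_row("del", exon_distance = 20)))
  expect_true(distance_rule(av_row("snv", exon_distance = 50)))  # SNVs pass here
  expect_false(distance_rule(av_row("ins", exon_distance = Inf)))
})

test_that("filters partition the input, tag reasons, and are order-free", {
  vs <- rbind(av_row(),                                        # clean
              av_row(reads = 5L),                              # vaf
              av_row("del", reads = 30L, fwd = 1L, rev = 29L), # strand
              av_row("del", exon_distance = 30),               # distance
              av_row("del", reads = 30L, fwd = 1L, rev = 29L,
                     exon_distance = 30))                      # strand+distance
  res <- apply_artifact_filters(vs)
  expect_equal(nrow(res$retained) + nrow(res$removed), nrow(vs))
  expect_equal(nrow(res$retained), 1)
  expect_equal(res$removed$failed_rules,
               c("vaf", "strand", "distance", "strand,distance"))
  # every removed variant carries at least one failed rule
  expect_true(all(nzchar(res$removed$failed_rules)))
  # rules are independent predicates: verdicts equal the rule functions
  expect_equal(unname(res$verdicts[, "vaf"]), vaf_rule(vs))
  expect_equal(unname(res$verdicts[, "strand"]), suppressMessages(strand_rule(vs)))
  expect_equal(unname(res$verdicts[, "distance"]), distance_rule(vs))
  # no artifacts -> nothing removed
  expect_equal(nrow(apply_artifact_filters(av_row())$removed), 0)
})

test_that("filtering is monotone in the VAF threshold", {
  set.seed(2)
  vs <- do.call(rbind, lapply(1:40, function(i) {
    depth <- sample(20:200, 1)
    av_row(reads = sample.int(depth, 1), depth = depth)
  }))
  kept <- sapply(c(0.05, 0.10, 0.20, 0.30, 0.50), function(th)
    nrow(apply_artifact_filters(vs, panelsift_config(min_vaf = th))$retained))
  expect_true(all(diff(kept) <= 0))
})

test_that("injected artifacts are removed and true variants survive", {
  cfg <- small_cfg(seed = 4)
  design <- simulate_panel(cfg)
  co <- simulate_cohort(design, cfg)
  av <- annotate_calls(co$calls, design)
  res <- apply_artifact_filters(av)
  truth_of <- co$truth$label  # truth rows parallel the emitted calls
  verdict_removed <- rowSums(!res$verdicts) > 0
  expect_true(all(verdict_removed[truth_of == "artifact:strand"]))
  expect_true(all(verdict_removed[truth_of == "artifact:low_vaf"]))
  expect_true(all(verdict_removed[truth_of == "artifact:deep_intronic"]))
  # filter safety: no true exonic call with VAF >= 0.2 is removed
  safe <- truth_of == "true_variant" & av$vaf >= 0.2 & av$exon_distance == 0
  expect_false(any(verdict_removed[safe]))
})
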