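---
title: "Methods: coverage QC, artifact filtering and prioritization for targeted panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage QC, artifact filtering and prioritization for targeted panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelsift)
```

# The problem

Targeted capture panels for genetically heterogeneous recessive disorders —
Usher syndrome and nonsyndromic deafness are the motivating case — sequence
a few hundred exons plus 100 bp of flanking intron across 10–20 genes at
high depth. On pyrosequencing chemistry the raw per-patient difference file
contains thousands of called variants, the vast majority of which are
systematic artifacts: sub-threshold noise calls, and indel miscalls in and
around homopolymer runs, which are the dominant error mode of
flow-based base calling. The diagnostic question is how to shrink ~4700 raw
calls per patient to a reviewable handful without losing true mutations —
including the notorious frequent deletions that sit *inside* homopolymer
tracts and therefore look superficially like the error mode itself.

`panelsift` implements that triage as a pipeline of small, independently
testable operations, plus a seeded generator that emulates the data so the
pipeline's operating characteristics can be measured against ground truth.

# Coordinates and the capture model

BED input is 0-based half-open; variant positions are 1-based. A single
internal conversion owns the mapping and every distance is computed in
1-based space. A design is a set of labeled `TargetRegion`s with feature
`exon`, `utr` or `intronic_extension`; flanks are explicit regions rather
than implicit padding because two different windows matter: *capture*
queries (on/off-target) use the merged footprint of everything, while the
±20 bp *filter* window is anchored on exon edges only. The 100 bp capture
flanks do not count as exon for any rule.

Merging unites overlapping **and book-ended** intervals, since the design's
"different regions" count its contiguous footprint components. Distance to
exon is 0 on exon bases and counts base steps otherwise (a base immediately
adjacent to an exon is at distance 1); chromosomes without exons return
`Inf` rather than an error so off-panel calls annotate as `off_gene`.

# Coverage statistics

aDOC of a region is the sum of per-base depth over the region length; the
per-gene value is the length-weighted mean over its regions, identical to
the aDOC of the concatenated profile. Two on-target accountings are exposed
because they disagree on boundary-straddling reads: the base-level ratio
(bases in target / bases mapped) and the read-level on/overlap/off
categories. Regions with aDOC strictly below 40× are flagged, annotated
with whether GC exceeds 0.60; regions lacking a GC value get `NA`, never
`FALSE`. Whether "covered less than 40×" should use the mean or the minimum
per-base depth is ambiguous in the source workflow; the mean is the default
and a minimum-DOC mode is provided (`low_coverage_stat = "min"`).

# The three artifact rules

Each rule is a pure predicate over one annotated call; the rules commute
and the composite verdict records every rule failed.

* **Allele fraction** — fail iff variant reads / total depth < 0.20.
  Exactly 20% passes: the wording is "less than". Zero-depth records fail
  and are logged as degenerate. The denominator is site depth, not amplicon
  reads.
* **Strand disequilibrium** — indels only; fail iff variant reads > 20 and
  the minor strand carries < 10% of the variant-supporting evidence.
  The denominator is variant-supporting reads: strand bias of the
  *evidence* is the artifact signature (a `total_depth` mode is available).
  "Coverage > 20 reads" is read as the variant-read count — the sequences
  exhibiting the disequilibrium; indels at or below 20 reads are exempt by
  the stated rule. Calls with unknown strand counts (e.g. from VCFs without
  strand-resolved AD) pass by default with a log line: absent evidence
  cannot fail a test.
* **Exon distance** — indels only; fail iff more than ±20 intronic bases
  from the nearest exon. Deep-intronic SNVs deliberately pass here: they
  are removed later at prioritization, which is where the positional rule
  applies to every variant type.

# Prioritization

Whitelisted known-pathogenic variants are kept unconditionally — this is
what protects frequent founder mutations, which would otherwise be masked
by their own cohort recurrence. All other variants are kept iff found in
fewer than five DNAs (`cohort_count <= 4`) *and* exonic or within 20 bp of
an exon. One DNA counts once toward the five regardless of zygosity or
duplicated rows; the patient's own DNA is included in the count. The
masking index can be rebuilt per run or frozen from a reference cohort, the
mode used when new patients are screened against an established background.

# Classification

The evidence-combination logic of UV grading differs between laboratories
and is under-determined by published class lists alone, so the classifier
is an ordered first-match rule table over an 8-field evidence vector, fully
overridable via YAML and shipped with defaults that reproduce the
unambiguous published anchor rows: predicted PTC → Pathogenic regardless of
all else; deleterious minigene result, or near-abolished splice site
(score change ≥ 0.8) → UV4; control allele frequency above the polymorphism
threshold (0.01) → Neutral; damaging missense (≥ 0.8) → UV3, escalated to
UV4 with patient-cohort enrichment; intermediate predictions → UV2; benign
predictions or low-level presence in controls → UV1; a vector matching no
rule defaults to UV2 (some evidence, nothing conclusive). The "high"
frequency (0.01) and "damaging" score (0.8) cutoffs are configuration
values: the published material states none, and these sit at the
conventional polymorphism threshold and at the upper tercile of in silico
damage scores respectively. Rows of the source class lists whose
contributor combinations map to different classes in different rows (the
printed evidence does not disambiguate them) are excluded from the mandatory
fixture and listed with reasons in the fixture file. In silico scores are
inputs, never computed: missense/splice predictors are upstream tools whose
outputs enter as opaque numbers in [0, 1].

An unknown field never satisfies a predicate, so severity is monotone under
added evidence of the PTC kind, and a vector that is entirely unknown is an
error rather than a silent default.

# What the generator emulates — and what it does not

The generator works at the call/coverage level, not the read level:
sequences, flowgrams and alignment are never simulated. This is sufficient
because every implemented formula consumes counts, positions and intervals;
read-level simulation would add cost without exercising any additional code
path. Consequences: homopolymer context is an annotation (tracts placed in
exons at ~1.5/kb) rather than an emergent property of sequence; "misaligned"
validation failures are labels, not alignments; and real data phenomena
such as mappability, duplicate reads, batch effects between runs, or
allele-fraction distortion by capture bias are absent. Passing the
truth-recovery tests therefore shows the *rules* are implemented exactly,
not that the thresholds are optimal on real sequencing data.

Default conditions (chosen once, to mirror the emulated study):

* design: 19 genes, 634 exons, 100 bp flanks, gaps drawn so the footprint
  unites into exactly 535 merged regions; exon lengths log-normal
  (median 170 bp, clipped to [60, 2000]).
* coverage: negative-binomial per-base depths (`size = 8`), design-wide
  mean 77×, GC factor `max(0, 1 - 5.5 (gc - 0.5)+)` renormalized so the
  design-wide average stays at the configured mean; unit GC is
  `0.32 + 0.48 Beta(2, 5)`, a right tail that puts ~5% of units above 0.60.
  The slope is set so that units beyond the 0.60 GC flag threshold fall
  below the 40× flag line.
* cohort: 47 patients; per patient, Poisson(7) rare true variants (85%
  exonic / 15% within 20 bp of an exon, 20% indels, het/hom allele
  fractions 0.5/1.0 with binomial read sampling), 638 shared polymorphism
  sites carried with probability 0.55 each (~351 calls/patient, virtually
  all in ≥ 5 DNAs and hence masked), and artifacts at Poisson rates
  4000 (low VAF), 200 (strand-biased homopolymer indels), 116
  (deep-intronic indels). Expected raw load ≈ 4674 calls/patient with
  92.3% removed by the first filter and ≈ 8 candidates surviving masking
  (7 rare + ~1.1 from the two whitelisted shared sites, the stand-ins for
  frequent known mutations).

## Truth-label guarantees

The acceptance-style tests assert 100%/0% recovery rates, which is only
honest if the injection distributions sit strictly inside the corresponding
decision regions. They do: low-VAF noise reads are capped at
`ceil(0.2 depth) - 1` with depth ≥ 6, so the observed fraction is strictly
below 0.20; strand artifacts draw 21–60 variant reads with minor-strand
count `floor(u · reads)`, `u < 0.095`, strictly below the 10% line;
deep-intronic positions are verified against `distance_to_exon` (> 20) at
generation time, because a flank of one exon can overlap the next exon when
footprints merge; true calls are resampled into the detection regime
(observed VAF ≥ 0.25; minor strand ≥ 15% of evidence whenever variant reads
exceed the strand gate). A real caller's detection thresholds impose the
same conditioning, which is why emitted true calls cannot sit in the
rejection regions. The guarantees are thus constructional and hold for
every seed, not tuned to one.

# Numerical and degenerate-input choices

* All thresholds live in one `panelsift_config()` block defaulting to the
  workflow's stated values (0.20, 20 reads, 0.10, 20 bp, 4 DNAs, 40×,
  0.60); every boundary is strict exactly as worded.
* Invalid call records are rejected per record with a reason and the run
  continues; file-level syntax errors abort.
* Left-normalization of indels shifts to the leftmost equivalent placement
  (verified against exhaustive enumeration); when the supplied context is
  too short the call is returned unchanged and flagged, never silently
  half-shifted.
* Zero-length regions, zero mapped bases and all-unknown evidence vectors
  are errors; zero-depth calls fail the VAF rule as degenerate.
* Ties and ordering: regions sort by (chrom, start); flagged regions
  ascend by the flag statistic; rule tables evaluate in order with
  first-match-wins and duplicate predicates warn.

# Problem sizes used in the shipped checks

Unit and property tests run on small randomized designs (hundreds of
instances against per-base brute-force oracles). The end-to-end checks use
the full default conditions: one 47-patient cohort (~220,000 calls) for
truth recovery, one 687-variant validation set with 13 constructed failures
(6 homopolymer, 4 misaligned, 3 low coverage → sensitivity 674/687 = 98.1%)
for the detection-rate computation, and the 60-row classification fixture.
These sizes keep a complete run in well under a minute of simulation plus a
few seconds of pipeline per cohort on one core.

# Known limitations

* The classifier defaults encode one laboratory's grading conventions
  reverse-engineered from class lists; they are a starting point to
  override, not a standard (and deliberately not ACMG/AMP).
* Whitelist matching is by normalized genomic key (with an optional
  gene + cDNA-label fallback); HGVS nomenclature generation is out of
  scope, so whitelists authored in cDNA coordinates must carry genomic
  coordinates too.
* VCF ingest takes the first sample's AD-style depths and leaves strand
  counts unknown, which exempts such calls from the strand rule by design.
* Population-database frequency filtering is intentionally absent from
  masking: frequency evidence enters at classification, as evidence.
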