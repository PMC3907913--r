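#' Variant classes, in increasing severity
#'
#' `Neutral < UV1 < UV2 < UV3 < UV4 < Pathogenic`. UV1 is the least and UV4
#' the most likely disease-causing grade of a variant of unknown clinical
#' significance.
#' @export
VARIANT_CLASSES <- c("Neutral", "UV1", "UV2", "UV3", "UV4", "Pathogenic")

EVIDENCE_FIELDS <- c("ptc", "control_af", "patient_af", "missense_score",
                     "splice_delta", "minigene_result",
                     "segregation_consistent", "genotype_context")

#' Evidence vector for variant classification
#'
#' Quantitative and categorical evidence items feeding the rule table; `NA`
#' means unknown. These mirror the evidence lines a diagnostic laboratory
#' combines: predicted premature termination codon, allele frequencies in
#' controls/public databases and in patients, in silico missense and
#' splice-impact scores, an ex vivo minigene splicing result, familial
#' segregation, and the genotype context (e.g. in trans with a pathogenic
#' allele).
#'
#' @param ptc logical: protein translation predicts a premature termination
#'   codon (nonsense, frameshift, canonical splice leading to PTC).
#' @param control_af allele frequency in controls / public databases.
#' @param patient_af allele frequency in the patient cohort.
#' @param missense_score in silico missense damage score in `[0, 1]`
#'   (higher = more damaging).
#' @param splice_delta in silico splice-site strength change in `[0, 1]`
#'   (higher = stronger predicted splicing impact).
#' @param minigene_result `"deleterious"`, `"neutral"` or `NA`.
#' @param segregation_consistent `"yes"`, `"no"` or `NA`.
#' @param genotype_context `"supports"`, `"conflicts"` or `NA`.
#' @return named list of class `evidence_vector`.
#' @export
evidence_vector <- function(ptc = NA, control_af = NA_real_,
                            patient_af = NA_real_,
                            missense_score = NA_real_,
                            splice_delta = NA_real_,
                            minigene_result = NA_character_,
                            segregation_consistent = NA_character_,
                            genotype_context = NA_character_) {
  ev <- list(ptc = as.logical(ptc), control_af = as.numeric(control_af),
             patient_af = as.numeric(patient_af),
             missense_score = as.numeric(missense_score),
             splice_delta = as.numeric(splice_delta),
             minigene_result = as.character(minigene_result),
             segregation_consistent = as.character(segregation_consistent),
             genotype_context = as.character(genotype_context))
  chk <- function(x, lo, hi) all(is.na(x) | (x >= lo & x <= hi))
  stopifnot(chk(ev$control_af, 0, 1), chk(ev$patient_af, 0, 1),
            chk(ev$missense_score, 0, 1))
  if (!is.na(ev$minigene_result) &&
      !ev$minigene_result %in% c("deleterious", "neutral"))
    stop("minigene_result must be deleterious/neutral/NA")
  structure(ev, class = "evidence_vector")
}

#' The default classification rule table
#'
#' An ordered first-match rule table combining the evidence lines. Anchors:
#' a predicted PTC is Pathogenic; a deleterious minigene result, or a
#' near-abolished splice site, is UV4; control allele frequency above the
#' polymorphism threshold (default 0.01) is Neutral; damaging missense
#' predictions (score >= 0.8) with or without patient-cohort enrichment give
#' UV3/UV4; intermediate predictions give UV2; benign predictions or low-level
#' presence in controls give UV1; evidence matching no rule defaults to UV2.
#'
#' @param high_af control-frequency threshold above which a variant is a
#'   polymorphism (Neutral), default 0.01.
#' @param damaging_missense missense score at or above which predictions are
#'   damaging, default 0.8.
#' @return a `class_rules` object (see [load_rules()]).
#' @export
default_rules <- function(high_af = 0.01, damaging_missense = 0.8) {
  rule <- function(class, ...) list(when = list(...), class = class)
  new_class_rules(list(
    rule("Pathogenic", ptc = list(eq = TRUE)),
    rule("UV4", minigene_result = list(eq = "deleterious")),
    rule("UV4", splice_delta = list(ge = 0.8)),
    rule("Neutral", control_af = list(gt = high_af)),
    rule("UV4", patient_af = list(gt = 0.01),
         missense_score = list(ge = damaging_missense)),
    rule("UV3", missense_score = list(ge = damaging_missense)),
    rule("UV3", patient_af = list(gt = 0.01)),
    rule("UV2", splice_delta = list(ge = 0.3)),
    rule("UV2", missense_score = list(ge = 0.5)),
    rule("UV1", missense_score = list(lt = 0.5)),
    rule("UV1", splice_delta = list(lt = 0.3)),
    rule("UV1", control_af = list(gt = 0.001))
  ), default = "UV2")
}

new_class_rules <- function(rules, default) {
  if (is.null(default)) stop("rule table must declare a default class")
  if (!default %in% VARIANT_CLASSES) stop("unknown default class: ", default)
  for (r in rules) {
    if (!r$class %in% VARIANT_CLASSES) stop("unknown class: ", r$class)
    bad <- setdiff(names(r$when), EVIDENCE_FIELDS)
    if (length(bad)) stop("rule predicate on unknown field(s): ",
                          paste(bad, collapse = ", "))
    for (cond in r$when) {
      ops <- setdiff(names(cond), c("eq", "ne", "gt", "ge", "lt", "le", "in"))
      if (length(ops)) stop("unknown operator(s): ", paste(ops, collapse = ", "))
    }
  }
  sig <- vapply(rules, function(r)
    paste(deparse(r$when, width.cutoff = 500), collapse = ""), "")
  if (anyDuplicated(sig))
    warning("duplicate rule predicate(s); first match wins")
  unconditional <- which(lengths(lapply(rules, `[[`, "when")) == 0)
  if (length(unconditional) && min(unconditional) < length(rules))
    warning("rule(s) after an unconditional rule are unreachable")
  structure(list(rules = rules, default = default), class = "class_rules")
}

eval_cond <- function(value, cond) {
  if (length(value) == 0 || is.na(value)) return(FALSE)  # unknown never matches
  for (op in names(cond)) {
    target <- cond[[op]]
    ok <- switch(op,
                 eq = value == target, ne = value != target,
                 gt = value > target, ge = value >= target,
                 lt = value < target, le = value <= target,
                 `in` = value %in% target)
    if (!isTRUE(ok)) return(FALSE)
  }
  TRUE
}

#' Classify an evidence vector
#'
#' First-match evaluation over the ordered rule table; an unknown (`NA`)
#' field never satisfies a predicate. A vector with every field unknown is an
#' error. The result is deterministic and total: every valid vector maps to
#' exactly one class.
#'
#' @param ev an [evidence_vector()].
#' @param rules a `class_rules` table; defaults to [default_rules()].
#' @return a single class from [VARIANT_CLASSES].
#' @export
#' @examples
#' classify(evidence_vector(ptc = TRUE))                         # "Pathogenic"
#' classify(evidence_vector(minigene_result = "deleterious"))    # "UV4"
#' classify(evidence_vector(control_af = 0.05))                  # "Neutral"
classify <- function(ev, rules = default_rules()) {
  stopifnot(inherits(rules, "class_rules"))
  if (!inherits(ev, "evidence_vector")) ev <- do.call(evidence_vector, as.list(ev))
  if (all(vapply(ev, function(x) length(x) == 0 || is.na(x), TRUE)))
    stop("cannot classify an all-unknown evidence vector")
  for (r in rules$rules) {
    hit <- all(vapply(names(r$when),
                      function(f) eval_cond(ev[[f]], r$when[[f]]), TRUE))
    if (hit) return(r$class)
  }
  rules$default
}

#' Classify a table of evidence vectors
#'
#' @param evidence data frame whose columns are evidence fields (one row per
#'   variant; missing columns are treated as unknown).
#' @param rules a `class_rules` table.
#' @return character vector of classes.
#' @export
classify_all <- function(evidence, rules = default_rules()) {
  vapply(seq_len(nrow(evidence)), function(i) {
    args <- as.list(evidence[i, intersect(names(evidence), EVIDENCE_FIELDS),
                             drop = FALSE])
    classify(do.call(evidence_vector, args), rules)
  }, "")
}

#' Load a classification rule table from YAML
#'
#' Format: `default: <class>` plus `rules:`, an ordered list of
#' `{when: {field: {op: value, ...}, ...}, class: <class>}` entries with
#' operators eq/ne/gt/ge/lt/le/in. A table without a default class aborts
#' (the table would not be total); duplicate predicates warn (first match
#' wins); rules after an unconditional rule are reported unreachable.
#'
#' @param path YAML file.
#' @return a `class_rules` object.
#' @export
load_rules <- function(path) {
  if (!file.exists(path)) stop("rules file not found: ", path)
  y <- yaml::read_yaml(path)
  rules <- lapply(y$rules, function(r) {
    list(when = lapply(r$when %||% list(), as.list), class = r$class)
  })
  new_class_rules(rules, default = y$default)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a rule table to YAML
#'
#' @param rules a `class_rules` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  yaml::write_yaml(list(default = rules$default, rules = rules$rules), path)
  invisible(path)
}

#' Compare two classes on the severity scale
#'
#' @param a,b class labels.
#' @return integer sign: negative when `a` is less severe than `b`.
#' @export
class_severity_cmp <- function(a, b) {
  match(a, VARIANT_CLASSES) - match(b, VARIANT_CLASSES)
}
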