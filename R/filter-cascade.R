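#' Somatic variant filter rules
#'
#' Each rule is a vectorised predicate over a variant table and returns
#' `TRUE` where the rule *fails* (filters out) the variant. They are
#' combined, all-evaluated, by [run_filter_cascade()]; exposing them
#' individually makes the cascade auditable rule by rule.
#'
#' The rules, with their defaults:
#' * `pon_filter()`: fail if the variant key (chrom, pos, ref, alt) was seen
#'   in at least `min_normals` (2) panel normals.
#' * `read_support_filter()`: fail if tumor alternate reads < `min_alt` (3),
#'   or if tumor alternate reads < `confirm_alt` (8) while the matched blood
#'   sample shows more than `max_blood_alt` (1) alternate reads. Without
#'   blood counts only the first clause applies.
#' * `vaf_filter()`: fail if the tumor variant allele fraction is strictly
#'   below `min_vaf` (5%); exactly 5% passes.
#' * `population_filter()`: fail if the population minor-allele frequency is
#'   `max_maf` (1%) or greater in either the 1000 Genomes or ESP column;
#'   unknown frequencies pass.
#' * `dbsnp_filter()`: fail dbSNP-listed variants unless any exception
#'   holds — dbSNP population MAF < 1% or unknown, a single mapping to the
#'   reference assembly, or a "clinically associated" tag.
#' * `shared_indel_filter()`: a cohort-level rule; fail every occurrence of
#'   an insertion/deletion/non-frameshift-MNV key found in at least
#'   `min_unmatched` (2) samples without matched germline and in no matched
#'   sample (a likely germline variant).
#'
#' @param variants Variant tibble; see [simulate_variant_cohort()] for the
#'   column schema.
#' @param pon Panel-of-normals tibble (chrom, pos, ref, alt, n_normals).
#' @param min_normals,min_alt,confirm_alt,max_blood_alt,min_vaf,max_maf,min_unmatched
#'   Rule thresholds as above.
#' @return Logical vector, `TRUE` where the rule fails the variant.
#' @name filter_rules
NULL

#' @rdname filter_rules
#' @export
pon_filter <- function(variants, pon, min_normals = 2) {
  assert_columns(variants, variant_key_cols)
  assert_columns(pon, c(variant_key_cols, "n_normals"))
  hot <- pon$n_normals[match(variant_key(variants), variant_key(pon))]
  !is.na(hot) & hot >= min_normals
}

#' @rdname filter_rules
#' @export
read_support_filter <- function(variants, min_alt = 3, confirm_alt = 8,
                                max_blood_alt = 1) {
  assert_columns(variants, c("tumor_alt_reads", "blood_alt_reads"))
  if (any(variants$tumor_alt_reads < 0, na.rm = TRUE) ||
    any(variants$blood_alt_reads < 0, na.rm = TRUE)) {
    abort("negative read counts")
  }
  low <- variants$tumor_alt_reads < min_alt
  blood <- !is.na(variants$blood_alt_reads) &
    variants$tumor_alt_reads < confirm_alt &
    variants$blood_alt_reads > max_blood_alt
  low | blood
}

#' @rdname filter_rules
#' @export
vaf_filter <- function(variants, min_vaf = 0.05) {
  assert_columns(variants, "tumor_vaf")
  variants$tumor_vaf < min_vaf
}

#' @rdname filter_rules
#' @export
population_filter <- function(variants, max_maf = 0.01) {
  assert_columns(variants, c("pop_maf_1000g", "pop_maf_esp"))
  (!is.na(variants$pop_maf_1000g) & variants$pop_maf_1000g >= max_maf) |
    (!is.na(variants$pop_maf_esp) & variants$pop_maf_esp >= max_maf)
}

#' @rdname filter_rules
#' @export
dbsnp_filter <- function(variants, max_maf = 0.01) {
  assert_columns(variants, c(
    "in_dbsnp", "dbsnp_pop_maf", "dbsnp_single_mapping", "dbsnp_clinical_tag"
  ))
  exception <- (is.na(variants$dbsnp_pop_maf) | variants$dbsnp_pop_maf < max_maf) |
    (!is.na(variants$dbsnp_single_mapping) & variants$dbsnp_single_mapping) |
    variants$dbsnp_clinical_tag
  variants$in_dbsnp & !exception
}

#' @rdname filter_rules
#' @export
shared_indel_filter <- function(variants, min_unmatched = 2) {
  assert_columns(variants, c(
    "sample_id", variant_key_cols, "variant_type", "matched_normal_available"
  ))
  key <- variant_key(variants)
  eligible <- variants$variant_type %in%
    c("insertion", "deletion", "MNV_nonframeshift")
  df <- tibble(
    key = key[eligible],
    matched = variants$matched_normal_available[eligible],
    sample_id = variants$sample_id[eligible]
  ) |>
    distinct() |>
    group_by(.data$key) |>
    summarise(
      n_unmatched = sum(!.data$matched),
      n_matched = sum(.data$matched),
      .groups = "drop"
    )
  bad_keys <- df$key[df$n_unmatched >= min_unmatched & df$n_matched == 0]
  eligible & key %in% bad_keys
}

#' Run the full somatic filter cascade over a cohort
#'
#' Applies every rule in [filter_rules] order (panel of normals, read
#' support, allele fraction, population frequency, dbSNP exception logic,
#' shared indel). All rules are evaluated for every variant — there is no
#' short-circuiting — so `failed_rules` is a complete audit trail; the kept
#' set is unaffected by evaluation order because the rules are independent
#' predicates (the shared-indel rule depends on the cohort, not on other
#' rule outcomes).
#'
#' @inheritParams filter_rules
#' @return A tibble of class `rb_filter_result`: the input columns plus
#'   `failed_rules` (list-column of character rule ids) and `kept`
#'   (`TRUE` iff no rule failed). [tidy()] gives per-rule failure counts,
#'   [glance()] a one-row summary, and [kept_variants()] the kept table.
#' @examples
#' sim <- simulate_variant_cohort(cohort_sim_config(n_tumors = 6, seed = 1))
#' res <- run_filter_cascade(sim$variants, sim$pon)
#' glance(res)
#' @export
run_filter_cascade <- function(variants, pon,
                               min_normals = 2, min_alt = 3, confirm_alt = 8,
                               max_blood_alt = 1, min_vaf = 0.05,
                               max_maf = 0.01, min_unmatched = 2) {
  rules <- list(
    panel_of_normals = pon_filter(variants, pon, min_normals),
    read_support = read_support_filter(variants, min_alt, confirm_alt, max_blood_alt),
    vaf = vaf_filter(variants, min_vaf),
    population = population_filter(variants, max_maf),
    dbsnp = dbsnp_filter(variants, max_maf),
    shared_indel = shared_indel_filter(variants, min_unmatched)
  )
  fail_mat <- do.call(cbind, rules)
  rule_names <- names(rules)
  failed_rules <- apply(fail_mat, 1, function(f) rule_names[f], simplify = FALSE)
  if (nrow(variants) == 0) failed_rules <- list()
  out <- variants
  out$failed_rules <- failed_rules
  out$kept <- !apply(fail_mat, 1, any) |> as.logical()
  if (nrow(variants) == 0) out$kept <- logical()
  class(out) <- c("rb_filter_result", class(out))
  out
}

#' Extract the kept variant table from a cascade result
#' @param result An `rb_filter_result` from [run_filter_cascade()].
#' @return The kept rows, without the bookkeeping columns.
#' @export
kept_variants <- function(result) {
  result |>
    filter(.data$kept) |>
    select(-"failed_rules", -"kept") |>
    as_tibble()
}
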