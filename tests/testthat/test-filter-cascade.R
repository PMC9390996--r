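test_that("panel-of-normals rule fails keys seen in two or more normals", {
  v <- dplyr::bind_rows(
    manual_variant(pos = 1L), # in panel twice
    manual_variant(pos = 2L), # in panel once
    manual_variant(pos = 3L) # absent
  )
  pon <- tibble::tibble(
    chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "T", n_normals = c(2L, 1L)
  )
  expect_equal(pon_filter(v, pon), c(TRUE, FALSE, FALSE))
})

test_that("read-support rule applies both clauses, blood clause only when matched", {
  cases <- dplyr::bind_rows(
    manual_variant(tumor_alt_reads = 2L, blood_alt_reads = 0L), # <3: fail
    manual_variant(tumor_alt_reads = 7L, blood_alt_reads = 2L), # <8 & blood>1: fail
    manual_variant(tumor_alt_reads = 7L, blood_alt_reads = 0L), # pass
    manual_variant(
      tumor_alt_reads = 3L, blood_alt_reads = NA_integer_,
      matched_normal_available = FALSE
    ), # unmatched: pass
    manual_variant(tumor_alt_reads = 8L, blood_alt_reads = 5L) # >=8: pass
  )
  expect_equal(read_support_filter(cases), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(
    read_support_filter(manual_variant(tumor_alt_reads = -1L)),
    "negative"
  )
})

test_that("allele-fraction cutoff is strict at 5%", {
  v <- dplyr::bind_rows(
    manual_variant(tumor_vaf = 0.04),
    manual_variant(tumor_vaf = 0.05),
    manual_variant(tumor_vaf = 0.50)
  )
  expect_equal(vaf_filter(v), c(TRUE, FALSE, FALSE))
})

test_that("population rule fails at 1% or greater in either study, unknown passes", {
  v <- dplyr::bind_rows(
    manual_variant(pop_maf_1000g = 0.02, pop_maf_esp = NA_real_),
    manual_variant(pop_maf_1000g = 0.009, pop_maf_esp = 0.009),
    manual_variant(pop_maf_1000g = NA_real_, pop_maf_esp = NA_real_),
    manual_variant(pop_maf_1000g = NA_real_, pop_maf_esp = 0.01)
  )
  expect_equal(population_filter(v), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("dbSNP rule honours the three exceptions with OR semantics", {
  v <- dplyr::bind_rows(
    manual_variant(in_dbsnp = TRUE, dbsnp_pop_maf = 0.05), # no exception: fail
    manual_variant(in_dbsnp = TRUE, dbsnp_pop_maf = NA_real_), # unknown MAF: pass
    manual_variant(in_dbsnp = TRUE, dbsnp_pop_maf = 0.005), # rare: pass
    manual_variant(
      in_dbsnp = TRUE, dbsnp_pop_maf = 0.05,
      dbsnp_single_mapping = TRUE
    ), # single mapping: pass
    manual_variant(
      in_dbsnp = TRUE, dbsnp_pop_maf = 0.05,
      dbsnp_clinical_tag = TRUE
    ), # clinical tag: pass
    manual_variant(in_dbsnp = FALSE) # not listed: pass
  )
  expect_equal(dbsnp_filter(v), c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
})

test_that("shared-indel rule targets indel/MNV keys private to unmatched samples", {
  base <- function(sample, matched, type = "deletion", pos = 500L) {
    manual_variant(
      sample_id = sample, matched_normal_available = matched,
      variant_type = type, pos = pos,
      blood_alt_reads = if (matched) 0L else NA_integer_
    )
  }
  # same deletion in two unmatched samples, no matched carrier: fail both
  v1 <- dplyr::bind_rows(base("U1", FALSE), base("U2", FALSE))
  expect_equal(shared_indel_filter(v1), c(TRUE, TRUE))
  # a matched carrier rescues every occurrence
  v2 <- dplyr::bind_rows(v1, base("M1", TRUE))
  expect_equal(shared_indel_filter(v2), c(FALSE, FALSE, FALSE))
  # SNVs are outside the rule's type set
  v3 <- dplyr::bind_rows(
    base("U1", FALSE, type = "SNV"), base("U2", FALSE, type = "SNV"),
    base("U3", FALSE, type = "SNV")
  )
  expect_equal(shared_indel_filter(v3), c(FALSE, FALSE, FALSE))
  # non-frameshift MNVs are inside it
  v4 <- dplyr::bind_rows(
    base("U1", FALSE, type = "MNV_nonframeshift"),
    base("U2", FALSE, type = "MNV_nonframeshift")
  )
  expect_equal(shared_indel_filter(v4), c(TRUE, TRUE))
})

test_that("cascade handles the empty cohort and records complete audit trails", {
  sim <- simulate_variant_cohort(
    cohort_sim_config(n_tumors = 0, somatic_rate = 0, germline_rate = 0, artifact_rate = 0)
  )
  res <- run_filter_cascade(sim$variants, sim$pon)
  expect_equal(nrow(res), 0)
  expect_true(all(c("failed_rules", "kept") %in% names(res)))

  v <- manual_variant(
    tumor_alt_reads = 1L, tumor_vaf = 0.01, in_dbsnp = TRUE, dbsnp_pop_maf = 0.2
  )
  res1 <- run_filter_cascade(v, empty_pon())
  expect_false(res1$kept)
  expect_setequal(res1$failed_rules[[1]], c("read_support", "vaf", "dbsnp"))
  expect_true(all(lengths(res1$failed_rules) > 0 | res1$kept))
})

test_that("cascade equals the naive rule-by-rule oracle on simulated cohorts", {
  for (seed in c(11, 12, 13)) {
    sim <- simulate_variant_cohort(cohort_sim_config(n_tumors = 15, seed = seed))
    res <- run_filter_cascade(sim$variants, sim$pon)
    expect_equal(res$kept, oracle_cascade_kept(sim$variants, sim$pon))
  }
})

test_that("cascade is idempotent on its own kept table", {
  sim <- simulate_variant_cohort(cohort_sim_config(n_tumors = 12, seed = 21))
  kept1 <- kept_variants(run_filter_cascade(sim$variants, sim$pon))
  kept2 <- kept_variants(run_filter_cascade(kept1, sim$pon))
  expect_equal(kept2, kept1)
})

test_that("raising alt-read or VAF thresholds never grows the kept set", {
  sim <- simulate_variant_cohort(cohort_sim_config(n_tumors = 12, seed = 31))
  key <- function(res) {
    with(dplyr::filter(res, kept), paste(sample_id, chrom, pos, ref, alt))
  }
  base <- key(run_filter_cascade(sim$variants, sim$pon))
  for (args in list(
    list(min_alt = 5), list(min_alt = 10), list(min_vaf = 0.1), list(min_vaf = 0.2)
  )) {
    stricter <- key(do.call(
      run_filter_cascade, c(list(sim$variants, sim$pon), args)
    ))
    expect_true(all(stricter %in% base))
  }
})

test_that("cascade recovers truth classes at the rates the generative model implies", {
  # somatic variants fail the cascade only through rare tail events (VAF
  # below 5%, dbSNP collisions); germline variants are caught by the panel,
  # population frequency or blood reads; artifacts mostly fall below the
  # read-support or allele-fraction floors
  sim <- simulate_variant_cohort(cohort_sim_config(n_tumors = 40, seed = 41))
  res <- run_filter_cascade(sim$variants, sim$pon)
  by_class <- split(res$kept, res$truth_class)
  expect_gt(mean(by_class$somatic), 0.95)
  expect_lt(mean(by_class$germline), 0.05)
  expect_lt(mean(by_class$artifact), 0.30)
})

test_that("filter result tidiers summarise rules and totals", {
  sim <- simulate_variant_cohort(cohort_sim_config(n_tumors = 5, seed = 51))
  res <- run_filter_cascade(sim$variants, sim$pon)
  td <- tidy(res)
  expect_equal(td$n_failed, vapply(
    td$rule,
    function(r) sum(vapply(res$failed_rules, function(f) r %in% f, logical(1))),
    integer(1)
  ), ignore_attr = TRUE)
  gl <- glance(res)
  expect_equal(gl$n_kept + gl$n_filtered, gl$n_input)
  expect_equal(nrow(kept_variants(res)), gl$n_kept)
})
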