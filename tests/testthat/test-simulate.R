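test_that("zero rates give an empty cohort and empty panel", {
  cfg <- cohort_sim_config(
    n_tumors = 5, somatic_rate = 0, germline_rate = 0, artifact_rate = 0
  )
  sim <- simulate_variant_cohort(cfg)
  expect_equal(nrow(sim$variants), 0)
  expect_equal(nrow(sim$pon), 0)
})

test_that("identical seeds reproduce the cohort exactly", {
  cfg <- cohort_sim_config(n_tumors = 6, seed = 99)
  expect_identical(simulate_variant_cohort(cfg), simulate_variant_cohort(cfg))
  s1 <- simulate_arm_segments(3, noise_sd = 0.05, seed = 7)
  s2 <- simulate_arm_segments(3, noise_sd = 0.05, seed = 7)
  expect_identical(s1, s2)
  f1 <- simulate_integration_fixture(30, 60, seed = 5)
  f2 <- simulate_integration_fixture(30, 60, seed = 5)
  expect_identical(f1, f2)
  m1 <- simulate_count_matrix(40, 200, seed = 3)
  m2 <- simulate_count_matrix(40, 200, seed = 3)
  expect_identical(m1, m2)
})

test_that("invalid configuration is rejected", {
  expect_error(cohort_sim_config(somatic_rate = -1), "non-negative")
  expect_error(cohort_sim_config(frac_matched = 1.5), "\\[0, 1\\]")
  expect_error(simulate_variant_cohort(list()), "cohort_sim_config")
})

test_that("somatic burden matches its Poisson rate within Monte-Carlo error", {
  cfg <- cohort_sim_config(n_tumors = 20, somatic_rate = 10, seed = 17)
  sim <- simulate_variant_cohort(cfg)
  n_somatic <- sum(sim$variants$truth_class == "somatic")
  se <- sqrt(10 / 20)
  expect_lt(abs(n_somatic / 20 - 10), 3 * se)
})

test_that("cohort variants satisfy their consuming-type invariants", {
  sim <- simulate_variant_cohort(cohort_sim_config(n_tumors = 8, seed = 23))
  v <- sim$variants
  expect_true(all(v$tumor_alt_reads >= 0))
  expect_true(all(v$tumor_vaf >= 0 & v$tumor_vaf <= 1))
  expect_true(all(is.na(v$blood_alt_reads) == !v$matched_normal_available |
    v$matched_normal_available))
  expect_false(any(is.na(v$blood_alt_reads) & v$matched_normal_available))
  expect_true(all(v$truth_class %in% c("somatic", "germline", "artifact")))
  # keys unique per sample
  expect_equal(anyDuplicated(paste(v$sample_id, v$chrom, v$pos, v$ref, v$alt)), 0L)
  # panel counts at least 1; somatic keys never in the panel
  expect_true(all(sim$pon$n_normals >= 1))
  som <- v[v$truth_class == "somatic", ]
  expect_equal(
    length(intersect(
      paste(som$chrom, som$pos, som$ref, som$alt),
      paste(sim$pon$chrom, sim$pon$pos, sim$pon$ref, sim$pon$alt)
    )), 0L
  )
})

test_that("truth-class counts fit their Poisson model across many seeds", {
  # pooled per-sample somatic counts over 100 seeded cohorts vs Poisson(5)
  rate <- 5
  counts <- unlist(lapply(1:100, function(s) {
    sim <- simulate_variant_cohort(cohort_sim_config(
      n_tumors = 2, somatic_rate = rate, germline_rate = 0, artifact_rate = 0,
      seed = s
    ))
    tab <- table(factor(sim$variants$sample_id, levels = c("RB001", "RB002")))
    as.integer(tab)
  }))
  breaks <- c(-0.5, seq(1.5, 9.5, 1), Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(c(0, ppois(c(1:9), rate), 1))
  gof <- suppressWarnings(chisq.test(as.integer(obs), p = pr))
  expect_gt(gof$p.value, 0.001)
})

test_that("noiseless arm simulation reproduces planted ratios exactly", {
  ev <- tibble::tibble(sample_id = "S01", arm = "1q", log2_ratio = 0.3)
  sim <- simulate_arm_segments(2, ev, noise_sd = 0, seed = 5)
  arms <- rb_arms()
  q1 <- arms[arms$arm == "1q", ]
  on_1q <- sim$segments$sample_id == "S01" & sim$segments$chrom == "chr1" &
    sim$segments$start >= q1$start
  expect_true(all(sim$segments$log2_ratio[on_1q] == 0.3))
  expect_true(all(sim$segments$log2_ratio[!on_1q] == 0))
  none <- simulate_arm_segments(2, noise_sd = 0, seed = 5)
  expect_true(all(none$segments$log2_ratio == 0))
  # segments tile each arm without overlap
  cover <- none$segments |>
    dplyr::left_join(dplyr::rename(arms, arm_start = start, arm_end = end),
      by = "chrom", relationship = "many-to-many"
    ) |>
    dplyr::filter(start >= arm_start, end <= arm_end) |>
    dplyr::group_by(sample_id, arm) |>
    dplyr::summarise(
      width = sum(end - start), arm_width = arm_end[1] - arm_start[1],
      .groups = "drop"
    )
  expect_true(all(cover$width == cover$arm_width))
})

test_that("unknown arm names are rejected", {
  expect_error(
    simulate_arm_segments(
      2, tibble::tibble(sample_id = "S01", arm = "99z", log2_ratio = 1)
    ),
    "unknown arm"
  )
})

test_that("arm scores recover planted gains within noise tolerance", {
  ev <- tidyr::expand_grid(
    sample_id = sprintf("S%02d", 1:50), arm = "1q", log2_ratio = 0.3
  )
  sim <- simulate_arm_segments(50, ev, noise_sd = 0.05, seed = 13)
  sc <- arm_scores(sim$segments) |> dplyr::filter(arm == "1q")
  expect_equal(nrow(sc), 50)
  expect_gte(mean(abs(sc$arm_score - 0.3) < 0.05), 0.95)
})

test_that("integration fixture honours its planted structure", {
  all_prom <- simulate_integration_fixture(40, 100, frac_promoter = 1, seed = 3)
  expect_true(all(all_prom$truth$bin == "promoter_3kb"))
  no_overlap <- simulate_integration_fixture(40, 80, overlap_frac = 0, seed = 3)
  expect_equal(nrow(high_confidence_peaks(no_overlap$peaks_a, no_overlap$peaks_b)), 0)
  expect_error(simulate_integration_fixture(0, 10), "n_genes")
  # zero-noise construction: computed links equal truth bins exactly
  fx <- simulate_integration_fixture(100, 250, seed = 8)
  links <- assign_peaks_to_genes(fx$peaks_a, fx$genes)
  cmp <- dplyr::left_join(links, fx$truth, by = c(name = "peak_id"))
  expect_equal(cmp$gene_id.x, cmp$gene_id.y)
  expect_equal(cmp$bin.x, cmp$bin.y)
  expect_equal(cmp$signed_distance.x, cmp$signed_distance.y)
})

test_that("count-matrix fixture plants exactly one violated rule per bad cell", {
  sim <- simulate_count_matrix(200, 400, frac_lowq = 0.25, seed = 31)
  qc <- sc_qc(sim$counts)
  called <- ifelse(qc$report$pass, "pass",
    vapply(qc$report$failed_rules, paste, character(1), collapse = "+")
  )
  truth <- sub("fail_", "", sim$cells$truth_label)
  truth[truth == "pass"] <- "pass"
  expect_equal(unname(called), ifelse(truth == "pass", "pass", truth))

  clean <- simulate_count_matrix(100, 300, frac_lowq = 0, seed = 32)
  expect_true(all(sc_qc(clean$counts)$report$pass))

  low <- simulate_count_matrix(100, 300, frac_lowq = 1, seed = 33)
  fail_umi <- low$cells$truth_label == "fail_umi"
  expect_true(any(fail_umi))
  totals <- Matrix::colSums(low$counts)
  expect_true(all(totals[fail_umi] <= 400))
})
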