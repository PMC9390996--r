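test_that("high-confidence intersection handles identity and disjoint sets", {
  a <- tibble::tibble(chrom = "chr1", start = c(100L, 500L), end = c(200L, 700L))
  expect_equal(high_confidence_peaks(a, a), a)
  b <- tibble::tibble(chrom = "chr1", start = 900L, end = 1000L)
  expect_equal(nrow(high_confidence_peaks(a, b)), 0)
  # adjacent but non-overlapping intervals do not cluster
  touch <- tibble::tibble(chrom = "chr1", start = 200L, end = 300L)
  expect_equal(nrow(high_confidence_peaks(a, touch)), 0)
  # 1 bp overlap does, and the union span is reported
  one_bp <- tibble::tibble(chrom = "chr1", start = 199L, end = 300L)
  expect_equal(
    high_confidence_peaks(a, one_bp),
    tibble::tibble(chrom = "chr1", start = 100L, end = 300L)
  )
  expect_warning(
    high_confidence_peaks(a[2:1, ], a),
    "not sorted"
  )
})

test_that("high-confidence intersection equals the all-pairs oracle and is symmetric", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      a <- random_peaks(sample(5:60, 1))
      b <- random_peaks(sample(5:60, 1))
      got <- high_confidence_peaks(a, b)
      expect_equal(got, oracle_high_confidence(a, b))
      swapped <- high_confidence_peaks(b, a)
      expect_equal(got, swapped)
    }
  })
})

test_that("peak-gene assignment follows the distance and strand conventions", {
  genes <- tibble::tibble(
    gene_id = c("GA", "GB"), chrom = "chr1", tss = c(10000L, 300000L),
    strand = c("+", "-")
  )
  peak_at <- function(center) {
    tibble::tibble(chrom = "chr1", start = center - 101L, end = center + 100L)
  }
  # center at TSS+2000 on + strand: promoter bin
  l <- assign_peaks_to_genes(peak_at(12000L), genes)
  expect_equal(l$gene_id, "GA")
  expect_equal(l$signed_distance, 2000L)
  expect_equal(l$bin, "promoter_3kb")
  # center at TSS+50000: distal enhancer band
  expect_equal(assign_peaks_to_genes(peak_at(60000L), genes)$bin, "distal_10to100kb")
  # minus strand: a peak 2000 bp left of the TSS is downstream (+2000)
  l2 <- assign_peaks_to_genes(peak_at(298000L), genes)
  expect_equal(l2$gene_id, "GB")
  expect_equal(l2$signed_distance, 2000L)
  expect_equal(l2$bin, "promoter_3kb")
  # promoter bin is inclusive at exactly 3000 bp
  expect_equal(assign_peaks_to_genes(peak_at(13000L), genes)$bin, "promoter_3kb")
  expect_equal(assign_peaks_to_genes(peak_at(13001L), genes)$bin, "mid_3to10kb")
  # chromosome without genes: NA gene, far bin
  far <- assign_peaks_to_genes(
    tibble::tibble(chrom = "chr9", start = 0L, end = 100L), genes
  )
  expect_true(is.na(far$gene_id))
  expect_equal(far$bin, "far_over100kb")
  expect_error(assign_peaks_to_genes(peak_at(100L), genes[0, ]), "nonempty")
})

test_that("peak-gene assignment equals the exhaustive nearest-TSS oracle", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      peaks <- random_peaks(sample(10:80, 1), chroms = c("chr1", "chr2", "chr3"))
      genes <- random_genes(sample(3:40, 1))
      got <- assign_peaks_to_genes(peaks, genes)
      ora <- oracle_assign(peaks, genes)
      expect_equal(got$gene_id, ora$gene_id)
      expect_equal(got$signed_distance, ora$signed_distance)
      expect_equal(got$bin, ora$bin)
      # bins partition the linked peaks
      expect_equal(sum(table(got$bin)), nrow(peaks))
    }
  })
})

test_that("feature annotation follows the fixed priority order", {
  genes <- tibble::tibble(
    gene_id = c("GA", "GB"), chrom = "chr1", tss = c(10000L, 50000L),
    strand = "+", gene_start = c(9000L, 49000L), gene_end = c(30000L, 80000L)
  )
  features <- tibble::tibble(
    gene_id = c("GB", "GB"), feature = c("exon", "utr5"),
    start = c(12000L, 12500L), end = c(13000L, 12800L)
  )
  peak_at <- function(center) {
    tibble::tibble(chrom = "chr1", start = center - 51L, end = center + 50L)
  }
  # promoter of GA even though inside an exon of GB
  expect_equal(
    annotate_peak_features(peak_at(12600L), genes, features)$feature, "promoter"
  )
  # outside all annotation: intergenic
  expect_equal(
    annotate_peak_features(peak_at(900000L), genes, features)$feature, "intergenic"
  )
  # inside GB span, no sub-feature: intron
  expect_equal(
    annotate_peak_features(peak_at(70000L), genes, features)$feature, "intron"
  )
})

test_that("feature annotation matches the brute-force priority scan", {
  withr::with_seed(19, {
    for (rep in 1:15) {
      genes <- random_genes(sample(3:15, 1)) |>
        dplyr::mutate(
          gene_start = pmax(0, tss - 5000L),
          gene_end = tss + sample(2000:20000, dplyr::n(), replace = TRUE)
        )
      features <- tibble::tibble(
        gene_id = sample(genes$gene_id, 10, replace = TRUE),
        feature = sample(c("exon", "utr5", "utr3"), 10, replace = TRUE)
      ) |>
        dplyr::mutate(
          start = floor(runif(10, 0, 50000)),
          end = start + sample(200:3000, 10, replace = TRUE)
        )
      peaks <- random_peaks(40)
      got <- annotate_peak_features(peaks, genes, features)$feature
      expect_equal(got, oracle_annotate(peaks, genes, features))
    }
  })
})

test_that("DE integration labels links and reports partition-consistent counts", {
  fx <- simulate_integration_fixture(120, 300, seed = 21)
  links <- assign_peaks_to_genes(fx$peaks_a, fx$genes)
  intg <- integrate_with_de(links, fx$de)
  s <- intg$summary
  # per-direction peaks sum to the DE-linked total; same for genes
  expect_equal(s$up_peaks + s$down_peaks, s$n_de_peaks)
  expect_equal(s$up_genes + s$down_genes, s$n_de_genes)
  expect_equal(sum(s$bin_counts$n_peaks), s$n_de_peaks)
  # planted truth: every link to a DE gene carries its planted direction
  truth_dir <- dplyr::mutate(
    fx$de,
    dir = dplyr::case_when(
      fdr >= 0.05 ~ "none", log_fold_change > 0 ~ "up", TRUE ~ "down"
    )
  )
  cmp <- dplyr::left_join(intg$links, truth_dir, by = "gene_id")
  expect_equal(cmp$de_direction, cmp$dir)
  # glance/tidy agree with the summary list
  expect_equal(glance(intg)$n_de_peaks, s$n_de_peaks)
  expect_equal(sum(tidy(intg)$n_peaks), s$n_de_peaks)

  # no significant DE genes: zero linked peaks
  null_de <- dplyr::mutate(fx$de, fdr = pmax(fdr, 0.5))
  expect_equal(integrate_with_de(links, null_de)$summary$n_de_peaks, 0)
  expect_error(
    integrate_with_de(links, dplyr::bind_rows(fx$de, fx$de[1, ])),
    "duplicate"
  )
})

test_that("super-enhancer overlap counts regions, not peaks", {
  se <- tibble::tibble(
    chrom = "chr1", start = c(0L, 1000L, 2000L, 3000L) * 10L,
    end = c(0L, 1000L, 2000L, 3000L) * 10L + 5000L
  )
  peaks <- tibble::tibble(
    chrom = "chr1", start = c(100L, 200L, 10100L), end = c(150L, 260L, 10200L)
  )
  got <- super_enhancer_overlap(peaks, se)
  expect_equal(got$n_se_with_peak, 2L) # three peaks, two SE regions hit
  expect_equal(got$n_se_total, 4L)
  expect_equal(got$percent, 50.0)
  none <- super_enhancer_overlap(peaks[0, ], se)
  expect_equal(none$n_se_with_peak, 0L)
  expect_equal(none$percent, 0.0)
})
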