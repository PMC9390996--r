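#' Simulate a ChIP-seq / RNA-seq integration fixture with known truth
#'
#' Builds a synthetic gene annotation (TSSs spaced 1 Mb apart so every peak
#' has an unambiguous nearest gene), two replicate peak sets, a
#' differential-expression table with planted up/down genes, and
#' super-enhancer intervals with a known number of peak-containing regions.
#' Each peak is planted at a known signed distance from a known TSS, so the
#' TSS-distance bin of every peak is recorded as truth.
#'
#' @param n_genes,n_peaks Numbers of genes and peaks (n_genes > 0 whenever
#'   n_peaks > 0).
#' @param frac_promoter Fraction of peaks planted within +/-3 kb of their
#'   TSS. The remaining mass is split over the 3-10 kb, 10-100 kb and
#'   >100 kb bins as 0.22/0.63/0.15, which at the default
#'   `frac_promoter = 0.18` puts about half of all peaks in the 10-100 kb
#'   enhancer band.
#' @param frac_de Fraction of genes planted as differentially expressed
#'   (FDR below 0.05; direction random).
#' @param seed Integer seed.
#' @param overlap_frac Fraction of peaks present in both replicates;
#'   replicate-only peaks never overlap the shared ones.
#' @param n_se Number of super-enhancer intervals.
#' @param frac_se_hit Fraction of super-enhancers planted over a peak.
#' @param peak_width Width of every peak in bp (odd, so centers are exact).
#' @return List of class `rb_integration_sim` with `genes`, `peaks_a`,
#'   `peaks_b`, `de`, `se` (with truth column `truth_has_peak`) and `truth`
#'   (peak_id, gene_id, signed_distance, bin, in_both).
#' @export
simulate_integration_fixture <- function(n_genes, n_peaks,
                                         frac_promoter = 0.18, frac_de = 0.3,
                                         seed = 1L, overlap_frac = 0.9,
                                         n_se = 40, frac_se_hit = 0.25,
                                         peak_width = 201L) {
  assert_fraction(frac_promoter, "frac_promoter")
  assert_fraction(frac_de, "frac_de")
  assert_fraction(overlap_frac, "overlap_frac")
  assert_fraction(frac_se_hit, "frac_se_hit")
  if (n_genes == 0 && n_peaks > 0) {
    abort("cannot place peaks with `n_genes = 0`")
  }
  withr::local_seed(seed)
  half <- (peak_width - 1L) %/% 2L

  genes <- tibble(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    chrom = "chr1",
    tss = as.integer(5e5 + (seq_len(n_genes) - 1) * 1e6),
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )

  rest <- 1 - frac_promoter
  bin_levels <- c("promoter_3kb", "mid_3to10kb", "distal_10to100kb", "far_over100kb")
  bin <- sample(bin_levels, n_peaks,
    replace = TRUE,
    prob = c(frac_promoter, rest * 0.22, rest * 0.63, rest * 0.15)
  )
  abs_d <- floor(dplyr::case_when(
    bin == "promoter_3kb" ~ runif(n_peaks, 0, 3000),
    bin == "mid_3to10kb" ~ runif(n_peaks, 3001, 10000),
    bin == "distal_10to100kb" ~ runif(n_peaks, 10001, 100000),
    TRUE ~ runif(n_peaks, 100001, 400000)
  ))
  signed_d <- abs_d * sample(c(-1L, 1L), n_peaks, replace = TRUE)
  host <- if (n_peaks > 0) sample.int(n_genes, n_peaks, replace = TRUE) else integer()
  dir <- ifelse(genes$strand[host] == "+", 1L, -1L)
  center <- genes$tss[host] + dir * signed_d

  truth <- tibble(
    peak_id = sprintf("peak%05d", seq_len(n_peaks)),
    gene_id = genes$gene_id[host],
    signed_distance = signed_d,
    bin = bin,
    in_both = runif(n_peaks) < overlap_frac
  )
  peaks_a <- tibble(
    chrom = "chr1",
    start = as.integer(center - half - 1L),
    end = as.integer(center + half),
    name = truth$peak_id
  ) |>
    arrange(.data$start)

  # replicate B: shared peaks jittered a few bp; B-only peaks live in a
  # 450-480 kb upstream band no shared peak can reach
  shared_b <- peaks_a |>
    filter(.data$name %in% truth$peak_id[truth$in_both]) |>
    mutate(
      shift = sample(-10:10, n(), replace = TRUE),
      start = .data$start + .data$shift, end = .data$end + .data$shift,
      shift = NULL
    )
  n_bonly <- n_peaks - sum(truth$in_both)
  b_only <- if (n_bonly > 0) {
    bg <- sample.int(n_genes, n_bonly, replace = TRUE)
    bc <- genes$tss[bg] - 450000L - floor(runif(n_bonly, 0, 30000))
    tibble(
      chrom = "chr1", start = as.integer(bc - half - 1L),
      end = as.integer(bc + half),
      name = sprintf("bonly%05d", seq_len(n_bonly))
    )
  } else {
    NULL
  }
  peaks_b <- bind_rows(shared_b, b_only) |> arrange(.data$start)

  is_de <- runif(n_genes) < frac_de
  lfc <- ifelse(is_de, sample(c(-1, 1), n_genes, replace = TRUE) *
    abs(rnorm(n_genes, 2, 0.5)), rnorm(n_genes, 0, 0.2))
  de <- tibble(
    gene_id = genes$gene_id,
    log_fold_change = lfc,
    fdr = ifelse(is_de, runif(n_genes, 0, 0.049), runif(n_genes, 0.051, 1))
  )

  n_hit <- round(frac_se_hit * n_se)
  se_hit <- if (n_hit > 0 && n_peaks > 0) {
    idx <- sample.int(n_peaks, min(n_hit, n_peaks), replace = FALSE)
    tibble(
      chrom = "chr1",
      start = as.integer(pmax(0, center[idx] - 10000L)),
      end = as.integer(center[idx] + 10000L),
      truth_has_peak = TRUE
    )
  } else {
    NULL
  }
  n_empty <- n_se - (if (is.null(se_hit)) 0 else nrow(se_hit))
  se_empty <- if (n_empty > 0) {
    # far beyond the last gene: nothing is ever planted there
    base <- as.integer((n_genes + 10) * 1e6)
    tibble(
      chrom = "chr1",
      start = base + (seq_len(n_empty) - 1L) * 50000L,
      end = base + (seq_len(n_empty) - 1L) * 50000L + 20000L,
      truth_has_peak = FALSE
    )
  } else {
    NULL
  }
  se <- bind_rows(se_hit, se_empty) |> arrange(.data$start)

  structure(
    list(
      genes = genes, peaks_a = peaks_a, peaks_b = peaks_b,
      de = de, se = se, truth = truth
    ),
    class = "rb_integration_sim"
  )
}
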