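#' Simulate per-sample arm segment tables with planted copy-number events
#'
#' Each arm is tiled by a random number of contiguous segments; every
#' segment's log2 copy ratio is the arm's planted mean (0 where nothing is
#' planted) plus Gaussian noise. B-allele frequencies sit near 0.5
#' (heterozygous) except on arms with planted isodisomy, where they collapse
#' toward 0/1.
#'
#' @param n_samples Number of samples (ids `S01`, `S02`, ...).
#' @param planted_events Tibble (sample_id, arm, log2_ratio) of true arm
#'   means; NULL plants nothing.
#' @param noise_sd Gaussian SD added per segment.
#' @param seed Integer seed.
#' @param arms Arm table, see [rb_arms()].
#' @param planted_isodisomy Optional tibble (sample_id, arm) of arms whose
#'   BAFs collapse to homozygous values at neutral copy number.
#' @param mean_segments Mean segments per arm (>= 1; Poisson-distributed).
#'   The default of 10 mirrors the fragmentation of exome-based copy-ratio
#'   segmentations, where per-segment noise averages out at arm level.
#' @param baf_noise_sd Gaussian SD of segment BAFs around their target.
#' @return List of class `rb_cnv_sim` with `segments` (sample_id, chrom,
#'   start, end, log2_ratio, baf; 0-based half-open) and `truth`
#'   (sample_id, arm, true_log2_ratio, true_isodisomy).
#' @examples
#' sim <- simulate_arm_segments(
#'   2, tibble::tibble(sample_id = "S01", arm = "1q", log2_ratio = 0.3),
#'   noise_sd = 0, seed = 1
#' )
#' arm_calls(sim$segments) |> dplyr::filter(call != "neutral")
#' @export
simulate_arm_segments <- function(n_samples, planted_events = NULL,
                                  noise_sd = 0.05, seed = 1L,
                                  arms = rb_arms(autosomes_only = TRUE),
                                  planted_isodisomy = NULL,
                                  mean_segments = 10,
                                  baf_noise_sd = 0.02) {
  assert_count(n_samples, "n_samples")
  assert_nonneg(noise_sd, "noise_sd")
  withr::local_seed(seed)
  samples <- sprintf("S%02d", seq_len(n_samples))
  if (!is.null(planted_events)) {
    assert_columns(planted_events, c("sample_id", "arm", "log2_ratio"))
    bad <- setdiff(planted_events$arm, arms$arm)
    if (length(bad) > 0) {
      abort(sprintf("unknown arm name(s): %s", paste(unique(bad), collapse = ", ")))
    }
  }
  if (!is.null(planted_isodisomy)) {
    assert_columns(planted_isodisomy, c("sample_id", "arm"))
    bad <- setdiff(planted_isodisomy$arm, arms$arm)
    if (length(bad) > 0) {
      abort(sprintf("unknown arm name(s): %s", paste(unique(bad), collapse = ", ")))
    }
  }

  grid <- tidyr::expand_grid(sample_id = samples, arms)
  truth <- grid |>
    select("sample_id", "arm") |>
    left_join(
      planted_events %||%
        tibble(sample_id = character(), arm = character(), log2_ratio = double()),
      by = c("sample_id", "arm")
    ) |>
    mutate(true_log2_ratio = dplyr::coalesce(.data$log2_ratio, 0), log2_ratio = NULL)
  iso_keys <- if (is.null(planted_isodisomy)) {
    character()
  } else {
    paste(planted_isodisomy$sample_id, planted_isodisomy$arm)
  }
  truth$true_isodisomy <- paste(truth$sample_id, truth$arm) %in% iso_keys

  n_seg <- 1L + rpois(nrow(grid), max(0, mean_segments - 1))
  segs <- grid |>
    mutate(
      true_log2_ratio = truth$true_log2_ratio,
      true_isodisomy = truth$true_isodisomy,
      n_seg = n_seg
    ) |>
    tidyr::uncount(.data$n_seg, .id = "seg_i") |>
    group_by(.data$sample_id, .data$arm) |>
    mutate(
      brk = list(sort(c(
        .data$start[1], .data$end[1],
        if (n() > 1) floor(runif(n() - 1, .data$start[1], .data$end[1]))
      )))
    ) |>
    mutate(
      seg_start = .data$brk[[1]][.data$seg_i],
      seg_end = .data$brk[[1]][.data$seg_i + 1L]
    ) |>
    ungroup() |>
    filter(.data$seg_end > .data$seg_start)
  m <- nrow(segs)
  baf_target <- ifelse(segs$true_isodisomy,
    sample(c(0.02, 0.98), m, replace = TRUE), 0.5
  )
  segments <- segs |>
    mutate(
      log2_ratio = .data$true_log2_ratio + rnorm(m, 0, noise_sd),
      baf = pmin(1, pmax(0, baf_target + rnorm(m, 0, baf_noise_sd)))
    ) |>
    select("sample_id", "chrom",
      start = "seg_start", end = "seg_end", "log2_ratio", "baf"
    ) |>
    arrange(.data$sample_id, .data$chrom, .data$start)
  structure(list(segments = segments, truth = truth), class = "rb_cnv_sim")
}
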