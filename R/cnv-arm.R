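#' Chromosome arm boundary table
#'
#' Ships hg19 arm intervals (0-based half-open, centromeres excluded) as a
#' config asset; any table with columns `chrom`, `arm`, `start`, `end` can
#' be substituted for other assemblies or namings.
#'
#' @param autosomes_only Drop chrX (and the acrocentric short-arm stubs are
#'   retained either way; they simply carry no segments in most data).
#' @return A tibble with columns chrom, arm, start, end.
#' @export
rb_arms <- function(autosomes_only = FALSE) {
  path <- system.file("extdata", "hg19_arms.tsv", package = "rbomics")
  arms <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (autosomes_only) arms <- filter(arms, .data$chrom != "chrX")
  arms
}

#' Length-weighted arm scores from segment tables
#'
#' The arm score is the length-weighted mean of segment log2 copy ratios
#' over the arm, using only the part of each segment that falls inside the
#' arm interval. When the segments carry a `baf` column, the median
#' deviation of segment B-allele frequencies from 0.5 is also reported (for
#' the isodisomy flag).
#'
#' @param segments Tibble with columns sample_id, chrom, start, end
#'   (0-based half-open), log2_ratio and optionally baf.
#' @param arms Arm table as from [rb_arms()].
#' @return Tibble (sample_id, arm, n_segments, arm_score[, baf_dev]).
#'   Arms with no overlapping segments are absent from the result (their
#'   score is undefined).
#' @export
arm_scores <- function(segments, arms = rb_arms()) {
  assert_columns(segments, c("sample_id", "chrom", "start", "end", "log2_ratio"))
  assert_columns(arms, c("chrom", "arm", "start", "end"))
  if (any(segments$end <= segments$start)) {
    abort("segments must have end > start")
  }
  unknown <- setdiff(unique(segments$chrom), unique(arms$chrom))
  if (length(unknown) > 0) {
    abort(sprintf(
      "segments on chromosome(s) not in the arm table: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  has_baf <- "baf" %in% names(segments)
  joined <- segments |>
    left_join(
      rename(arms, arm_start = "start", arm_end = "end"),
      by = "chrom", relationship = "many-to-many"
    ) |>
    mutate(w = pmin(.data$end, .data$arm_end) - pmax(.data$start, .data$arm_start)) |>
    filter(.data$w > 0)
  out <- joined |>
    group_by(.data$sample_id, .data$arm) |>
    summarise(
      n_segments = n(),
      arm_score = sum(.data$w * .data$log2_ratio) / sum(.data$w),
      baf_dev = if (has_baf) median(abs(.data$baf - 0.5), na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )
  if (!has_baf) out$baf_dev <- NULL
  out
}

#' Call gain/loss/neutral from an arm score
#'
#' Strict threshold on the absolute arm score: gain if score > `cut`, loss
#' if score < -`cut`, neutral otherwise (a score of exactly +/-0.1 is
#' neutral).
#'
#' @param score Numeric vector of arm scores.
#' @param cut Absolute-score threshold (default 0.1).
#' @return Character vector in {gain, loss, neutral}.
#' @export
call_arm <- function(score, cut = 0.1) {
  dplyr::case_when(
    score > cut ~ "gain",
    score < -cut ~ "loss",
    TRUE ~ "neutral"
  )
}

#' Arm-level calls for a whole cohort
#'
#' @inheritParams arm_scores
#' @param cut Absolute arm-score threshold passed to [call_arm()].
#' @return Tibble (sample_id, arm, arm_score, call[, baf_dev]).
#' @export
arm_calls <- function(segments, arms = rb_arms(), cut = 0.1) {
  arm_scores(segments, arms) |>
    mutate(call = call_arm(.data$arm_score, cut))
}

# complete sample x arm call matrix ("neutral" where no score exists)
calls_matrix <- function(calls, arms) {
  samples <- sort(unique(calls$sample_id))
  m <- matrix("neutral",
    nrow = length(samples), ncol = length(arms),
    dimnames = list(samples, arms)
  )
  m[cbind(match(calls$sample_id, samples), match(calls$arm, arms))] <- calls$call
  m
}

# permutation null counts for gains/losses under within-sample arm-label
# shuffles; returns list of B x k count matrices
perm_arm_counts <- function(G, L, n_perm) {
  k <- ncol(G)
  gain_pos <- apply(G, 1, which, simplify = FALSE)
  loss_pos <- apply(L, 1, which, simplify = FALSE)
  n_gain <- lengths(gain_pos)
  n_loss <- lengths(loss_pos)
  active <- which(n_gain + n_loss > 0)
  cg <- matrix(0L, n_perm, k)
  cl <- matrix(0L, n_perm, k)
  for (b in seq_len(n_perm)) {
    for (i in active) {
      pos <- sample.int(k, n_gain[i] + n_loss[i])
      if (n_gain[i] > 0) {
        g <- pos[seq_len(n_gain[i])]
        cg[b, g] <- cg[b, g] + 1L
      }
      if (n_loss[i] > 0) {
        l <- pos[n_gain[i] + seq_len(n_loss[i])]
        cl[b, l] <- cl[b, l] + 1L
      }
    }
  }
  list(gain = cg, loss = cl)
}

#' Cohort recurrence test for arm-level gains and losses
#'
#' Permutation analog of an arm-level significance analysis: for each arm
#' and direction the observed cohort frequency is compared to a null built
#' by shuffling each sample's arm labels (the sample's set of altered arms
#' is kept, their identity randomised). z = (observed frequency - null
#' mean) / null SD; p is the permutation upper tail; p-values are BH-adjusted
#' across arms x directions. An arm is significant when z >= `z_cut` and
#' FDR < `fdr_cut`.
#'
#' @param calls Tibble of arm calls as from [arm_calls()].
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @param z_cut Inclusive z-score cutoff (default 6).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @param seed Optional seed for the permutation RNG.
#' @return Tibble of class `rb_recurrence` with one row per arm x direction:
#'   arm, direction, n_altered, frequency, z, p, fdr, significant.
#' @export
arm_recurrence <- function(calls, n_perm = 10000, z_cut = 6, fdr_cut = 0.05,
                           seed = NULL) {
  assert_columns(calls, c("sample_id", "arm", "call"))
  if (n_perm < 100) abort("`n_perm` must be at least 100")
  if (dplyr::n_distinct(calls$sample_id) < 2) {
    abort("recurrence testing needs at least 2 samples")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  arms <- sort(unique(calls$arm))
  m <- calls_matrix(calls, arms)
  n_samples <- nrow(m)
  G <- m == "gain"
  L <- m == "loss"
  perm <- perm_arm_counts(G, L, n_perm)
  obs <- list(gain = colSums(G), loss = colSums(L))
  res <- purrr::map(c("gain", "loss"), function(dir) {
    cnt <- perm[[dir]]
    mu <- colMeans(cnt)
    sdev <- apply(cnt, 2, sd)
    o <- obs[[dir]]
    z <- ifelse(sdev > 0, (o - mu) / sdev, ifelse(o > mu, Inf, 0))
    p <- (1 + colSums(cnt >= rep(o, each = n_perm))) / (n_perm + 1)
    tibble(
      arm = arms, direction = dir, n_altered = as.integer(o),
      frequency = unname(o) / n_samples, z = unname(z), p = unname(p)
    )
  }) |>
    purrr::list_rbind() |>
    mutate(
      fdr = p.adjust(.data$p, method = "BH"),
      significant = .data$z >= z_cut & .data$fdr < fdr_cut
    ) |>
    arrange(desc(.data$z))
  structure(res,
    class = c("rb_recurrence", class(res)),
    n_samples = n_samples, n_perm = n_perm, z_cut = z_cut, fdr_cut = fdr_cut
  )
}

#' Focal amplification flag for a locus
#'
#' Per-sample permutation test of whether the length-weighted mean log2
#' ratio over a locus window stands out from the sample's own segment
#' background: segment ratios are shuffled across the sample's segment
#' positions and the locus score recomputed. Flagged when
#' z = (observed - null mean)/null SD >= `z_cut` (inclusive). A locus
#' indistinguishable from background (null SD 0) is never flagged.
#'
#' @param segments Per-sample segment tibble (sample_id, chrom, start, end,
#'   log2_ratio), 0-based half-open.
#' @param locus_chrom,locus_start,locus_end Locus window (0-based half-open),
#'   e.g. the MYCN locus chr2:15,940,550-16,087,129 for hg19.
#' @param z_cut Inclusive z cutoff (default 3).
#' @param n_perm Number of ratio permutations (default 1000).
#' @param seed Optional RNG seed.
#' @return Tibble (sample_id, locus_score, z, amplified).
#' @export
focal_amplification <- function(segments, locus_chrom, locus_start, locus_end,
                                z_cut = 3, n_perm = 1000, seed = NULL) {
  assert_columns(segments, c("sample_id", "chrom", "start", "end", "log2_ratio"))
  if (!is.null(seed)) withr::local_seed(seed)
  segments |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      w_locus <- ifelse(
        df$chrom == locus_chrom,
        pmax(0, pmin(df$end, locus_end) - pmax(df$start, locus_start)), 0
      )
      if (sum(w_locus) == 0) {
        return(tibble(locus_score = NA_real_, z = NA_real_, amplified = FALSE))
      }
      score_for <- function(r) sum(w_locus * r) / sum(w_locus)
      obs <- score_for(df$log2_ratio)
      null <- vapply(
        seq_len(n_perm),
        function(b) score_for(sample(df$log2_ratio)), numeric(1)
      )
      mu <- mean(null)
      sdev <- sd(null)
      z <- if (sdev > 0) (obs - mu) / sdev else 0
      tibble(locus_score = obs, z = z, amplified = z >= z_cut)
    }) |>
    ungroup()
}

#' Copy-neutral isodisomy flag per arm
#'
#' Flags arms whose B-allele frequencies have collapsed to homozygous values
#' (arm-median |BAF - 0.5| above `baf_dev`) while the copy ratio stays
#' neutral (|arm score| <= `neutral_cut`).
#'
#' @inheritParams arm_scores
#' @param baf_dev Median |BAF - 0.5| threshold (default 0.3; heterozygous
#'   arms sit near 0, fully homozygous arms near 0.5).
#' @param neutral_cut Copy-neutrality bound on |arm score| (default 0.1).
#' @return Tibble (sample_id, arm, arm_score, baf_dev, isodisomy).
#' @export
isodisomy_flags <- function(segments, arms = rb_arms(), baf_dev = 0.3,
                            neutral_cut = 0.1) {
  assert_columns(segments, c("sample_id", "chrom", "start", "end", "log2_ratio", "baf"))
  dev_thr <- baf_dev
  arm_scores(segments, arms) |>
    mutate(
      isodisomy = .data$baf_dev > dev_thr & abs(.data$arm_score) <= neutral_cut
    ) |>
    select("sample_id", "arm", "arm_score", "baf_dev", "isodisomy")
}
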