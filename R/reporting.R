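#' Percentage with round-half-up at one decimal
#'
#' The fixed rounding convention for every printed percentage in cohort
#' summaries: 100 * count / total, rounded half-up to one decimal (base R's
#' banker's rounding is deliberately not used, so e.g. 39.85 prints 39.9).
#'
#' @param count,total Non-negative counts with `count <= total`, `total > 0`.
#' @return Numeric percentage(s) with one decimal.
#' @examples
#' percent_of(41, 103) # 39.8
#' percent_of(446, 1834) # 24.3
#' @export
percent_of <- function(count, total) {
  if (any(total <= 0)) abort("`total` must be positive")
  if (any(count < 0) || any(count > total)) {
    abort("`count` must satisfy 0 <= count <= total")
  }
  floor(1000 * count / total + 0.5) / 10
}

default_alteration_priority <- c(
  "homozygous_deletion", "stop_gain", "splicing", "indel", "missense"
)

#' Map classified variants to oncoprint alteration calls
#'
#' Reduces a classified (deleterious) variant table to one row per
#' (sample, gene, alteration), mapping the consequence annotation onto the
#' oncoprint vocabulary: stop_gain, splicing, indel, missense. Synonymous
#' and nonexonic consequences carry no alteration and are dropped, as are
#' non-deleterious rows when a `deleterious` column is present.
#'
#' @param variants Tibble with sample_id, gene and consequence columns
#'   (and optionally deleterious).
#' @return Tibble (sample_id, gene, alteration).
#' @export
alteration_calls <- function(variants) {
  assert_columns(variants, c("sample_id", "gene", "consequence"))
  if ("deleterious" %in% names(variants)) {
    variants <- filter(variants, .data$deleterious)
  }
  variants |>
    filter(.data$consequence %in% default_alteration_priority) |>
    select("sample_id", "gene", alteration = "consequence") |>
    distinct()
}

#' Build an oncoprint matrix and cohort summary
#'
#' One cell per gene x sample holding the highest-priority alteration
#' (default priority homozygous_deletion > stop_gain > splicing > indel >
#' missense > none); columns (samples) ordered by total alteration burden,
#' descending; rows (genes) by altered-sample count, descending. Per-gene
#' frequencies use [percent_of()] over `n_samples`.
#'
#' @param alterations Tibble (sample_id, gene, alteration), e.g. from
#'   [alteration_calls()]; rows from CNV callers (such as
#'   "homozygous_deletion") can be bound in before the call.
#' @param n_samples Cohort size for frequency denominators; defaults to the
#'   number of distinct samples in `alterations` or `sample_metadata`.
#' @param sample_metadata Optional tibble with a sample_id column; samples
#'   present in `alterations` but not here are kept with a warning.
#' @param priority Character vector, highest first.
#' @return Object of class `rb_oncoprint`: list with `matrix` (gene x
#'   sample character matrix, "none" where unaltered), `gene_counts`
#'   (gene, n_altered, frequency_pct) and `n_samples`.
#' @export
build_oncoprint <- function(alterations, n_samples = NULL,
                            sample_metadata = NULL,
                            priority = default_alteration_priority) {
  assert_columns(alterations, c("sample_id", "gene", "alteration"))
  bad <- setdiff(unique(alterations$alteration), priority)
  if (length(bad) > 0) {
    abort(sprintf(
      "alteration(s) not in `priority`: %s", paste(bad, collapse = ", ")
    ))
  }
  samples <- unique(alterations$sample_id)
  if (!is.null(sample_metadata)) {
    assert_columns(sample_metadata, "sample_id")
    missing_meta <- setdiff(samples, sample_metadata$sample_id)
    if (length(missing_meta) > 0) {
      warn(sprintf(
        "sample(s) without metadata kept with empty metadata: %s",
        paste(missing_meta, collapse = ", ")
      ))
    }
    samples <- union(sample_metadata$sample_id, samples)
  }
  n_samples <- n_samples %||% length(samples)
  if (nrow(alterations) == 0) {
    return(structure(
      list(
        matrix = matrix(character(), 0, length(samples),
          dimnames = list(NULL, samples)
        ),
        gene_counts = tibble(
          gene = character(), n_altered = integer(), frequency_pct = double()
        ),
        n_samples = n_samples
      ),
      class = "rb_oncoprint"
    ))
  }
  best <- alterations |>
    mutate(rank = match(.data$alteration, priority)) |>
    group_by(.data$sample_id, .data$gene) |>
    slice_min(.data$rank, n = 1, with_ties = FALSE) |>
    ungroup()
  genes <- unique(best$gene)
  m <- matrix("none",
    nrow = length(genes), ncol = length(samples),
    dimnames = list(genes, samples)
  )
  m[cbind(match(best$gene, genes), match(best$sample_id, samples))] <- best$alteration
  burden <- colSums(m != "none")
  m <- m[, order(-burden, colnames(m)), drop = FALSE]
  gene_counts <- tibble(
    gene = rownames(m),
    n_altered = as.integer(rowSums(m != "none"))
  ) |>
    mutate(frequency_pct = percent_of(.data$n_altered, n_samples)) |>
    arrange(desc(.data$n_altered), .data$gene)
  m <- m[gene_counts$gene, , drop = FALSE]
  structure(
    list(matrix = m, gene_counts = gene_counts, n_samples = n_samples),
    class = "rb_oncoprint"
  )
}

#' @export
print.rb_oncoprint <- function(x, ...) {
  cat(sprintf(
    "<rb_oncoprint> %d genes x %d samples (cohort n = %d)\n",
    nrow(x$matrix), ncol(x$matrix), x$n_samples
  ))
  print(head(x$gene_counts, 10))
  invisible(x)
}

#' Cohort summary of alteration and arm-level CNV frequencies
#'
#' @param oncoprint An `rb_oncoprint` from [build_oncoprint()].
#' @param arm_calls Optional arm-call tibble from [arm_calls()]; per-arm
#'   gain/loss frequencies are added.
#' @return List (class `rb_cohort_summary`) with n_samples, gene_counts and
#'   optionally arm_frequencies.
#' @export
cohort_summary <- function(oncoprint, arm_calls = NULL) {
  out <- list(
    n_samples = oncoprint$n_samples,
    gene_counts = oncoprint$gene_counts
  )
  if (!is.null(arm_calls)) {
    n_cnv <- dplyr::n_distinct(arm_calls$sample_id)
    out$arm_frequencies <- arm_calls |>
      filter(.data$call != "neutral") |>
      count(.data$arm, .data$call, name = "n_samples_altered") |>
      mutate(frequency_pct = percent_of(.data$n_samples_altered, n_cnv)) |>
      arrange(desc(.data$n_samples_altered))
  }
  structure(out, class = "rb_cohort_summary")
}
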