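# peaks are tibbles (chrom, start, end, ...) in BED convention:
# 0-based half-open. Conversion to 1-based IRanges is centralised here.

peaks_to_granges <- function(peaks, what = "peaks") {
  assert_columns(peaks, c("chrom", "start", "end"), what)
  if (any(peaks$end <= peaks$start)) {
    abort(sprintf("`%s` must have end > start (0-based half-open)", what))
  }
  GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end)
  )
}

granges_to_peaks <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

check_sorted <- function(peaks, what) {
  o <- order(peaks$chrom, peaks$start)
  if (!identical(o, seq_len(nrow(peaks)))) {
    warn(sprintf("`%s` was not sorted by (chrom, start); sorting", what))
    peaks <- peaks[o, ]
  }
  peaks
}

# 1-based center position of a 0-based half-open peak
peak_center <- function(peaks) {
  peaks$start + (peaks$end - peaks$start - 1L) %/% 2L + 1L
}

#' High-confidence peaks shared between two replicates
#'
#' Clusters the union of both peak sets by transitive >= 1 bp overlap and
#' keeps one output peak — the union span of the cluster — for every
#' cluster containing at least one peak from each replicate. Peaks present
#' in only one replicate are dropped. The operation is symmetric in its
#' arguments.
#'
#' @param a,b Peak tibbles (chrom, start, end), 0-based half-open, sorted
#'   by (chrom, start); unsorted input is sorted with a warning.
#' @return Tibble (chrom, start, end) of shared-cluster spans.
#' @export
high_confidence_peaks <- function(a, b) {
  a <- check_sorted(a, "a")
  b <- check_sorted(b, "b")
  gr_a <- peaks_to_granges(a, "a")
  gr_b <- peaks_to_granges(b, "b")
  all <- c(gr_a, gr_b)
  clusters <- GenomicRanges::reduce(all, min.gapwidth = 0L)
  has_a <- GenomicRanges::countOverlaps(clusters, gr_a, minoverlap = 1L) > 0
  has_b <- GenomicRanges::countOverlaps(clusters, gr_b, minoverlap = 1L) > 0
  granges_to_peaks(GenomicRanges::sort(clusters[has_a & has_b]))
}

distance_bins <- c(
  promoter_3kb = 3000, mid_3to10kb = 10000,
  distal_10to100kb = 100000, far_over100kb = Inf
)

bin_distance <- function(abs_distance) {
  dplyr::case_when(
    is.na(abs_distance) ~ "far_over100kb",
    abs_distance <= 3000 ~ "promoter_3kb",
    abs_distance <= 10000 ~ "mid_3to10kb",
    abs_distance <= 100000 ~ "distal_10to100kb",
    TRUE ~ "far_over100kb"
  )
}

#' Assign each peak to its nearest gene by TSS distance
#'
#' Links every peak to the gene whose TSS is closest to the peak center
#' (unlimited range; ties broken by lexicographically smallest gene_id).
#' The signed distance runs TSS -> peak center and is flipped on the minus
#' strand, so negative always means upstream of the gene. Distances are
#' binned as promoter (|d| <= 3 kb, inclusive), 3-10 kb, 10-100 kb and
#' > 100 kb. Peaks on chromosomes without genes get an NA gene and the
#' far bin.
#'
#' @param peaks Peak tibble (chrom, start, end[, name]), 0-based half-open.
#' @param genes Gene tibble (gene_id, chrom, tss, strand); tss is 1-based.
#' @return Tibble: the peak columns plus gene_id, signed_distance, bin.
#' @export
assign_peaks_to_genes <- function(peaks, genes) {
  assert_columns(peaks, c("chrom", "start", "end"))
  assert_columns(genes, c("gene_id", "chrom", "tss", "strand"))
  if (nrow(genes) == 0) abort("`genes` must be nonempty")
  center <- peak_center(peaks)

  # one representative gene per (chrom, tss): the lexicographically
  # smallest id also wins any cross-position tie it takes part in
  reps <- genes |>
    arrange(.data$chrom, .data$tss, .data$gene_id) |>
    distinct(.data$chrom, .data$tss, .keep_all = TRUE)

  out <- peaks
  out$gene_id <- NA_character_
  out$signed_distance <- NA_integer_
  for (ch in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == ch)
    g <- reps[reps$chrom == ch, ]
    if (nrow(g) == 0) next
    tss <- g$tss # sorted
    pos <- center[pk]
    right <- findInterval(pos, tss) + 1L # first tss >= pos (almost)
    left <- right - 1L
    cand_left <- ifelse(left >= 1 & left <= length(tss), left, NA_integer_)
    cand_right <- ifelse(right <= length(tss), right, NA_integer_)
    d_left <- abs(pos - tss[cand_left])
    d_right <- abs(tss[cand_right] - pos)
    use_left <- !is.na(cand_left) & (
      is.na(cand_right) | d_left < d_right |
        (d_left == d_right & g$gene_id[cand_left] <= g$gene_id[cand_right])
    )
    pick <- ifelse(use_left, cand_left, cand_right)
    out$gene_id[pk] <- g$gene_id[pick]
    d_abs <- abs(pos - tss[pick])
    out$signed_distance[pk] <- as.integer(
      ifelse(g$strand[pick] == "+", pos - tss[pick], tss[pick] - pos)
    )
  }
  out$bin <- bin_distance(abs(out$signed_distance))
  out
}

#' Annotate peaks with a genomic feature class
#'
#' Classifies the peak center into the first matching class in the fixed
#' priority order promoter > 5'UTR > 3'UTR > exon > intron > intergenic.
#' The promoter is TSS +/- `promoter_window`; exon/UTR intervals come from
#' the optional `features` table; a center inside a gene span but in no
#' higher class is intronic.
#'
#' @inheritParams assign_peaks_to_genes
#' @param genes Gene tibble; `gene_start`/`gene_end` columns (0-based
#'   half-open span), when present, define intron territory.
#' @param features Optional tibble (gene_id, feature, start, end) with
#'   feature in {utr5, utr3, exon}, 0-based half-open.
#' @param promoter_window Promoter half-width in bp (default 3000).
#' @return The peak tibble with a `feature` column appended.
#' @export
annotate_peak_features <- function(peaks, genes, features = NULL,
                                   promoter_window = 3000) {
  assert_columns(peaks, c("chrom", "start", "end"))
  assert_columns(genes, c("gene_id", "chrom", "tss"))
  center <- peak_center(peaks)
  center_gr <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(center, center))
  in_any <- function(gr) {
    GenomicRanges::countOverlaps(center_gr, gr) > 0
  }
  prom <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$tss - promoter_window), genes$tss + promoter_window)
  )
  hit <- list(promoter = in_any(prom))
  for (f in c("utr5", "utr3", "exon")) {
    hit[[f]] <- if (!is.null(features) && any(features$feature == f)) {
      ft <- features[features$feature == f, ]
      gch <- genes$chrom[match(ft$gene_id, genes$gene_id)]
      in_any(GenomicRanges::GRanges(gch, IRanges::IRanges(ft$start + 1L, ft$end)))
    } else {
      rep(FALSE, nrow(peaks))
    }
  }
  hit$intron <- if (all(c("gene_start", "gene_end") %in% names(genes))) {
    in_any(GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$gene_start + 1L, genes$gene_end)
    ))
  } else {
    rep(FALSE, nrow(peaks))
  }
  peaks$feature <- dplyr::case_when(
    hit$promoter ~ "promoter",
    hit$utr5 ~ "utr5",
    hit$utr3 ~ "utr3",
    hit$exon ~ "exon",
    hit$intron ~ "intron",
    TRUE ~ "intergenic"
  )
  peaks
}

#' Integrate peak-gene links with differential expression
#'
#' Labels every link up/down/none by its gene's DE row (significant iff
#' fdr < `fdr_cut`, direction by the sign of the log fold change) and
#' summarises: peaks linked to DE genes, DE genes with at least one peak,
#' per-direction gene and peak counts, and the TSS-distance bin
#' distribution of DE-linked peaks.
#'
#' @param links Peak-gene links from [assign_peaks_to_genes()].
#' @param de DE tibble (gene_id, log_fold_change, fdr); gene_id unique.
#' @param fdr_cut Significance cutoff on the FDR (default 0.05).
#' @return An object of class `rb_integration`: list with `links` (labeled)
#'   and `summary`. Use [tidy()] for per-direction counts and [glance()]
#'   for the one-row summary.
#' @export
integrate_with_de <- function(links, de, fdr_cut = 0.05) {
  assert_columns(links, c("gene_id", "bin"))
  assert_columns(de, c("gene_id", "log_fold_change", "fdr"))
  if (anyDuplicated(de$gene_id)) {
    abort("duplicate gene_id in DE table")
  }
  if (any(de$fdr < 0 | de$fdr > 1, na.rm = TRUE)) {
    abort("`fdr` must lie in [0, 1]")
  }
  labeled <- links |>
    left_join(select(de, "gene_id", "log_fold_change", "fdr"), by = "gene_id") |>
    mutate(de_direction = dplyr::case_when(
      is.na(.data$fdr) | .data$fdr >= fdr_cut ~ "none",
      .data$log_fold_change > 0 ~ "up",
      .data$log_fold_change < 0 ~ "down",
      TRUE ~ "none"
    ))
  de_linked <- filter(labeled, .data$de_direction != "none")
  by_dir <- function(dir) {
    rows <- filter(de_linked, .data$de_direction == dir)
    list(genes = dplyr::n_distinct(rows$gene_id), peaks = nrow(rows))
  }
  up <- by_dir("up")
  down <- by_dir("down")
  summary <- list(
    n_links = nrow(labeled),
    n_de_peaks = nrow(de_linked),
    n_de_genes = dplyr::n_distinct(de_linked$gene_id),
    up_genes = up$genes, up_peaks = up$peaks,
    down_genes = down$genes, down_peaks = down$peaks,
    bin_counts = de_linked |>
      count(.data$bin, name = "n_peaks") |>
      arrange(match(.data$bin, names(distance_bins)))
  )
  structure(list(links = labeled, summary = summary, fdr_cut = fdr_cut),
    class = "rb_integration"
  )
}

#' @export
print.rb_integration <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<rb_integration> %d peak-gene links; %d peaks on %d DE genes ",
      "(FDR < %g)\n  up: %d genes (%d peaks); down: %d genes (%d peaks)\n"
    ),
    s$n_links, s$n_de_peaks, s$n_de_genes, x$fdr_cut,
    s$up_genes, s$up_peaks, s$down_genes, s$down_peaks
  ))
  invisible(x)
}

#' Fraction of super-enhancer regions containing a peak
#'
#' Counts super-enhancer intervals containing at least 1 bp of at least one
#' peak; the fraction is reported as a one-decimal percent with the
#' package's round-half-up convention (see [percent_of()]).
#'
#' @param peaks,se_regions Interval tibbles (chrom, start, end), 0-based
#'   half-open.
#' @return One-row tibble (n_se_with_peak, n_se_total, percent).
#' @export
super_enhancer_overlap <- function(peaks, se_regions) {
  se_gr <- peaks_to_granges(se_regions, "se_regions")
  n_hit <- if (nrow(peaks) > 0) {
    sum(GenomicRanges::countOverlaps(se_gr, peaks_to_granges(peaks), minoverlap = 1L) > 0)
  } else {
    0L
  }
  tibble(
    n_se_with_peak = as.integer(n_hit),
    n_se_total = nrow(se_regions),
    percent = percent_of(n_hit, nrow(se_regions))
  )
}
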