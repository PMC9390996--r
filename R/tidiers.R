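# broom-style tidiers for the package's result objects

#' @export
tidy.rb_filter_result <- function(x, ...) {
  rules <- c(
    "panel_of_normals", "read_support", "vaf", "population", "dbsnp",
    "shared_indel"
  )
  failed <- unlist(x$failed_rules)
  tibble(rule = rules) |>
    mutate(
      n_failed = vapply(rules, function(r) sum(failed == r), integer(1)),
      frac_failed = if (nrow(x) > 0) .data$n_failed / nrow(x) else 0
    )
}

#' @export
glance.rb_filter_result <- function(x, ...) {
  tibble(
    n_input = nrow(x),
    n_kept = sum(x$kept),
    n_filtered = sum(!x$kept),
    frac_kept = if (nrow(x) > 0) sum(x$kept) / nrow(x) else NA_real_
  )
}

#' @export
tidy.rb_recurrence <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.rb_recurrence <- function(x, ...) {
  tibble(
    n_samples = attr(x, "n_samples"),
    n_perm = attr(x, "n_perm"),
    n_tests = nrow(x),
    n_significant = sum(x$significant)
  )
}

#' @export
tidy.rb_integration <- function(x, ...) {
  s <- x$summary
  tibble(
    direction = c("up", "down"),
    n_genes = c(s$up_genes, s$down_genes),
    n_peaks = c(s$up_peaks, s$down_peaks)
  )
}

#' @export
glance.rb_integration <- function(x, ...) {
  s <- x$summary
  tibble(
    n_links = s$n_links, n_de_peaks = s$n_de_peaks,
    n_de_genes = s$n_de_genes,
    up_genes = s$up_genes, up_peaks = s$up_peaks,
    down_genes = s$down_genes, down_peaks = s$down_peaks
  )
}

#' @export
tidy.rb_sc_qc <- function(x, ...) {
  x$report
}

#' @export
glance.rb_sc_qc <- function(x, ...) {
  failed <- unlist(x$report$failed_rules)
  tibble(
    n_cells = nrow(x$report),
    n_pass = sum(x$report$pass),
    n_fail_umi = sum(failed == "umi"),
    n_fail_genes_low = sum(failed == "genes_low"),
    n_fail_genes_high = sum(failed == "genes_high"),
    n_fail_mito = sum(failed == "mito")
  )
}

#' @export
tidy.rb_oncoprint <- function(x, ...) {
  x$gene_counts
}

#' @export
glance.rb_oncoprint <- function(x, ...) {
  tibble(
    n_genes = nrow(x$matrix),
    n_samples = x$n_samples,
    n_altered_samples = sum(colSums(x$matrix != "none") > 0)
  )
}
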