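#' Single-cell quality-control filter
#'
#' Applies the cell-level QC rules to a genes x cells sparse count matrix:
#' a cell is kept iff its total UMI count is strictly greater than
#' `min_umi` (400), it expresses between `min_genes` and `max_genes`
#' detected genes inclusive (100-6000), and its mitochondrial content is
#' strictly below `max_mito` (10%). Mitochondrial genes are identified by a
#' symbol prefix (default "MT-") or an explicit list.
#'
#' @param counts A genes x cells matrix (dgCMatrix or dense) with gene
#'   symbols as rownames and cell barcodes as colnames.
#' @param mito_prefix Gene-symbol prefix marking mitochondrial genes.
#' @param mito_genes Optional explicit character vector of mitochondrial
#'   gene symbols (overrides the prefix).
#' @param min_umi,min_genes,max_genes,max_mito Rule thresholds as above.
#' @return Object of class `rb_sc_qc`: list with `report` (barcode,
#'   total_umi, n_genes_detected, mito_fraction, pass, failed_rules) and
#'   `filtered` (the matrix restricted to passing cells). Rule ids are
#'   umi, genes_low, genes_high, mito.
#' @examples
#' sim <- simulate_count_matrix(50, 200, frac_lowq = 0.2, seed = 1)
#' qc <- sc_qc(sim$counts)
#' table(qc$report$pass, sim$cells$truth_label)
#' @export
sc_qc <- function(counts, mito_prefix = "MT-", mito_genes = NULL,
                  min_umi = 400, min_genes = 100, max_genes = 6000,
                  max_mito = 0.10) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` needs gene symbols as rownames and barcodes as colnames")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort("gene symbols and barcodes must be unique")
  }
  mito <- if (!is.null(mito_genes)) {
    rownames(counts) %in% mito_genes
  } else {
    startsWith(rownames(counts), mito_prefix)
  }
  total <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito_umi <- if (any(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE])
  } else {
    rep(0, ncol(counts))
  }
  mito_fraction <- ifelse(total > 0, mito_umi / total, 0)
  fails <- cbind(
    umi = !(total > min_umi),
    genes_low = n_genes < min_genes,
    genes_high = n_genes > max_genes,
    mito = !(mito_fraction < max_mito)
  )
  rule_ids <- colnames(fails)
  failed_rules <- apply(fails, 1, function(f) rule_ids[f], simplify = FALSE)
  if (ncol(counts) == 0) failed_rules <- list()
  report <- tibble(
    barcode = colnames(counts),
    total_umi = unname(as.numeric(total)),
    n_genes_detected = unname(as.integer(n_genes)),
    mito_fraction = unname(as.numeric(mito_fraction)),
    pass = unname(rowSums(fails) == 0),
    failed_rules = unname(failed_rules)
  )
  structure(
    list(report = report, filtered = counts[, report$pass, drop = FALSE]),
    class = "rb_sc_qc"
  )
}

#' @export
print.rb_sc_qc <- function(x, ...) {
  cat(sprintf(
    "<rb_sc_qc> %d of %d cells pass QC\n",
    sum(x$report$pass), nrow(x$report)
  ))
  invisible(x)
}

#' Per-group detection fraction and mean normalized expression
#'
#' For each cell group and each requested gene: the fraction of cells with
#' a raw count above zero, and the mean log1p counts-per-million (the
#' normalization used for dot-plot style summaries).
#'
#' @param counts Genes x cells count matrix with dimnames.
#' @param cell_groups Character/factor vector of group labels, one per cell
#'   (in column order), or a named vector keyed by barcode.
#' @param genes Gene symbols to summarise.
#' @return Tibble (group, gene, n_cells, detection_fraction, mean_log1p_cpm).
#' @export
group_expression_summary <- function(counts, cell_groups, genes) {
  missing_genes <- setdiff(genes, rownames(counts))
  if (length(missing_genes) > 0) {
    abort(sprintf("gene(s) not in matrix: %s", paste(missing_genes, collapse = ", ")))
  }
  if (!is.null(names(cell_groups))) {
    cell_groups <- cell_groups[colnames(counts)]
  }
  if (length(cell_groups) != ncol(counts)) {
    abort("`cell_groups` must supply one label per cell")
  }
  total <- Matrix::colSums(counts)
  sub <- counts[genes, , drop = FALSE]
  cpm <- log1p(t(t(as.matrix(sub)) / ifelse(total > 0, total, 1)) * 1e6)
  detected <- as.matrix(sub) > 0
  purrr::map(split(seq_len(ncol(counts)), cell_groups), function(idx) {
    tibble(
      gene = genes,
      n_cells = length(idx),
      detection_fraction = unname(rowMeans(detected[, idx, drop = FALSE])),
      mean_log1p_cpm = unname(rowMeans(cpm[, idx, drop = FALSE]))
    )
  }) |>
    purrr::list_rbind(names_to = "group")
}

#' Co-detection association between two genes
#'
#' Cross-classifies cells by detection (count > 0) of each gene and tests
#' the 2 x 2 table with a two-sided Fisher exact test. The odds ratio is
#' the sample (cross-product) odds ratio; tables with an off-diagonal zero
#' report `Inf` (or 0) by that convention.
#'
#' @param counts Genes x cells count matrix with dimnames.
#' @param gene_a,gene_b Gene symbols.
#' @return One-row tibble (gene_a, gene_b, n_both, n_a_only, n_b_only,
#'   n_neither, odds_ratio, p).
#' @export
codetection_association <- function(counts, gene_a, gene_b) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(counts)) abort(sprintf("gene not in matrix: %s", g))
  }
  da <- as.vector(counts[gene_a, ] > 0)
  db <- as.vector(counts[gene_b, ] > 0)
  n11 <- sum(da & db)
  n10 <- sum(da & !db)
  n01 <- sum(!da & db)
  n00 <- sum(!da & !db)
  tab <- matrix(c(n11, n01, n10, n00), 2)
  or <- (n11 * n00) / (n10 * n01) # Inf when an off-diagonal is empty
  p <- fisher.test(tab)$p.value
  tibble(
    gene_a = gene_a, gene_b = gene_b,
    n_both = n11, n_a_only = n10, n_b_only = n01, n_neither = n00,
    odds_ratio = or, p = p
  )
}
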