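#' Simulate a sparse single-cell count matrix with planted QC failures
#'
#' Good cells are built to pass every QC rule with margin (total UMI well
#' above 400, detected genes well inside [100, 6000], mitochondrial fraction
#' capped below 9%). Each low-quality cell is planted to violate exactly one
#' named rule: `fail_umi` (total UMI <= 400), `fail_genes_low` (< 100
#' detected genes), `fail_genes_high` (> 6000 detected genes; only feasible
#' when the gene universe allows it), or `fail_mito` (mitochondrial content
#' >= 10%).
#'
#' @param n_cells,n_genes Matrix dimensions. `n_genes` should be at least
#'   ~150 so that passing cells can detect 100+ genes.
#' @param frac_lowq Fraction of cells planted as QC failures.
#' @param mito_gene_frac Fraction of genes given an `MT-` symbol.
#' @param seed Integer seed.
#' @return List of class `rb_sc_sim` with `counts` (genes x cells
#'   dgCMatrix, dimnames set), `cells` (barcode, truth_label) and `genes`
#'   (symbol, is_mito).
#' @export
simulate_count_matrix <- function(n_cells, n_genes, frac_lowq = 0.1,
                                  mito_gene_frac = 0.05, seed = 1L) {
  assert_count(n_cells, "n_cells")
  assert_count(n_genes, "n_genes")
  assert_fraction(frac_lowq, "frac_lowq")
  assert_fraction(mito_gene_frac, "mito_gene_frac")
  if (n_genes < 150) {
    abort("`n_genes` must be at least 150 so passing cells can exist")
  }
  withr::local_seed(seed)
  n_mito <- round(mito_gene_frac * n_genes)
  symbols <- c(
    sprintf("MT-G%03d", seq_len(n_mito)),
    sprintf("GENE%05d", seq_len(n_genes - n_mito))
  )
  is_mito <- startsWith(symbols, "MT-")
  # expression weights: mito genes get ~4% of the library of a good cell
  w <- rgamma(n_genes, 0.8)
  if (n_mito > 0) {
    w[is_mito] <- w[is_mito] / sum(w[is_mito]) * 0.04
    w[!is_mito] <- w[!is_mito] / sum(w[!is_mito]) * 0.96
  } else {
    w <- w / sum(w)
  }

  n_lowq <- round(frac_lowq * n_cells)
  feasible <- c(
    "fail_umi", "fail_genes_low",
    if (n_genes > 6100) "fail_genes_high", if (n_mito > 0) "fail_mito"
  )
  labels <- c(
    rep("pass", n_cells - n_lowq),
    if (n_lowq > 0) sample(feasible, n_lowq, replace = TRUE)
  )
  labels <- sample(labels)

  max_detect <- min(3000L, n_genes - 10L, 6000L)
  build_cell <- function(label) {
    if (label == "pass") {
      total <- sample(1500:8000, 1)
      d <- sample(150:min(800, max_detect), 1)
      mito_cap <- 0.09
    } else if (label == "fail_umi") {
      total <- sample(150:400, 1)
      d <- sample(110:min(140, 400), 1)
      mito_cap <- 0.09
    } else if (label == "fail_genes_low") {
      total <- sample(500:2000, 1)
      d <- sample(20:90, 1)
      mito_cap <- 0.09
    } else if (label == "fail_genes_high") {
      d <- sample(6001:min(n_genes, 6100), 1)
      total <- d + sample(500:2000, 1)
      mito_cap <- 0.09
    } else { # fail_mito
      total <- sample(1500:5000, 1)
      d <- sample(150:min(400, max_detect), 1)
      mito_cap <- NA # forced high instead
    }
    d <- min(d, total) # every detected gene needs >= 1 count
    gene_idx <- sample.int(n_genes, d, prob = w)
    extra <- total - d
    counts <- rep(1L, d) +
      if (extra > 0) as.integer(rmultinom(1, extra, w[gene_idx])) else 0L
    mito_in <- which(is_mito[gene_idx])
    if (label == "fail_mito") {
      # force one mito gene into the cell and load it to ~25% of the library
      if (length(mito_in) == 0) {
        gene_idx[1] <- which(is_mito)[1]
        mito_in <- 1L
      }
      target <- ceiling(0.25 * total)
      k <- mito_in[1]
      donor <- which(!is_mito[gene_idx] & counts > 1)
      need <- target - sum(counts[mito_in])
      while (need > 0 && length(donor) > 0) {
        take <- pmin(counts[donor] - 1L, need)
        counts[donor] <- counts[donor] - take
        counts[k] <- counts[k] + sum(take)
        need <- target - sum(counts[mito_in])
        donor <- which(!is_mito[gene_idx] & counts > 1)
      }
    } else if (length(mito_in) > 0) {
      # cap mito content below the QC threshold, preserving totals/detection
      excess <- sum(counts[mito_in]) - floor(mito_cap * total)
      if (excess > 0) {
        recipient <- which(!is_mito[gene_idx])[1]
        for (k in mito_in) {
          take <- min(counts[k] - 1L, excess)
          counts[k] <- counts[k] - take
          counts[recipient] <- counts[recipient] + take
          excess <- excess - take
          if (excess <= 0) break
        }
        if (excess > 0) {
          # mito genes already at 1 count each: swap them for unused
          # non-mito genes so the planted label stays exact
          unused <- setdiff(which(!is_mito), gene_idx)
          nrep <- min(length(mito_in), length(unused))
          gene_idx[mito_in[seq_len(nrep)]] <- unused[seq_len(nrep)]
        }
      }
    }
    list(idx = gene_idx, counts = counts)
  }

  cells <- purrr::map(labels, build_cell)
  i <- unlist(purrr::map(cells, "idx"))
  x <- unlist(purrr::map(cells, "counts"))
  j <- rep(seq_len(n_cells), vapply(cells, function(c) length(c$idx), integer(1)))
  barcodes <- sprintf("BC%05d", seq_len(n_cells))
  counts <- Matrix::sparseMatrix(
    i = i, j = j, x = x, dims = c(n_genes, n_cells),
    dimnames = list(symbols, barcodes)
  )
  structure(
    list(
      counts = counts,
      cells = tibble(barcode = barcodes, truth_label = labels),
      genes = tibble(symbol = symbols, is_mito = is_mito)
    ),
    class = "rb_sc_sim"
  )
}
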