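#' Readers and writers for the pipeline's plain-text formats
#'
#' Thin wrappers around readr/Matrix with the coordinate conventions fixed
#' in one place: BED files are 0-based half-open; gene tables carry 1-based
#' TSS positions; sparse counts use the MatrixMarket + barcodes/features
#' layout.
#'
#' @param path File (or, for sparse counts, directory) path.
#' @name rb_io
NULL

#' @rdname rb_io
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  df <- readr::read_tsv(path,
    col_names = FALSE, show_col_types = FALSE, progress = FALSE,
    comment = "#"
  )
  names(df) <- cols[seq_len(min(ncol(df), 6))]
  df
}

#' @rdname rb_io
#' @param intervals Tibble with chrom/start/end and optional name, score,
#'   strand columns (BED6 order).
#' @export
write_bed <- function(intervals, path) {
  assert_columns(intervals, c("chrom", "start", "end"))
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(intervals))
  readr::write_tsv(intervals[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname rb_io
#' @export
read_gene_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname rb_io
#' @param genes Gene tibble (gene_id, chrom, tss, strand).
#' @export
write_gene_tsv <- function(genes, path) {
  assert_columns(genes, c("gene_id", "chrom", "tss", "strand"))
  readr::write_tsv(genes, path, progress = FALSE)
  invisible(path)
}

#' @rdname rb_io
#' @export
read_variant_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname rb_io
#' @param variants Variant tibble, one row per variant per sample.
#' @export
write_variant_tsv <- function(variants, path) {
  out <- variants
  if ("failed_rules" %in% names(out)) {
    out$failed_rules <- vapply(
      out$failed_rules, paste, character(1), collapse = ";"
    )
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname rb_io
#' @param sample_id Sample whose rows are written (a VCF holds one tumor).
#' @export
write_variant_vcf <- function(variants, path, sample_id = NULL) {
  assert_columns(variants, c("sample_id", "chrom", "pos", "ref", "alt"))
  sample_id <- sample_id %||% unique(variants$sample_id)
  if (length(sample_id) != 1) {
    abort("`variants` spans several samples; pass `sample_id`")
  }
  v <- filter(variants, .data$sample_id == .env$sample_id) |>
    arrange(.data$chrom, .data$pos)
  ad <- if (all(c("tumor_ref_reads", "tumor_alt_reads") %in% names(v))) {
    sprintf("%d,%d", v$tumor_ref_reads, v$tumor_alt_reads)
  } else {
    rep(".", nrow(v))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0(
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id
    )
  )
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD\t%s",
    v$chrom, v$pos, v$ref, v$alt, ad
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname rb_io
#' @export
read_pon_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname rb_io
#' @param pon Panel-of-normals tibble (chrom, pos, ref, alt, n_normals).
#' @export
write_pon_tsv <- function(pon, path) {
  assert_columns(pon, c("chrom", "pos", "ref", "alt", "n_normals"))
  readr::write_tsv(pon, path, progress = FALSE)
  invisible(path)
}

#' @rdname rb_io
#' @param dir Directory holding matrix.mtx, barcodes.tsv and features.tsv.
#' @export
read_sparse_counts <- function(dir) {
  counts <- methods::as(
    Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix"
  )
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- readLines(file.path(dir, "features.tsv"))
  dimnames(counts) <- list(features, barcodes)
  counts
}

#' @rdname rb_io
#' @param counts Genes x cells sparse matrix with dimnames.
#' @export
write_sparse_counts <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' @rdname rb_io
#' @export
read_motifs <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  models <- purrr::map(parts, function(p) {
    if (length(p) < 2) abort("motif lines must be `name consensus`")
    motif_model(p[1], consensus = p[2])
  })
  setNames(models, vapply(models, function(m) m$name, character(1)))
}
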