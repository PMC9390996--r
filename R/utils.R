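# internal helpers shared across modules

variant_key_cols <- c("chrom", "pos", "ref", "alt")

# paste a stable string key for (chrom, pos, ref, alt)
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number", name))
  }
  invisible(x)
}

assert_count <- function(x, name) {
  assert_nonneg(x, name)
  if (x != as.integer(x)) abort(sprintf("`%s` must be a whole number", name))
  invisible(x)
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(
    seq_len(n),
    function(i) paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = ""),
    character(1)
  )
}

reverse_complement <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}
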