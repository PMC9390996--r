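# random fixtures used by the property-style tests

random_peaks <- function(n, chroms = c("chr1", "chr2"), span = 50000,
                         max_width = 800) {
  start <- floor(runif(n, 0, span))
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + floor(runif(n, 1, max_width))
  ) |>
    dplyr::arrange(chrom, start)
}

random_genes <- function(n, chroms = c("chr1", "chr2"), span = 50000) {
  tibble::tibble(
    gene_id = sprintf("G%03d", sample.int(9 * n, n)),
    chrom = sample(chroms, n, replace = TRUE),
    tss = floor(runif(n, 1, span)),
    strand = sample(c("+", "-"), n, replace = TRUE)
  ) |>
    dplyr::distinct(gene_id, .keep_all = TRUE)
}

random_sequence <- function(n, n_frac = 0.02) {
  paste(sample(c("A", "C", "G", "T", "N"), n,
    replace = TRUE,
    prob = c(rep((1 - n_frac) / 4, 4), n_frac)
  ), collapse = "")
}

# tiny arm table for toy CNV tests (coordinates small enough for the
# per-base oracle)
toy_arms <- function() {
  tibble::tibble(
    chrom = c("chrA", "chrA", "chrB"),
    arm = c("Ap", "Aq", "Bq"),
    start = c(0L, 5000L, 0L),
    end = c(4000L, 12000L, 8000L)
  )
}

manual_variant <- function(...) {
  defaults <- list(
    sample_id = "S1", chrom = "chr1", pos = 100L, ref = "A", alt = "T",
    gene = "RB1", variant_type = "SNV",
    functional_class = "nonsynonymous_exonic", consequence = "missense",
    tumor_alt_reads = 30L, tumor_ref_reads = 70L, blood_alt_reads = 0L,
    tumor_vaf = 0.3, pop_maf_1000g = NA_real_, pop_maf_esp = NA_real_,
    in_dbsnp = FALSE, dbsnp_pop_maf = NA_real_,
    dbsnp_single_mapping = FALSE, dbsnp_clinical_tag = FALSE,
    matched_normal_available = TRUE,
    polyphen = "benign", fathmm = "tolerated", metalr = "tolerated",
    truth_class = "somatic", truth_deleterious = FALSE
  )
  args <- list(...)
  defaults[names(args)] <- args
  tibble::as_tibble(defaults)
}

empty_pon <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), n_normals = integer()
  )
}
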