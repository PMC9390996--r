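#' Configuration for the synthetic tumor cohort simulator
#'
#' Bundles every knob of [simulate_variant_cohort()] with validation. The
#' defaults emulate a 103-exome retinoblastoma cohort in which most tumors
#' have a matched blood sample and a 117-sample panel of normals is
#' available: somatic variants are rare (low mutation burden), germline
#' polymorphisms are drawn from a shared population pool, and artifacts have
#' low allele fractions by construction.
#'
#' @param n_tumors Number of tumor samples.
#' @param frac_matched Fraction of tumors with a matched blood sample.
#' @param n_panel_normals Number of normals in the panel of normals.
#' @param somatic_rate,germline_rate,artifact_rate Expected number of
#'   variants per sample in each truth class (Poisson means; the germline
#'   rate is realised through a shared population pool so the same germline
#'   key can recur across samples and panel normals).
#' @param vaf_somatic_mean,vaf_somatic_conc Mean and concentration of the
#'   Beta distribution of somatic allele fractions (default mean 0.35).
#' @param vaf_artifact_mean,vaf_artifact_conc Same for artifacts (default
#'   mean 0.03, i.e. mostly below the 5% allele-fraction cutoff).
#' @param vaf_germline_conc Concentration of the heterozygous germline Beta
#'   centred on 0.5.
#' @param tumor_depth,blood_depth Mean sequencing depths (Poisson).
#' @param predictor_error Probability that each of the three effect
#'   predictors miscalls a variant's true deleteriousness.
#' @param predictor_missing_rate Probability a predictor returns no call.
#' @param possibly_damaging_frac Fraction of damaging PolyPhen-2 calls
#'   emitted as "possibly_damaging" rather than "probably_damaging".
#' @param pon_share_prob Probability that a germline population variant
#'   segregates in the panel-of-normals population at all; variants that do
#'   are carried by each panel normal with their population frequency.
#' @param artifact_pon_prob Probability that an artifact is a recurrent
#'   process artifact also observed in panel normals.
#' @param seed Integer seed; identical seeds give identical cohorts.
#'
#' @return A validated list of class `cohort_sim_config`.
#' @seealso [simulate_variant_cohort()]
#' @export
cohort_sim_config <- function(n_tumors = 103,
                              frac_matched = 96 / 103,
                              n_panel_normals = 117,
                              somatic_rate = 10,
                              germline_rate = 40,
                              artifact_rate = 15,
                              vaf_somatic_mean = 0.35,
                              vaf_somatic_conc = 10,
                              vaf_artifact_mean = 0.03,
                              vaf_artifact_conc = 10,
                              vaf_germline_conc = 100,
                              tumor_depth = 100,
                              blood_depth = 80,
                              predictor_error = 0.1,
                              predictor_missing_rate = 0.05,
                              possibly_damaging_frac = 0.25,
                              pon_share_prob = 0.9,
                              artifact_pon_prob = 0.3,
                              seed = 1L) {
  assert_count(n_tumors, "n_tumors")
  assert_count(n_panel_normals, "n_panel_normals")
  assert_fraction(frac_matched, "frac_matched")
  for (nm in c("somatic_rate", "germline_rate", "artifact_rate")) {
    assert_nonneg(get(nm), nm)
  }
  for (nm in c(
    "vaf_somatic_mean", "vaf_artifact_mean", "predictor_error",
    "predictor_missing_rate", "possibly_damaging_frac", "pon_share_prob",
    "artifact_pon_prob"
  )) {
    assert_fraction(get(nm), nm)
  }
  assert_nonneg(tumor_depth, "tumor_depth")
  assert_nonneg(blood_depth, "blood_depth")
  structure(
    list(
      n_tumors = as.integer(n_tumors), frac_matched = frac_matched,
      n_panel_normals = as.integer(n_panel_normals),
      somatic_rate = somatic_rate, germline_rate = germline_rate,
      artifact_rate = artifact_rate,
      vaf_somatic_mean = vaf_somatic_mean, vaf_somatic_conc = vaf_somatic_conc,
      vaf_artifact_mean = vaf_artifact_mean, vaf_artifact_conc = vaf_artifact_conc,
      vaf_germline_conc = vaf_germline_conc,
      tumor_depth = tumor_depth, blood_depth = blood_depth,
      predictor_error = predictor_error,
      predictor_missing_rate = predictor_missing_rate,
      possibly_damaging_frac = possibly_damaging_frac,
      pon_share_prob = pon_share_prob, artifact_pon_prob = artifact_pon_prob,
      seed = as.integer(seed)
    ),
    class = "cohort_sim_config"
  )
}

variant_type_levels <- c("SNV", "insertion", "deletion", "MNV_nonframeshift", "MNV_other")
functional_class_levels <- c("nonsynonymous_exonic", "synonymous", "nonexonic", "splicing")

# recurrently mutated genes emulating a retinoblastoma cohort, plus filler
sim_gene_pool <- function() {
  recurrent <- c(
    "RB1", "BCOR", "FCGBP", "NSD1", "BRCA2", "CREBBP", "DST", "MACF1",
    "PI4KA", "SCN5A", "CHD1", "NCOA3", "PML"
  )
  c(recurrent, sprintf("GENE%03d", seq_len(120)))
}

# draw random variant identities (key + annotation-independent fields)
sim_variant_identities <- function(n, type_probs = c(0.82, 0.07, 0.07, 0.03, 0.01)) {
  arms <- rb_arms()
  chrom_len <- arms |>
    group_by(.data$chrom) |>
    summarise(len = max(.data$end), .groups = "drop") |>
    filter(.data$chrom != "chrX")
  idx <- sample.int(nrow(chrom_len), n, replace = TRUE)
  chrom <- chrom_len$chrom[idx]
  pos <- floor(runif(n, 1e5, chrom_len$len[idx] - 1e5))
  variant_type <- sample(variant_type_levels, n, replace = TRUE, prob = type_probs)
  ins_len <- 1L + rpois(n, 1.5)
  ref <- random_dna(n, ifelse(variant_type == "deletion", 1L + ins_len,
    ifelse(startsWith(variant_type, "MNV"), 2L, 1L)
  ))
  alt <- random_dna(n, ifelse(variant_type == "insertion", 1L + ins_len,
    ifelse(startsWith(variant_type, "MNV"), 2L, 1L)
  ))
  functional_class <- sample(functional_class_levels, n,
    replace = TRUE, prob = c(0.45, 0.2, 0.25, 0.1)
  )
  tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    variant_type = variant_type, functional_class = functional_class
  )
}

rbeta_mean <- function(n, mean, conc) rbeta(n, mean * conc, (1 - mean) * conc)

empty_variant_table <- function() {
  tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    variant_type = character(), functional_class = character(),
    consequence = character(),
    tumor_alt_reads = integer(), tumor_ref_reads = integer(),
    blood_alt_reads = integer(), tumor_vaf = double(),
    pop_maf_1000g = double(), pop_maf_esp = double(),
    in_dbsnp = logical(), dbsnp_pop_maf = double(),
    dbsnp_single_mapping = logical(), dbsnp_clinical_tag = logical(),
    matched_normal_available = logical(),
    polyphen = character(), fathmm = character(), metalr = character(),
    truth_class = character(), truth_deleterious = logical()
  )
}

#' Simulate a labeled tumor/normal variant cohort and panel of normals
#'
#' Generates per-sample variant calls with truth classes
#' (somatic/germline/artifact), read counts drawn as Binomial(depth, VAF)
#' with Poisson depth, population and dbSNP annotations, and categorical
#' calls from three effect predictors (PolyPhen-2-style three-level plus two
#' binary tools). Germline variants come from a shared population pool, so
#' they recur across samples, appear in matched blood reads, and — with
#' configurable probability — in the panel of normals. Somatic variants are
#' never planted in the panel; artifacts get low allele fractions and may
#' recur in the panel as process artifacts.
#'
#' @param cfg A [cohort_sim_config()].
#' @return A list of class `rb_cohort_sim` with elements
#'   * `variants`: tibble of variant records plus `truth_class` and
#'     `truth_deleterious`;
#'   * `pon`: tibble (chrom, pos, ref, alt, n_normals) of panel-of-normals
#'     keys with the number of normals carrying each.
#' @examples
#' sim <- simulate_variant_cohort(cohort_sim_config(n_tumors = 4, seed = 7))
#' dplyr::count(sim$variants, truth_class)
#' @export
simulate_variant_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_sim_config")) {
    abort("`cfg` must be created with cohort_sim_config()")
  }
  withr::local_seed(cfg$seed)
  genes <- sim_gene_pool()
  somatic_gene_prob <- c(
    0.35, 0.08, rep(0.02, 11), rep(0.21 / 120, 120)
  )
  n <- cfg$n_tumors
  samples <- sprintf("RB%03d", seq_len(n))
  n_matched <- round(cfg$frac_matched * n)
  matched <- samples %in% samples[seq_len(n_matched)]

  ## -- germline population pool ------------------------------------------
  pool_size <- if (cfg$germline_rate > 0) max(1L, round(4 * cfg$germline_rate)) else 0L
  if (pool_size > 0) {
    w <- rgamma(pool_size, shape = 0.6)
    freq <- pmin(0.9, cfg$germline_rate * w / sum(w))
    pool <- sim_variant_identities(pool_size)
    pool$freq <- freq
    pool$gene <- sample(genes, pool_size, replace = TRUE)
    pool$pop_maf_1000g <- ifelse(runif(pool_size) < 0.9,
      pmin(0.5, freq / 2 * runif(pool_size, 0.5, 1.5)), NA_real_
    )
    pool$pop_maf_esp <- ifelse(runif(pool_size) < 0.85,
      pmin(0.5, freq / 2 * runif(pool_size, 0.5, 1.5)), NA_real_
    )
    pool$in_dbsnp <- runif(pool_size) < 0.85
    pool$dbsnp_pop_maf <- ifelse(pool$in_dbsnp & runif(pool_size) < 0.9,
      pmin(0.5, freq / 2 * runif(pool_size, 0.5, 1.5)), NA_real_
    )
    pool$dbsnp_single_mapping <- pool$in_dbsnp & runif(pool_size) < 0.15
    pool$dbsnp_clinical_tag <- pool$in_dbsnp & runif(pool_size) < 0.02
    in_panel <- runif(pool_size) < cfg$pon_share_prob
    pool$pon_count <- ifelse(in_panel,
      rbinom(pool_size, cfg$n_panel_normals, pmin(1, freq)), 0L
    )
  } else {
    pool <- NULL
  }

  per_class <- function(truth_class) {
    counts <- rpois(n, switch(truth_class,
      somatic = cfg$somatic_rate, artifact = cfg$artifact_rate
    ))
    total <- sum(counts)
    if (total == 0) return(NULL)
    ids <- sim_variant_identities(total)
    ids$sample_id <- rep(samples, counts)
    ids$gene <- if (truth_class == "somatic") {
      sample(genes, total, replace = TRUE, prob = somatic_gene_prob)
    } else {
      sample(genes, total, replace = TRUE)
    }
    ids$truth_class <- truth_class
    ids
  }

  rows <- list()
  if (cfg$somatic_rate > 0) rows$somatic <- per_class("somatic")
  if (cfg$artifact_rate > 0) rows$artifact <- per_class("artifact")
  if (!is.null(pool)) {
    carrier <- matrix(runif(pool_size * n) < rep(pool$freq, n), nrow = pool_size)
    hit <- which(carrier, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      g <- pool[hit[, 1], c(
        "chrom", "pos", "ref", "alt", "variant_type", "functional_class", "gene"
      )]
      g$sample_id <- samples[hit[, 2]]
      g$truth_class <- "germline"
      g$pool_idx <- hit[, 1]
      rows$germline <- g
    }
  }
  variants <- bind_rows(rows)
  if (is.null(variants) || nrow(variants) == 0) {
    return(structure(
      list(
        variants = empty_variant_table(),
        pon = tibble(
          chrom = character(), pos = integer(), ref = character(),
          alt = character(), n_normals = integer()
        )
      ),
      class = "rb_cohort_sim"
    ))
  }

  m <- nrow(variants)
  variants$matched_normal_available <- matched[match(variants$sample_id, samples)]

  ## -- read counts --------------------------------------------------------
  vaf_true <- numeric(m)
  is_som <- variants$truth_class == "somatic"
  is_ger <- variants$truth_class == "germline"
  is_art <- variants$truth_class == "artifact"
  vaf_true[is_som] <- rbeta_mean(sum(is_som), cfg$vaf_somatic_mean, cfg$vaf_somatic_conc)
  vaf_true[is_ger] <- rbeta_mean(sum(is_ger), 0.5, cfg$vaf_germline_conc)
  vaf_true[is_art] <- rbeta_mean(sum(is_art), cfg$vaf_artifact_mean, cfg$vaf_artifact_conc)
  depth <- pmax(1L, rpois(m, cfg$tumor_depth))
  alt <- rbinom(m, depth, vaf_true)
  variants$tumor_alt_reads <- alt
  variants$tumor_ref_reads <- depth - alt
  variants$tumor_vaf <- alt / depth
  blood_vaf <- ifelse(is_ger, vaf_true, ifelse(is_art, 0.01, 0.002))
  blood_depth <- pmax(1L, rpois(m, cfg$blood_depth))
  variants$blood_alt_reads <- ifelse(
    variants$matched_normal_available,
    rbinom(m, blood_depth, blood_vaf), NA_integer_
  )

  ## -- population / dbSNP annotation -------------------------------------
  ann <- tibble(
    pop_maf_1000g = ifelse(runif(m) < 0.9, NA_real_, runif(m, 0, 0.005)),
    pop_maf_esp = ifelse(runif(m) < 0.9, NA_real_, runif(m, 0, 0.005)),
    in_dbsnp = runif(m) < ifelse(is_art, 0.05, 0.02),
    dbsnp_pop_maf = NA_real_,
    dbsnp_single_mapping = FALSE,
    dbsnp_clinical_tag = FALSE
  )
  ann$dbsnp_single_mapping <- ann$in_dbsnp & runif(m) < 0.5
  if ("pool_idx" %in% names(variants)) {
    gi <- which(is_ger)
    pi <- variants$pool_idx[gi]
    for (col in c(
      "pop_maf_1000g", "pop_maf_esp", "in_dbsnp", "dbsnp_pop_maf",
      "dbsnp_single_mapping", "dbsnp_clinical_tag"
    )) {
      ann[[col]][gi] <- pool[[col]][pi]
    }
    variants$pool_idx <- NULL
  }
  variants <- bind_cols(variants, ann)

  ## -- truth deleteriousness + predictor calls ---------------------------
  del_prob <- ifelse(is_som, 0.6, ifelse(is_ger, 0.05, 0.3))
  is_indel <- variants$variant_type %in% c("insertion", "deletion")
  truth_del <- runif(m) < del_prob
  truth_del[is_indel | variants$functional_class == "splicing"] <- TRUE
  variants$truth_deleterious <- truth_del

  call_of <- function(truth) {
    flip <- runif(m) < cfg$predictor_error
    miss <- runif(m) < cfg$predictor_missing_rate
    out <- ifelse(xor(truth, flip), "damaging", "tolerated")
    out[miss] <- "missing"
    out[is_indel] <- "missing" # predictors score substitutions only
    out
  }
  fathmm <- call_of(truth_del)
  metalr <- call_of(truth_del)
  polyphen <- call_of(truth_del)
  pp_dam <- polyphen == "damaging"
  polyphen[pp_dam] <- ifelse(
    runif(sum(pp_dam)) < cfg$possibly_damaging_frac,
    "possibly_damaging", "probably_damaging"
  )
  polyphen[polyphen == "tolerated"] <- "benign"
  variants$polyphen <- polyphen
  variants$fathmm <- fathmm
  variants$metalr <- metalr

  ## -- consequence (for oncoprint-style reporting) -----------------------
  variants$consequence <- dplyr::case_when(
    is_indel ~ "indel",
    variants$functional_class == "splicing" ~ "splicing",
    variants$functional_class == "synonymous" ~ "synonymous",
    variants$functional_class == "nonexonic" ~ "nonexonic",
    runif(m) < 0.15 ~ "stop_gain",
    TRUE ~ "missense"
  )

  variants <- variants |>
    distinct(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt,
      .keep_all = TRUE
    ) |>
    select(all_of(names(empty_variant_table()))) |>
    arrange(.data$sample_id, .data$chrom, .data$pos)

  recurrent_artifacts <- variants |>
    filter(.data$truth_class == "artifact") |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt)
  n_art <- nrow(recurrent_artifacts)
  art_counts <- if (n_art > 0) {
    ifelse(runif(n_art) < cfg$artifact_pon_prob, 2L + rpois(n_art, 4), 0L)
  } else {
    integer()
  }
  pon_germline <- if (!is.null(pool)) {
    pool |>
      filter(.data$pon_count >= 1) |>
      select("chrom", "pos", "ref", "alt", n_normals = "pon_count")
  } else {
    NULL
  }
  pon <- bind_rows(
    pon_germline,
    recurrent_artifacts[art_counts >= 1, ] |>
      mutate(n_normals = art_counts[art_counts >= 1])
  )
  if (nrow(pon) == 0) {
    pon <- tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), n_normals = integer()
    )
  } else {
    pon <- distinct(pon, .data$chrom, .data$pos, .data$ref, .data$alt,
      .keep_all = TRUE
    )
  }

  structure(list(variants = variants, pon = pon), class = "rb_cohort_sim")
}

#' @export
print.rb_cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<rb_cohort_sim> %d variants in %d samples; %d panel-of-normals keys\n",
    nrow(x$variants), dplyr::n_distinct(x$variants$sample_id), nrow(x$pon)
  ))
  invisible(x)
}
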