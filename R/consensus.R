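#' Binarize a categorical predictor call into a deleteriousness vote
#'
#' "probably_damaging", "possibly_damaging" and "damaging" all count as
#' deleterious votes; "benign" and "tolerated" as benign votes; "missing"
#' (or NA) stays missing.
#'
#' @param call Character vector of predictor calls.
#' @return Character vector in {deleterious, benign, missing}.
#' @export
binarize_predictor <- function(call) {
  out <- dplyr::case_when(
    call %in% c("probably_damaging", "possibly_damaging", "damaging") ~ "deleterious",
    call %in% c("benign", "tolerated") ~ "benign",
    is.na(call) | call == "missing" ~ "missing"
  )
  if (anyNA(out)) {
    abort(sprintf(
      "unrecognised predictor call(s): %s",
      paste(unique(call[is.na(out)]), collapse = ", ")
    ))
  }
  out
}

#' Two-of-three predictor consensus deleteriousness classification
#'
#' Classifies every kept variant with the class-dependent consensus rule:
#' * insertions, deletions and splicing-junction alterations are always
#'   deleterious (`rule_used = "indel_or_splicing"`);
#' * nonexonic and synonymous substitutions are deleterious iff at least two
#'   of the three predictors vote deleterious;
#' * nonsynonymous exonic substitutions are *not* deleterious iff at least
#'   two of three vote benign — so they default to deleterious when calls
#'   are missing, the mirror image of the nonexonic default.
#'
#' With no missing calls the two substitution rules coincide; they differ
#' only in which side wins when votes are absent.
#'
#' @param variants Tibble with columns variant_type, functional_class and
#'   predictor calls polyphen, fathmm, metalr.
#' @return The input with columns `deleterious` (logical), `rule_used` and
#'   vote counts `n_deleterious_votes`, `n_benign_votes` appended.
#' @examples
#' classify_deleteriousness(tibble::tibble(
#'   variant_type = "SNV", functional_class = "nonsynonymous_exonic",
#'   polyphen = "benign", fathmm = "tolerated", metalr = "damaging"
#' ))
#' @export
classify_deleteriousness <- function(variants) {
  assert_columns(variants, c(
    "variant_type", "functional_class", "polyphen", "fathmm", "metalr"
  ))
  votes <- cbind(
    binarize_predictor(variants$polyphen),
    binarize_predictor(variants$fathmm),
    binarize_predictor(variants$metalr)
  )
  n_del <- rowSums(votes == "deleterious")
  n_ben <- rowSums(votes == "benign")
  forced <- variants$variant_type %in% c("insertion", "deletion") |
    variants$functional_class == "splicing"
  snv_like <- !forced
  bad <- snv_like &
    !variants$functional_class %in% c("nonsynonymous_exonic", "synonymous", "nonexonic")
  if (any(bad)) {
    abort(sprintf(
      "substitution with unknown functional_class: %s",
      paste(unique(variants$functional_class[bad]), collapse = ", ")
    ))
  }
  del <- ifelse(
    forced, TRUE,
    ifelse(variants$functional_class == "nonsynonymous_exonic",
      n_ben < 2, # not deleterious iff two of three benign/tolerated
      n_del >= 2 # deleterious iff two of three damaging
    )
  )
  variants |>
    mutate(
      deleterious = .env$del,
      rule_used = dplyr::case_when(
        forced ~ "indel_or_splicing",
        .data$functional_class == "nonsynonymous_exonic" ~ "nonsynonymous_exonic",
        TRUE ~ "nonexonic_synonymous"
      ),
      n_deleterious_votes = as.integer(n_del),
      n_benign_votes = as.integer(n_ben)
    )
}
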