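iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Construct a binding-site motif model
#'
#' Either an IUPAC consensus string or a position weight matrix (4 x L,
#' rows A/C/G/T, columns summing to 1). PWM scanning scores windows by
#' log2 odds against the background and calls a hit when the score reaches
#' `score_threshold` times the maximum achievable score.
#'
#' @param name Motif name.
#' @param consensus IUPAC consensus string (A,C,G,T plus ambiguity codes).
#' @param pwm Numeric 4 x L matrix of per-position base probabilities.
#' @param background Background base frequencies (default uniform).
#' @param score_threshold Fraction of the maximum log-odds score in [0, 1]
#'   required for a PWM hit (default 0.8).
#' @return Object of class `motif_model`.
#' @export
motif_model <- function(name, consensus = NULL, pwm = NULL,
                        background = rep(0.25, 4), score_threshold = 0.8) {
  if (is.null(consensus) == is.null(pwm)) {
    abort("provide exactly one of `consensus` or `pwm`")
  }
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    bad <- setdiff(strsplit(consensus, "")[[1]], names(iupac_sets))
    if (length(bad) > 0) {
      abort(sprintf("non-IUPAC code(s) in consensus: %s", paste(bad, collapse = ", ")))
    }
  } else {
    if (!is.matrix(pwm) || nrow(pwm) != 4) abort("`pwm` must be a 4 x L matrix")
    if (any(abs(colSums(pwm) - 1) > 1e-6)) abort("`pwm` columns must sum to 1")
    rownames(pwm) <- c("A", "C", "G", "T")
    assert_fraction(score_threshold, "score_threshold")
  }
  structure(
    list(
      name = name, consensus = consensus, pwm = pwm,
      background = background / sum(background),
      score_threshold = score_threshold
    ),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf(
    "<motif_model> %s: %s\n", x$name,
    if (!is.null(x$consensus)) {
      paste0("consensus ", x$consensus)
    } else {
      sprintf("PWM of width %d (threshold %.2f of max)", ncol(x$pwm), x$score_threshold)
    }
  ))
  invisible(x)
}

motif_width <- function(motif) {
  if (!is.null(motif$consensus)) nchar(motif$consensus) else ncol(motif$pwm)
}

#' Bundled motif models
#'
#' Default models for the four motif families interrogated around
#' retinoblastoma regulatory regions: the estrogen-related receptor
#' response element (ERRE, TNAAGGTCA class) and canonical consensus
#' placeholders for the CRX/OTX2 (K50 homeodomain), NEUROD (E-box) and LHX
#' homeodomain families. These are implementer-chosen stand-ins for public
#' motif-collection matrices, not curated PWMs; swap in your own
#' [motif_model()]s for production scans.
#'
#' @return Named list of `motif_model`s.
#' @export
rb_motifs <- function() {
  models <- list(
    motif_model("ERRE", consensus = "TNAAGGTCA"),
    motif_model("CRX_OTX2", consensus = "TAATCC"),
    motif_model("NEUROD", consensus = "CAKCTG"),
    motif_model("LHX", consensus = "TAATTA")
  )
  setNames(models, vapply(models, function(m) m$name, character(1)))
}

# integer-encode a sequence; non-ACGT (incl. N) -> NA so it never matches
encode_dna <- function(sequence) {
  x <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  match(x, c("A", "C", "G", "T"))
}

# + strand hits of a motif on an encoded sequence; returns (start, score)
scan_plus <- function(enc, motif) {
  L <- motif_width(motif)
  n <- length(enc)
  if (L > n) {
    return(tibble(start = integer(), score = double()))
  }
  n_win <- n - L + 1L
  if (!is.null(motif$consensus)) {
    letters_ <- strsplit(motif$consensus, "", fixed = TRUE)[[1]]
    ok <- rep(TRUE, n_win)
    for (k in seq_len(L)) {
      allowed <- match(iupac_sets[[letters_[k]]], c("A", "C", "G", "T"))
      b <- enc[k:(k + n_win - 1L)]
      ok <- ok & !is.na(b) & b %in% allowed
    }
    tibble(start = which(ok), score = rep(as.numeric(L), sum(ok)))
  } else {
    lo <- log2(motif$pwm / motif$background)
    max_score <- sum(apply(lo, 2, max))
    score <- rep(0, n_win)
    valid <- rep(TRUE, n_win)
    for (k in seq_len(L)) {
      b <- enc[k:(k + n_win - 1L)]
      valid <- valid & !is.na(b)
      s <- lo[cbind(ifelse(is.na(b), 1L, b), k)]
      score <- score + ifelse(is.na(b), 0, s)
    }
    hit <- valid & score >= motif$score_threshold * max_score
    tibble(start = which(hit), score = score[hit])
  }
}

#' Scan a sequence for motif hits on both strands
#'
#' Consensus mode reports every window matching the IUPAC pattern; PWM mode
#' reports windows whose log2-odds score reaches the model threshold. An N
#' (or any non-ACGT character) in the sequence never matches. Minus-strand
#' hits are found on the reverse complement and reported in the original
#' coordinates (start = leftmost base of the site on the + strand).
#'
#' @param sequence A single DNA string over A/C/G/T/N.
#' @param motif A [motif_model()].
#' @return Tibble (start, strand, score), 1-based starts, sorted.
#' @export
scan_motif <- function(sequence, motif) {
  if (!inherits(motif, "motif_model")) abort("`motif` must be a motif_model")
  enc <- encode_dna(sequence)
  L <- motif_width(motif)
  n <- length(enc)
  plus <- scan_plus(enc, motif) |> mutate(strand = "+")
  enc_rc <- rev(5L - enc) # A<->T, C<->G on the reversed sequence
  minus <- scan_plus(enc_rc, motif) |>
    mutate(start = n - (.data$start + L - 1L) + 1L, strand = "-")
  bind_rows(plus, minus) |>
    select("start", "strand", "score") |>
    arrange(.data$start, .data$strand)
}

#' Motif presence matrix over regions or gene windows
#'
#' One row per named sequence (a peak region or a TSS +/- 3 kb gene
#' window), one column per motif; `TRUE` when the sequence holds at least
#' one hit on either strand.
#'
#' @param sequences Named character vector of DNA sequences.
#' @param motifs List of [motif_model()]s (named, or names taken from the
#'   models).
#' @return Logical matrix with sequence names as rows, motif names as
#'   columns.
#' @export
presence_matrix <- function(sequences, motifs) {
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("region%04d", seq_along(sequences))
  }
  if (anyDuplicated(names(sequences))) abort("sequence names must be unique")
  motif_names <- vapply(motifs, function(m) m$name, character(1))
  m <- vapply(
    motifs,
    function(mo) {
      vapply(sequences, function(s) nrow(scan_motif(s, mo)) > 0, logical(1))
    },
    logical(length(sequences))
  )
  m <- matrix(m,
    nrow = length(sequences),
    dimnames = list(names(sequences), motif_names)
  )
  m
}

#' Exact-subset (UpSet) co-occurrence counts of a presence matrix
#'
#' Counts rows by the exact set of motifs present (mutually exclusive
#' intersections, as in an UpSet plot); every possible subset is listed, so
#' the counts partition the rows and sum to `nrow(m)`.
#'
#' @param m Logical presence matrix from [presence_matrix()].
#' @return Tibble (subset, n) where subset is "+"-joined motif names
#'   ("none" for the empty set), plus one indicator column per motif.
#' @export
cooccurrence_counts <- function(m) {
  motifs <- colnames(m)
  k <- length(motifs)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(combos) <- motifs
  pattern_of <- function(mat) {
    apply(mat, 1, function(r) paste(ifelse(r, "1", "0"), collapse = ""))
  }
  obs <- table(factor(pattern_of(m), levels = pattern_of(as.matrix(combos))))
  label <- apply(combos, 1, function(r) {
    if (!any(r)) "none" else paste(motifs[as.logical(r)], collapse = "+")
  })
  bind_cols(
    tibble(subset = label, n = as.integer(obs)),
    as_tibble(combos)
  ) |>
    arrange(desc(.data$n))
}

#' Hypergeometric motif enrichment in a target row set
#'
#' One-sided hypergeometric test for over-representation of motif presence
#' in the target rows against the background rows (the universe is their
#' union; the sets are expected to be disjoint unless
#' `background_includes_target`). BH-adjusted across motifs.
#'
#' @param m Presence matrix from [presence_matrix()].
#' @param target_rows,background_rows Row names (or indices) of `m`.
#' @param background_includes_target Set TRUE when the background is the
#'   whole universe including the target.
#' @return Tibble (motif, n_target, n_universe, k_target, k_universe, p, q).
#' @export
enrichment_test <- function(m, target_rows, background_rows,
                            background_includes_target = FALSE) {
  to_names <- function(x) if (is.character(x)) x else rownames(m)[x]
  target <- to_names(target_rows)
  background <- to_names(background_rows)
  if (!all(c(target, background) %in% rownames(m))) {
    abort("target/background rows must be rows of `m`")
  }
  if (!background_includes_target && length(intersect(target, background)) > 0) {
    abort("target and background overlap; set `background_includes_target = TRUE`")
  }
  universe <- union(target, background)
  mt <- m[target, , drop = FALSE]
  mu <- m[universe, , drop = FALSE]
  res <- tibble(
    motif = colnames(m),
    n_target = length(target),
    n_universe = length(universe),
    k_target = as.integer(colSums(mt)),
    k_universe = as.integer(colSums(mu))
  ) |>
    mutate(
      p = phyper(.data$k_target - 1, .data$k_universe,
        .data$n_universe - .data$k_universe, .data$n_target,
        lower.tail = FALSE
      ),
      q = p.adjust(.data$p, method = "BH")
    )
  res
}
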