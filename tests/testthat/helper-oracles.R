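# Independent brute-force oracles. Deliberately naive: rule-by-rule,
# per-element loops, quadratic interval scans. They never call the package
# functions they check.

oracle_cascade_kept <- function(v, pon) {
  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = "_")
  pon_key <- paste(pon$chrom, pon$pos, pon$ref, pon$alt, sep = "_")
  indel_types <- c("insertion", "deletion", "MNV_nonframeshift")

  # shared-indel scan: keys in >=2 unmatched samples and 0 matched samples
  bad_shared <- character()
  for (k in unique(key[v$variant_type %in% indel_types])) {
    rows <- which(key == k & v$variant_type %in% indel_types)
    n_un <- length(unique(v$sample_id[rows][!v$matched_normal_available[rows]]))
    n_ma <- length(unique(v$sample_id[rows][v$matched_normal_available[rows]]))
    if (n_un >= 2 && n_ma == 0) bad_shared <- c(bad_shared, k)
  }

  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    ok <- TRUE
    j <- match(key[i], pon_key)
    if (!is.na(j) && pon$n_normals[j] >= 2) ok <- FALSE
    if (v$tumor_alt_reads[i] < 3) ok <- FALSE
    if (!is.na(v$blood_alt_reads[i]) &&
      v$tumor_alt_reads[i] < 8 && v$blood_alt_reads[i] > 1) {
      ok <- FALSE
    }
    if (v$tumor_vaf[i] < 0.05) ok <- FALSE
    if (!is.na(v$pop_maf_1000g[i]) && v$pop_maf_1000g[i] >= 0.01) ok <- FALSE
    if (!is.na(v$pop_maf_esp[i]) && v$pop_maf_esp[i] >= 0.01) ok <- FALSE
    if (v$in_dbsnp[i]) {
      exc <- (is.na(v$dbsnp_pop_maf[i]) || v$dbsnp_pop_maf[i] < 0.01) ||
        (!is.na(v$dbsnp_single_mapping[i]) && v$dbsnp_single_mapping[i]) ||
        v$dbsnp_clinical_tag[i]
      if (!exc) ok <- FALSE
    }
    if (v$variant_type[i] %in% indel_types && key[i] %in% bad_shared) ok <- FALSE
    keep[i] <- ok
  }
  keep
}

# all-pairs overlap clustering; returns tibble(chrom, start, end) of union
# spans of clusters containing peaks from both sets
oracle_high_confidence <- function(a, b) {
  all <- rbind(
    data.frame(chrom = a$chrom, start = a$start, end = a$end, src = "a"),
    data.frame(chrom = b$chrom, start = b$start, end = b$end, src = "b")
  )
  n <- nrow(all)
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    all$chrom[i] == all$chrom[j] &
      all$start[i] < all$end[j] & all$start[j] < all$end[i]
  })
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    nc <- nc + 1L
    queue <- s
    while (length(queue) > 0) {
      i <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[i])) next
      comp[i] <- nc
      queue <- c(queue, which(adj[i, ] & is.na(comp)))
    }
  }
  out <- NULL
  for (cl in unique(comp)) {
    members <- which(comp == cl)
    if (all(c("a", "b") %in% all$src[members])) {
      out <- rbind(out, data.frame(
        chrom = all$chrom[members[1]],
        start = min(all$start[members]),
        end = max(all$end[members])
      ))
    }
  }
  if (is.null(out)) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  tibble::as_tibble(out[order(out$chrom, out$start), ])
}

# exhaustive nearest-TSS scan, ties by smallest gene_id
oracle_assign <- function(peaks, genes) {
  center <- peaks$start + (peaks$end - peaks$start - 1L) %/% 2L + 1L
  gene_id <- rep(NA_character_, nrow(peaks))
  signed <- rep(NA_integer_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (nrow(g) == 0) next
    d <- abs(center[i] - g$tss)
    cand <- which(d == min(d))
    best <- cand[order(g$gene_id[cand])][1]
    gene_id[i] <- g$gene_id[best]
    signed[i] <- if (g$strand[best] == "+") {
      center[i] - g$tss[best]
    } else {
      g$tss[best] - center[i]
    }
  }
  ad <- abs(signed)
  bin <- ifelse(is.na(ad), "far_over100kb",
    ifelse(ad <= 3000, "promoter_3kb",
      ifelse(ad <= 10000, "mid_3to10kb",
        ifelse(ad <= 100000, "distal_10to100kb", "far_over100kb")
      )
    )
  )
  tibble::tibble(gene_id = gene_id, signed_distance = signed, bin = bin)
}

# priority scan of the peak center over promoter/utr/exon/intron classes
oracle_annotate <- function(peaks, genes, features = NULL, window = 3000) {
  center <- peaks$start + (peaks$end - peaks$start - 1L) %/% 2L + 1L
  out <- character(nrow(peaks))
  in_feature <- function(i, f) {
    if (is.null(features)) return(FALSE)
    ft <- features[features$feature == f, ]
    if (nrow(ft) == 0) return(FALSE)
    hit <- FALSE
    for (r in seq_len(nrow(ft))) {
      gch <- genes$chrom[genes$gene_id == ft$gene_id[r]][1]
      if (!is.na(gch) && gch == peaks$chrom[i] &&
        center[i] >= ft$start[r] + 1 && center[i] <= ft$end[r]) {
        hit <- TRUE
      }
    }
    hit
  }
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (any(abs(center[i] - g$tss) <= window)) {
      out[i] <- "promoter"
    } else if (in_feature(i, "utr5")) {
      out[i] <- "utr5"
    } else if (in_feature(i, "utr3")) {
      out[i] <- "utr3"
    } else if (in_feature(i, "exon")) {
      out[i] <- "exon"
    } else if (all(c("gene_start", "gene_end") %in% names(genes)) &&
      nrow(g) > 0 &&
      any(center[i] >= g$gene_start + 1 & center[i] <= g$gene_end)) {
      out[i] <- "intron"
    } else {
      out[i] <- "intergenic"
    }
  }
  out
}

oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(s, "")[[1]])), collapse = "")
}

# naive per-position scan, both strands
oracle_scan <- function(sequence, motif) {
  iupac <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  scan_one <- function(seq_chars) {
    n <- length(seq_chars)
    hits <- integer()
    scores <- numeric()
    if (!is.null(motif$consensus)) {
      pat <- strsplit(motif$consensus, "")[[1]]
      L <- length(pat)
      for (i in seq_len(max(0, n - L + 1))) {
        ok <- TRUE
        for (k in seq_len(L)) {
          ch <- seq_chars[i + k - 1]
          if (!(ch %in% c("A", "C", "G", "T")) || !(ch %in% iupac[[pat[k]]])) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          hits <- c(hits, i)
          scores <- c(scores, L)
        }
      }
    } else {
      lo <- log2(motif$pwm / motif$background)
      L <- ncol(lo)
      max_score <- sum(apply(lo, 2, max))
      for (i in seq_len(max(0, n - L + 1))) {
        s <- 0
        ok <- TRUE
        for (k in seq_len(L)) {
          ch <- seq_chars[i + k - 1]
          if (!(ch %in% c("A", "C", "G", "T"))) {
            ok <- FALSE
            break
          }
          s <- s + lo[ch, k]
        }
        if (ok && s >= motif$score_threshold * max_score) {
          hits <- c(hits, i)
          scores <- c(scores, s)
        }
      }
    }
    list(start = hits, score = scores)
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  L <- if (!is.null(motif$consensus)) nchar(motif$consensus) else ncol(motif$pwm)
  p <- scan_one(chars)
  m <- scan_one(strsplit(oracle_revcomp(toupper(sequence)), "")[[1]])
  df <- rbind(
    data.frame(start = p$start, strand = rep("+", length(p$start)), score = p$score),
    data.frame(
      start = n - (m$start + L - 1) + 1,
      strand = rep("-", length(m$start)), score = m$score
    )
  )
  tibble::as_tibble(df[order(df$start, df$strand), ])
}

# per-base copy-ratio mean over an arm (segments must not overlap)
oracle_arm_score <- function(segments, arm_start, arm_end) {
  vals <- rep(NA_real_, arm_end - arm_start)
  for (i in seq_len(nrow(segments))) {
    lo <- max(segments$start[i], arm_start)
    hi <- min(segments$end[i], arm_end)
    if (hi > lo) vals[(lo - arm_start + 1):(hi - arm_start)] <- segments$log2_ratio[i]
  }
  mean(vals, na.rm = TRUE)
}
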