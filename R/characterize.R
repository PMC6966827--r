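#' GC content of nucleotide sequences
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from the denominator.
#' An all-N (or empty) sequence yields `NA`.
#'
#' @param seq Character vector of sequences over ACGTN (case-insensitive).
#' @return Numeric vector of GC fractions.
#' @export
#' @examples
#' gc_content(c("GCGC", "ATAT", "ATGC")) # 1, 0, 0.5
gc_content <- function(seq) {
  seq <- toupper(as.character(seq))
  vapply(seq, function(s) {
    if (!nzchar(s)) return(NA_real_)
    tab <- table(strsplit(s, "", fixed = TRUE)[[1]])
    gc <- sum(tab[names(tab) %in% c("G", "C")])
    acgt <- sum(tab[names(tab) %in% c("A", "C", "G", "T")])
    if (acgt == 0) NA_real_ else gc / acgt
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-event GC content of an intron and its flanking exons
#'
#' @param intron_seq,upstream_seq,downstream_seq Character vectors of equal
#'   length (one entry per event).
#' @return data.frame gc_intron, gc_flank (pooled flanks), gc_diff
#'   (intron minus flank).
#' @export
event_gc <- function(intron_seq, upstream_seq, downstream_seq) {
  gi <- gc_content(intron_seq)
  gf <- gc_content(paste0(upstream_seq, downstream_seq))
  data.frame(gc_intron = gi, gc_flank = gf, gc_diff = gi - gf)
}

#' One-tailed Welch comparison of two groups
#'
#' Welch's unequal-variance t statistic with a one-tailed p-value for the
#' stated alternative; intended for log2 intron lengths and per-event GC
#' differences. When both groups have zero variance and equal means the
#' p-value is 0.5 by convention (with a warning).
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param alternative "greater" (mean of `a` exceeds mean of `b`) or "less".
#' @param log2_transform Apply `log2` to both groups first (for lengths).
#' @return List: statistic, df, p_value, mean_a, mean_b.
#' @export
group_compare <- function(a, b, alternative = c("greater", "less"),
                          log2_transform = FALSE) {
  alternative <- match.arg(alternative)
  if (length(a) < 2L || length(b) < 2L)
    stop_input("input error: each group needs >= 2 values")
  if (log2_transform) {
    if (any(c(a, b) <= 0))
      stop_input("input error: log2 transform requires positive values")
    a <- log2(a); b <- log2(b)
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      warning("zero variance in both groups with equal means; p = 0.5")
      return(list(statistic = 0, df = NA_real_, p_value = 0.5,
                  mean_a = mean(a), mean_b = mean(b)))
    }
    tstat <- if (mean(a) > mean(b)) Inf else -Inf
    p <- switch(alternative,
                greater = as.numeric(tstat < 0),
                less = as.numeric(tstat > 0))
    return(list(statistic = tstat, df = NA_real_, p_value = p,
                mean_a = mean(a), mean_b = mean(b)))
  }
  se2 <- va / length(a) + vb / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  p <- switch(alternative,
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              less = stats::pt(tstat, df, lower.tail = TRUE))
  list(statistic = tstat, df = df, p_value = p,
       mean_a = mean(a), mean_b = mean(b))
}

#' Quantile-normalize the columns of a matrix
#'
#' Maps every column to the mean sorted profile; tied values receive the
#' mean of their tied ranks' target quantiles. After normalization all
#' columns have identical sorted values and the transform is idempotent.
#'
#' @param x Numeric matrix (rows = regions, columns = samples).
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  ref <- rowMeans(apply(x, 2L, sort))
  apply(x, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    # interpolate target quantiles at (possibly fractional) average ranks
    stats::approx(seq_along(ref), ref, xout = r)$y
  })
}

#' RPKM, quantile normalization, and per-event standardization of ChIP signal
#'
#' Converts region counts to RPKM
#' (`count / ((length/1000) * (libsize/1e6))`), quantile-normalizes the
#' sample columns, and standardizes each event's (upstream exon, intron,
#' downstream exon) triplet to mean 0 and sample (n-1) standard deviation 1
#' within each sample -- removing the 5'-to-3' polymerase coverage decay so
#' retained and spliced events can be compared. Set `scope = "region"` to
#' standardize across samples per region instead.
#'
#' @param counts Numeric matrix regions x samples.
#' @param lengths Region lengths in bp (> 0), one per row.
#' @param lib_sizes Library sizes (> 0), one per column.
#' @param event Factor/vector of event ids grouping rows into triplets.
#' @param scope "event" (default; standardize within each event's triplet
#'   per sample) or "region" (standardize each row across samples).
#' @return List: rpkm, normalized (quantile-normalized RPKM), standardized.
#' @export
normalize_signal <- function(counts, lengths, lib_sizes, event,
                             scope = c("event", "region")) {
  scope <- match.arg(scope)
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop_input("input error: zero-length region")
  if (any(lib_sizes <= 0)) stop_input("input error: library sizes must be > 0")
  if (length(lengths) != nrow(counts) || length(lib_sizes) != ncol(counts))
    stop_input("input error: dimension mismatch")
  rpkm <- sweep(sweep(counts, 1L, lengths / 1000, "/"),
                2L, lib_sizes / 1e6, "/")
  qn <- quantile_normalize(rpkm)
  std <- qn
  if (scope == "event") {
    for (ev in split(seq_len(nrow(qn)), event)) {
      block <- qn[ev, , drop = FALSE]
      mu <- colMeans(block)
      sdv <- apply(block, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      std[ev, ] <- sweep(sweep(block, 2L, mu), 2L, sdv, "/")
    }
  } else {
    mu <- rowMeans(qn)
    sdv <- apply(qn, 1L, stats::sd)
    sdv[sdv == 0] <- 1
    std <- sweep(sweep(qn, 1L, mu), 1L, sdv, "/")
  }
  list(rpkm = rpkm, normalized = qn, standardized = std)
}

#' Paired uORF-overlap test between increased- and decreased-retention introns
#'
#' Filters uORFs to those shorter than 201 bp, computes per line the
#' proportion of positive-dPSI introns overlapping at least one uORF and
#' the same for negative-dPSI introns, logit-transforms the proportions
#' with the continuity correction `(x + 0.5) / (n + 1)`, and applies a
#' paired one-tailed t-test across lines (alternative: positive > negative).
#' Lines lacking introns of either sign are excluded with a warning.
#'
#' @param introns data.frame with columns line, chrom, start, end,
#'   dpsi_sign (+1 / -1), 0-based half-open coordinates.
#' @param uorfs data.frame with chrom, start, end (0-based half-open).
#' @param max_uorf_length uORFs of this length or longer are dropped
#'   (default 201, i.e., keep < 201 bp).
#' @return List: per_line (line, prop_pos, prop_neg, n_pos, n_neg),
#'   statistic, df, p_value, n_lines_used, n_uorfs_used.
#' @export
uorf_overlap_test <- function(introns, uorfs, max_uorf_length = 201L) {
  u <- uorfs[(uorfs$end - uorfs$start) < max_uorf_length, , drop = FALSE]
  per_line <- lapply(split(introns, introns$line), function(d) {
    pos <- d[d$dpsi_sign > 0, , drop = FALSE]
    neg <- d[d$dpsi_sign < 0, , drop = FALSE]
    if (nrow(pos) == 0L || nrow(neg) == 0L) return(NULL)
    ov <- function(x) {
      hits <- rep(FALSE, nrow(x))
      for (ch in unique(x$chrom)) {
        xi <- x$chrom == ch
        ui <- u[u$chrom == ch, , drop = FALSE]
        if (!nrow(ui)) next
        q <- IRanges::IRanges(x$start[xi] + 1L, x$end[xi])
        s <- IRanges::IRanges(ui$start + 1L, ui$end)
        hits[xi] <- IRanges::overlapsAny(q, s)
      }
      hits
    }
    data.frame(line = d$line[1],
               n_pos = nrow(pos), n_neg = nrow(neg),
               x_pos = sum(ov(pos)), x_neg = sum(ov(neg)),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(per_line, is.null, logical(1)))
  if (dropped > 0L)
    warning(dropped, " line(s) without introns of both signs excluded")
  per_line <- do.call(rbind, per_line)
  if (is.null(per_line) || nrow(per_line) < 2L)
    stop_input("input error: fewer than 2 usable lines")
  per_line$prop_pos <- per_line$x_pos / per_line$n_pos
  per_line$prop_neg <- per_line$x_neg / per_line$n_neg
  lp <- logit_cc(per_line$x_pos, per_line$n_pos)
  ln <- logit_cc(per_line$x_neg, per_line$n_neg)
  diffs <- lp - ln
  n <- length(diffs)
  sdd <- stats::sd(diffs)
  if (sdd == 0) {
    tstat <- if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
    p <- if (mean(diffs) > 0) 0 else if (mean(diffs) == 0) 0.5 else 1
  } else {
    tstat <- mean(diffs) / (sdd / sqrt(n))
    p <- stats::pt(tstat, n - 1, lower.tail = FALSE)
  }
  rownames(per_line) <- NULL
  list(per_line = per_line, statistic = tstat, df = n - 1, p_value = p,
       n_lines_used = n, n_uorfs_used = nrow(u))
}
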