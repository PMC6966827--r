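#' Filter isoforms by assigned read support
#'
#' Keeps an isoform only if it has more than `min_reads` reads assigned in at
#' least `min_sample_frac` of the samples (default: more than one read in 90%
#' of samples). Ratios of surviving isoforms are renormalized to sum to 1 per
#' sample; genes left with fewer than two isoforms are excluded from
#' differential testing but retained for entropy (a single-isoform gene has
#' H = 0).
#'
#' @param tensor A `ratio_tensor` (long data frame with line, condition,
#'   gene_id, isoform_id, ratio, count).
#' @param min_reads Reads an isoform must exceed per sample.
#' @param min_sample_frac Fraction of samples in which the read rule must
#'   hold.
#' @return The filtered `ratio_tensor`; attribute `excluded_genes` lists
#'   genes with < 2 surviving isoforms, attribute `dropped_isoforms` the
#'   removed isoforms.
#' @export
filter_isoforms <- function(tensor, min_reads = 1, min_sample_frac = 0.9) {
  if (!"count" %in% names(tensor) || all(is.na(tensor$count)))
    stop_input("input error: 'tensor' carries no assigned read counts")

  ok_frac <- tapply(tensor$count > min_reads, tensor$isoform_id, mean)
  keep_iso <- names(ok_frac)[ok_frac >= min_sample_frac]
  dropped <- setdiff(unique(tensor$isoform_id), keep_iso)

  out <- tensor[tensor$isoform_id %in% keep_iso, , drop = FALSE]
  if (nrow(out)) {
    key <- interaction(out$line, out$condition, out$gene_id, drop = TRUE)
    tot <- tapply(out$ratio, key, sum)
    denom <- as.numeric(tot[match(key, names(tot))])
    out$ratio <- ifelse(denom > 0, out$ratio / denom, 0)
  }
  n_iso <- tapply(out$isoform_id, out$gene_id,
                  function(x) length(unique(x)))
  excluded <- union(names(n_iso)[n_iso < 2L],
                    setdiff(unique(tensor$gene_id), names(n_iso)))
  rownames(out) <- NULL
  structure(out,
            truth = attr(tensor, "truth"),
            lines = attr(tensor, "lines"),
            excluded_genes = sort(excluded),
            dropped_isoforms = sort(dropped),
            class = c("ratio_tensor", "data.frame"))
}

#' Shannon entropy of a proportion vector
#'
#' `H = -sum(p_i * log(p_i))` in nats, with `0 * log(0)` taken as 0. This is
#' the Shannon diversity of a gene's isoform ratios; it is 0 for a
#' single-isoform gene and at most `log(K)` for `K` isoforms.
#'
#' @param p Numeric proportion vector summing to 1.
#' @return Entropy in nats.
#' @export
#' @examples
#' shannon_entropy(c(0.5, 0.5))        # log(2)
#' shannon_entropy(c(0.5, 0.25, 0.25)) # 1.5 * log(2)
shannon_entropy <- function(p) {
  if (any(is.na(p)) || any(p < 0))
    stop_input("input error: proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6)
    stop_input("input error: proportions must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-sample, per-gene Shannon entropy
#'
#' @param tensor A `ratio_tensor`.
#' @return data.frame with line, condition, gene_id, n_isoforms, entropy.
#' @export
entropy_by_sample <- function(tensor) {
  key <- interaction(tensor$line, tensor$condition, tensor$gene_id,
                     drop = TRUE, sep = "\r")
  ent <- tapply(tensor$ratio, key, function(p) {
    p <- p / sum(p)
    p <- p[p > 0]
    -sum(p * log(p))
  })
  n_iso <- tapply(tensor$ratio, key, length)
  parts <- do.call(rbind, strsplit(names(ent), "\r", fixed = TRUE))
  out <- data.frame(line = parts[, 1], condition = parts[, 2],
                    gene_id = parts[, 3],
                    n_isoforms = as.integer(n_iso),
                    entropy = as.numeric(ent),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$line, out$condition, out$gene_id), ]
}

#' Summarize per-line diversity shifts and entropy strata
#'
#' For each line, counts genes whose entropy increased (`dH > eps`) or
#' decreased (`dH < -eps`) after infection, where
#' `dH = H(infected) - H(control)`, and reports the net shift. Also returns
#' mean entropy per isoform-count stratum and condition (and per resistance
#' class when `class_labels` is supplied), together with a per-stratum
#' two-factor least-squares fit of per-sample mean entropy on condition and
#' class.
#'
#' @param entropy data.frame from [entropy_by_sample()], containing both
#'   conditions for every line.
#' @param eps Unchanged tolerance on `dH` (default 1e-9; exact ties occur
#'   only for unchanged ratio vectors).
#' @param class_labels Optional named character vector mapping line to a
#'   class label (e.g., resistant/susceptible).
#' @return List with `shift` (per-line counts and net), `delta` (per
#'   line x gene dH), `strata` (mean entropy per stratum), and `class_lm`
#'   (per-stratum class p-values, or NULL).
#' @export
diversity_shift_summary <- function(entropy, eps = 1e-9,
                                    class_labels = NULL) {
  conds <- unique(entropy$condition)
  if (!all(c("control", "infected") %in% conds))
    stop_input("input error: both conditions must be present")

  wide <- merge(
    entropy[entropy$condition == "control",
            c("line", "gene_id", "n_isoforms", "entropy")],
    entropy[entropy$condition == "infected", c("line", "gene_id", "entropy")],
    by = c("line", "gene_id"), suffixes = c("_control", "_infected")
  )
  if (!nrow(wide)) stop_input("input error: no line/gene pairs with both conditions")
  wide$delta <- wide$entropy_infected - wide$entropy_control

  shift <- do.call(rbind, lapply(split(wide, wide$line), function(d) {
    data.frame(line = d$line[1],
               n_up = sum(d$delta > eps),
               n_down = sum(d$delta < -eps),
               net = sum(d$delta > eps) - sum(d$delta < -eps),
               stringsAsFactors = FALSE)
  }))
  rownames(shift) <- NULL

  # per-sample mean entropy within isoform-count strata
  samp <- stats::aggregate(entropy ~ line + condition + n_isoforms,
                           data = entropy, FUN = mean)
  if (!is.null(class_labels)) samp$class <- class_labels[samp$line]

  strata_by <- if (is.null(class_labels)) {
    list(n_isoforms = samp$n_isoforms, condition = samp$condition)
  } else {
    list(n_isoforms = samp$n_isoforms, condition = samp$condition,
         class = samp$class)
  }
  strata <- stats::aggregate(samp$entropy, by = strata_by, FUN = mean)
  names(strata)[names(strata) == "x"] <- "mean_entropy"

  class_lm <- NULL
  if (!is.null(class_labels)) {
    class_lm <- do.call(rbind, lapply(split(samp, samp$n_isoforms),
                                      function(d) {
      if (length(unique(d$class)) < 2L) return(NULL)
      fit <- stats::lm(entropy ~ condition + class, data = d)
      cf <- summary(fit)$coefficients
      row <- grep("^class", rownames(cf))
      data.frame(n_isoforms = d$n_isoforms[1],
                 class_estimate = cf[row[1], 1],
                 class_p = cf[row[1], 4], stringsAsFactors = FALSE)
    }))
    if (!is.null(class_lm)) rownames(class_lm) <- NULL
  }

  list(shift = shift, delta = wide, strata = strata, class_lm = class_lm)
}

#' Distance-based multivariate test of isoform-ratio differences
#'
#' Permutation test on Euclidean distances between per-sample isoform-ratio
#' vectors (a two-group PERMANOVA): the statistic is the pseudo-F of
#' between-condition versus within-condition squared distances, the effect
#' size is the between-group fraction of the total sum of squares
#' (R-squared, in `[0, 1]`), and significance is the permutation tail
#' probability with the add-one correction `(count + 1) / (n_perm + 1)`.
#' A companion homogeneity (dispersion) test permutes distances to the own
#' group centroid and reports the tail probability of the dispersion F; the
#' main test is only interpretable when dispersions are comparable.
#'
#' @param x Numeric matrix, samples x isoforms, rows the per-sample ratio
#'   vectors of one gene.
#' @param labels Condition label per row (two groups).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed for the permutation draw.
#' @param perm_index Optional precomputed permutation matrix
#'   (`n_perm x n`, each row a permutation of `1:n`), shared across genes.
#' @return List with `statistic` (pseudo-F), `effect_size`, `p_value`,
#'   `homogeneity_p`, `n_perm`.
#' @export
distance_splicing_test <- function(x, labels, n_perm = 10000, seed = NULL,
                                   perm_index = NULL) {
  x <- as.matrix(x)
  f <- factor(labels)
  if (nlevels(f) != 2L) stop_input("input error: exactly two conditions required")
  n_g <- table(f)
  if (any(n_g < 2L)) stop_input("input error: >= 2 samples per condition required")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  n <- nrow(x)

  grand <- colMeans(x)
  sst <- sum(sweep(x, 2L, grand)^2)
  if (sst < 1e-12) {
    return(list(statistic = 0, effect_size = 0, p_value = 1,
                homogeneity_p = 1, n_perm = n_perm))
  }

  g1 <- f == levels(f)[1]
  n1 <- sum(g1); n2 <- n - n1
  ssb_of <- function(sel) {
    m1 <- colMeans(x[sel, , drop = FALSE])
    m2 <- colMeans(x[!sel, , drop = FALSE])
    n1 * sum((m1 - grand)^2) + n2 * sum((m2 - grand)^2)
  }
  ssb <- ssb_of(g1)
  ssw <- sst - ssb
  fstat <- (ssb / 1) / (ssw / (n - 2L))
  r2 <- ssb / sst

  # dispersion: distances to own group centroid
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  d <- sqrt(rowSums((x - rbind(m1, m2)[2L - g1, , drop = FALSE])^2))
  disp_f <- function(dv, sel) {
    mu1 <- mean(dv[sel]); mu2 <- mean(dv[!sel]); mu <- mean(dv)
    b <- n1 * (mu1 - mu)^2 + n2 * (mu2 - mu)^2
    w <- sum((dv[sel] - mu1)^2) + sum((dv[!sel] - mu2)^2)
    if (w < 1e-15) return(if (b < 1e-15) 0 else Inf)
    (b / 1) / (w / (n - 2L))
  }
  disp_obs <- disp_f(d, g1)

  perm <- perm_index
  if (is.null(perm)) {
    perm <- with_seed(seed, {
      t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
    })
  }
  n_perm <- nrow(perm)

  # vectorized permuted SSB via group-1 sums
  sel_mat <- matrix(FALSE, n_perm, n)
  sel_mat[cbind(rep(seq_len(n_perm), n1),
                as.vector(perm[, seq_len(n1), drop = FALSE]))] <- TRUE
  s1 <- (sel_mat + 0) %*% x                       # n_perm x K group-1 sums
  stot <- colSums(x)
  m1p <- s1 / n1
  m2p <- sweep(-s1, 2L, stot, "+") / n2
  ssb_perm <- n1 * rowSums(sweep(m1p, 2L, grand)^2) +
    n2 * rowSums(sweep(m2p, 2L, grand)^2)
  p_val <- (sum(ssb_perm >= ssb - 1e-12 * max(1, ssb)) + 1) / (n_perm + 1)

  s1d <- as.numeric((sel_mat + 0) %*% d)
  s1d2 <- as.numeric((sel_mat + 0) %*% d^2)
  mu1p <- s1d / n1
  mu2p <- (sum(d) - s1d) / n2
  mu <- mean(d)
  bp <- n1 * (mu1p - mu)^2 + n2 * (mu2p - mu)^2
  wp <- (s1d2 - n1 * mu1p^2) + ((sum(d^2) - s1d2) - n2 * mu2p^2)
  fp <- ifelse(wp < 1e-15, ifelse(bp < 1e-15, 0, Inf),
               bp / (wp / (n - 2L)))
  homog_p <- (sum(fp >= disp_obs - 1e-12 * max(1, disp_obs)) + 1) /
    (n_perm + 1)

  list(statistic = fstat, effect_size = r2, p_value = p_val,
       homogeneity_p = homog_p, n_perm = n_perm)
}

#' Differential-splicing test across all genes of a ratio tensor
#'
#' Runs [distance_splicing_test()] per gene on the samples of a (filtered)
#' ratio tensor, shares one permutation draw across genes, applies
#' Benjamini-Hochberg adjustment, and flags genes significant when the
#' homogeneity p exceeds `homog_alpha`, the adjusted p falls below `alpha`,
#' and the effect size exceeds `effect_threshold`.
#'
#' @param tensor A `ratio_tensor`, ideally after [filter_isoforms()].
#' @param n_perm Permutations per gene.
#' @param effect_threshold Effect-size cutoff (0.1 by default; 0.2 is the
#'   stricter variant reported in some analyses).
#' @param alpha BH-adjusted significance level.
#' @param homog_alpha Minimum homogeneity p required to trust the location
#'   test.
#' @param seed Optional seed for the shared permutation draw.
#' @return data.frame per gene: n_isoforms, statistic, effect_size, p_value,
#'   p_adj, homogeneity_p, significant.
#' @export
splicing_test_all <- function(tensor, n_perm = 10000, effect_threshold = 0.1,
                              alpha = 0.05, homog_alpha = 0.05, seed = NULL) {
  excluded <- attr(tensor, "excluded_genes") %||% character()
  genes <- setdiff(unique(tensor$gene_id), excluded)
  n_iso_g <- tapply(tensor$isoform_id, tensor$gene_id,
                    function(x) length(unique(x)))
  genes <- genes[n_iso_g[genes] >= 2L]
  if (!length(genes))
    return(data.frame(gene_id = character(), n_isoforms = integer(),
                      statistic = numeric(), effect_size = numeric(),
                      p_value = numeric(), p_adj = numeric(),
                      homogeneity_p = numeric(), significant = logical()))

  # one sample set and one permutation draw shared by all genes
  d0 <- tensor[tensor$gene_id == genes[1], ]
  samp_key <- unique(d0[, c("line", "condition")])
  n <- nrow(samp_key)
  perm <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  })

  res <- lapply(genes, function(g) {
    d <- tensor[tensor$gene_id == g, ]
    iso <- sort(unique(d$isoform_id))
    m <- matrix(0, n, length(iso))
    ri <- match(paste(d$line, d$condition),
                paste(samp_key$line, samp_key$condition))
    m[cbind(ri, match(d$isoform_id, iso))] <- d$ratio
    tt <- distance_splicing_test(m, samp_key$condition, perm_index = perm)
    data.frame(gene_id = g, n_isoforms = length(iso),
               statistic = tt$statistic, effect_size = tt$effect_size,
               p_value = tt$p_value, homogeneity_p = tt$homogeneity_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$homogeneity_p > homog_alpha &
    out$p_adj < alpha & out$effect_size > effect_threshold
  rownames(out) <- NULL
  out[, c("gene_id", "n_isoforms", "statistic", "effect_size", "p_value",
          "p_adj", "homogeneity_p", "significant")]
}
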