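#' Ratio-weighted effective length
#'
#' The effective length of a gene (or of a feature such as its 5'UTR) in a
#' sample is the sum of per-isoform lengths weighted by that sample's isoform
#' ratios: `sum(L_i * p_i)`. It lies between the shortest and the longest
#' isoform length and equals the single length for one-isoform genes.
#'
#' @param lengths Numeric vector of per-isoform lengths (bp).
#' @param ratios Numeric proportion vector, same order, summing to 1.
#' @return Effective length in bp.
#' @export
#' @examples
#' effective_length(c(100, 200, 300), c(0.2, 0.3, 0.5)) # 230
effective_length <- function(lengths, ratios) {
  if (length(lengths) != length(ratios))
    stop_input("input error: length/ratio dimension mismatch")
  if (any(is.na(ratios)) || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-6)
    stop_input("input error: ratios must be a proportion vector summing to 1")
  sum(lengths * ratios)
}

#' Effective feature lengths for every sample of a ratio tensor
#'
#' Computes, per line, condition, and gene, the ratio-weighted effective
#' length of the transcript, 5'UTR, CDS, and 3'UTR, plus the
#' "transcript-minus-feature" variants (`minus_utr5`, `minus_cds`,
#' `minus_utr3`) used to attribute a length shift to a single feature.
#'
#' @param tensor A `ratio_tensor`.
#' @param lengths Per-isoform feature length table with columns gene_id,
#'   isoform_id, transcript_length, utr5_length, cds_length, utr3_length
#'   (e.g., from [lengths_from_genes()]).
#' @return data.frame line, condition, gene_id, feature, eff_length in long
#'   form, class `efflen_table`.
#' @export
effective_length_table <- function(tensor, lengths) {
  need <- c("gene_id", "isoform_id", "transcript_length", "utr5_length",
            "cds_length", "utr3_length")
  if (!all(need %in% names(lengths)))
    stop_input("input error: 'lengths' must have columns ",
               paste(need, collapse = ", "))
  li <- match(tensor$isoform_id, lengths$isoform_id)
  if (anyNA(li))
    stop_input("input error: isoforms missing from the length table: ",
               paste(utils::head(unique(tensor$isoform_id[is.na(li)])),
                     collapse = ", "))
  base <- c(transcript = "transcript_length", utr5 = "utr5_length",
            cds = "cds_length", utr3 = "utr3_length")
  key <- interaction(tensor$line, tensor$condition, tensor$gene_id,
                     drop = TRUE, sep = "\r")
  cols <- lapply(base, function(cn) {
    as.numeric(tapply(tensor$ratio * lengths[[cn]][li], key, sum))
  })
  parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  wide <- data.frame(line = parts[, 1], condition = parts[, 2],
                     gene_id = parts[, 3], stringsAsFactors = FALSE)
  wide$transcript <- cols$transcript
  wide$utr5 <- cols$utr5
  wide$cds <- cols$cds
  wide$utr3 <- cols$utr3
  wide$minus_utr5 <- wide$transcript - wide$utr5
  wide$minus_cds <- wide$transcript - wide$cds
  wide$minus_utr3 <- wide$transcript - wide$utr3
  long <- stats::reshape(wide, direction = "long",
                         varying = c("transcript", "utr5", "cds", "utr3",
                                     "minus_utr5", "minus_cds", "minus_utr3"),
                         v.names = "eff_length", timevar = "feature",
                         times = c("transcript", "utr5", "cds", "utr3",
                                   "minus_utr5", "minus_cds", "minus_utr3"),
                         idvar = c("line", "condition", "gene_id"))
  rownames(long) <- NULL
  structure(long[order(long$feature, long$line, long$condition,
                       long$gene_id), ],
            class = c("efflen_table", "data.frame"))
}

#' Per-line effective-length deltas (infected - control)
#'
#' @param efflen An `efflen_table` from [effective_length_table()].
#' @return data.frame line, gene_id, feature, delta.
#' @export
effective_length_deltas <- function(efflen) {
  ctrl <- efflen[efflen$condition == "control", ]
  inf <- efflen[efflen$condition == "infected", ]
  m <- merge(ctrl[, c("line", "gene_id", "feature", "eff_length")],
             inf[, c("line", "gene_id", "feature", "eff_length")],
             by = c("line", "gene_id", "feature"),
             suffixes = c("_control", "_infected"))
  m$delta <- m$eff_length_infected - m$eff_length_control
  m[, c("line", "gene_id", "feature", "delta")]
}

#' Classify effective-length deltas into increase / decrease / unchanged
#'
#' @param deltas Numeric vector of per-gene deltas (bp).
#' @param eps_bp Tolerance below which a delta counts as unchanged
#'   (default 1e-6 bp; single-isoform and ratio-stable genes produce exact
#'   zeros).
#' @return Named integer vector `c(increase, decrease, unchanged)`.
#' @export
classify_deltas <- function(deltas, eps_bp = 1e-6) {
  if (any(!is.finite(deltas))) stop_input("input error: deltas must be finite")
  c(increase = sum(deltas > eps_bp),
    decrease = sum(deltas < -eps_bp),
    unchanged = sum(abs(deltas) <= eps_bp))
}

#' G statistic for observed vs expected category counts
#'
#' `G = 2 * sum(O * log(O / E))` over categories, with `O = 0` terms
#' contributing 0. Expected counts of 0 paired with a positive observation
#' are floored at 0.5 with a warning (the statistic is undefined at E = 0).
#'
#' @param observed,expected Non-negative count vectors of equal length;
#'   `expected` is rescaled to the observed total.
#' @return The G statistic.
#' @export
#' @examples
#' g_statistic(c(20, 10, 0), c(10, 10, 10)) # 40 * log(2)
g_statistic <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop_input("input error: observed/expected length mismatch")
  e <- expected / sum(expected) * sum(observed)
  bad <- e == 0 & observed > 0
  if (any(bad)) {
    warning("expected count of 0 with positive observation; flooring at 0.5")
    e[bad] <- 0.5
  }
  keep <- observed > 0
  2 * sum(observed[keep] * log(observed[keep] / e[keep]))
}

#' Permutation/G-test of feature-length change proportions
#'
#' For each line and feature, classifies per-gene effective-length deltas
#' into increase/decrease/unchanged and compares the observed counts to a
#' permutation null obtained by randomly re-assigning infection status to
#' the samples (`mode = "full"`: samples are randomly re-paired into
#' pseudo-lines; `mode = "within_line"`: each line's two samples are
#' swapped at random, which with one sample per condition per line is the
#' paired variant of the same null). Expected counts are the mean category
#' proportions over permutations; the G statistic is referred to a
#' chi-squared distribution with 2 degrees of freedom, and a Bonferroni
#' threshold across line x feature tests is reported.
#'
#' @param efflen An `efflen_table`.
#' @param n_perm Number of permutations (default 100).
#' @param eps_bp Unchanged tolerance passed to [classify_deltas()].
#' @param mode Permutation scheme, see above.
#' @param seed Optional RNG seed.
#' @return List with `tests` (data.frame line, feature, increase, decrease,
#'   unchanged, observed proportions, expected proportions, G, p),
#'   `null_proportions` (per feature, an `n_perm x 3` matrix of null
#'   category proportions), `bonferroni` (adjusted alpha), `n_perm`.
#' @export
permutation_g_test <- function(efflen, n_perm = 100, eps_bp = 1e-6,
                               mode = c("full", "within_line"),
                               seed = NULL) {
  mode <- match.arg(mode)
  features <- unique(efflen$feature)
  lines <- sort(unique(efflen$line))
  n_lines <- length(lines)
  genes <- sort(unique(efflen$gene_id))
  n_genes <- length(genes)

  # genes x samples matrix per feature; samples = (line, condition)
  samp <- expand.grid(line = lines, condition = c("control", "infected"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_samp <- nrow(samp)
  mats <- lapply(features, function(ft) {
    d <- efflen[efflen$feature == ft, ]
    m <- matrix(NA_real_, n_genes, n_samp)
    ri <- match(d$gene_id, genes)
    ci <- match(paste(d$line, d$condition), paste(samp$line, samp$condition))
    m[cbind(ri, ci)] <- d$eff_length
    if (anyNA(m)) stop_input("input error: incomplete effective-length table")
    m
  })
  names(mats) <- features
  ctrl_col <- which(samp$condition == "control")
  inf_col <- which(samp$condition == "infected")

  prop3 <- function(delta_mat) {
    # delta_mat: genes x pairs -> category proportions per pair (3 x pairs)
    inc <- colSums(delta_mat > eps_bp)
    dec <- colSums(delta_mat < -eps_bp)
    unc <- nrow(delta_mat) - inc - dec
    rbind(increase = inc, decrease = dec, unchanged = unc) / nrow(delta_mat)
  }

  with_seed(seed, {
    null_props <- list()
    tests <- list()
    for (ft in features) {
      m <- mats[[ft]]
      obs_delta <- m[, inf_col, drop = FALSE] - m[, ctrl_col, drop = FALSE]
      obs_prop <- prop3(obs_delta)           # 3 x n_lines

      acc <- matrix(0, n_perm, 3L,
                    dimnames = list(NULL,
                                    c("increase", "decrease", "unchanged")))
      exp_line <- matrix(0, 3L, n_lines)
      for (b in seq_len(n_perm)) {
        if (mode == "full") {
          idx <- sample.int(n_samp)
          a <- idx[seq_len(n_lines)]
          bcol <- idx[n_lines + seq_len(n_lines)]
          pd <- m[, bcol, drop = FALSE] - m[, a, drop = FALSE]
        } else {
          swap <- stats::runif(n_lines) < 0.5
          sgn <- ifelse(swap, -1, 1)
          pd <- sweep(obs_delta, 2L, sgn, "*")
        }
        pp <- prop3(pd)
        acc[b, ] <- rowMeans(pp)
        exp_line <- exp_line + pp
      }
      exp_line <- exp_line / n_perm
      null_props[[ft]] <- acc

      expected <- if (mode == "full") {
        matrix(colMeans(acc), 3L, n_lines)   # pooled null per feature
      } else {
        exp_line                              # per-line null
      }

      g <- numeric(n_lines); pv <- numeric(n_lines)
      for (l in seq_len(n_lines)) {
        o <- obs_prop[, l] * n_genes
        e <- expected[, l] * n_genes
        g[l] <- g_statistic(o, e)
        pv[l] <- stats::pchisq(g[l], df = 2, lower.tail = FALSE)
      }
      tests[[ft]] <- data.frame(
        line = lines, feature = ft,
        increase = obs_prop[1, ] * n_genes,
        decrease = obs_prop[2, ] * n_genes,
        unchanged = obs_prop[3, ] * n_genes,
        prop_increase = obs_prop[1, ], prop_decrease = obs_prop[2, ],
        prop_unchanged = obs_prop[3, ],
        exp_increase = expected[1, ], exp_decrease = expected[2, ],
        exp_unchanged = expected[3, ],
        G = g, p_value = pv, stringsAsFactors = FALSE)
    }
    tests <- do.call(rbind, tests)
    rownames(tests) <- NULL
    list(tests = tests, null_proportions = null_props,
         bonferroni = 0.05 / nrow(tests), n_perm = n_perm)
  })
}

#' Classify how a gene's 3'UTR set can change its effective length
#'
#' Multi-isoform genes fall into three mechanistic classes: no annotated
#' 3'UTR length difference (the UTR cannot contribute to effective-length
#' diversity), `Splicing` (isoform 3'UTRs are built from different numbers
#' of exons), and `Alternate3Poly` (same exon count, common start, different
#' end positions, i.e., alternative polyadenylation). Anything else is
#' ambiguous and pooled with the no-difference class.
#'
#' @param isoforms data.frame of one gene's isoforms with columns
#'   utr3_length, utr3_exons, utr3_start, utr3_end.
#' @return One of "NoAnnotatedDiff/Ambiguous", "Splicing", "Alternate3Poly".
#' @export
classify_3utr_mechanism <- function(isoforms) {
  need <- c("utr3_length", "utr3_exons", "utr3_start", "utr3_end")
  if (!all(need %in% names(isoforms)))
    stop_input("input error: missing 3'UTR records (need ",
               paste(need, collapse = ", "), ")")
  if (nrow(isoforms) == 0L) stop_input("input error: no isoforms supplied")
  if (nrow(isoforms) < 2L || length(unique(isoforms$utr3_length)) < 2L)
    return("NoAnnotatedDiff/Ambiguous")
  if (length(unique(isoforms$utr3_exons)) > 1L)
    return("Splicing")
  if (length(unique(isoforms$utr3_start)) == 1L &&
      length(unique(isoforms$utr3_end)) > 1L)
    return("Alternate3Poly")
  "NoAnnotatedDiff/Ambiguous"
}

#' Classify the 3'UTR mechanism of every gene in a model set
#'
#' @param genes A `gene_models` object.
#' @return data.frame gene_id, utr3_class.
#' @export
classify_3utr_all <- function(genes) {
  stopifnot(inherits(genes, "gene_models"))
  iso_split <- split(genes$isoforms, genes$isoforms$gene_id)
  data.frame(gene_id = names(iso_split),
             utr3_class = vapply(iso_split, classify_3utr_mechanism,
                                 character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
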