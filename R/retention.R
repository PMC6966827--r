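#' Beta posterior for percent spliced-in (PSI)
#'
#' With retention-supporting reads `k_r` and splicing-supporting reads
#' `k_s`, the PSI posterior under a Beta prior is
#' `Beta(prior[1] + k_r', prior[2] + k_s')`, where the effective counts `k'`
#' are the raw counts divided by per-category position normalizers when the
#' event geometry supplies them (junction and intron-body reads have unequal
#' numbers of distinct start positions) and the raw counts otherwise.
#'
#' @param k_r Retention-supporting read count (exon-intron boundary plus
#'   intron body).
#' @param k_s Splicing-supporting read count (exon-exon junction).
#' @param prior Beta prior parameters, default uniform `c(1, 1)`.
#' @param normalizers Optional positive pair `c(retention, splicing)` of
#'   distinct read-start position counts.
#' @param conf Credible-interval mass (default 0.95).
#' @return List of class `psi_posterior`: alpha, beta, mean, ci (lower,
#'   upper), uncovered flag.
#' @export
#' @examples
#' psi_posterior(3, 7)$mean # 4/12
psi_posterior <- function(k_r, k_s, prior = c(1, 1), normalizers = NULL,
                          conf = 0.95) {
  if (any(prior <= 0)) stop_input("input error: prior parameters must be > 0")
  if (k_r < 0 || k_s < 0) stop_input("input error: counts must be >= 0")
  if (!is.null(normalizers)) {
    if (length(normalizers) != 2L || any(normalizers <= 0))
      stop_input("input error: normalizers must be two positive values")
    k_r <- k_r / normalizers[1]
    k_s <- k_s / normalizers[2]
  }
  a <- prior[1] + k_r
  b <- prior[2] + k_s
  lo <- (1 - conf) / 2
  structure(list(alpha = a, beta = b, mean = a / (a + b),
                 ci = c(lower = stats::qbeta(lo, a, b),
                        upper = stats::qbeta(1 - lo, a, b)),
                 uncovered = (k_r + k_s) == 0),
            class = "psi_posterior")
}

#' @export
print.psi_posterior <- function(x, ...) {
  cat(sprintf("PSI ~ Beta(%.3g, %.3g): mean %.4f, 95%% CI [%.4f, %.4f]%s\n",
              x$alpha, x$beta, x$mean, x$ci[1], x$ci[2],
              if (x$uncovered) " (uncovered)" else ""))
  invisible(x)
}

# Savage-Dickey Bayes factor for dPSI != 0 from Beta posterior parameters,
# vectorized over events. The prior density of the difference of two
# independent uniform PSIs at 0 is exactly 1 (triangular density); the
# posterior density at 0 is a Gaussian-kernel estimate from Monte-Carlo
# posterior draws (bandwidth by the standard bw.nrd0 rule).
bf_savage_dickey <- function(a_ctrl, b_ctrl, a_inf, b_inf, n_mc = 1e5,
                             seed = NULL, chunk = 500L) {
  m <- length(a_ctrl)
  stopifnot(length(b_ctrl) == m, length(a_inf) == m, length(b_inf) == m)
  with_seed(seed, {
    bf <- numeric(m); dens_se <- numeric(m)
    for (lo in seq(1L, m, by = chunk)) {
      hi <- min(lo + chunk - 1L, m)
      idx <- lo:hi
      k <- length(idx)
      d <- matrix(stats::rbeta(n_mc * k, rep(a_inf[idx], each = n_mc),
                               rep(b_inf[idx], each = n_mc)) -
                    stats::rbeta(n_mc * k, rep(a_ctrl[idx], each = n_mc),
                                 rep(b_ctrl[idx], each = n_mc)),
                  nrow = n_mc)
      for (j in seq_len(k)) {
        dj <- d[, j]
        bw <- stats::bw.nrd0(dj)
        kern <- stats::dnorm(0, mean = dj, sd = bw)
        f0 <- mean(kern)
        se0 <- stats::sd(kern) / sqrt(n_mc)
        bf[idx[j]] <- 1 / f0
        dens_se[idx[j]] <- se0
      }
    }
    list(bf = bf, dens_se = dens_se)
  })
}

#' Bayes-factor comparison of PSI between two conditions
#'
#' Places independent Beta posteriors on control and infected PSI (uniform
#' priors by default), reports the posterior expectation of
#' `dPSI = PSI(infected) - PSI(control)` (exact, from the Beta means), and
#' quantifies evidence against `dPSI = 0` with a Savage-Dickey density
#' ratio: prior density of dPSI at 0 (exactly 1 for independent uniform
#' priors) divided by a Monte-Carlo kernel estimate of the posterior density
#' of dPSI at 0.
#'
#' @param ctrl,inf Count pairs `c(k_r, k_s)` for the control and infected
#'   condition.
#' @param prior Beta prior parameters shared by both conditions.
#' @param n_mc Monte-Carlo draws for the posterior density estimate
#'   (default 1e5; < 1000 warns).
#' @param seed Optional RNG seed.
#' @return List: delta_psi (exact posterior mean difference), bf,
#'   bf_mc_se (propagated Monte-Carlo standard error), uncovered flag.
#' @export
#' @examples
#' r <- delta_psi_bayes_factor(c(2, 98), c(40, 60), seed = 1)
#' round(r$delta_psi, 4) # 0.3725
delta_psi_bayes_factor <- function(ctrl, inf, prior = c(1, 1), n_mc = 1e5,
                                   seed = NULL) {
  if (n_mc < 1000) warning("n_mc < 1000: Bayes factor will be noisy")
  if (any(c(ctrl, inf) < 0)) stop_input("input error: counts must be >= 0")
  uncovered <- sum(ctrl) == 0 || sum(inf) == 0
  a_c <- prior[1] + ctrl[1]; b_c <- prior[2] + ctrl[2]
  a_i <- prior[1] + inf[1]; b_i <- prior[2] + inf[2]
  dpsi <- a_i / (a_i + b_i) - a_c / (a_c + b_c)
  if (uncovered)
    return(list(delta_psi = NA_real_, bf = NA_real_, bf_mc_se = NA_real_,
                uncovered = TRUE))
  sd1 <- bf_savage_dickey(a_c, b_c, a_i, b_i, n_mc = n_mc, seed = seed)
  list(delta_psi = dpsi, bf = sd1$bf,
       bf_mc_se = sd1$dens_se * sd1$bf^2,  # delta method on 1/f0
       uncovered = FALSE)
}

#' Event x line PSI comparison table
#'
#' Applies [delta_psi_bayes_factor()] to every event x line of a retention
#' count table (both conditions required per pair) and flags pairs with
#' `bf > bf_threshold` and `|delta_psi| > dpsi_threshold` as significant.
#'
#' @param counts `retention_counts`-style data.frame with event_id, line,
#'   condition, k_r, k_s.
#' @param prior Beta prior parameters.
#' @param n_mc Monte-Carlo draws per pair (default 20000, adequate for a
#'   BF-vs-10 decision; raise for publication-grade Bayes factors).
#' @param bf_threshold,dpsi_threshold Significance thresholds (10 and 0.2).
#' @param seed Optional RNG seed.
#' @return data.frame event_id, line, delta_psi, bf, uncovered, significant,
#'   direction (sign of delta_psi for significant pairs, 0 otherwise).
#' @export
delta_psi_table <- function(counts, prior = c(1, 1), n_mc = 20000,
                            bf_threshold = 10, dpsi_threshold = 0.2,
                            seed = NULL) {
  ctrl <- counts[counts$condition == "control", ]
  inf <- counts[counts$condition == "infected", ]
  m <- merge(ctrl[, c("event_id", "line", "k_r", "k_s")],
             inf[, c("event_id", "line", "k_r", "k_s")],
             by = c("event_id", "line"), suffixes = c("_ctrl", "_inf"))
  a_c <- prior[1] + m$k_r_ctrl; b_c <- prior[2] + m$k_s_ctrl
  a_i <- prior[1] + m$k_r_inf; b_i <- prior[2] + m$k_s_inf
  m$delta_psi <- a_i / (a_i + b_i) - a_c / (a_c + b_c)
  m$uncovered <- (m$k_r_ctrl + m$k_s_ctrl) == 0 |
    (m$k_r_inf + m$k_s_inf) == 0
  res <- bf_savage_dickey(a_c, b_c, a_i, b_i, n_mc = n_mc, seed = seed)
  m$bf <- res$bf
  m$bf[m$uncovered] <- NA_real_
  m$delta_psi[m$uncovered] <- NA_real_
  m$significant <- !m$uncovered & m$bf > bf_threshold &
    abs(m$delta_psi) > dpsi_threshold
  m$direction <- ifelse(m$significant, sign(m$delta_psi), 0)
  m[, c("event_id", "line", "delta_psi", "bf", "uncovered", "significant",
        "direction")]
}

#' Cross-line recurrence of significant retention changes
#'
#' Counts, per event, the lines in which it is significantly increased or
#' decreased, lists events significant in at least `k` lines by direction,
#' and summarizes sign consistency: of the events increased in >= `k`
#' lines, how many are decreased in 0, 1, 2, ... other lines.
#'
#' @param results data.frame from [delta_psi_table()] (event_id, line,
#'   significant, direction).
#' @param k Recurrence threshold in lines (the motivating analyses used 4
#'   or 5; no canonical value is asserted).
#' @return List: `per_event` (event_id, up_lines, down_lines), `up_k`,
#'   `down_k` (event id vectors), `sign_consistency` (table of down-counts
#'   among `up_k` events), `k`.
#' @export
call_and_recur <- function(results, k) {
  n_lines <- length(unique(results$line))
  if (n_lines < 2L) stop_input("input error: at least 2 lines required")
  if (k > n_lines) stop_input("input error: k exceeds the number of lines")
  up <- tapply(results$direction == 1, results$event_id, sum)
  down <- tapply(results$direction == -1, results$event_id, sum)
  per_event <- data.frame(event_id = names(up),
                          up_lines = as.integer(up),
                          down_lines = as.integer(down[names(up)]),
                          row.names = NULL, stringsAsFactors = FALSE)
  up_k <- per_event$event_id[per_event$up_lines >= k]
  down_k <- per_event$event_id[per_event$down_lines >= k]
  cons <- table(per_event$down_lines[per_event$event_id %in% up_k])
  list(per_event = per_event, up_k = up_k, down_k = down_k,
       sign_consistency = cons, k = k)
}

#' Expected size and simulated significance of a multi-set overlap
#'
#' For sets of stated sizes drawn uniformly and independently from a
#' universe of `universe_n` items, the expected intersection size is
#' `N * prod(n_i / N)`. A simulated tail probability for an observed
#' intersection is computed by drawing `n_sim` random set collections and
#' applying the add-one correction.
#'
#' @param set_sizes Integer vector of set sizes.
#' @param universe_n Universe size.
#' @param observed Observed intersection size (optional; p is NA without
#'   it).
#' @param n_sim Simulation draws (default 10000).
#' @param seed Optional RNG seed.
#' @return List: expected, sim_mean, sim_sd, p_value, n_sim.
#' @export
#' @examples
#' expected_multiset_overlap(c(100, 50), 1000)$expected # 5
expected_multiset_overlap <- function(set_sizes, universe_n, observed = NULL,
                                      n_sim = 10000, seed = NULL) {
  if (any(set_sizes > universe_n))
    stop_input("input error: set size exceeds universe")
  expected <- universe_n * prod(set_sizes / universe_n)
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      tab <- integer(universe_n)
      for (sz in set_sizes) {
        idx <- sample.int(universe_n, sz)
        tab[idx] <- tab[idx] + 1L
      }
      sum(tab == length(set_sizes))
    }, integer(1))
  })
  p <- if (is.null(observed)) NA_real_
       else (1 + sum(sims >= observed)) / (1 + n_sim)
  list(expected = expected, sim_mean = mean(sims), sim_sd = stats::sd(sims),
       p_value = p, n_sim = n_sim)
}
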