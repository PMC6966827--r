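# Independent oracles kept deliberately naive; they never call the package
# code paths they are used to check.

# All-substrings motif scan: every (possibly overlapping) exact match.
# Enumerates every length-w window of the sequence and compares it with
# each motif.
brute_scan <- function(seq, motifs) {
  seq <- as.character(seq)
  n <- nchar(seq)
  out <- list()
  w <- 6L
  if (n < w)
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), stringsAsFactors = FALSE))
  windows <- substring(seq, seq_len(n - w + 1L), seq_len(n - w + 1L) + w - 1L)
  for (m in unique(motifs)) {
    starts <- which(windows == m)
    if (length(starts))
      out[[length(out) + 1L]] <- data.frame(start = starts - 1L,
                                            end = starts - 1L + w,
                                            motif = m,
                                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(start = integer(), end = integer(),
                      motif = character(), stringsAsFactors = FALSE)
  res <- res[order(res$start, res$end, res$motif), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Exact Savage-Dickey Bayes factor: the posterior density of
# D = PSI_inf - PSI_ctrl at 0 is the overlap integral of the two Beta
# posteriors; the prior density of D at 0 is exactly 1.
bf_oracle <- function(ctrl, inf, prior = c(1, 1)) {
  a_c <- prior[1] + ctrl[1]; b_c <- prior[2] + ctrl[2]
  a_i <- prior[1] + inf[1]; b_i <- prior[2] + inf[2]
  f0 <- stats::integrate(function(t) stats::dbeta(t, a_i, b_i) *
                           stats::dbeta(t, a_c, b_c),
                         0, 1, rel.tol = 1e-10)$value
  1 / f0
}

# Direct log-likelihood-ratio statistic for observed vs expected counts.
llr_oracle <- function(obs, expd) {
  e <- expd / sum(expd) * sum(obs)
  s <- 0
  for (i in seq_along(obs)) {
    if (obs[i] > 0) s <- s + obs[i] * log(obs[i] / e[i])
  }
  2 * s
}

# Character-count GC fraction.
gc_oracle <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  gc <- sum(ch %in% c("G", "C"))
  tot <- sum(ch %in% c("A", "C", "G", "T"))
  if (tot == 0) NA_real_ else gc / tot
}

# Small default-effect configuration used by several parameter-recovery
# tests; effect parameters stay at package defaults, only the sizes are
# scaled down for runtime.
small_sim_config <- function(seed, ...) {
  sim_config(n_genes = 60, n_lines = 8, n_events = 60,
             n_variants = 4000, n_sqtls = 400, seed = seed, ...)
}
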