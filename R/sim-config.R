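#' Default splicing-enhancer hexamer set
#'
#' A fixed, deterministic catalogue of 330 distinct hexamers standing in for
#' published exonic/intronic splicing enhancer (ESE/ISE) collections of that
#' size. Taking every 12th hexamer of the lexicographic enumeration spreads
#' the set evenly over sequence space, so on random sequence its per-base
#' coverage (roughly 40%) matches what a set of 330 real hexamers achieves.
#'
#' @param n Number of hexamers (default 330).
#' @return Character vector of distinct 6-mers over ACGT.
#' @export
#' @examples
#' length(default_hexamer_set())
default_hexamer_set <- function(n = 330L) {
  n <- check_count(n, "n", min = 1L)
  if (n > 4096L) stop_input("at most 4096 distinct hexamers exist")
  bases <- c("A", "C", "G", "T")
  all6 <- do.call(paste0, expand.grid(rep(list(bases), 6),
                                      stringsAsFactors = FALSE)[, 6:1])
  all6 <- sort(all6)
  idx <- round(seq(1L, 4096L, length.out = n))
  all6[idx]
}

#' Simulation configuration for the synthetic splicing dataset
#'
#' Bundles every tunable of the synthetic-data generators. Defaults encode
#' the study design the statistics were built for: inbred fly lines sampled
#' once per condition (control vs. enteric infection), genes with a handful
#' of annotated isoforms, intron-retention events read out by binomial
#' junction counts, and dense natural variation around genes.
#'
#' @param n_genes Number of genes.
#' @param isoform_count_distribution Probability vector over 1..K isoforms
#'   per gene.
#' @param n_lines Number of genetic lines; each contributes one control and
#'   one infected sample (38 lines in the motivating design).
#' @param dirichlet_concentration Dirichlet concentration of per-sample
#'   isoform-ratio draws around the gene's mean ratios; larger = tighter.
#' @param responder_fraction Fraction of genes whose isoform ratios respond
#'   to infection.
#' @param responder_utr5_shift Mean usage shift, in the infected condition,
#'   toward the responder gene's longest-5'UTR isoform (proportion moved to
#'   that isoform's mean ratio).
#' @param responder_concentration_factor Multiplier (< 1) on the Dirichlet
#'   concentration of responder genes in the infected condition; models the
#'   noisier post-infection ratios. Kept close to 1 so the planted response
#'   is primarily a mean shift (the distance test's homogeneity gate must
#'   not reject true responders).
#' @param responder_baseline_usage Length-2 range: the baseline (control)
#'   mean usage of the longest-5'UTR isoform in responder genes with two
#'   isoforms (scaled by `2/K` for `K` isoforms). Chosen so the planted
#'   usage gain ends at or below the uniform point, i.e., it evens the
#'   ratios (raising entropy and 5'UTR effective length) without inflating
#'   dispersion.
#' @param gene_read_depth Mean reads assigned per gene per sample (Poisson).
#' @param n_events Number of intron-retention events.
#' @param event_coverage Mean informative reads per event per sample
#'   (Poisson).
#' @param planted_delta_psi Planted PSI change (infected - control), in
#'   (-1, 1); applied with sign per event direction.
#' @param planted_event_fraction Fraction of events carrying a planted PSI
#'   change.
#' @param planted_up_fraction Of planted events, the fraction with increased
#'   retention (0.62, the observed 535:331 ratio of increased to decreased
#'   retention events).
#' @param shared_planted_fraction Fraction of planted events planted in all
#'   lines; the rest are planted in a random subset of lines.
#' @param line_plant_rate Per-line probability that a non-shared planted
#'   event carries the effect in that line.
#' @param n_variants Total number of variants (background + sQTLs).
#' @param n_sqtls Number of variants flagged as sQTLs.
#' @param af_spectrum Function `n -> n` allele frequencies in (0, 0.5]; the
#'   default is a low-frequency-skewed spectrum typical of population panels.
#' @param sqtl_positional_bias Fraction of planted sQTLs placed within
#'   `donor_window` bp immediately upstream of a splice donor.
#' @param donor_window Width (bp) of the donor-proximal placement window.
#' @param sqtl_element_enrichment Odds multiplier for a planted sQTL to fall
#'   inside a predicted splicing-enhancer hexamer match.
#' @param hexamer_set Character vector of 6-mers used as the ESE/ISE
#'   catalogue.
#' @param hexamer_plant_rate Expected number of additional hexamer copies
#'   planted per kb of intronic sequence (0 = rely on background matches).
#' @param uorf_enrichment Odds multiplier for an intron with planted
#'   increased retention to overlap a uORF.
#' @param uorf_base_rate Baseline probability that an intron overlaps a
#'   uORF.
#' @param seed Integer seed; identical seeds give bit-identical outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 20, n_lines = 4, seed = 1)
#' cfg$n_genes
sim_config <- function(n_genes = 200L,
                       isoform_count_distribution = c(0.4, 0.3, 0.2, 0.1),
                       n_lines = 38L,
                       dirichlet_concentration = 60,
                       responder_fraction = 0.3,
                       responder_utr5_shift = 0.1,
                       responder_concentration_factor = 0.95,
                       responder_baseline_usage = c(0.25, 0.4),
                       gene_read_depth = 200,
                       n_events = 500L,
                       event_coverage = 50,
                       planted_delta_psi = 0.4,
                       planted_event_fraction = 0.2,
                       planted_up_fraction = 0.62,
                       shared_planted_fraction = 0.5,
                       line_plant_rate = 0.3,
                       n_variants = 60000L,
                       n_sqtls = 6000L,
                       af_spectrum = function(n) {
                         pmax(0.5 * stats::rbeta(n, 0.7, 2.0), 1e-4)
                       },
                       sqtl_positional_bias = 0.2,
                       donor_window = 100L,
                       sqtl_element_enrichment = 1.15,
                       hexamer_set = default_hexamer_set(),
                       hexamer_plant_rate = 0,
                       uorf_enrichment = 2,
                       uorf_base_rate = 0.25,
                       seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", 1L),
    isoform_count_distribution = isoform_count_distribution,
    n_lines = check_count(n_lines, "n_lines", 1L),
    dirichlet_concentration = dirichlet_concentration,
    responder_fraction = check_proportion(responder_fraction,
                                          "responder_fraction"),
    responder_utr5_shift = responder_utr5_shift,
    responder_concentration_factor = responder_concentration_factor,
    responder_baseline_usage = responder_baseline_usage,
    gene_read_depth = gene_read_depth,
    n_events = check_count(n_events, "n_events", 0L),
    event_coverage = event_coverage,
    planted_delta_psi = planted_delta_psi,
    planted_event_fraction = check_proportion(planted_event_fraction,
                                              "planted_event_fraction"),
    planted_up_fraction = check_proportion(planted_up_fraction,
                                           "planted_up_fraction"),
    shared_planted_fraction = check_proportion(shared_planted_fraction,
                                               "shared_planted_fraction"),
    line_plant_rate = check_proportion(line_plant_rate, "line_plant_rate"),
    n_variants = check_count(n_variants, "n_variants", 0L),
    n_sqtls = check_count(n_sqtls, "n_sqtls", 0L),
    af_spectrum = af_spectrum,
    sqtl_positional_bias = check_proportion(sqtl_positional_bias,
                                            "sqtl_positional_bias"),
    donor_window = check_count(donor_window, "donor_window", 1L),
    sqtl_element_enrichment = sqtl_element_enrichment,
    hexamer_set = hexamer_set,
    hexamer_plant_rate = hexamer_plant_rate,
    uorf_enrichment = uorf_enrichment,
    uorf_base_rate = check_proportion(uorf_base_rate, "uorf_base_rate"),
    seed = check_count(seed, "seed", 0L)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  d <- cfg$isoform_count_distribution
  if (!is.numeric(d) || length(d) < 1L || any(d < 0) ||
      abs(sum(d) - 1) > 1e-8)
    stop_input("config error: 'isoform_count_distribution' must be ",
               "non-negative and sum to 1")
  if (!is.numeric(cfg$dirichlet_concentration) ||
      cfg$dirichlet_concentration <= 0)
    stop_input("config error: 'dirichlet_concentration' must be > 0")
  if (abs(cfg$planted_delta_psi) >= 1)
    stop_input("config error: 'planted_delta_psi' must lie in (-1, 1)")
  if (cfg$responder_utr5_shift < 0 || cfg$responder_utr5_shift > 1)
    stop_input("config error: 'responder_utr5_shift' must lie in [0, 1]")
  if (cfg$responder_concentration_factor <= 0)
    stop_input("config error: 'responder_concentration_factor' must be > 0")
  bu <- cfg$responder_baseline_usage
  if (length(bu) != 2L || any(bu <= 0) || bu[1] > bu[2] ||
      bu[2] + max(cfg$responder_utr5_shift, 0) >= 1)
    stop_input("config error: 'responder_baseline_usage' must be an ",
               "increasing pair with upper bound + shift < 1")
  if (cfg$event_coverage < 0)
    stop_input("config error: 'event_coverage' must be >= 0")
  if (!is.function(cfg$af_spectrum))
    stop_input("config error: 'af_spectrum' must be a function(n)")
  if (cfg$n_sqtls > cfg$n_variants)
    stop_input("config error: 'n_sqtls' cannot exceed 'n_variants'")
  if (length(cfg$hexamer_set) &&
      any(nchar(cfg$hexamer_set) != 6L |
            grepl("[^ACGT]", cfg$hexamer_set)))
    stop_input("config error: 'hexamer_set' must contain 6-mers over ACGT")
  if (cfg$hexamer_plant_rate > 0 && length(cfg$hexamer_set) == 0L)
    stop_input("config error: hexamer planting requested with an empty ",
               "'hexamer_set'")
  if (cfg$sqtl_element_enrichment <= 0 || cfg$uorf_enrichment <= 0)
    stop_input("config error: odds multipliers must be > 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic splicing dataset configuration\n")
  cat(sprintf("  genes: %d (isoforms 1..%d), lines: %d (x2 conditions)\n",
              x$n_genes, length(x$isoform_count_distribution), x$n_lines))
  cat(sprintf("  responders: %.0f%% (5'UTR shift %.2f)\n",
              100 * x$responder_fraction, x$responder_utr5_shift))
  cat(sprintf("  retention events: %d, coverage %.0f, planted dPSI %.2f (%.0f%%)\n",
              x$n_events, x$event_coverage, x$planted_delta_psi,
              100 * x$planted_event_fraction))
  cat(sprintf("  variants: %d (%d sQTLs), hexamers: %d, seed: %d\n",
              x$n_variants, x$n_sqtls, length(x$hexamer_set), x$seed))
  invisible(x)
}
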