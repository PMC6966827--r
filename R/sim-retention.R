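# Event selection and planted-truth construction shared by the retention
# count generator and the variant/uORF generator, so both see the same
# planted introns under a given seed.
retention_truth <- function(genes, config) {
  with_seed(derive_seed(config$seed, 303L), {
    introns <- genes$introns
    if (is.null(introns) || nrow(introns) < config$n_events)
      stop_input("n_events exceeds the number of available introns")
    ev_idx <- sort(sample.int(nrow(introns), config$n_events))
    events <- introns[ev_idx, , drop = FALSE]
    events$event_id <- sprintf("E%04d", seq_len(config$n_events))
    rownames(events) <- NULL

    n_ev <- config$n_events
    n_planted <- round(config$planted_event_fraction * n_ev)
    planted <- rep(FALSE, n_ev)
    planted[sample.int(n_ev, n_planted)] <- TRUE
    direction <- integer(n_ev)
    n_up <- round(config$planted_up_fraction * n_planted)
    up_pick <- sample_safe(which(planted), n_up)
    direction[up_pick] <- 1L
    direction[planted & direction == 0L] <- -1L

    shared <- rep(FALSE, n_ev)
    pl <- which(planted)
    if (length(pl))
      shared[sample_safe(pl,
                         round(config$shared_planted_fraction *
                                 length(pl)))] <- TRUE

    # Baseline PSI: planted-up events start low, planted-down start high so
    # the planted delta is realisable without heavy clipping; null events
    # follow a retention-skewed Beta.
    psi_ctrl <- stats::rbeta(n_ev, 2, 5)
    psi_ctrl[direction == 1L] <- stats::runif(sum(direction == 1L), 0.05, 0.45)
    psi_ctrl[direction == -1L] <- stats::runif(sum(direction == -1L), 0.55, 0.95)

    # Line application matrix: shared planted events carry the effect in all
    # lines, others in a random subset (at least one line).
    apply_mat <- matrix(FALSE, n_ev, config$n_lines)
    for (i in pl) {
      if (shared[i]) {
        apply_mat[i, ] <- TRUE
      } else {
        hit <- stats::runif(config$n_lines) < config$line_plant_rate
        if (!any(hit)) hit[sample.int(config$n_lines, 1L)] <- TRUE
        apply_mat[i, ] <- hit
      }
    }

    delta <- config$planted_delta_psi * direction
    psi_inf <- outer(psi_ctrl, rep(1, config$n_lines)) +
      apply_mat * delta
    psi_inf <- pmin(pmax(psi_inf, 0), 1)

    list(events = events,
         truth = data.frame(event_id = events$event_id,
                            gene_id = events$gene_id,
                            planted = planted, direction = direction,
                            shared = shared, psi_control = psi_ctrl,
                            stringsAsFactors = FALSE),
         apply_mat = apply_mat, psi_inf = psi_inf)
  })
}

#' Generate intron-retention read counts with planted PSI changes
#'
#' Samples `n_events` introns from the gene models. For each event, line,
#' and condition, total informative coverage is Poisson(`event_coverage`),
#' retention-supporting reads are Binomial(n, PSI) and splicing-supporting
#' reads make up the remainder. A `planted_event_fraction` of events carries
#' `planted_delta_psi` in the infected condition (clipped to `[0, 1]`); of
#' these, `shared_planted_fraction` are planted in every line (emulating
#' recurrent, genotype-independent retention changes), the rest in a random
#' subset of lines.
#'
#' @param genes A `gene_models` object.
#' @param config A [sim_config()].
#' @return An object of class `retention_counts`: a long data frame with
#'   columns event_id, line, condition, n, k_r, k_s, uncovered, plus
#'   attributes `events` (intron coordinates), `truth` (planted flags,
#'   directions, shared flags, baseline PSI), and `psi` (true PSI per
#'   event x line x condition).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 20, n_lines = 3, n_events = 10, seed = 1)
#' rc <- gen_retention_counts(gen_gene_models(cfg), cfg)
#' head(rc)
gen_retention_counts <- function(genes, config) {
  stopifnot(inherits(genes, "gene_models"), inherits(config, "sim_config"))
  if (abs(config$planted_delta_psi) >= 1)
    stop_input("config error: 'planted_delta_psi' must lie in (-1, 1)")
  tr <- retention_truth(genes, config)

  with_seed(derive_seed(config$seed, 304L), {
    n_ev <- config$n_events
    n_lines <- config$n_lines
    lines <- sprintf("L%02d", seq_len(n_lines))

    # event x line grids for the two conditions
    psi_c <- matrix(tr$truth$psi_control, n_ev, n_lines)
    psi_i <- tr$psi_inf

    draw <- function(psi) {
      n <- stats::rpois(length(psi), config$event_coverage)
      k_r <- stats::rbinom(length(psi), n, as.numeric(psi))
      list(n = n, k_r = k_r)
    }
    dc <- draw(psi_c)
    di <- draw(psi_i)

    grid <- expand.grid(event_id = tr$events$event_id, line = lines,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out <- rbind(
      data.frame(grid, condition = "control", n = dc$n, k_r = dc$k_r,
                 stringsAsFactors = FALSE),
      data.frame(grid, condition = "infected", n = di$n, k_r = di$k_r,
                 stringsAsFactors = FALSE)
    )
    out$k_s <- out$n - out$k_r
    out$uncovered <- out$n == 0L
    out <- out[, c("event_id", "line", "condition", "n", "k_r", "k_s",
                   "uncovered")]
    rownames(out) <- NULL

    psi_long <- rbind(
      data.frame(grid, condition = "control", psi = as.numeric(psi_c),
                 stringsAsFactors = FALSE),
      data.frame(grid, condition = "infected", psi = as.numeric(psi_i),
                 stringsAsFactors = FALSE)
    )

    structure(out, events = tr$events, truth = tr$truth,
              apply_mat = tr$apply_mat, psi = psi_long,
              class = c("retention_counts", "data.frame"))
  })
}
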