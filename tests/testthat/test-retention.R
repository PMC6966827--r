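test_that("psi_posterior follows the Beta update", {
  p <- psi_posterior(3, 7)
  expect_equal(p$alpha, 4)
  expect_equal(p$beta, 8)
  expect_equal(p$mean, 1 / 3)
  # no coverage: posterior is the prior, flagged uncovered
  p0 <- psi_posterior(0, 0, prior = c(2, 5))
  expect_equal(p0$alpha, 2)
  expect_equal(p0$beta, 5)
  expect_true(p0$uncovered)
  # interval concentrates with counts
  wide <- psi_posterior(5, 5)
  narrow <- psi_posterior(50, 50)
  expect_equal(narrow$mean, 0.5)
  expect_lt(diff(narrow$ci), diff(wide$ci))
  # effective-count normalizers
  pe <- psi_posterior(10, 20, normalizers = c(2, 4))
  expect_equal(pe$alpha, 1 + 5)
  expect_equal(pe$beta, 1 + 5)
  expect_error(psi_posterior(-1, 3), "counts")
  expect_error(psi_posterior(1, 1, prior = c(0, 1)), "prior")
})

test_that("posterior mean approaches the MLE as counts grow", {
  set.seed(8)
  for (i in 1:20) {
    n <- 1000 + rpois(1, 500)
    k <- rbinom(1, n, runif(1, 0.05, 0.95))
    p <- psi_posterior(k, n - k)
    expect_lt(abs(p$mean - k / n), 0.01)
  }
})

test_that("delta PSI Bayes factor matches the exact overlap-integral oracle", {
  # equal moderate counts: no difference, BF < 1
  r1 <- delta_psi_bayes_factor(c(50, 50), c(50, 50), n_mc = 2e5, seed = 1)
  expect_equal(r1$delta_psi, 0)
  expect_lt(r1$bf, 1)
  expect_equal(r1$bf, bf_oracle(c(50, 50), c(50, 50)), tolerance = 0.1)

  # strong difference: exact posterior means, BF > 10
  r2 <- delta_psi_bayes_factor(c(2, 98), c(40, 60), n_mc = 2e5, seed = 1)
  expect_equal(r2$delta_psi, 41 / 102 - 3 / 102, tolerance = 1e-12)
  expect_gt(r2$bf, 10)

  # minimal coverage: BF ~ 1 (oracle: 1 / 1.2)
  r3 <- delta_psi_bayes_factor(c(1, 1), c(1, 1), n_mc = 2e5, seed = 1)
  expect_equal(bf_oracle(c(1, 1), c(1, 1)), 1 / 1.2, tolerance = 1e-6)
  expect_equal(r3$bf, 1 / 1.2, tolerance = 0.15)
  expect_lt(abs(r3$bf - 1), 0.5)

  # symmetry: swapping conditions negates dPSI and preserves BF
  a <- delta_psi_bayes_factor(c(10, 40), c(30, 20), n_mc = 1e5, seed = 2)
  b <- delta_psi_bayes_factor(c(30, 20), c(10, 40), n_mc = 1e5, seed = 3)
  expect_equal(a$delta_psi, -b$delta_psi, tolerance = 1e-12)
  expect_equal(a$bf, b$bf, tolerance = 0.1 * a$bf)

  # uncovered events are flagged, not computed
  r4 <- delta_psi_bayes_factor(c(0, 0), c(5, 5), n_mc = 2000, seed = 1)
  expect_true(r4$uncovered)
  expect_true(is.na(r4$bf))
  expect_warning(delta_psi_bayes_factor(c(5, 5), c(5, 5), n_mc = 500,
                                        seed = 1), "noisy")
})

test_that("delta_psi_table flags by BF and |dPSI| thresholds", {
  counts <- rbind(
    data.frame(event_id = "e1", line = "L1", condition = "control",
               k_r = 2, k_s = 98),
    data.frame(event_id = "e1", line = "L1", condition = "infected",
               k_r = 60, k_s = 40),
    data.frame(event_id = "e2", line = "L1", condition = "control",
               k_r = 30, k_s = 70),
    data.frame(event_id = "e2", line = "L1", condition = "infected",
               k_r = 32, k_s = 68),
    data.frame(event_id = "e3", line = "L1", condition = "control",
               k_r = 0, k_s = 0),
    data.frame(event_id = "e3", line = "L1", condition = "infected",
               k_r = 10, k_s = 10))
  res <- delta_psi_table(counts, n_mc = 20000, seed = 4)
  expect_true(res$significant[res$event_id == "e1"])
  expect_equal(res$direction[res$event_id == "e1"], 1)
  expect_false(res$significant[res$event_id == "e2"])
  expect_true(res$uncovered[res$event_id == "e3"])
})

test_that("call_and_recur tabulates recurrence and sign consistency", {
  grid <- expand.grid(event_id = c("e1", "e2", "e3"),
                      line = sprintf("L%d", 1:4),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$direction <- 0
  grid$direction[grid$event_id == "e1"] <- 1           # up everywhere
  grid$direction[grid$event_id == "e2" & grid$line == "L1"] <- -1
  grid$significant <- grid$direction != 0
  for (k in 1:4) {
    r <- call_and_recur(grid, k)
    expect_true("e1" %in% r$up_k)
  }
  r2 <- call_and_recur(grid, 2)
  expect_false("e2" %in% r2$down_k)
  expect_equal(r2$per_event$down_lines[r2$per_event$event_id == "e1"], 0)
  expect_equal(names(r2$sign_consistency), "0")
  r0 <- call_and_recur(transform(grid, direction = 0, significant = FALSE), 2)
  expect_length(r0$up_k, 0)
  expect_length(r0$down_k, 0)
  expect_error(call_and_recur(grid, 9), "exceeds")
})

test_that("expected multi-set overlap: closed forms and simulation agreement", {
  expect_equal(expected_multiset_overlap(c(100, 50), 1000, n_sim = 10,
                                         seed = 1)$expected, 5)
  expect_equal(expected_multiset_overlap(c(100, 100, 100), 1000, n_sim = 10,
                                         seed = 1)$expected, 1)
  expect_error(expected_multiset_overlap(c(2000), 1000, n_sim = 10), "universe")
  r <- expected_multiset_overlap(c(100, 50), 1000, observed = 20,
                                 n_sim = 10000, seed = 5)
  se <- r$sim_sd / sqrt(r$n_sim)
  expect_lt(abs(r$sim_mean - r$expected), 3 * se + 1e-9)
  expect_lt(r$p_value, 0.01) # 20 shared of expected 5 is extreme
})

test_that("recurrence recovers shared planted events from synthetic counts", {
  cfg <- sim_config(n_genes = 60, n_lines = 10, n_events = 60,
                    planted_event_fraction = 0.25,
                    shared_planted_fraction = 0.6,
                    event_coverage = 50, planted_delta_psi = 0.4, seed = 53)
  rc <- gen_retention_counts(gen_gene_models(cfg), cfg)
  res <- delta_psi_table(rc, n_mc = 4000, seed = 6)
  rec <- call_and_recur(res, k = 5)
  truth <- attr(rc, "truth")
  shared_up <- truth$event_id[truth$planted & truth$shared &
                                truth$direction == 1]
  expect_gte(mean(shared_up %in% rec$up_k), 0.8)
  false_in_list <- setdiff(rec$up_k,
                           truth$event_id[truth$planted &
                                            truth$direction == 1])
  expect_lte(length(false_in_list), max(1, 0.05 * length(rec$up_k)))
})
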