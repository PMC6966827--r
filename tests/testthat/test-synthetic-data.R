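test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(n_genes = 5), "sim_config")
  expect_error(sim_config(isoform_count_distribution = c(0.5, 0.4)),
               "sum to 1")
  expect_error(sim_config(dirichlet_concentration = 0), "> 0")
  expect_error(sim_config(planted_delta_psi = 1), "-1, 1")
  expect_error(sim_config(hexamer_plant_rate = 1, hexamer_set = character()),
               "empty")
  expect_error(sim_config(n_sqtls = 10, n_variants = 5), "exceed")
})

test_that("gene models respect the config and the length decomposition", {
  cfg1 <- sim_config(n_genes = 10,
                     isoform_count_distribution = 1, seed = 3)
  gm1 <- gen_gene_models(cfg1)
  expect_equal(nrow(gm1$genes), 10L)
  expect_true(all(gm1$genes$n_isoforms == 1L))

  cfg2 <- sim_config(n_genes = 25,
                     isoform_count_distribution = c(0, 1), seed = 3)
  gm2 <- gen_gene_models(cfg2)
  expect_true(all(gm2$genes$n_isoforms == 2L))

  iso <- gm2$isoforms
  expect_equal(iso$transcript_length,
               iso$utr5_length + iso$cds_length + iso$utr3_length)

  # intron intervals disjoint and within the gene span
  for (gid in gm2$genes$gene_id) {
    itr <- gm2$introns[gm2$introns$gene_id == gid, ]
    g <- gm2$genes[gm2$genes$gene_id == gid, ]
    if (!nrow(itr)) next
    itr <- itr[order(itr$start), ]
    expect_true(all(itr$start >= g$start & itr$end <= g$end))
    if (nrow(itr) > 1L)
      expect_true(all(itr$start[-1] >= itr$end[-nrow(itr)]))
  }
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 15, n_lines = 3, n_events = 15,
                    n_variants = 500, n_sqtls = 50, seed = 11)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
})

test_that("ratio samples sum to one and responders are flagged as forced", {
  cfg <- sim_config(n_genes = 50, n_lines = 4,
                    isoform_count_distribution = c(0, 0.5, 0.5),
                    responder_fraction = 0.3, seed = 5)
  rt <- gen_ratio_samples(gen_gene_models(cfg), cfg)
  sums <- tapply(rt$ratio,
                 interaction(rt$line, rt$condition, rt$gene_id, drop = TRUE),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(rt$ratio >= 0 & rt$ratio <= 1))
  truth <- attr(rt, "truth")
  expect_equal(sum(truth$responder), round(0.3 * 50))
  # counts conserve the multinomial structure
  expect_true(all(rt$count >= 0))
})

test_that("null configuration leaves the two conditions exchangeable", {
  cfg <- sim_config(n_genes = 80, n_lines = 10, responder_fraction = 0,
                    isoform_count_distribution = c(0, 1), seed = 13)
  rt <- gen_ratio_samples(gen_gene_models(cfg), cfg)
  ent <- entropy_by_sample(rt)
  s <- diversity_shift_summary(ent)
  # with no planted effect the mean per-line net shift is ~0
  tt <- t.test(s$shift$net)
  expect_gt(tt$p.value, 0.01)
})

test_that("retention counts conserve reads and honour the planted truth", {
  cfg <- sim_config(n_genes = 40, n_lines = 5, n_events = 50,
                    planted_event_fraction = 0.1, seed = 7)
  rc <- gen_retention_counts(gen_gene_models(cfg), cfg)
  expect_true(all(rc$k_r + rc$k_s == rc$n))
  expect_true(all(rc$k_r >= 0 & rc$k_s >= 0))
  truth <- attr(rc, "truth")
  expect_equal(sum(truth$planted), round(0.1 * 50))

  # zero coverage flags every event uncovered
  cfg0 <- sim_config(n_genes = 40, n_lines = 2, n_events = 20,
                     event_coverage = 0, seed = 7)
  rc0 <- gen_retention_counts(gen_gene_models(cfg0), cfg0)
  expect_true(all(rc0$n == 0L))
  expect_true(all(rc0$uncovered))

  # unplanted delta: mean empirical dPSI across events ~ 0
  cfgn <- sim_config(n_genes = 60, n_lines = 10, n_events = 80,
                     planted_event_fraction = 0, event_coverage = 100,
                     seed = 19)
  rcn <- gen_retention_counts(gen_gene_models(cfgn), cfgn)
  psi_hat <- with(rcn, tapply(k_r / pmax(n, 1),
                              interaction(condition, event_id), mean))
  dpsi <- psi_hat[grep("^infected", names(psi_hat))] -
    psi_hat[grep("^control", names(psi_hat))]
  se <- sd(dpsi) / sqrt(length(dpsi))
  expect_lt(abs(mean(dpsi)), 3 * se + 1e-12)
})

test_that("variant generator honours point-mass AF and full donor bias", {
  cfg <- sim_config(n_genes = 30, n_lines = 2, n_events = 20,
                    n_variants = 600, n_sqtls = 100,
                    af_spectrum = function(n) rep(0.5, n),
                    sqtl_positional_bias = 1, seed = 23)
  gm <- gen_gene_models(cfg)
  vs <- gen_variants_and_elements(gm, cfg)
  expect_true(all(vs$variants$af == 0.5))

  sq <- vs$variants[vs$variants$is_sqtl, ]
  expect_true(all(sq$planted_donor))
  # every planted sQTL within donor_window bp upstream of some splice donor
  ok <- vapply(seq_len(nrow(sq)), function(i) {
    any((gm$introns$strand == "+" &
           sq$pos[i] >= gm$introns$donor - cfg$donor_window &
           sq$pos[i] < gm$introns$donor) |
          (gm$introns$strand == "-" &
             sq$pos[i] >= gm$introns$donor &
             sq$pos[i] < gm$introns$donor + cfg$donor_window))
  }, logical(1))
  expect_true(all(ok))
})

test_that("uORF enrichment at odds 1 leaves planted and other introns equal", {
  # pool overlap indicators over replicates: with uorf_enrichment = 1 the
  # planted-up introns must not be preferentially covered
  hits_up <- hits_other <- n_up <- n_other <- 0
  for (seed in 1:6) {
    cfg <- sim_config(n_genes = 60, n_lines = 2, n_events = 80,
                      n_variants = 200, n_sqtls = 20,
                      uorf_enrichment = 1, seed = seed)
    gm <- gen_gene_models(cfg)
    vs <- gen_variants_and_elements(gm, cfg)
    tr <- vs$truth
    ev <- attr(gen_retention_counts(gm, cfg), "events")
    up_introns <- ev$intron_id[match(tr$event_id[tr$planted & tr$direction == 1],
                                     ev$event_id)]
    u <- vs$uorfs
    ov <- vapply(seq_len(nrow(gm$introns)), function(i) {
      any(u$start < gm$introns$end[i] & u$end > gm$introns$start[i])
    }, logical(1))
    is_up <- gm$introns$intron_id %in% up_introns
    hits_up <- hits_up + sum(ov[is_up]); n_up <- n_up + sum(is_up)
    hits_other <- hits_other + sum(ov[!is_up]); n_other <- n_other + sum(!is_up)
  }
  p <- prop.test(c(hits_up, hits_other), c(n_up, n_other))$p.value
  expect_gt(p, 0.01)
})

test_that("planted 3'UTR classes are recovered by the classifier", {
  cfg <- sim_config(n_genes = 60,
                    isoform_count_distribution = c(0.2, 0.4, 0.2, 0.2),
                    seed = 29)
  gm <- gen_gene_models(cfg)
  called <- classify_3utr_all(gm)
  truth <- gm$genes[, c("gene_id", "utr3_class")]
  m <- merge(called, truth, by = "gene_id")
  expect_equal(m$utr3_class.x, m$utr3_class.y)
})
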