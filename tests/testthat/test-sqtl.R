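test_that("relative positions follow the strand-aware conventions", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c1",
                      start = c(1000L, 50000L), end = c(3000L, 52000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  v <- data.frame(chrom = "c1",
                  pos = c(1000L,   # TSS of + gene -> 0
                          2000L,   # midpoint of + gene -> 0.5
                          51999L,  # last base of - gene -> 0 after flip
                          50000L,  # start of - gene -> ~1 after flip
                          900L,    # 100 bp upstream of + gene
                          30000L)) # > 10 kb from both -> excluded
  r <- relative_positions(v, genes, flank = 10000L)
  expect_equal(attr(r, "n_excluded"), 1L)
  expect_equal(r$gene_metacoord[1], 0)
  expect_equal(r$gene_metacoord[2], 0.5)
  expect_equal(r$gene_metacoord[3], 1 - 1999 / 2000)
  expect_equal(r$gene_metacoord[4], 1 - 0)
  expect_equal(r$gene_metacoord[5], -100 / 10000)

  # intron-relative: 0 at the donor, 0.5 at the midpoint
  gm <- gen_gene_models(sim_config(n_genes = 6, seed = 43))
  itr <- gm$introns[1, ]
  mid <- floor((itr$start + itr$end) / 2)
  vv <- data.frame(chrom = itr$chrom, pos = c(itr$start, mid))
  rr <- relative_positions(vv, gm)
  if (itr$strand == "+") {
    expect_equal(rr$intron_metacoord[1], 0)
  }
  expect_equal(rr$intron_metacoord[2],
               if (itr$strand == "+") (mid - itr$start) / (itr$end - itr$start)
               else 1 - (mid - itr$start) / (itr$end - itr$start),
               tolerance = 1e-9)
})

test_that("metagene density integrates to one over the composite domain", {
  set.seed(5)
  x <- c(runif(500), -runif(200), 1 + runif(300))
  d <- metagene_density(x, n_body_bins = 50, n_flank_bins = 25)
  expect_equal(sum(d$density * (d$hi - d$lo)), 1, tolerance = 1e-9)
  expect_equal(sum(d$count), 1000)
})

test_that("AF-matched null sets reproduce the target AF histogram exactly", {
  set.seed(6)
  v <- data.frame(af = 0.5 * rbeta(5000, 0.8, 2) + 1e-4,
                  is_sqtl = rep(c(TRUE, FALSE), c(400, 4600)))
  sets <- af_matched_sample(v, n_sets = 25, af_bin_width = 0.02, seed = 1)
  expect_length(sets, 25)
  breaks <- seq(0, 0.52, by = 0.02)
  tgt <- table(cut(v$af[v$is_sqtl], breaks))
  for (s in sets[1:5]) {
    expect_length(s, 400)
    expect_false(any(v$is_sqtl[s]))
    expect_equal(as.integer(table(cut(v$af[s], breaks))), as.integer(tgt))
    expect_false(any(duplicated(s)))
  }
  # a bin without candidates errors with the bin named
  v2 <- data.frame(af = c(0.01, 0.30), is_sqtl = c(FALSE, TRUE))
  expect_error(af_matched_sample(v2, n_sets = 2), "candidates")
})

test_that("hexamer_scan matches examples and the brute-force oracle", {
  expect_equal(hexamer_scan("GATTACA", "ATTACA")[, c("start", "end")],
               data.frame(start = 1L, end = 7L))
  expect_equal(hexamer_scan("AAAAAAA", "AAAAAA")$start, c(0L, 1L))
  expect_equal(nrow(hexamer_scan("AAAAAAA", character())), 0L)
  # N in the subject never matches: no window may cross it
  expect_equal(hexamer_scan("AAAAAANAAAAAA", "AAAAAA")$start, c(0L, 7L))
  expect_error(hexamer_scan("ACGT", "ACG"), "6-mers")

  set.seed(7)
  motifs <- default_hexamer_set(12)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 2000,
                      replace = TRUE, prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    got <- hexamer_scan(s, motifs)
    want <- brute_scan(s, motifs)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$motif, want$motif)
  }
})

test_that("overlap_enrichment handles degenerate element sets", {
  nulls <- replicate(25, sample.int(1000, 50), simplify = FALSE)
  sq <- sample.int(1000, 50)
  # elements cover everything -> all percentages 100, z undefined, p = 1
  full <- data.frame(start = 0L, end = 2000L)
  r <- overlap_enrichment(sq, full, nulls)
  expect_equal(r$observed_pct, 100)
  expect_true(is.na(r$z))
  expect_equal(r$p_empirical, 1)
  # no elements -> observed 0
  none <- data.frame(start = integer(), end = integer())
  expect_equal(overlap_enrichment(sq, none, nulls)$observed_pct, 0)
  expect_error(overlap_enrichment(sq, full, nulls[1:5]), "20 null sets")
})

test_that("planted donor bias produces an intron-5' peak above the null", {
  cfg <- small_sim_config(seed = 47)
  gm <- gen_gene_models(cfg)
  vs <- gen_variants_and_elements(gm, cfg)
  rel <- relative_positions(vs$variants, gm)
  nulls_idx <- af_matched_sample(rel, n_sets = 40, seed = 2)
  nulls <- lapply(nulls_idx, function(i) rel[i, , drop = FALSE])
  mg <- sqtl_metagene(rel, nulls, axis = "intron", n_body_bins = 20,
                      n_flank_bins = 6)
  # peak bin: the upstream flank bin adjacent to the donor (hi == 0)
  peak <- which(abs(mg$bins$hi) < 1e-9)
  expect_gt(mg$observed$density[peak],
            mg$null_mean[peak] + 3 * mg$null_sd[peak])
})
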