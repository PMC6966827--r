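# Hand-built four-sample tensor: 2 lines x 2 conditions, one 3-isoform gene
# and one 2-isoform gene whose minor isoform has no read support.
toy_tensor <- function() {
  samples <- expand.grid(line = c("L1", "L2"),
                         condition = c("control", "infected"),
                         stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    rows[[length(rows) + 1L]] <- data.frame(
      line = samples$line[i], condition = samples$condition[i],
      gene_id = "gA", isoform_id = c("gA.1", "gA.2", "gA.3"),
      ratio = c(0.5, 0.3, 0.2), count = c(50L, 30L, 20L),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      line = samples$line[i], condition = samples$condition[i],
      gene_id = "gB", isoform_id = c("gB.1", "gB.2"),
      ratio = c(0.98, 0.02), count = c(98L, 0L),
      stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows),
            class = c("ratio_tensor", "data.frame"))
}

test_that("filter_isoforms applies the read-support rule and renormalizes", {
  tt <- toy_tensor()
  f <- filter_isoforms(tt)
  # gB.2 has 0 reads everywhere -> dropped; gB left with 1 isoform
  expect_false("gB.2" %in% f$isoform_id)
  expect_true("gB" %in% attr(f, "excluded_genes"))
  expect_true(all(abs(tapply(f$ratio,
                             interaction(f$line, f$condition, f$gene_id,
                                         drop = TRUE), sum) - 1) < 1e-9))
  # an isoform with 2 reads in 95% of samples is kept
  tt2 <- tt
  tt2$count[tt2$isoform_id == "gB.2"] <- 2L
  f2 <- filter_isoforms(tt2, min_reads = 1, min_sample_frac = 0.9)
  expect_true("gB.2" %in% f2$isoform_id)
  # counts are mandatory
  tt$count <- NULL
  expect_error(filter_isoforms(tt), "count")
})

test_that("shannon_entropy matches closed forms and bounds", {
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5 * log(2),
               tolerance = 1e-12)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
  expect_error(shannon_entropy(c(0.2, 0.2)), "sum to 1")
  # bounds: 0 <= H <= log(K) on random proportion vectors
  set.seed(1)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    p <- as.numeric(rexp(k)); p <- p / sum(p)
    h <- shannon_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log(k) + 1e-12)
  }
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4), tolerance = 1e-12)
})

test_that("entropy and the distance test agree with vegan", {
  set.seed(21)
  for (i in 1:20) {
    p <- as.numeric(rexp(sample(2:5, 1))); p <- p / sum(p)
    expect_equal(shannon_entropy(p),
                 unname(vegan::diversity(p, index = "shannon")),
                 tolerance = 1e-12)
  }
  # PERMANOVA statistic and effect size against adonis2 on the same matrix
  x <- rbind(matrix(rnorm(20, 0.4, 0.05), ncol = 2),
             matrix(rnorm(20, 0.5, 0.05), ncol = 2))
  grp <- rep(c("a", "b"), each = 10)
  mine <- distance_splicing_test(x, grp, n_perm = 499, seed = 1)
  ref <- vegan::adonis2(dist(x) ~ grp, permutations = 499)
  expect_equal(mine$effect_size, ref$R2[1], tolerance = 1e-9)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-9)
})

test_that("diversity_shift_summary counts shifts per line", {
  ent <- expand.grid(line = c("L1", "L2"), condition = c("control", "infected"),
                     gene_id = sprintf("g%d", 1:5),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ent$n_isoforms <- 2L
  ent$entropy <- 0.3
  # identical conditions -> net 0 everywhere
  s0 <- diversity_shift_summary(ent)
  expect_true(all(s0$shift$net == 0))
  # all infected entropies strictly greater -> net = gene count
  ent$entropy[ent$condition == "infected"] <- 0.5
  s1 <- diversity_shift_summary(ent)
  expect_true(all(s1$shift$net == 5))
  expect_true(all(s1$shift$n_down == 0))
  ent2 <- ent[ent$condition == "control", ]
  expect_error(diversity_shift_summary(ent2), "both conditions")
})

test_that("distance test: degenerate and separated cases", {
  # identical ratio vectors -> effect 0, p 1
  x <- matrix(rep(c(0.6, 0.4), each = 8), ncol = 2)
  r <- distance_splicing_test(x, rep(c("a", "b"), each = 4), n_perm = 200,
                              seed = 1)
  expect_equal(r$effect_size, 0)
  expect_equal(r$p_value, 1)

  # disjoint fixed vectors, 5 + 5 samples -> p <= 0.01
  x2 <- rbind(matrix(rep(c(0.9, 0.1), 5), ncol = 2, byrow = TRUE),
              matrix(rep(c(0.1, 0.9), 5), ncol = 2, byrow = TRUE))
  r2 <- distance_splicing_test(x2, rep(c("a", "b"), each = 5),
                               n_perm = 10000, seed = 1)
  expect_lte(r2$p_value, 0.01)
  expect_gt(r2$effect_size, 0.9)

  expect_error(distance_splicing_test(x2, rep("a", 10)), "two conditions")
  expect_error(distance_splicing_test(x2[1:6, ], c("a", rep("b", 5))),
               ">= 2 samples")
  expect_warning(distance_splicing_test(x2, rep(c("a", "b"), each = 5),
                                        n_perm = 50, seed = 1), "n_perm")
})

test_that("splicing_test_all recovers a strong responder and adjusts p", {
  set.seed(42)
  lines <- sprintf("L%d", 1:8)
  mk_gene <- function(gid, shift) {
    rows <- list()
    for (cond in c("control", "infected")) {
      for (l in lines) {
        p <- as.numeric(rdirichlet_local(c(6, 4)))
        if (cond == "infected" && shift > 0) {
          p <- (1 - shift) * p + shift * c(0, 1)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          line = l, condition = cond, gene_id = gid,
          isoform_id = paste0(gid, ".", 1:2), ratio = p,
          count = as.integer(rmultinom(1, 200, p)),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  rdirichlet_local <- function(alpha) {
    g <- rgamma(length(alpha), alpha)
    g / sum(g)
  }
  tensor <- structure(
    rbind(mk_gene("resp", 0.5), mk_gene("null1", 0), mk_gene("null2", 0)),
    class = c("ratio_tensor", "data.frame"))
  res <- splicing_test_all(tensor, n_perm = 999, seed = 1)
  expect_true(res$significant[res$gene_id == "resp"])
  expect_true(all(res$p_adj >= res$p_value - 1e-12))
  # BH monotone in raw p
  o <- order(res$p_value)
  expect_true(all(diff(res$p_adj[o]) >= -1e-12))
})
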