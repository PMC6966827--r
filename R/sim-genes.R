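#' Generate synthetic gene models
#'
#' Builds `n_genes` gene models on a single synthetic chromosome. Each gene
#' has an exon/intron backbone, a strand, and between 1 and K isoforms whose
#' transcript length decomposes exactly into 5'UTR + CDS + 3'UTR. Every
#' multi-isoform gene's 3'UTR set is constructed to fall deterministically
#' into one of the three mechanism classes recognized by
#' [classify_3utr_mechanism()] (no annotated difference, splicing, or
#' alternative polyadenylation), and the class is recorded as ground truth.
#'
#' Coordinates are 0-based, half-open. Minus-strand genes store per-isoform
#' features in transcription order, so "5' end" is strand-aware.
#'
#' @param config A [sim_config()].
#' @return An object of class `gene_models`: a list with data frames
#'   `genes` (gene_id, chrom, start, end, strand, n_isoforms, utr3_class,
#'   longest_utr5_isoform), `isoforms` (per-isoform feature lengths and
#'   3'UTR structure), and `introns` (genomic intron intervals with donor
#'   coordinates).
#' @export
#' @examples
#' gm <- gen_gene_models(sim_config(n_genes = 5, seed = 1))
#' gm$genes$utr3_class
gen_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 101L), {
    n <- config$n_genes
    kdist <- config$isoform_count_distribution
    kmax <- length(kdist)
    n_iso <- sample.int(kmax, n, replace = TRUE, prob = kdist)

    chrom <- "chrS"
    gap <- 25000L
    pos <- 20000L

    genes <- vector("list", n)
    isoforms <- vector("list", n)
    introns <- vector("list", n)

    # Observed frequencies of the three 3'UTR mechanism classes among
    # multi-isoform genes (387 splicing, 1138 alternative polyadenylation,
    # 2208 no-difference/ambiguous of 3733).
    class_levels <- c("NoAnnotatedDiff/Ambiguous", "Splicing", "Alternate3Poly")
    class_prob <- c(2208, 387, 1138) / 3733

    for (i in seq_len(n)) {
      gid <- sprintf("G%04d", i)
      k <- n_iso[i]
      strand <- sample(c("+", "-"), 1L)

      n_exons <- sample(2:8, 1L,
                        prob = c(0.25, 0.25, 0.2, 0.12, 0.08, 0.06, 0.04))
      exon_len <- pmin(pmax(round(stats::rlnorm(n_exons, log(250), 0.6)),
                            50L), 2000L)
      intron_len <- pmin(pmax(round(stats::rlnorm(n_exons - 1L, log(100), 1)),
                              40L), 5000L)

      # Gene-local layout: exon1 intron1 exon2 ... exonE.
      piece_len <- integer(2L * n_exons - 1L)
      piece_len[seq(1L, by = 2L, length.out = n_exons)] <- exon_len
      piece_len[seq(2L, by = 2L, length.out = n_exons - 1L)] <- intron_len
      offs <- cumsum(c(0L, piece_len))
      span <- offs[length(offs)]
      intron_local_start <- offs[seq(2L, by = 2L, length.out = n_exons - 1L)]
      intron_local_end <- intron_local_start +
        intron_len[seq_len(n_exons - 1L)]

      g_start <- pos
      g_end <- pos + span
      pos <- g_end + gap

      # Donor = 5' end of the intron in transcription order.
      donor <- if (strand == "+") g_start + intron_local_start
               else g_start + intron_local_end

      utr5 <- pmin(pmax(round(stats::rlnorm(k, log(150), 0.9)), 20L), 1500L)
      cds <- pmin(pmax(round(stats::rlnorm(1L, log(1200), 0.5)), 300L), 6000L)
      cds <- rep(cds, k)

      if (k == 1L) {
        cls <- "NoAnnotatedDiff/Ambiguous"
      } else {
        cls <- sample(class_levels, 1L, prob = class_prob)
      }
      base3 <- pmin(pmax(round(stats::rlnorm(1L, log(300), 0.5)), 50L), 2000L)
      if (cls == "NoAnnotatedDiff/Ambiguous") {
        utr3 <- rep(base3, k)
        utr3_exons <- rep(1L, k)
        utr3_start <- rep(0L, k)
        utr3_end <- utr3_start + utr3
      } else if (cls == "Splicing") {
        # Distinct 3'UTR exon counts force the splicing class.
        utr3 <- base3 + 60L * (seq_len(k) - 1L) +
          sample(0:40, k, replace = TRUE)
        utr3_exons <- c(1L, sample(2:3, k - 1L, replace = TRUE))
        utr3_start <- rep(0L, k)
        utr3_end <- utr3_start + utr3
      } else { # Alternate3Poly: single exon, common start, distinct ends.
        utr3 <- base3 + c(0L, cumsum(sample(50:400, k - 1L, replace = TRUE)))
        utr3 <- as.integer(sample(utr3))
        utr3_exons <- rep(1L, k)
        utr3_start <- rep(0L, k)
        utr3_end <- utr3_start + utr3
      }

      tx <- utr5 + cds + utr3
      genes[[i]] <- data.frame(
        gene_id = gid, chrom = chrom, start = g_start, end = g_end,
        strand = strand, n_isoforms = k, utr3_class = cls,
        longest_utr5_isoform = sprintf("%s.%d", gid, which.max(utr5)),
        stringsAsFactors = FALSE
      )
      isoforms[[i]] <- data.frame(
        gene_id = gid,
        isoform_id = sprintf("%s.%d", gid, seq_len(k)),
        transcript_length = tx, utr5_length = utr5, cds_length = cds,
        utr3_length = as.integer(utr3), exon_count = pmin(n_exons, 8L),
        utr3_exons = utr3_exons, utr3_start = utr3_start,
        utr3_end = as.integer(utr3_end),
        stringsAsFactors = FALSE
      )
      if (n_exons > 1L) {
        introns[[i]] <- data.frame(
          gene_id = gid,
          intron_id = sprintf("%s.I%d", gid, seq_len(n_exons - 1L)),
          chrom = chrom,
          start = g_start + intron_local_start,
          end = g_start + intron_local_end,
          strand = strand, donor = donor,
          stringsAsFactors = FALSE
        )
      }
    }

    out <- list(
      genes = do.call(rbind, genes),
      isoforms = do.call(rbind, isoforms),
      introns = do.call(rbind, introns)
    )
    rownames(out$genes) <- rownames(out$isoforms) <-
      rownames(out$introns) <- NULL
    structure(out, class = "gene_models")
  })
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d isoforms, %d introns on %s\n",
              nrow(x$genes), nrow(x$isoforms), nrow(x$introns),
              x$genes$chrom[1]))
  invisible(x)
}

#' Per-isoform feature length table from gene models
#'
#' Flattens gene models into the table consumed by
#' [effective_length_table()]: one row per isoform with transcript, 5'UTR,
#' CDS, and 3'UTR lengths. The synthetic annotation is shared across lines
#' (no per-line indel adjustment).
#'
#' @param genes A `gene_models` object.
#' @return data.frame with columns gene_id, isoform_id, transcript_length,
#'   utr5_length, cds_length, utr3_length.
#' @export
lengths_from_genes <- function(genes) {
  stopifnot(inherits(genes, "gene_models"))
  genes$isoforms[, c("gene_id", "isoform_id", "transcript_length",
                     "utr5_length", "cds_length", "utr3_length")]
}
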