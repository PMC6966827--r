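#' Generate variants, gene sequences with enhancer hexamers, and uORFs
#'
#' Emits the inputs of the positional-enrichment and intron-characterization
#' stages with planted effects:
#' \itemize{
#'   \item random gene-body sequences (uniform base composition at GC 0.43),
#'     optionally with extra hexamer copies planted in introns;
#'   \item predicted ESE/ISE element intervals obtained by scanning the
#'     hexamer catalogue against those sequences;
#'   \item background variants placed uniformly within gene bodies +/- 10 kb
#'     with allele frequencies drawn from `af_spectrum`;
#'   \item a planted sQTL subset of which `sqtl_positional_bias` are placed
#'     within `donor_window` bp immediately upstream of a splice donor, and
#'     whose odds of falling inside a predicted element are multiplied by
#'     `sqtl_element_enrichment`;
#'   \item uORF intervals whose odds of overlapping an intron with planted
#'     increased retention are multiplied by `uorf_enrichment`.
#' }
#'
#' @param genes A `gene_models` object.
#' @param config A [sim_config()].
#' @param truth Optional result of the internal retention-truth constructor;
#'   when `NULL` it is re-derived from `config$seed`, so the planted introns
#'   agree with [gen_retention_counts()] run on the same config.
#' @return A list of class `variant_sim` with components `variants`
#'   (data.frame chrom, pos, af, is_sqtl, gene_id, distance, planted_donor,
#'   in_element), `sequences` (named `Biostrings::DNAStringSet`, one per
#'   gene), `elements` (data.frame chrom, start, end of hexamer matches,
#'   0-based half-open), `uorfs` (data.frame chrom, start, end, length), and
#'   `truth` (planted retention events used for the uORF enrichment).
#' @export
gen_variants_and_elements <- function(genes, config, truth = NULL) {
  stopifnot(inherits(genes, "gene_models"), inherits(config, "sim_config"))
  if (nrow(genes$genes) == 0L) stop_input("'genes' is empty")
  if (config$hexamer_plant_rate > 0 && length(config$hexamer_set) == 0L)
    stop_input("config error: hexamer planting requested with an empty ",
               "'hexamer_set'")
  if (is.null(truth)) truth <- retention_truth(genes, config)

  gtab <- genes$genes
  introns <- genes$introns

  with_seed(derive_seed(config$seed, 505L), {
    ## --- sequences -------------------------------------------------------
    gc <- 0.43
    base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    span <- gtab$end - gtab$start
    seqs <- vapply(span, function(w) {
      paste(sample(names(base_prob), w, replace = TRUE, prob = base_prob),
            collapse = "")
    }, character(1))
    names(seqs) <- gtab$gene_id

    if (config$hexamer_plant_rate > 0 && !is.null(introns) &&
        nrow(introns) > 0L) {
      for (ii in seq_len(nrow(introns))) {
        gid <- introns$gene_id[ii]
        gi <- match(gid, gtab$gene_id)
        loc_start <- introns$start[ii] - gtab$start[gi]
        loc_end <- introns$end[ii] - gtab$start[gi]
        ilen <- loc_end - loc_start
        n_plant <- stats::rpois(1L, config$hexamer_plant_rate * ilen / 1000)
        if (n_plant > 0L && ilen >= 6L) {
          s <- seqs[[gid]]
          at <- sample.int(ilen - 5L, min(n_plant, ilen - 5L)) + loc_start
          for (a in at) {
            hx <- sample(config$hexamer_set, 1L)
            substr(s, a + 1L, a + 6L) <- hx
          }
          seqs[[gid]] <- s
        }
      }
    }
    sequences <- Biostrings::DNAStringSet(seqs)

    ## --- elements --------------------------------------------------------
    elements <- scan_elements(sequences, config$hexamer_set,
                              offsets = stats::setNames(gtab$start,
                                                        gtab$gene_id),
                              chrom = gtab$chrom[1])

    ## --- background variants --------------------------------------------
    flank <- 10000L
    n_bg <- config$n_variants - config$n_sqtls
    w <- span + 2L * flank
    gi_bg <- sample.int(nrow(gtab), n_bg, replace = TRUE, prob = w)
    pos_bg <- gtab$start[gi_bg] - flank +
      floor(stats::runif(n_bg) * w[gi_bg])

    ## --- sQTLs -----------------------------------------------------------
    n_sq <- config$n_sqtls
    cov <- element_coverage(elements, gtab)
    # odds multiplier applied to the probability of landing in an element
    p_in <- function(p0, mult) {
      odds <- mult * p0 / (1 - p0)
      odds / (1 + odds)
    }

    donor_biased <- stats::runif(n_sq) < config$sqtl_positional_bias
    pos_sq <- integer(n_sq)
    gi_sq <- integer(n_sq)

    # non-donor placement: same gene +/- 10 kb law as the background, with
    # the element-membership odds tilted by the enrichment multiplier
    n_body <- sum(!donor_biased)
    if (n_body > 0L) {
      gsel <- sample.int(nrow(gtab), n_body, replace = TRUE, prob = w)
      f0_window <- sum(vapply(cov$by_gene,
                              function(cv) sum(cv$end - cv$start),
                              numeric(1))) / sum(w)
      inside <- stats::runif(n_body) <
        p_in(max(f0_window, 1e-6), config$sqtl_element_enrichment)
      pos <- integer(n_body)
      for (v in seq_len(n_body)) {
        g <- gsel[v]
        pos[v] <- place_in_gene(gtab$start[g] - flank, gtab$end[g] + flank,
                                cov$by_gene[[gtab$gene_id[g]]], inside[v])
      }
      pos_sq[!donor_biased] <- pos
      gi_sq[!donor_biased] <- gsel
    }

    # donor-proximal placement: window immediately upstream (exonic side)
    # of a random splice donor, element-odds applied within the window
    n_don <- sum(donor_biased)
    if (n_don > 0L) {
      if (is.null(introns) || nrow(introns) == 0L)
        stop_input("donor-biased sQTLs requested but gene models have no introns")
      isel <- sample.int(nrow(introns), n_don, replace = TRUE)
      pos <- integer(n_don)
      for (v in seq_len(n_don)) {
        ir <- introns[isel[v], ]
        win <- if (ir$strand == "+") {
          c(ir$donor - config$donor_window, ir$donor)
        } else {
          c(ir$donor, ir$donor + config$donor_window)
        }
        g <- match(ir$gene_id, gtab$gene_id)
        win[1] <- max(win[1], gtab$start[g])
        cov_g <- cov$by_gene[[ir$gene_id]]
        cov_win <- cov_g[cov_g$end > win[1] & cov_g$start < win[2], ,
                         drop = FALSE]
        cov_win$start <- pmax(cov_win$start, win[1])
        cov_win$end <- pmin(cov_win$end, win[2])
        frac_win <- if (nrow(cov_win)) {
          sum(cov_win$end - cov_win$start) / (win[2] - win[1])
        } else 0
        inside <- stats::runif(1) <
          p_in(max(min(frac_win, 0.999), 1e-6),
               config$sqtl_element_enrichment)
        pos[v] <- place_in_gene(win[1], win[2], cov_win, inside)
      }
      pos_sq[donor_biased] <- pos
      gi_sq[donor_biased] <- match(introns$gene_id[isel], gtab$gene_id)
    }

    variants <- data.frame(
      chrom = gtab$chrom[1],
      pos = c(pos_bg, pos_sq),
      af = config$af_spectrum(config$n_variants),
      is_sqtl = rep(c(FALSE, TRUE), c(n_bg, n_sq)),
      gene_id = gtab$gene_id[c(gi_bg, gi_sq)],
      planted_donor = c(rep(FALSE, n_bg), donor_biased),
      stringsAsFactors = FALSE
    )
    if (any(variants$af <= 0 | variants$af > 0.5))
      stop_input("af_spectrum produced frequencies outside (0, 0.5]")
    variants$distance <- pmax(0L,
                              pmax(gtab$start[match(variants$gene_id,
                                                    gtab$gene_id)] -
                                     variants$pos,
                                   variants$pos -
                                     gtab$end[match(variants$gene_id,
                                                    gtab$gene_id)] + 1L))
    variants$in_element <- positions_in_intervals(variants$pos, elements)

    ## --- uORFs -----------------------------------------------------------
    uorfs <- gen_uorfs(genes, config, truth)

    structure(list(variants = variants, sequences = sequences,
                   elements = elements, uorfs = uorfs,
                   truth = truth$truth),
              class = "variant_sim")
  })
}

# Scan a hexamer catalogue against per-gene sequences; returns genomic
# 0-based half-open intervals (merged per gene is NOT applied -- overlaps
# are kept, matching the scan contract).
scan_elements <- function(sequences, hexamers, offsets, chrom) {
  if (length(hexamers) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  pd <- Biostrings::PDict(unique(hexamers))
  out <- vector("list", length(sequences))
  nms <- names(sequences)
  for (i in seq_along(sequences)) {
    m <- Biostrings::matchPDict(pd, sequences[[i]])
    ir <- unlist(m)
    if (length(ir)) {
      out[[i]] <- data.frame(
        chrom = chrom,
        start = offsets[[nms[i]]] + BiocGenerics::start(ir) - 1L,
        end = offsets[[nms[i]]] + BiocGenerics::end(ir),
        gene_id = nms[i], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), gene_id = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Reduced (merged) element coverage per gene plus the pooled covered
# fraction of gene bodies.
element_coverage <- function(elements, gtab) {
  by_gene <- stats::setNames(vector("list", nrow(gtab)), gtab$gene_id)
  total_cov <- 0
  for (gi in seq_len(nrow(gtab))) {
    gid <- gtab$gene_id[gi]
    el <- elements[elements$gene_id == gid, , drop = FALSE]
    if (nrow(el) == 0L) {
      by_gene[[gid]] <- data.frame(start = integer(), end = integer())
      next
    }
    ir <- IRanges::reduce(IRanges::IRanges(el$start + 1L, el$end))
    cov <- data.frame(start = BiocGenerics::start(ir) - 1L,
                      end = BiocGenerics::end(ir))
    by_gene[[gid]] <- cov
    total_cov <- total_cov + sum(cov$end - cov$start)
  }
  list(by_gene = by_gene,
       fraction = total_cov / sum(gtab$end - gtab$start))
}

# Sample one position uniformly from the covered (inside = TRUE) or
# uncovered part of [start, end); falls back to the full interval if the
# requested stratum is empty.
place_in_gene <- function(start, end, cov, inside) {
  if (nrow(cov) == 0L || sum(cov$end - cov$start) == 0L) {
    if (inside) return(start + floor(stats::runif(1) * (end - start)))
    return(start + floor(stats::runif(1) * (end - start)))
  }
  if (inside) {
    w <- cov$end - cov$start
    seg <- sample.int(nrow(cov), 1L, prob = w)
    return(cov$start[seg] + floor(stats::runif(1) * w[seg]))
  }
  # complement of cov within [start, end)
  gaps_start <- c(start, cov$end)
  gaps_end <- c(cov$start, end)
  keep <- gaps_end > gaps_start
  gaps_start <- gaps_start[keep]; gaps_end <- gaps_end[keep]
  if (!length(gaps_start))
    return(start + floor(stats::runif(1) * (end - start)))
  w <- gaps_end - gaps_start
  seg <- sample.int(length(w), 1L, prob = w)
  gaps_start[seg] + floor(stats::runif(1) * w[seg])
}

# Exonic segments of every gene: the complement of its introns within the
# gene span (0-based half-open).
exon_segments <- function(genes) {
  gtab <- genes$genes
  introns <- genes$introns
  out <- vector("list", nrow(gtab))
  for (gi in seq_len(nrow(gtab))) {
    gid <- gtab$gene_id[gi]
    itr <- introns[introns$gene_id == gid, , drop = FALSE]
    if (nrow(itr) == 0L) {
      out[[gi]] <- data.frame(chrom = gtab$chrom[gi],
                              start = gtab$start[gi], end = gtab$end[gi],
                              stringsAsFactors = FALSE)
      next
    }
    itr <- itr[order(itr$start), , drop = FALSE]
    starts <- c(gtab$start[gi], itr$end)
    ends <- c(itr$start, gtab$end[gi])
    keep <- ends > starts
    out[[gi]] <- data.frame(chrom = gtab$chrom[gi],
                            start = starts[keep], end = ends[keep],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# TRUE for each position falling inside any 0-based half-open interval.
positions_in_intervals <- function(pos, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  q <- IRanges::IRanges(pos + 1L, pos + 1L)
  s <- IRanges::reduce(IRanges::IRanges(intervals$start + 1L,
                                        intervals$end))
  IRanges::overlapsAny(q, s)
}

# uORF intervals. uorf_enrichment is defined as the multiplier on the odds
# that an intron OVERLAPS at least one uORF, so the generator realizes that
# definition exactly: the overlap indicator is drawn per intron (p1 for
# introns with planted increased retention, p0 otherwise) and the planted
# uORF is placed fully inside its intron; background uORFs are confined to
# exons so they cannot contaminate intron overlap rates. Background lengths
# extend past the 200 bp filter limit so the length filter has work to do.
gen_uorfs <- function(genes, config, truth) {
  introns <- genes$introns
  gtab <- genes$genes
  p0 <- config$uorf_base_rate
  odds <- p0 / (1 - p0)
  p1 <- config$uorf_enrichment * odds / (1 + config$uorf_enrichment * odds)

  planted_up <- truth$truth$event_id[truth$truth$planted &
                                       truth$truth$direction == 1L]
  up_introns <- truth$events$intron_id[match(planted_up,
                                             truth$events$event_id)]

  rows <- list()
  for (ii in seq_len(nrow(introns))) {
    p <- if (introns$intron_id[ii] %in% up_introns) p1 else p0
    if (stats::runif(1) < p) {
      # planted uORFs stay inside the intron and under the 201 bp filter so
      # the planted odds survive both the overlap and the length rule
      ilen <- introns$end[ii] - introns$start[ii]
      len <- sample_safe(20:min(200L, max(20L, ilen - 2L)), 1L)
      at <- introns$start[ii] + 1L +
        floor(stats::runif(1) * max(1L, ilen - len - 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = introns$chrom[ii], start = at, end = at + len,
        stringsAsFactors = FALSE)
    }
  }
  # background uORFs fully inside exons (never overlapping an intron)
  exons <- exon_segments(genes)
  n_bg <- stats::rpois(1L, nrow(gtab))
  if (n_bg > 0L && nrow(exons) > 0L) {
    w <- exons$end - exons$start
    ei <- sample.int(nrow(exons), n_bg, replace = TRUE, prob = w)
    len <- pmin(sample(20:260, n_bg, replace = TRUE), w[ei])
    at <- exons$start[ei] +
      floor(stats::runif(n_bg) * pmax(1L, w[ei] - len))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = exons$chrom[ei], start = at, end = at + len,
      stringsAsFactors = FALSE)
  }
  u <- do.call(rbind, rows)
  if (is.null(u))
    u <- data.frame(chrom = character(), start = integer(),
                    end = integer(), stringsAsFactors = FALSE)
  u$length <- u$end - u$start
  u <- u[order(u$start), , drop = FALSE]
  rownames(u) <- NULL
  u
}
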