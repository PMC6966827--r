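#' Gene- and intron-relative variant positions
#'
#' Assigns each variant to its nearest gene (variants farther than `flank`
#' bp from every gene are dropped, with the count recorded) and reports
#' strand-aware relative coordinates:
#' \itemize{
#'   \item `gene_metacoord`: position on a composite axis where `[-1, 0)` is
#'     the upstream flank (bp / `flank`, 0 at the TSS), `[0, 1]` the
#'     length-normalized gene body (0 = TSS, 1 = 3' end), and `(1, 2]` the
#'     downstream flank;
#'   \item `intron_metacoord`: the same construction around the nearest
#'     intron (0 = donor / 5' end, 1 = acceptor), with exonic flanks of
#'     `intron_flank` bp, `NA` when no intron lies within that window.
#' }
#' Minus-strand genes are flipped so 0 is always the transcription start.
#'
#' @param variants data.frame with columns chrom, pos (0-based).
#' @param genes Either a `gene_models` object or a data.frame with gene_id,
#'   chrom, start, end, strand (and optionally an `introns` attribute-style
#'   list component).
#' @param flank Gene flank in bp (default 10000, the "local" window).
#' @param intron_flank Exonic flank around introns in bp (default 300).
#' @return data.frame of retained variants with gene_id, distance,
#'   gene_metacoord, intron_metacoord; attribute `n_excluded` counts
#'   variants beyond `flank` of every gene.
#' @export
relative_positions <- function(variants, genes, flank = 10000L,
                               intron_flank = 300L) {
  if (inherits(genes, "gene_models")) {
    gtab <- genes$genes
    introns <- genes$introns
  } else {
    gtab <- genes
    introns <- attr(genes, "introns")
  }
  out_list <- vector("list", 0L)
  n_excluded <- 0L
  for (ch in unique(variants$chrom)) {
    v <- variants[variants$chrom == ch, , drop = FALSE]
    g <- gtab[gtab$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) { n_excluded <- n_excluded + nrow(v); next }
    gr <- IRanges::IRanges(g$start + 1L, g$end)
    q <- IRanges::IRanges(v$pos + 1L, v$pos + 1L)
    nr <- IRanges::nearest(q, gr)
    dist <- pmax(g$start[nr] - v$pos, v$pos - (g$end[nr] - 1L), 0L)
    keep <- !is.na(nr) & dist <= flank
    n_excluded <- n_excluded + sum(!keep)
    v <- v[keep, , drop = FALSE]
    nr <- nr[keep]; dist <- dist[keep]
    if (!nrow(v)) next

    gs <- g$start[nr]; ge <- g$end[nr]; minus <- g$strand[nr] == "-"
    inside <- v$pos >= gs & v$pos < ge
    rel <- (v$pos - gs) / (ge - gs)
    rel[minus] <- 1 - rel[minus]
    upstream_bp <- ifelse(minus, v$pos - (ge - 1L), gs - v$pos)
    meta <- ifelse(inside, rel,
                   ifelse(upstream_bp > 0, -upstream_bp / flank,
                          1 + dist / flank))

    v$gene_id <- g$gene_id[nr]
    v$distance <- dist
    v$gene_metacoord <- meta

    v$intron_metacoord <- NA_real_
    if (!is.null(introns) && nrow(introns) > 0L) {
      itr <- introns[introns$chrom == ch, , drop = FALSE]
      if (nrow(itr)) {
        ir <- IRanges::IRanges(itr$start + 1L, itr$end)
        qi <- IRanges::IRanges(v$pos + 1L, v$pos + 1L)
        ni <- IRanges::nearest(qi, ir)
        di <- pmax(itr$start[ni] - v$pos, v$pos - (itr$end[ni] - 1L), 0L)
        ok <- !is.na(ni) & di <= intron_flank
        is_s <- itr$start[ni]; is_e <- itr$end[ni]
        im <- itr$strand[ni] == "-"
        ins <- v$pos >= is_s & v$pos < is_e
        reli <- (v$pos - is_s) / (is_e - is_s)
        reli[im] <- 1 - reli[im]
        up_bp <- ifelse(im, v$pos - (is_e - 1L), is_s - v$pos)
        metai <- ifelse(ins, reli,
                        ifelse(up_bp > 0, -up_bp / intron_flank,
                               1 + di / intron_flank))
        v$intron_metacoord[ok] <- metai[ok]
      }
    }
    out_list[[length(out_list) + 1L]] <- v
  }
  out <- do.call(rbind, out_list)
  if (is.null(out)) out <- variants[0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_excluded = n_excluded)
}

#' Binned density over a composite metagene coordinate
#'
#' Bins positions on the `[-1, 2]` composite axis produced by
#' [relative_positions()] (flank / body / flank, each rescaled to unit
#' length) and normalizes so the density integrates to 1 over the whole
#' domain.
#'
#' @param metacoord Numeric positions in `[-1, 2]`; NAs dropped.
#' @param n_body_bins,n_flank_bins Bins per segment (100 each by default;
#'   with a 10 kb flank this gives 100 bp flank bins).
#' @return data.frame mid, lo, hi, count, density.
#' @export
metagene_density <- function(metacoord, n_body_bins = 100L,
                             n_flank_bins = 100L) {
  x <- metacoord[!is.na(metacoord)]
  breaks <- c(seq(-1, 0, length.out = n_flank_bins + 1L)[-(n_flank_bins + 1L)],
              seq(0, 1, length.out = n_body_bins + 1L)[-(n_body_bins + 1L)],
              seq(1, 2, length.out = n_flank_bins + 1L))
  cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  w <- diff(breaks)
  dens <- if (length(x)) cnt / sum(cnt) / w else rep(0, length(w))
  data.frame(lo = breaks[-length(breaks)], hi = breaks[-1L],
             mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
             count = cnt, density = dens)
}

#' Observed vs null metagene densities for an sQTL set
#'
#' Computes the positional density of the sQTL-flagged variants and of each
#' allele-frequency-matched null set on the gene-relative or intron-relative
#' composite axis, returning the per-bin null mean and standard deviation.
#'
#' @param variants data.frame as returned by [relative_positions()]
#'   including an `is_sqtl` column.
#' @param null_sets List of variant data.frames (same columns), e.g., from
#'   [af_matched_sample()] joined back to positions.
#' @param axis Either "gene" or "intron".
#' @param ... Passed to [metagene_density()].
#' @return List with `observed` (density data.frame), `null_mean`,
#'   `null_sd` (per-bin vectors), and `bins`.
#' @export
sqtl_metagene <- function(variants, null_sets, axis = c("gene", "intron"),
                          ...) {
  axis <- match.arg(axis)
  col <- if (axis == "gene") "gene_metacoord" else "intron_metacoord"
  obs <- metagene_density(variants[[col]][variants$is_sqtl], ...)
  nulls <- vapply(null_sets, function(ns) {
    metagene_density(ns[[col]], ...)$density
  }, numeric(nrow(obs)))
  list(observed = obs,
       null_mean = rowMeans(nulls),
       null_sd = apply(nulls, 1L, stats::sd),
       bins = obs[, c("lo", "hi", "mid")])
}

#' Allele-frequency-matched null variant sets
#'
#' Draws `n_sets` random variant sets that reproduce the sQTL set's allele
#' frequency histogram exactly at the chosen bin width: each null set has
#' the target's size and per-bin counts, is sampled without replacement
#' within a set from the non-target variants, and never contains a target
#' variant.
#'
#' @param variants data.frame with columns af and is_sqtl (targets).
#' @param n_sets Number of null sets (default 100).
#' @param af_bin_width Width of the minor-allele-frequency bins
#'   (default 0.02).
#' @param seed Optional RNG seed.
#' @return List of integer row-index vectors into `variants`, one per set.
#' @export
af_matched_sample <- function(variants, n_sets = 100L, af_bin_width = 0.02,
                              seed = NULL) {
  target <- which(variants$is_sqtl)
  if (!length(target)) stop_input("input error: no sQTL-flagged variants")
  cand <- which(!variants$is_sqtl)
  breaks <- seq(0, 0.5 + af_bin_width, by = af_bin_width)
  tb <- findInterval(variants$af[target], breaks, rightmost.closed = TRUE)
  cb <- findInterval(variants$af[cand], breaks, rightmost.closed = TRUE)
  need <- table(tb)
  have <- table(factor(cb, levels = names(need)))
  short <- names(need)[as.integer(have) < as.integer(need)]
  if (length(short)) {
    b <- as.integer(short[1])
    stop_input(sprintf(
      "AF bin [%.2f, %.2f) has %d candidates for %d targets",
      breaks[b], breaks[b + 1L],
      as.integer(have[short[1]]), as.integer(need[short[1]])))
  }
  cand_by_bin <- split(cand, cb)
  with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      unlist(lapply(names(need), function(b) {
        sample_safe(cand_by_bin[[b]], as.integer(need[[b]]))
      }), use.names = FALSE)
    })
  })
}

#' Exact hexamer matches in a nucleotide sequence
#'
#' Finds every exact, possibly overlapping occurrence of each motif on the
#' given strand; `N` never matches. Intervals are 0-based, half-open.
#'
#' @param sequence A character string or `Biostrings::DNAString` over ACGTN.
#' @param motifs Character vector of 6-mers (an ESE/ISE catalogue).
#' @return data.frame start, end, motif (0-based half-open), ordered by
#'   start.
#' @export
#' @examples
#' hexamer_scan("GATTACA", "ATTACA") # one match at [1, 7)
hexamer_scan <- function(sequence, motifs) {
  if (length(motifs) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), stringsAsFactors = FALSE))
  if (any(nchar(motifs) != 6L | grepl("[^ACGT]", motifs)))
    stop_input("input error: motifs must be 6-mers over ACGT")
  subject <- if (inherits(sequence, "DNAString")) sequence
             else Biostrings::DNAString(as.character(sequence))
  um <- unique(motifs)
  res <- lapply(um, function(m) {
    hits <- Biostrings::matchPattern(m, subject)
    if (!length(hits)) return(NULL)
    data.frame(start = BiocGenerics::start(hits) - 1L,
               end = BiocGenerics::end(hits), motif = m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      motif = character(), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Element-overlap enrichment of an sQTL set against AF-matched nulls
#'
#' Computes the percentage of sQTLs falling inside any predicted element
#' interval (a variant is counted once even if covered by several
#' elements), the same percentage for each null set, and summarizes the
#' enrichment as `z = (obs - mean_null) / sd_null` plus the empirical
#' tail probability `(1 + #null >= obs) / (1 + n_sets)`.
#'
#' @param sqtl_pos Integer vector of sQTL positions (0-based).
#' @param elements data.frame with start, end (0-based half-open) element
#'   intervals, e.g., genomic hexamer matches.
#' @param null_pos_sets List of integer position vectors, one per null set
#'   (at least 20).
#' @return List observed_pct, null_mean, null_sd, z, p_empirical, n_sets.
#' @export
overlap_enrichment <- function(sqtl_pos, elements, null_pos_sets) {
  if (length(null_pos_sets) < 20L)
    stop_input("input error: at least 20 null sets required")
  pct <- function(pos) {
    100 * mean(positions_in_intervals(pos, elements))
  }
  obs <- pct(sqtl_pos)
  nulls <- vapply(null_pos_sets, pct, numeric(1))
  sdn <- stats::sd(nulls)
  z <- if (isTRUE(sdn > 0)) (obs - mean(nulls)) / sdn else NA_real_
  list(observed_pct = obs, null_mean = mean(nulls), null_sd = sdn,
       z = z,
       p_empirical = (1 + sum(nulls >= obs)) / (1 + length(nulls)),
       n_sets = length(null_pos_sets))
}
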