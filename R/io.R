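#' Run every synthetic generator on one configuration
#'
#' Convenience wrapper producing the full synthetic dataset (gene models,
#' ratio tensor, retention counts, variants/sequences/elements/uORFs) from a
#' single config. With identical seeds the result is bit-identical.
#'
#' @param config A [sim_config()].
#' @return List of class `splice_sim`: genes, ratios, retention, variants.
#' @export
simulate_dataset <- function(config) {
  genes <- gen_gene_models(config)
  list2 <- list(
    genes = genes,
    ratios = gen_ratio_samples(genes, config),
    retention = gen_retention_counts(genes, config),
    variants = gen_variants_and_elements(genes, config)
  )
  structure(list2, class = "splice_sim")
}

tsv_write <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic dataset to standard plain-text formats
#'
#' Emits a GTF-like annotation (attributes `gene_id`, `transcript_id`),
#' BED6 files for introns and uORFs, FASTA gene sequences, TSVs for ratios,
#' retention counts, and variants, truth tables for every planted effect,
#' and a `schema.tsv` documenting the columns. Output is deterministic
#' given the simulation seed.
#'
#' @param sim A `splice_sim` from [simulate_dataset()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_sim_outputs <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- sim$genes
  written <- character()

  # GTF: gene and transcript rows, 1-based closed coordinates
  gt <- g$genes
  iso <- g$isoforms
  gi <- match(iso$gene_id, gt$gene_id)
  gtf <- c(
    sprintf("%s\tsplicestress\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            gt$chrom, gt$start + 1L, gt$end, gt$strand, gt$gene_id),
    sprintf(paste0("%s\tsplicestress\ttranscript\t%d\t%d\t.\t%s\t.\t",
                   "gene_id \"%s\"; transcript_id \"%s\";"),
            gt$chrom[gi], gt$start[gi] + 1L, gt$end[gi], gt$strand[gi],
            iso$gene_id, iso$isoform_id)
  )
  f <- file.path(outdir, "annotation.gtf")
  writeLines(gtf, f); written <- c(written, f)

  bed6 <- function(d, names, path) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                       d$chrom, d$start, d$end, names,
                       if ("strand" %in% colnames(d)) d$strand else "."),
               path)
  }
  f <- file.path(outdir, "introns.bed")
  bed6(g$introns, g$introns$intron_id, f); written <- c(written, f)
  uorfs <- sim$variants$uorfs
  f <- file.path(outdir, "uorfs.bed")
  bed6(cbind(uorfs, strand = "."),
       sprintf("uORF%05d", seq_len(nrow(uorfs))), f)
  written <- c(written, f)

  f <- file.path(outdir, "sequences.fa")
  Biostrings::writeXStringSet(sim$variants$sequences, f)
  written <- c(written, f)

  tables <- list(
    "ratios.tsv" = as.data.frame(sim$ratios),
    "retention_counts.tsv" = as.data.frame(sim$retention),
    "variants.tsv" = sim$variants$variants,
    "elements.tsv" = sim$variants$elements,
    "feature_lengths.tsv" = lengths_from_genes(g),
    "truth_responders.tsv" = attr(sim$ratios, "truth"),
    "truth_retention.tsv" = attr(sim$retention, "truth"),
    "truth_utr3_class.tsv" = gt[, c("gene_id", "utr3_class")]
  )
  for (nm in names(tables)) {
    f <- file.path(outdir, nm)
    tsv_write(tables[[nm]], f)
    written <- c(written, f)
  }

  schema <- data.frame(
    file = c("ratios.tsv", "retention_counts.tsv", "variants.tsv"),
    columns = c("line condition gene_id isoform_id ratio count",
                "event_id line condition n k_r k_s uncovered",
                "chrom pos af is_sqtl gene_id planted_donor distance in_element"),
    stringsAsFactors = FALSE)
  f <- file.path(outdir, "schema.tsv")
  tsv_write(schema, f); written <- c(written, f)
  invisible(written)
}

#' Read a ratio tensor from TSV
#'
#' @param path TSV with columns line, condition, gene_id, isoform_id, ratio
#'   and optionally count.
#' @return A `ratio_tensor`.
#' @export
read_ratio_tensor <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("line", "condition", "gene_id", "isoform_id", "ratio")
  if (!all(need %in% names(d)))
    stop_input("input error: ratio TSV needs columns ",
               paste(need, collapse = ", "))
  structure(d, class = c("ratio_tensor", "data.frame"))
}

#' Read retention counts from TSV
#'
#' @param path TSV with columns event_id, line, condition, k_r, k_s.
#' @return data.frame.
#' @export
read_retention_counts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("event_id", "line", "condition", "k_r", "k_s")
  if (!all(need %in% names(d)))
    stop_input("input error: counts TSV needs columns ",
               paste(need, collapse = ", "))
  d
}

#' Read gene spans from a GTF-like annotation
#'
#' Extracts `gene` feature rows; coordinates are converted to 0-based
#' half-open.
#'
#' @param path GTF file with `gene_id` attributes.
#' @return data.frame gene_id, chrom, start, end, strand.
#' @export
read_gtf_genes <- function(path) {
  d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 9L) stop_input("input error: not a 9-column GTF")
  d <- d[d$V3 == "gene", , drop = FALSE]
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", d$V9)
  data.frame(gene_id = gid, chrom = d$V1, start = d$V4 - 1L, end = d$V5,
             strand = d$V7, stringsAsFactors = FALSE)
}

#' Read a BED file (first six columns)
#'
#' @param path BED file (0-based half-open, as BED defines).
#' @return data.frame chrom, start, end and, when present, name, score,
#'   strand.
#' @export
read_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[seq_len(min(6L, ncol(d)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6L, ncol(d)))]
  d
}

#' Command-line interface
#'
#' Dispatches the subcommands `simulate`, `diversity`, and `retention`, the
#' three file-level pipelines. Example:
#' `Rscript -e 'splicestress::splicestress_cli()' simulate --outdir D --seed 7`.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Invisibly, 0 on success.
#' @export
splicestress_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: splicestress <command> [options]",
    "  simulate     --outdir D [--seed N] [--n-genes N] [--n-lines N]",
    "  diversity    --ratios R.tsv --out OUT.tsv [--n-perm N]",
    "               [--effect-threshold X] [--seed N]",
    "  efflen       --ratios R.tsv --lengths L.tsv --out OUT.tsv",
    "               [--n-perm N] [--seed N]",
    "  sqtl-pos     --variants V.tsv --genes G.gtf --out OUT.tsv",
    "               [--introns I.bed] [--n-null N] [--seed N]",
    "  retention    --counts C.tsv --out OUT.tsv [--bf-threshold X]",
    "               [--dpsi-threshold X] [--seed N]",
    "  characterize --events E.tsv --uorfs U.bed --out OUT.tsv",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  getopt <- function(name, default = NULL) {
    if (name %in% names(opts)) opts[[name]] else default
  }
  seed <- as.integer(getopt("seed", 1L))

  if (cmd == "simulate") {
    outdir <- getopt("outdir")
    if (is.null(outdir)) stop_input("simulate: --outdir is required")
    n_genes <- as.integer(getopt("n-genes", 200L))
    cfg <- sim_config(
      n_genes = n_genes,
      n_lines = as.integer(getopt("n-lines", 38L)),
      n_events = as.integer(getopt("n-events", n_genes)),
      n_variants = as.integer(getopt("n-variants", 200L * n_genes)),
      n_sqtls = as.integer(getopt("n-sqtls", 20L * n_genes)),
      seed = seed)
    write_sim_outputs(simulate_dataset(cfg), outdir)
    message("wrote synthetic dataset to ", outdir)
  } else if (cmd == "diversity") {
    tensor <- read_ratio_tensor(getopt("ratios"))
    if ("count" %in% names(tensor)) tensor <- filter_isoforms(tensor)
    res <- splicing_test_all(
      tensor,
      n_perm = as.integer(getopt("n-perm", 10000L)),
      effect_threshold = as.numeric(getopt("effect-threshold", 0.1)),
      seed = seed)
    tsv_write(res, getopt("out", "diversity_results.tsv"))
  } else if (cmd == "efflen") {
    tensor <- read_ratio_tensor(getopt("ratios"))
    lengths <- utils::read.delim(getopt("lengths"), stringsAsFactors = FALSE)
    et <- effective_length_table(tensor, lengths)
    res <- permutation_g_test(et, n_perm = as.integer(getopt("n-perm", 100L)),
                              seed = seed)
    tsv_write(res$tests, getopt("out", "efflen_results.tsv"))
    message(sprintf("Bonferroni threshold across %d tests: %.3g",
                    nrow(res$tests), res$bonferroni))
  } else if (cmd == "sqtl-pos") {
    variants <- utils::read.delim(getopt("variants"),
                                  stringsAsFactors = FALSE)
    genes <- read_gtf_genes(getopt("genes"))
    if (!is.null(getopt("introns"))) {
      itr <- read_bed(getopt("introns"))
      attr(genes, "introns") <- itr
    }
    rel <- relative_positions(variants, genes)
    null_idx <- af_matched_sample(rel,
                                  n_sets = as.integer(getopt("n-null", 100L)),
                                  seed = seed)
    nulls <- lapply(null_idx, function(i) rel[i, , drop = FALSE])
    mg <- sqtl_metagene(rel, nulls, axis = "gene")
    out <- cbind(mg$observed, null_mean = mg$null_mean,
                 null_sd = mg$null_sd)
    tsv_write(out, getopt("out", "sqtl_metagene.tsv"))
  } else if (cmd == "characterize") {
    events <- utils::read.delim(getopt("events"), stringsAsFactors = FALSE)
    uorfs <- read_bed(getopt("uorfs"))
    r <- uorf_overlap_test(events, uorfs)
    tsv_write(r$per_line, getopt("out", "uorf_overlap.tsv"))
    message(sprintf("paired one-tailed t: t = %.3f, df = %d, p = %.3g",
                    r$statistic, r$df, r$p_value))
  } else if (cmd == "retention") {
    counts <- read_retention_counts(getopt("counts"))
    res <- delta_psi_table(
      counts,
      bf_threshold = as.numeric(getopt("bf-threshold", 10)),
      dpsi_threshold = as.numeric(getopt("dpsi-threshold", 0.2)),
      seed = seed)
    tsv_write(res, getopt("out", "retention_results.tsv"))
  } else {
    message(usage)
    stop_input("unknown command: ", cmd)
  }
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop_input("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}
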