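# Intersection of ChIP target genes with differential-expression results,
# direct/indirect classification, the end-to-end pipeline driver, and the
# run report.

norm_ids <- function(x, what) {
  x <- toupper(as.character(x))
  if (anyDuplicated(x)) {
    warning("collapsing ", sum(duplicated(x)), " duplicate ", what,
            " gene id(s)")
    x <- unique(x)
  }
  x
}

#' Overlap of ChIP target genes with differentially expressed genes
#'
#' Gene identifiers are matched exactly after case normalization (the two
#' screens share a platform namespace; no alias resolution is attempted).
#' Duplicated ids are collapsed with a warning; the result is invariant to
#' input order and duplication.
#'
#' @param chip_genes character vector of ChIP target gene ids.
#' @param de_genes character vector of differentially expressed gene ids.
#' @return list with `genes` (the intersection), `n`, and `pct_of_de`
#'   (`100 * n / |DE|`, rounded to 1 decimal; 0 when the DE list is empty).
#' @export
overlap_genes <- function(chip_genes, de_genes) {
  chip <- norm_ids(chip_genes, "ChIP")
  de <- norm_ids(de_genes, "DE")
  common <- sort(intersect(chip, de))
  pct <- if (length(de) == 0) 0 else round(100 * length(common) / length(de), 1)
  list(genes = common, n = length(common), pct_of_de = pct)
}

#' Classify genes as direct-regulated, direct-bound-only or indirect
#'
#' Every gene appearing in either screen is assigned exactly one class:
#' *direct-regulated* (promoter bound and expression changed),
#' *direct-bound-only* (bound, no expression change detected) or
#' *indirect* (expression changed downstream without detected binding).
#'
#' @param chip_genes data frame with `gene_id` and `tier`
#'   (`"long"`/`"strict"`), or a character vector (tier `"long"`).
#' @param de_genes data frame with `gene_id` and `direction`
#'   (`"up"`/`"down"`), or a character vector (direction unknown, coded
#'   `"up"`... supply the frame to keep directions). Either input may be
#'   empty.
#' @return data frame: gene_id, chip_tier (`none`/`long`/`strict`),
#'   de_status (`none`/`up`/`down`), class. Attribute `"counts"` holds the
#'   per-class tally.
#' @export
classify_targets <- function(chip_genes, de_genes) {
  if (is.character(chip_genes))
    chip_genes <- data.frame(gene_id = chip_genes,
                             tier = rep("long", length(chip_genes)),
                             stringsAsFactors = FALSE)
  if (is.character(de_genes))
    de_genes <- data.frame(gene_id = de_genes,
                           direction = rep("up", length(de_genes)),
                           stringsAsFactors = FALSE)
  chip_genes$gene_id <- toupper(chip_genes$gene_id)
  de_genes$gene_id <- toupper(de_genes$gene_id)
  # keep the strongest tier per gene
  tier_rank <- c(long = 1, strict = 2)
  chip_genes <- chip_genes[order(-tier_rank[chip_genes$tier]), ]
  chip_genes <- chip_genes[!duplicated(chip_genes$gene_id), ]
  de_genes <- de_genes[!duplicated(de_genes$gene_id), ]

  all_ids <- sort(union(chip_genes$gene_id, de_genes$gene_id))
  chip_tier <- chip_genes$tier[match(all_ids, chip_genes$gene_id)]
  chip_tier[is.na(chip_tier)] <- "none"
  de_status <- de_genes$direction[match(all_ids, de_genes$gene_id)]
  de_status[is.na(de_status)] <- "none"
  class <- ifelse(chip_tier != "none" & de_status != "none",
                  "direct-regulated",
                  ifelse(chip_tier != "none", "direct-bound-only",
                         "indirect"))
  out <- data.frame(gene_id = all_ids, chip_tier = chip_tier,
                    de_status = de_status, class = class,
                    stringsAsFactors = FALSE)
  structure(out, counts = table(factor(class,
    levels = c("direct-regulated", "direct-bound-only", "indirect"))))
}

#' Run the full synthetic-study analysis pipeline
#'
#' Drives simulate -> normalize -> probe scores -> window scores ->
#' empirical null threshold -> two-tier target calling -> gene mapping and
#' null cross-filtering -> motif over-representation -> expression
#' preprocessing and litter-aware DE -> ChIP/expression integration, on
#' data generated under `cfg`. True DE genes are planted among the
#' ChIP-bound genes so the direct-regulated class is exercised end to end.
#'
#' @param cfg a [sim_config()].
#' @param strict_threshold window-score cutoff of the strict tier
#'   (default 1.5).
#' @param percentile null-exclusion fraction for the long tier
#'   (default 0.99).
#' @param de_alpha per-gene DE significance level (default 0.01).
#' @param permute run the litter-constrained permutation test.
#' @param motifs run the motif over-representation scan on the strict-tier
#'   promoters versus a size-matched background.
#' @return a `nullchip_run`: a list with every intermediate artifact
#'   (design, arrays, scores, threshold, calls, curated gene tables,
#'   motif table, DE table, permutation report, integration table) plus a
#'   `counts` summary. Ready for [write_report()].
#' @export
run_pipeline <- function(cfg, strict_threshold = 1.5, percentile = 0.99,
                         de_alpha = 0.01, permute = FALSE, motifs = TRUE) {
  design <- gen_design(cfg)
  arrays <- gen_chip_arrays(design, cfg)
  ps_wt <- compute_probe_scores(quantile_normalize(arrays$wt))
  ps_null <- compute_probe_scores(quantile_normalize(arrays$null))
  ws_wt <- window_scores(ps_wt, design)
  ws_null <- window_scores(ps_null, design)
  threshold <- derive_null_threshold(ws_null, percentile)

  long_calls <- call_enriched_promoters(ws_wt, design, threshold, "long")
  strict_calls <- call_enriched_promoters(ws_wt, design, strict_threshold,
                                          "strict")
  long_genes <- map_regions_to_genes(long_calls, design)
  strict_genes <- map_regions_to_genes(strict_calls, design)
  long_cur <- filter_against_null(long_genes, ws_null, design, threshold)
  strict_cur <- filter_against_null(strict_genes, ws_null, design, threshold)

  motif_table <- NULL
  seqs <- NULL
  if (motifs) {
    target_ids <- unique(strict_calls$promoter_id)
    pool <- setdiff(design$promoters$promoter_id,
                    unique(long_calls$promoter_id))
    n_bg <- max(10L, length(target_ids))
    if (length(target_ids) >= 2 && length(pool) >= n_bg) {
      bg_ids <- with_seed(cfg$seed + 4L, sort(sample(pool, n_bg)))
      # plant the configured motif in the promoters truly bound in the
      # simulation, so the scan is tested against ground truth
      seqs <- gen_promoter_sequences(cfg, target_ids, bg_ids)
      motif_table <- enumerate_and_test(seqs$targets, seqs$background)
    }
  }

  expr_sim <- gen_expression(cfg, gene_ids = design$genes$gene_id,
                             de_pool = unique(long_cur$kept$gene_id))
  corrected <- background_correct(expr_sim$raw, expr_sim$control_means)
  transformed <- vst_glog(corrected)
  qc <- qc_outliers(transformed)
  keep <- !qc$flagged
  if (any(qc$flagged))
    transformed <- vst_glog(corrected[, keep, drop = FALSE])
  samples <- expr_sim$samples[keep, , drop = FALSE]
  filt <- detection_filter(transformed, expr_sim$detection[, keep,
                                                           drop = FALSE])
  de <- fit_de(filt$exprs, samples)
  de_sig <- de[de$p < de_alpha, , drop = FALSE]
  perm <- if (permute)
    litter_permutation_test(filt$exprs, samples, alpha = de_alpha)
  else NULL

  ov <- overlap_genes(unique(long_cur$kept$gene_id), de_sig$gene_id)
  chip_tbl <- rbind(
    data.frame(gene_id = unique(long_cur$kept$gene_id), tier = "long",
               stringsAsFactors = FALSE),
    data.frame(gene_id = unique(strict_cur$kept$gene_id), tier = "strict",
               stringsAsFactors = FALSE))
  integrated <- classify_targets(chip_tbl,
                                 de_sig[, c("gene_id", "direction")])

  counts <- c(
    probes = nrow(design$probes),
    window_enriched = sum(ws_wt >= threshold$value),
    regions_long = nrow(long_calls),
    genes_long = length(unique(long_genes$gene_id)),
    genes_long_curated = length(unique(long_cur$kept$gene_id)),
    regions_strict = nrow(strict_calls),
    genes_strict = length(unique(strict_genes$gene_id)),
    genes_strict_curated = length(unique(strict_cur$kept$gene_id)),
    genes_de = nrow(de_sig),
    de_down = sum(de_sig$direction == "down"),
    de_up = sum(de_sig$direction == "up"),
    overlap = ov$n)

  structure(list(cfg = cfg, design = design, arrays = arrays,
                 probe_scores = list(wt = ps_wt, null = ps_null),
                 window_scores = list(wt = ws_wt, null = ws_null),
                 threshold = threshold,
                 long_calls = long_calls, strict_calls = strict_calls,
                 long_genes = long_cur, strict_genes = strict_cur,
                 motif_table = motif_table, sequences = seqs,
                 expr_sim = expr_sim, qc = qc, de = de, de_sig = de_sig,
                 permutation = perm, overlap = ov, integrated = integrated,
                 counts = counts),
            class = "nullchip_run")
}

#' @export
print.nullchip_run <- function(x, ...) {
  cat("nullchip_run (seed", x$cfg$seed, ")\n")
  print(x$counts)
  invisible(x)
}

#' Write the structured run report and machine-readable tables
#'
#' Emits `report.txt` (thresholds, stage counts, motif table, DE summary,
#' permutation report, seed and configuration echo — no timestamps, so a
#' rerun under the same seed is byte-identical) alongside TSV/BED tables:
#' peak regions as BED, curated and excluded gene tables, the DE table and
#' the integrated classification.
#'
#' @param run a `nullchip_run` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(run, dir) {
  required <- c("design", "threshold", "long_calls", "strict_calls",
                "long_genes", "strict_genes", "de", "integrated", "counts")
  missing <- required[vapply(required, function(f) is.null(run[[f]]),
                             logical(1))]
  if (length(missing))
    stop("cannot write report; missing upstream artifact(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  bed <- function(calls, file) {
    df <- data.frame(chrom = calls$chrom,
                     start = as.integer(floor(calls$peak_start)),
                     end = as.integer(ceiling(calls$peak_end)),
                     name = calls$promoter_id,
                     score = round(calls$max_score, 4),
                     stringsAsFactors = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    file
  }
  files <- c(files,
    bed(run$long_calls, file.path(dir, "peaks_long.bed")),
    bed(run$strict_calls, file.path(dir, "peaks_strict.bed")))
  tsv <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(files,
    tsv(run$long_genes$kept, "genes_long_curated.tsv"),
    tsv(run$long_genes$excluded, "genes_long_excluded.tsv"),
    tsv(run$strict_genes$kept, "genes_strict_curated.tsv"),
    tsv(run$strict_genes$excluded, "genes_strict_excluded.tsv"),
    tsv(as.data.frame(run$de), "de_results.tsv"),
    tsv(run$integrated, "integrated_targets.tsv"))
  if (!is.null(run$motif_table))
    files <- c(files, tsv(as.data.frame(run$motif_table), "motifs.tsv"))

  rpt <- file.path(dir, "report.txt")
  con <- file(rpt, "w")
  writeLines(c(
    "nullchip run report",
    "===================",
    paste0("seed: ", run$cfg$seed),
    sprintf("null threshold: %.6g (percentile %.2f, n_null %d, %.2f%% strictly below)",
            run$threshold$value, run$threshold$percentile,
            run$threshold$n_null, 100 * run$threshold$frac_below),
    "",
    "stage counts:",
    sprintf("  %-22s %d", names(run$counts), run$counts),
    "",
    sprintf("integration: %d ChIP x DE genes in common (%.1f%% of DE genes)",
            run$overlap$n, run$overlap$pct_of_de),
    sprintf("classification: %s",
            paste(sprintf("%s=%d", names(attr(run$integrated, "counts")),
                          attr(run$integrated, "counts")), collapse = ", ")),
    if (!is.null(run$permutation)) sprintf(
      "permutation test: %d/%d permutations reach >= %d DE genes (empirical p = %.4g)",
      run$permutation$count_ge_observed, run$permutation$total,
      run$permutation$observed, run$permutation$empirical_p) else NULL,
    if (!is.null(run$motif_table) && nrow(run$motif_table) > 0) c(
      "", "top over-represented motifs:",
      utils::capture.output(print(utils::head(
        as.data.frame(run$motif_table), 8), row.names = FALSE))) else NULL,
    "",
    "config:",
    utils::capture.output(utils::str(unclass(run$cfg), give.attr = FALSE))),
    con)
  close(con)
  invisible(c(files, rpt))
}
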