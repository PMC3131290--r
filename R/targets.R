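#' Empirical null significance threshold from knockout-control arrays
#'
#' Window scores observed in arrays from genotype-null tissue (no protein
#' available for pulldown) estimate the null distribution of non-specific
#' ChIP signal. The significance threshold is the value excluding the
#' configured fraction (default 99%) of those null window scores. The
#' default rank rule returns the smallest observed score with at least
#' `ceiling(p * n)` null scores strictly below it — the order statistic at
#' rank `ceiling(p * n) + 1`, advanced past any ties so the exclusion
#' guarantee holds exactly (window scores tie frequently because adjacent
#' windows share probes); ties at the threshold are reported. When even the
#' largest score cannot exclude the requested fraction the maximum is
#' returned with a degeneracy warning. `method = "interpolate"` returns the
#' type-7 sample quantile instead (no exclusion guarantee).
#'
#' @param null_ws numeric vector of null-genotype window scores (>= 100).
#' @param percentile fraction of null scores to exclude (default 0.99).
#' @param method `"rank"` (default) or `"interpolate"`.
#' @return a `null_threshold`: list with `value`, `percentile`, `n_null`,
#'   `n_ties` (count of null scores equal to the threshold, the threshold
#'   order statistic itself included) and `frac_below` (realized fraction
#'   strictly below).
#' @export
derive_null_threshold <- function(null_ws, percentile = 0.99,
                                  method = c("rank", "interpolate")) {
  method <- match.arg(method)
  null_ws <- null_ws[!is.na(null_ws)]
  n <- length(null_ws)
  if (n < 100)
    stop("need >= 100 null window scores to calibrate a threshold",
         call. = FALSE)
  if (percentile <= 0 || percentile >= 1)
    stop("`percentile` must be in (0, 1)", call. = FALSE)
  sorted <- sort(null_ws)
  value <- if (method == "rank") {
    target <- ceiling(percentile * n)       # scores required strictly below
    cand <- unique(sorted[(target + 1L):n])
    below <- match(cand, sorted) - 1L       # count strictly below each
    ok <- cand[below >= target]
    if (length(ok) == 0) {
      warning("null window scores too tied to exclude the requested ",
              "fraction; threshold is degenerate")
      sorted[n]
    } else ok[1]
  } else {
    unname(stats::quantile(null_ws, percentile, type = 7))
  }
  n_ties <- sum(null_ws == value)
  structure(list(value = value, percentile = percentile, n_null = n,
                 n_ties = n_ties, frac_below = mean(null_ws < value)),
            class = "null_threshold")
}

#' @export
print.null_threshold <- function(x, ...) {
  cat(sprintf(
    "null_threshold: %.4g (%.0f%% of %d null window scores strictly below: %.2f%%%s)\n",
    x$value, 100 * x$percentile, x$n_null, 100 * x$frac_below,
    if (x$n_ties > 1) sprintf("; %d ties at threshold", x$n_ties) else ""))
  invisible(x)
}

#' Call enriched promoter regions from wild-type window scores
#'
#' A promoter region is called when at least one of its probes has a
#' window-adjusted score >= `threshold` (the window score itself already
#' requires three locally positive probes, supplying the multi-probe
#' evidence a real binding peak shows). The peak interval of a called
#' region is the maximal contiguous run of probes with window score >=
#' threshold containing the maximal probe, reported from the first to the
#' last probe midpoint of the run — the most likely stretch for the binding
#' site. `min_enriched_probes = 2` activates the stricter alternative
#' calling rule (>= 2 probes above threshold).
#'
#' @param ws numeric vector of wild-type window scores aligned with
#'   `design$probes`.
#' @param design a `tiling_design`.
#' @param threshold calling threshold, either a number or a
#'   `null_threshold`.
#' @param tier label stored with the calls (`"long"` or `"strict"`).
#' @param min_enriched_probes number of probes that must reach the
#'   threshold for a region to be called (default 1).
#' @return a `target_calls` data frame: promoter_id, chrom, peak_start,
#'   peak_end, max_score, n_enriched, enriched_probes (comma-separated),
#'   tier; attributes `"threshold"` and `"tier"`.
#' @export
call_enriched_promoters <- function(ws, design, threshold, tier = "long",
                                    min_enriched_probes = 1) {
  if (inherits(threshold, "null_threshold")) threshold <- threshold$value
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  if (length(ws) != nrow(design$probes))
    stop("`ws` must align with `design$probes`", call. = FALSE)
  mids <- (design$probes$start + design$probes$end) / 2
  idx_by_prom <- split(seq_along(ws), design$probes$promoter_id)
  prom_info <- design$promoters
  rows <- vector("list", length(idx_by_prom))
  for (j in seq_along(idx_by_prom)) {
    idx <- idx_by_prom[[j]]
    ord <- idx[order(mids[idx])]
    s <- ws[ord]
    hits <- s >= threshold
    if (sum(hits) < min_enriched_probes || !any(hits)) next
    imax <- which.max(s)
    # maximal contiguous run of enriched probes containing the argmax
    lo <- imax
    while (lo > 1 && hits[lo - 1]) lo <- lo - 1
    hi <- imax
    while (hi < length(s) && hits[hi + 1]) hi <- hi + 1
    pid <- names(idx_by_prom)[j]
    rows[[j]] <- data.frame(
      promoter_id = pid,
      chrom = prom_info$chrom[match(pid, prom_info$promoter_id)],
      peak_start = mids[ord][lo],
      peak_end = mids[ord][hi],
      max_score = max(s),
      n_enriched = sum(hits),
      enriched_probes = paste(design$probes$probe_id[ord][hits],
                              collapse = ","),
      tier = tier,
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(calls))
    calls <- data.frame(promoter_id = character(0), chrom = character(0),
                        peak_start = numeric(0), peak_end = numeric(0),
                        max_score = numeric(0), n_enriched = integer(0),
                        enriched_probes = character(0), tier = character(0),
                        stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(calls, threshold = threshold, tier = tier,
            class = c("target_calls", "data.frame"))
}

#' Expand called promoter regions to gene-level calls
#'
#' One row per (region, gene) pair: a region lying between the TSSs of two
#' divergently transcribed genes contributes one row per gene, so the
#' deduplicated gene count can exceed the region count. Regions without a
#' gene link are retained with an empty gene field and a warning.
#'
#' @param calls a `target_calls` data frame.
#' @param design a `tiling_design` carrying the promoter-to-gene links.
#' @return data frame with columns of `calls` plus gene_id, tss, strand.
#' @export
map_regions_to_genes <- function(calls, design) {
  if (nrow(calls) == 0) {
    out <- cbind(as.data.frame(calls),
                 data.frame(gene_id = character(0), tss = integer(0),
                            strand = character(0)))
    return(out)
  }
  merged <- merge(as.data.frame(calls), design$genes,
                  by = "promoter_id", all.x = TRUE, sort = FALSE)
  orphan <- is.na(merged$gene_id)
  if (any(orphan)) {
    warning(sum(orphan), " called region(s) have no gene link")
    merged$gene_id[orphan] <- ""
  }
  merged <- merged[order(merged$promoter_id, merged$gene_id), ]
  rownames(merged) <- NULL
  merged
}

#' Cross-filter gene-level calls against the null-genotype track
#'
#' Removes any called gene whose promoter contains at least one
#' null-genotype probe with a window score strictly exceeding the null
#' threshold: enrichment that the ChIP protocol produces even without the
#' protein cannot be trusted as binding evidence. Excluded genes are
#' returned with the offending probe and its null score. The operation is
#' idempotent and order-independent.
#'
#' @param gene_calls data frame from [map_regions_to_genes()].
#' @param null_ws numeric vector of null-genotype window scores aligned
#'   with `design$probes`.
#' @param design a `tiling_design`.
#' @param threshold the null threshold (number or `null_threshold`);
#'   exclusion uses a strict `>` comparison.
#' @return list with `kept` (curated gene calls) and `excluded` (the
#'   removed rows plus null_probe, null_score).
#' @export
filter_against_null <- function(gene_calls, null_ws, design, threshold) {
  if (inherits(threshold, "null_threshold")) threshold <- threshold$value
  if (length(null_ws) != nrow(design$probes))
    stop("`null_ws` must align with `design$probes`", call. = FALSE)
  if (nrow(gene_calls) == 0)
    return(list(kept = gene_calls,
                excluded = cbind(gene_calls,
                                 data.frame(null_probe = character(0),
                                            null_score = numeric(0)))))
  hot <- null_ws > threshold
  idx_by_prom <- split(seq_along(null_ws), design$probes$promoter_id)
  flag_prom <- vapply(idx_by_prom, function(i) any(hot[i]), logical(1))
  offender <- vapply(idx_by_prom, function(i) {
    h <- i[hot[i]]
    if (length(h) == 0) NA_character_
    else design$probes$probe_id[h[which.max(null_ws[h])]]
  }, character(1))
  off_score <- vapply(idx_by_prom, function(i) {
    h <- i[hot[i]]
    if (length(h) == 0) NA_real_ else max(null_ws[h])
  }, numeric(1))

  drop <- flag_prom[gene_calls$promoter_id]
  excluded <- gene_calls[drop, , drop = FALSE]
  if (nrow(excluded) > 0) {
    excluded$null_probe <- offender[excluded$promoter_id]
    excluded$null_score <- off_score[excluded$promoter_id]
  } else {
    excluded$null_probe <- character(0)
    excluded$null_score <- numeric(0)
  }
  kept <- gene_calls[!drop, , drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}
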