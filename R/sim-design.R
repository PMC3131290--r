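#' Generate a synthetic promoter tiling-array design
#'
#' Lays out `cfg$n_promoters` promoter regions across the autosomes and
#' tiles each with 60-mer probes whose strand-oriented offsets fall inside
#' the configured span around the TSS (default -5500..+2500 bp), with
#' consecutive spacings drawn uniformly from `cfg$probe_spacing`. A
#' configured fraction of regions is linked to two divergently transcribed
#' genes, exercising the one-region/two-genes mapping that arises on real
#' promoter arrays.
#'
#' @param cfg a [sim_config()].
#' @return a `tiling_design`: list with data frames `probes` (probe_id,
#'   chrom, start, end, promoter_id; 0-based half-open), `promoters`
#'   (promoter_id, chrom, region_start, region_end) and `genes`
#'   (promoter_id, gene_id, tss, strand). The master seed is attached as
#'   attribute `"seed"` and echoed into file headers by [write_design()].
#' @export
gen_design <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_promoters
    up <- cfg$promoter_span[["upstream"]]
    down <- cfg$promoter_span[["downstream"]]
    span_width <- up + down
    chroms <- paste0("chr", 1 + (seq_len(n) - 1L) %% 19L)
    idx_on_chrom <- stats::ave(seq_len(n), chroms, FUN = seq_along)
    tss <- 10000 + (idx_on_chrom - 1L) * 10000
    strand <- sample(c("+", "-"), n, replace = TRUE)
    bidir <- stats::runif(n) < cfg$bidirectional_fraction

    probe_rows <- vector("list", n)
    for (i in seq_len(n)) {
      n_probes <- max(2L, stats::rpois(1, cfg$probes_per_promoter))
      # whole-bp spacings keep the configured bounds exact after placement
      gaps <- sample(seq.int(ceiling(cfg$probe_spacing[1]),
                             floor(cfg$probe_spacing[2])),
                     n_probes - 1L, replace = TRUE)
      offs <- cumsum(c(0L, gaps))
      offs <- offs[offs <= span_width]          # keep probes inside the span
      anchor <- floor(stats::runif(1, -up, down - max(offs)))
      offs <- anchor + offs
      mids <- if (strand[i] == "+") tss[i] + offs else tss[i] - offs
      probe_rows[[i]] <- data.frame(
        probe_id = sprintf("PR%05d_%02d", i, seq_along(offs)),
        chrom = chroms[i],
        start = as.integer(mids - 30L),
        end = as.integer(mids + 30L),
        promoter_id = sprintf("PR%05d", i),
        stringsAsFactors = FALSE)
    }
    probes <- do.call(rbind, probe_rows)

    promoters <- data.frame(
      promoter_id = sprintf("PR%05d", seq_len(n)),
      chrom = chroms,
      region_start = as.integer(ifelse(strand == "+", tss - up, tss - down)),
      region_end = as.integer(ifelse(strand == "+", tss + down, tss + up)),
      stringsAsFactors = FALSE)

    genes <- data.frame(
      promoter_id = promoters$promoter_id,
      tss = as.integer(tss),
      strand = strand,
      stringsAsFactors = FALSE)
    if (any(bidir)) {
      # divergent partner: TSS a short distance away, opposite strand
      shift <- round(stats::runif(sum(bidir), 300, 1500))
      partner <- data.frame(
        promoter_id = promoters$promoter_id[bidir],
        tss = as.integer(tss[bidir] +
                           ifelse(strand[bidir] == "+", -shift, shift)),
        strand = ifelse(strand[bidir] == "+", "-", "+"),
        stringsAsFactors = FALSE)
      genes <- rbind(genes, partner)
      genes <- genes[order(genes$promoter_id, genes$tss), ]
    }
    genes$gene_id <- sprintf("G%05d", seq_len(nrow(genes)))
    genes <- genes[, c("promoter_id", "gene_id", "tss", "strand")]
    rownames(genes) <- NULL

    structure(list(probes = probes, promoters = promoters, genes = genes),
              class = "tiling_design", seed = cfg$seed)
  })
}

#' @export
print.tiling_design <- function(x, ...) {
  cat("tiling_design:", nrow(x$promoters), "promoters,",
      nrow(x$probes), "probes,", nrow(x$genes), "gene links\n")
  invisible(x)
}

#' Probe midpoints of a tiling design
#'
#' All probe-to-probe and probe-to-site distances in the pipeline are
#' measured between interval midpoints (may be half-integral).
#'
#' @param design a `tiling_design`.
#' @return named numeric vector of midpoints, one per probe.
#' @export
probe_midpoints <- function(design) {
  stats::setNames((design$probes$start + design$probes$end) / 2,
                  design$probes$probe_id)
}
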