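# Shared fixtures and independent brute-force oracles used across tests.

# tiny config for fast generator runs
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_promoters = 50, n_genes = 400, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# build a tiling_design directly from per-promoter probe midpoints
design_from_mids <- function(mid_list, bidirectional = logical(0)) {
  probes <- do.call(rbind, lapply(seq_along(mid_list), function(i) {
    mids <- sort(mid_list[[i]])
    data.frame(probe_id = sprintf("PR%03d_%02d", i, seq_along(mids)),
               chrom = "chr1",
               start = as.integer(mids - 30),
               end = as.integer(mids + 30),
               promoter_id = sprintf("PR%03d", i),
               stringsAsFactors = FALSE)
  }))
  promoters <- data.frame(
    promoter_id = sprintf("PR%03d", seq_along(mid_list)),
    chrom = "chr1",
    region_start = vapply(mid_list, function(m) as.integer(min(m) - 30),
                          integer(1)),
    region_end = vapply(mid_list, function(m) as.integer(max(m) + 30),
                        integer(1)),
    stringsAsFactors = FALSE)
  genes <- data.frame(promoter_id = promoters$promoter_id,
                      gene_id = sprintf("G%03d", seq_along(mid_list)),
                      tss = promoters$region_start,
                      strand = "+", stringsAsFactors = FALSE)
  if (length(bidirectional)) {
    extra <- promoters$promoter_id[bidirectional]
    if (length(extra))
      genes <- rbind(genes, data.frame(
        promoter_id = extra,
        gene_id = paste0("G", seq_along(extra) + 900),
        tss = promoters$region_start[bidirectional] + 500,
        strand = "-", stringsAsFactors = FALSE))
  }
  structure(list(probes = probes, promoters = promoters, genes = genes),
            class = "tiling_design")
}

# naive re-evaluation of the window-score rule: for each probe, scan all
# probes of its promoter, take the closest on each side, apply the median
# and zeroing clauses literally
naive_window_scores <- function(scores, design, halfwidth = 500,
                                min_probes = 3, background = 0) {
  mids <- (design$probes$start + design$probes$end) / 2
  prom <- design$probes$promoter_id
  out <- numeric(length(scores))
  for (i in seq_along(scores)) {
    same <- which(prom == prom[i])
    d <- mids[same] - mids[i]
    up <- same[d < 0 & abs(d) <= halfwidth]
    dn <- same[d > 0 & d <= halfwidth]
    set <- i
    if (length(up)) set <- c(set, up[which.max(mids[up])])
    if (length(dn)) set <- c(set, dn[which.min(mids[dn])])
    out[i] <- if (sum(scores[set] > background) < min_probes) 0
              else median(scores[set])
  }
  out
}

# literal step-up BH: q_i = min_{j: p_(j) >= p_(i)} p_(j) * n / j
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(which(ps >= ps[i]), function(j) ps[j] * n / j, numeric(1))
    q[o[i]] <- min(1, cand)
  }
  q
}

# brute-force hypergeometric upper tail: P(X >= x) for x successes among n
# draws from N with K marked
naive_hyper_tail <- function(x, K, n, N) {
  ii <- max(x, max(0, n - (N - K))):min(K, n)
  sum(choose(K, ii) * choose(N - K, n - ii)) / choose(N, n)
}

# regex-based motif scan oracle: union of match start positions of all
# concrete variants on the forward and reverse-complement strands
naive_scan <- function(pattern, seqs) {
  sets <- parse_motif(pattern)
  variants <- apply(expand.grid(sets, stringsAsFactors = FALSE), 1,
                    paste, collapse = "")
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  rx_f <- paste0("(?=(", paste(variants, collapse = "|"), "))")
  rx_r <- paste0("(?=(", paste(vapply(variants, rc, character(1)),
                               collapse = "|"), "))")
  vapply(as.character(seqs), function(s) {
    st_f <- gregexpr(rx_f, s, perl = TRUE)[[1]]
    st_r <- gregexpr(rx_r, s, perl = TRUE)[[1]]
    length(union(st_f[st_f > 0], st_r[st_r > 0]))
  }, integer(1), USE.NAMES = FALSE)
}
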