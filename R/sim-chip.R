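#' Planted-peak enrichment kernel
#'
#' Expected log2 enrichment contributed by a binding site to a probe at
#' distance `d` (bp). The default triangular kernel decays linearly to zero
#' at `halfwidth`: chromatin shearing produces overlapping fragments, so
#' probes nearer the site capture more immunoprecipitated fragments and the
#' expected enrichment falls off roughly linearly with distance. The
#' gaussian variant (sd = halfwidth/2) is available for sensitivity
#' analysis; its value at `halfwidth` is not exactly zero.
#'
#' @param d numeric distances (bp) from the binding site.
#' @param amplitude peak log2 enrichment at the site.
#' @param halfwidth bp at which the triangular kernel reaches zero.
#' @param shape `"triangular"` or `"gaussian"`.
#' @return numeric vector of expected log2 enrichments.
#' @export
peak_kernel <- function(d, amplitude, halfwidth,
                        shape = c("triangular", "gaussian")) {
  shape <- match.arg(shape)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  switch(shape,
    triangular = amplitude * pmax(0, 1 - abs(d) / halfwidth),
    gaussian = amplitude * exp(-d^2 / (2 * (halfwidth / 2)^2)))
}

#' Generate synthetic ChIP-chip replicate arrays for both genotypes
#'
#' Null-genotype (protein-null) replicates carry zero-mean Gaussian noise
#' only: with no protein available for pulldown, any signal is background.
#' Wild-type replicates add, for each planted bound promoter, an enrichment
#' peak centred on its binding site (see [peak_kernel()]) on top of the same
#' noise. Binding sites are drawn uniformly over each bound promoter's
#' probe-covered extent, so every planted peak is observable. An optional
#' `null_contamination` fraction plants peaks in the null arrays too
#' (antibody cross-reactivity emulation; off by default).
#'
#' @param design a `tiling_design` from [gen_design()].
#' @param cfg the [sim_config()] used to build `design`.
#' @return list with `wt` and `null` (probes x replicates matrices of
#'   log2(ChIP/input) ratios, rownames = probe ids) and `truth` (data frame
#'   promoter_id, site, amplitude; `site` is the genomic binding-site
#'   coordinate). Seed attached as attribute `"seed"`.
#' @export
gen_chip_arrays <- function(design, cfg) {
  stopifnot(inherits(design, "tiling_design"), inherits(cfg, "sim_config"))
  if (cfg$peak_amplitude < 0)
    stop("`peak_amplitude` must be >= 0", call. = FALSE)
  with_seed(cfg$seed + 1L, {
    probes <- design$probes
    n_probes <- nrow(probes)
    mids <- (probes$start + probes$end) / 2
    reps <- cfg$n_replicates

    idx_by_prom <- split(seq_len(n_probes), probes$promoter_id)
    plant <- function(bound_ids) {
      signal <- numeric(n_probes)
      sites <- numeric(length(bound_ids))
      for (k in seq_along(bound_ids)) {
        sel <- idx_by_prom[[bound_ids[k]]]
        sites[k] <- stats::runif(1, min(mids[sel]), max(mids[sel]))
        signal[sel] <- signal[sel] +
          peak_kernel(mids[sel] - sites[k], cfg$peak_amplitude,
                      cfg$peak_halfwidth, cfg$peak_shape)
      }
      list(signal = signal,
           truth = data.frame(promoter_id = as.character(bound_ids),
                              site = sites,
                              amplitude = rep(cfg$peak_amplitude,
                                              length(bound_ids)),
                              stringsAsFactors = FALSE))
    }

    ids <- design$promoters$promoter_id
    n_bound <- round(cfg$bound_fraction * length(ids))
    wt_plant <- plant(sort(sample(ids, n_bound)))
    n_cont <- round(cfg$null_contamination * length(ids))
    null_plant <- plant(if (n_cont > 0) sort(sample(ids, n_cont))
                        else character(0))

    noise <- function() matrix(stats::rnorm(n_probes * reps, 0, cfg$noise_sd),
                               n_probes, reps)
    wt <- wt_plant$signal + noise()
    null <- null_plant$signal + noise()
    dimnames(wt) <- list(probes$probe_id, paste0("wt_", seq_len(reps)))
    dimnames(null) <- list(probes$probe_id, paste0("null_", seq_len(reps)))

    structure(list(wt = wt, null = null,
                   truth = wt_plant$truth, null_truth = null_plant$truth),
              seed = cfg$seed)
  })
}
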