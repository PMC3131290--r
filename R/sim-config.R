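#' Simulation configuration for the synthetic tiling-array / expression study
#'
#' Bundles every knob of the synthetic-data generator into one validated
#' object. Defaults emulate the study design the pipeline was built for: an
#' Agilent-style promoter tiling array (~17,000 promoters, ~25 60-mer probes
#' per promoter spanning 5.5 kb upstream to 2.5 kb downstream of the TSS at
#' 100-300 bp spacing, three biological replicates per genotype) and an
#' Illumina WG-6-style expression study with litter structure (three litters
#' splitting 2WT/2MUT, 2WT/2MUT and 1WT/2MUT, i.e. 5 wild-type and 6 mutant
#' usable samples, which admits exactly 108 litter-preserving genotype-label
#' permutations).
#'
#' @param n_promoters number of promoter regions on the array.
#' @param probes_per_promoter mean probe count per promoter (Poisson draw,
#'   floored at 2).
#' @param probe_spacing length-2 numeric, the closed range (bp) that
#'   consecutive probe spacings are drawn from uniformly.
#' @param promoter_span named length-2 numeric `c(upstream=, downstream=)`,
#'   strand-oriented extent of the tiled region around the TSS in bp.
#' @param n_replicates biological replicates per genotype.
#' @param noise_sd per-probe, per-replicate Gaussian noise sd of the
#'   log2(ChIP/input) ratios.
#' @param bound_fraction proportion of promoters carrying a planted binding
#'   peak in the wild-type arrays.
#' @param peak_amplitude expected log2 enrichment at the planted binding
#'   site (score units: 1 means 2-fold).
#' @param peak_halfwidth bp at which the planted enrichment decays to zero;
#'   the default 750 is the midpoint of a 300-1000 bp chromatin shear range.
#' @param peak_shape `"triangular"` (linear decay, default: overlapping
#'   sheared fragments give enrichment falling off linearly with distance
#'   from the site) or `"gaussian"`.
#' @param null_contamination proportion of promoters receiving a planted
#'   peak in the *null-genotype* arrays (antibody cross-reactivity
#'   emulation). Off (0) by default.
#' @param bidirectional_fraction proportion of promoter regions linked to
#'   two divergently transcribed genes.
#' @param n_genes number of expression probes/genes.
#' @param detected_fraction proportion of genes that are expressed above the
#'   detection limit in the simulated tissue.
#' @param litters list of named length-2 integer vectors `c(wt=, mut=)`
#'   giving each litter's genotype split.
#' @param de_fraction proportion of detected genes that are truly
#'   differentially expressed.
#' @param effect_size absolute log2 genotype effect of true DE genes (sign
#'   drawn at random per gene).
#' @param expr_noise_sd residual sd of the expression values (transformed
#'   scale).
#' @param litter_sd sd of the per-gene, per-litter random effect.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline
#'   expression on the transformed scale.
#' @param motif planted degenerate 8-mer, IUPAC or bracket notation
#'   (at most two alternative bases per position).
#' @param prevalence_target,prevalence_background probability that a target
#'   (resp. background) promoter sequence receives a planted motif instance.
#' @param seq_length promoter sequence length (bp).
#' @param gc_fraction GC content of the background sequence.
#' @param seed integer master seed; every generator derives its stream from
#'   it and records it on its outputs.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_promoters = 17000,
                       probes_per_promoter = 25,
                       probe_spacing = c(100, 300),
                       promoter_span = c(upstream = 5500, downstream = 2500),
                       n_replicates = 3,
                       noise_sd = 0.35,
                       bound_fraction = 0.05,
                       peak_amplitude = 2.0,
                       peak_halfwidth = 750,
                       peak_shape = c("triangular", "gaussian"),
                       null_contamination = 0,
                       bidirectional_fraction = 0.03,
                       n_genes = 45281,
                       detected_fraction = 0.54,
                       litters = list(c(wt = 2, mut = 2),
                                      c(wt = 2, mut = 2),
                                      c(wt = 1, mut = 2)),
                       de_fraction = 0.02,
                       effect_size = 1.5,
                       expr_noise_sd = 0.5,
                       litter_sd = 0.3,
                       baseline_mean = 8,
                       baseline_sd = 2,
                       motif = "AAAG[G/C]AAA",
                       prevalence_target = 0.7,
                       prevalence_background = 0.2,
                       seq_length = 1000,
                       gc_fraction = 0.5,
                       seed = 1L) {
  peak_shape <- match.arg(peak_shape)
  if (!is.numeric(n_promoters) || length(n_promoters) != 1 || n_promoters < 1)
    stop("`n_promoters` must be a positive count", call. = FALSE)
  if (length(probe_spacing) != 2 || any(probe_spacing <= 0) ||
      probe_spacing[1] > probe_spacing[2])
    stop("`probe_spacing` must be a positive closed range c(min, max)",
         call. = FALSE)
  if (length(promoter_span) != 2 || any(promoter_span <= 0))
    stop("`promoter_span` must be positive c(upstream, downstream) extents",
         call. = FALSE)
  props <- c(bound_fraction = bound_fraction,
             null_contamination = null_contamination,
             bidirectional_fraction = bidirectional_fraction,
             detected_fraction = detected_fraction,
             de_fraction = de_fraction,
             prevalence_target = prevalence_target,
             prevalence_background = prevalence_background,
             gc_fraction = gc_fraction)
  bad <- props < 0 | props > 1
  if (any(bad))
    stop("proportions must lie in [0, 1]: ",
         paste(names(props)[bad], collapse = ", "), call. = FALSE)
  if (peak_amplitude < 0)
    stop("`peak_amplitude` must be >= 0", call. = FALSE)
  if (peak_halfwidth <= 0) stop("`peak_halfwidth` must be > 0", call. = FALSE)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (noise_sd < 0 || expr_noise_sd < 0 || litter_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (prevalence_target < prevalence_background)
    stop("`prevalence_target` must be >= `prevalence_background`",
         call. = FALSE)
  pat <- parse_motif(motif)   # validates IUPAC / bracket notation
  if (length(pat) > seq_length)
    stop("planted motif is longer than `seq_length`", call. = FALSE)
  if (!all(vapply(litters, function(l)
        all(c("wt", "mut") %in% names(l)) && all(l >= 0), logical(1))))
    stop("each litter must be a named vector c(wt=, mut=)", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)

  structure(list(
    n_promoters = as.integer(n_promoters),
    probes_per_promoter = probes_per_promoter,
    probe_spacing = as.numeric(probe_spacing),
    promoter_span = c(upstream = as.numeric(promoter_span[["upstream"]]),
                      downstream = as.numeric(promoter_span[["downstream"]])),
    n_replicates = as.integer(n_replicates),
    noise_sd = noise_sd,
    bound_fraction = bound_fraction,
    peak_amplitude = peak_amplitude,
    peak_halfwidth = peak_halfwidth,
    peak_shape = peak_shape,
    null_contamination = null_contamination,
    bidirectional_fraction = bidirectional_fraction,
    n_genes = as.integer(n_genes),
    detected_fraction = detected_fraction,
    litters = litters,
    de_fraction = de_fraction,
    effect_size = effect_size,
    expr_noise_sd = expr_noise_sd,
    litter_sd = litter_sd,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    motif = motif,
    prevalence_target = prevalence_target,
    prevalence_background = prevalence_background,
    seq_length = as.integer(seq_length),
    gc_fraction = gc_fraction,
    seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_promoters, "promoters x ~", x$probes_per_promoter, "probes,",
      x$n_replicates, "replicates/genotype; bound_fraction",
      x$bound_fraction, "amplitude", x$peak_amplitude, "\n")
  n_samp <- sum(vapply(x$litters, sum, numeric(1)))
  cat("  expression:", x$n_genes, "genes x", n_samp, "samples in",
      length(x$litters), "litters; de_fraction", x$de_fraction, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without clobbering the caller's
# random stream. All generator randomness funnels through this.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
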