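#' Generate a synthetic litter-structured expression study
#'
#' Emulates a bead-array expression experiment comparing wild-type and
#' protein-null littermates. Each gene's value on the transformed
#' (log-like) scale is
#' `baseline + genotype effect (true DE genes only) + litter effect + noise`,
#' where the litter effect is a per-gene, per-litter draw of sd
#' `cfg$litter_sd` (embryos from one pregnancy share environment and
#' genetic background). A `detected_fraction` of genes is expressed above
#' the platform detection limit; the rest receive detection scores below
#' 0.95 in every sample and carry no signal structure. True DE genes are
#' always detected. A raw intensity-scale matrix (per-array gain times
#' `2^value` plus additive noise and an array background) and the per-array
#' negative-control means are emitted alongside, feeding the background
#' correction / variance-stabilization path.
#'
#' @param cfg a [sim_config()].
#' @param gene_ids optional character vector of gene identifiers (e.g. from
#'   a [gen_design()] gene table) to use for the first genes, sharing the
#'   identifier namespace with the ChIP side; remaining genes get
#'   generator-local ids.
#' @param de_pool optional character vector of gene ids from which the true
#'   DE genes are drawn (forced detected); used to plant DE genes among the
#'   ChIP-bound genes for end-to-end integration checks.
#' @return an `expression_sim`: list with `exprs` (genes x samples,
#'   transformed scale), `raw` (intensity scale), `control_means` (one per
#'   array), `detection` (genes x samples in `[0,1]`), `samples` (data
#'   frame sample_id, genotype, litter) and `truth` (data frame gene_id,
#'   effect — signed log2, mutant minus wild-type). Seed attached as
#'   attribute `"seed"`.
#' @export
gen_expression <- function(cfg, gene_ids = NULL, de_pool = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 2L, {
    litters <- cfg$litters
    one_genotype <- vapply(litters, function(l) any(l == 0), logical(1))
    if (any(one_genotype))
      warning("litter(s) ", paste(which(one_genotype), collapse = ", "),
              " contain a single genotype; the constrained permutation ",
              "test is degenerate for them")
    genotype <- unlist(lapply(litters, function(l)
      c(rep("wt", l[["wt"]]), rep("mut", l[["mut"]]))))
    litter <- unlist(lapply(seq_along(litters), function(i)
      rep(paste0("L", i), sum(litters[[i]]))))
    n_samp <- length(genotype)
    samples <- data.frame(sample_id = sprintf("S%02d", seq_len(n_samp)),
                          genotype = genotype, litter = litter,
                          stringsAsFactors = FALSE)

    g <- cfg$n_genes
    gene_id <- sprintf("EG%05d", seq_len(g))
    if (!is.null(gene_ids)) {
      k <- min(g, length(gene_ids))
      gene_id[seq_len(k)] <- gene_ids[seq_len(k)]
    }
    detected <- stats::runif(g) < cfg$detected_fraction
    n_de <- round(cfg$de_fraction * sum(detected))
    if (!is.null(de_pool)) {
      pool <- which(gene_id %in% de_pool)
      detected[pool] <- TRUE
      de_idx <- sample(pool, min(n_de, length(pool)))
      if (length(de_idx) < n_de)
        de_idx <- c(de_idx, sample(setdiff(which(detected), pool),
                                   n_de - length(de_idx)))
    } else {
      de_idx <- sample(which(detected), n_de)
    }
    effect <- numeric(g)
    effect[de_idx] <- cfg$effect_size * sample(c(-1, 1), n_de, replace = TRUE)

    baseline <- stats::rnorm(g, cfg$baseline_mean, cfg$baseline_sd)
    n_lit <- length(litters)
    litter_eff <- matrix(stats::rnorm(g * n_lit, 0, cfg$litter_sd), g, n_lit,
                         dimnames = list(gene_id, paste0("L", seq_len(n_lit))))
    is_mut <- as.numeric(genotype == "mut")
    exprs <- baseline +
      outer(effect, is_mut) +
      litter_eff[, litter, drop = FALSE] +
      matrix(stats::rnorm(g * n_samp, 0, cfg$expr_noise_sd), g, n_samp)
    # undetected genes: flat low-level noise, no biological structure
    if (any(!detected)) {
      exprs[!detected, ] <- matrix(
        stats::rnorm(sum(!detected) * n_samp, cfg$baseline_mean - 6, 0.2),
        sum(!detected), n_samp)
    }
    dimnames(exprs) <- list(gene_id, samples$sample_id)

    detection <- matrix(stats::runif(g * n_samp, 0.96, 1), g, n_samp,
                        dimnames = dimnames(exprs))
    detection[!detected, ] <- stats::runif(sum(!detected) * n_samp, 0, 0.94)

    gain <- stats::runif(n_samp, 0.8, 1.2)
    bg <- stats::runif(n_samp, 30, 70)
    raw <- sweep(2^exprs, 2, gain, `*`) +
      matrix(stats::rnorm(g * n_samp, 0, 5), g, n_samp)
    raw <- sweep(raw, 2, bg, `+`)
    dimnames(raw) <- dimnames(exprs)

    structure(list(exprs = exprs, raw = raw,
                   control_means = stats::setNames(bg, samples$sample_id),
                   detection = detection, samples = samples,
                   truth = data.frame(gene_id = gene_id[de_idx],
                                      effect = effect[de_idx],
                                      stringsAsFactors = FALSE)),
              class = "expression_sim", seed = cfg$seed)
  })
}

#' Generate synthetic promoter sequences with a planted degenerate motif
#'
#' Emits i.i.d. uppercase ACGT sequences at the configured GC content for
#' the supplied target and background promoter ids, and inserts one random
#' concrete instantiation of the configured degenerate 8-mer into a
#' `prevalence_target` (resp. `prevalence_background`) fraction of them at
#' a uniform random offset. Plant positions and variants are recorded so
#' the over-representation scan can be validated against ground truth.
#'
#' @param cfg a [sim_config()].
#' @param target_ids,background_ids character vectors of promoter ids.
#' @return list with `targets` and `background` (`DNAStringSet`s named by
#'   promoter id) and `truth` (data frame seq_id, set, planted, position,
#'   variant). Seed attached as attribute `"seed"`.
#' @export
gen_promoter_sequences <- function(cfg, target_ids, background_ids) {
  stopifnot(inherits(cfg, "sim_config"))
  sets <- parse_motif(cfg$motif)
  if (length(sets) > cfg$seq_length)
    stop("planted motif is longer than `seq_length`", call. = FALSE)
  with_seed(cfg$seed + 3L, {
    variants <- pattern_variants(sets)
    base_p <- c(A = (1 - cfg$gc_fraction) / 2, C = cfg$gc_fraction / 2,
                G = cfg$gc_fraction / 2, T = (1 - cfg$gc_fraction) / 2)
    gen_set <- function(ids, prevalence, set_label) {
      n <- length(ids)
      seqs <- vapply(seq_len(n), function(i)
        paste(sample(names(base_p), cfg$seq_length, replace = TRUE,
                     prob = base_p), collapse = ""), character(1))
      planted <- stats::runif(n) < prevalence
      pos <- rep(NA_integer_, n)
      var <- rep(NA_character_, n)
      for (i in which(planted)) {
        pos[i] <- sample.int(cfg$seq_length - length(sets) + 1L, 1)
        var[i] <- sample(variants, 1)
        substr(seqs[i], pos[i], pos[i] + length(sets) - 1L) <- var[i]
      }
      list(seqs = stats::setNames(Biostrings::DNAStringSet(seqs), ids),
           truth = data.frame(seq_id = ids, set = set_label,
                              planted = planted, position = pos,
                              variant = var, stringsAsFactors = FALSE))
    }
    tg <- gen_set(target_ids, cfg$prevalence_target, "target")
    bg <- gen_set(background_ids, cfg$prevalence_background, "background")
    structure(list(targets = tg$seqs, background = bg$seqs,
                   truth = rbind(tg$truth, bg$truth)),
              seed = cfg$seed)
  })
}
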