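# Expression preprocessing and litter-aware differential expression.

#' Background-correct expression arrays with negative-control means
#'
#' Subtracts each array's average negative-control signal from every value
#' on that array. Values may become negative; the downstream generalized-log
#' transform is defined on the whole real line.
#'
#' @param raw numeric matrix, genes x arrays.
#' @param control_means numeric vector, one negative-control mean per array
#'   (recycled by column name when named).
#' @return matrix of the same shape.
#' @export
background_correct <- function(raw, control_means) {
  raw <- as.matrix(raw)
  if (is.null(control_means) || any(is.na(control_means)))
    stop("a negative-control mean is required for every array", call. = FALSE)
  if (!is.null(names(control_means)) && !is.null(colnames(raw)))
    control_means <- control_means[colnames(raw)]
  if (length(control_means) != ncol(raw))
    stop("need one control mean per array", call. = FALSE)
  sweep(raw, 2, control_means, `-`)
}

#' Variance-stabilizing generalized-log transform
#'
#' Applies a per-array affine calibration (arrays are brought to a common
#' robust location and scale via their medians and MADs) followed by the
#' generalized-log transform
#' `glog2(x) = log2((x + sqrt(x^2 + c^2)) / 2)`,
#' with `c` estimated per array as the MAD of the array's below-median
#' values (the additive-noise-dominated regime). The transform is monotone,
#' approaches `log2(x)` for `x >> c`, is approximately linear near zero,
#' and equals `log2(c/2)` at `x = 0`. It flattens the mean-variance
#' relationship of intensity-scale data whose noise is multiplicative at
#' high signal and additive near background.
#'
#' @param mat background-corrected matrix, genes x arrays.
#' @return transformed matrix; attributes `"offsets"`, `"scales"` and
#'   `"glog_c"` record the calibration.
#' @export
vst_glog <- function(mat) {
  mat <- as.matrix(mat)
  o <- apply(mat, 2, stats::median)
  s <- apply(mat, 2, stats::mad)
  if (any(s == 0))
    stop("constant array: affine calibration is degenerate", call. = FALSE)
  s_ref <- exp(mean(log(s)))
  o_ref <- mean(o)
  cal <- sweep(sweep(mat, 2, o, `-`), 2, s / s_ref, `/`)
  cal <- cal + o_ref
  cc <- apply(cal, 2, function(x) {
    spread <- stats::mad(x[x < stats::median(x)])
    max(spread, 1e-8)
  })
  out <- sapply(seq_len(ncol(cal)), function(j) glog2(cal[, j], cc[j]))
  dimnames(out) <- dimnames(mat)
  structure(out, offsets = o, scales = s, glog_c = cc)
}

#' @rdname vst_glog
#' @param x numeric values (any sign).
#' @param c glog calibration constant (> 0).
#' @export
glog2 <- function(x, c) log2((x + sqrt(x^2 + c^2)) / 2)

#' Remove undetected probes
#'
#' A gene is kept iff its detection score is at least `threshold` (default
#' 0.95) in at least one sample; genes below the threshold in every sample
#' carry no usable signal and are removed. Idempotent.
#'
#' @param exprs genes x samples expression matrix.
#' @param detection congruent matrix of detection scores in `[0,1]`.
#' @param threshold detection-score cutoff.
#' @return list with the filtered `exprs` and `detection` and the removed
#'   gene ids (`removed`).
#' @export
detection_filter <- function(exprs, detection, threshold = 0.95) {
  if (!all(dim(exprs) == dim(detection)))
    stop("`detection` must be congruent with `exprs`", call. = FALSE)
  keep <- apply(detection >= threshold, 1, any)
  list(exprs = exprs[keep, , drop = FALSE],
       detection = detection[keep, , drop = FALSE],
       removed = rownames(exprs)[!keep])
}

#' Flag outlier samples by inter-sample correlation
#'
#' Computes each sample's median Pearson correlation with the other
#' samples and flags samples lying strictly more than `n_mad` robust
#' deviations (MADs) below the cohort median of those values. Idempotent
#' given the same cohort; refuses (with diagnostics) if more than 25% of
#' samples would be flagged, since that indicates a cohort-level problem
#' rather than individual outliers.
#'
#' @param exprs genes x samples matrix (transformed scale).
#' @param n_mad robust-deviation multiplier (default 3).
#' @return data frame: sample_id, median_cor, flagged.
#' @export
qc_outliers <- function(exprs, n_mad = 3) {
  if (ncol(exprs) < 4)
    stop("outlier QC needs >= 4 samples", call. = FALSE)
  cc <- stats::cor(exprs)
  diag(cc) <- NA
  med_cor <- apply(cc, 2, stats::median, na.rm = TRUE)
  centre <- stats::median(med_cor)
  spread <- stats::mad(med_cor)
  flagged <- med_cor < centre - n_mad * spread   # strictly below
  if (mean(flagged) > 0.25) {
    stop("more than 25% of samples flagged as outliers (median correlations: ",
         paste(sprintf("%s=%.3f", colnames(exprs), med_cor), collapse = ", "),
         ")", call. = FALSE)
  }
  data.frame(sample_id = colnames(exprs), median_cor = unname(med_cor),
             flagged = unname(flagged), stringsAsFactors = FALSE)
}

# design matrix for ~ genotype + litter, genotype coded mut = 1.
# Errors when genotype is confounded with litter (aliased columns).
de_design <- function(samples) {
  build_design(factor(samples$genotype, levels = c("wt", "mut")),
               factor(samples$litter))
}

# with a single litter the blocking term drops and the model reduces to the
# ordinary two-group comparison
build_design <- function(genotype, litter) {
  X <- if (nlevels(litter) < 2) stats::model.matrix(~ genotype)
       else stats::model.matrix(~ genotype + litter)
  if (qr(X)$rank < ncol(X))
    stop("genotype is confounded with litter: the genotype effect is not ",
         "estimable", call. = FALSE)
  X
}

# core least-squares engine shared by fit_de and the permutation test:
# genotype coefficient, ordinary t and two-sided p for every gene.
ols_genotype <- function(Y, X) {
  n <- ncol(Y)
  p <- ncol(X)
  qx <- qr(X)
  coefs <- qr.coef(qx, t(Y))
  fitted <- X %*% coefs
  res <- t(Y) - fitted
  df <- n - p
  s2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  v_g <- xtx_inv[2, 2]                      # genotype column is second
  b <- coefs[2, ]
  t_ord <- b / sqrt(s2 * v_g)
  list(effect = b, s2 = s2, df = df, v_g = v_g, t = t_ord,
       p = 2 * stats::pt(-abs(t_ord), df))
}

# moment-matched squeezing of per-gene variances towards a common prior:
# model s2 ~ s0^2 * F(df, d0); match mean and variance of log(s2).
moderate_variances <- function(s2, df) {
  ok <- s2 > 0
  z <- log(s2[ok])
  evar <- stats::var(z) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    ls0 <- mean(z) - digamma(df / 2) + log(df / 2)
  } else {
    d0 <- 2 * stats::uniroot(function(x) trigamma(x) - evar,
                             lower = 1e-3, upper = 1e7)$root
    ls0 <- mean(z) - digamma(df / 2) + log(df / 2) +
      digamma(d0 / 2) - log(d0 / 2)
  }
  s0_2 <- exp(ls0)
  s2_tilde <- if (is.infinite(d0)) rep(s0_2, length(s2))
              else (d0 * s0_2 + df * s2) / (d0 + df)
  list(s2_tilde = s2_tilde, d0 = d0, s0_2 = s0_2)
}

#' Litter-aware differential-expression fit
#'
#' Fits, per gene, the least-squares linear model
#' `value ~ intercept + genotype + litter` with litter as a fixed blocking
#' factor and genotype coded mutant = 1, so the reported effect is the
#' log2 difference mutant minus wild-type. Both the ordinary t-test
#' (exact residual df) and a moderated t-test are computed; the moderated
#' variant squeezes per-gene variances towards a common prior estimated by
#' log-scale moment matching across genes, stabilising inference at small
#' replicate numbers. With `moderated = TRUE` (default) the moderated
#' statistics populate the primary `t`/`p`/`q` columns; both sets are
#' always present.
#'
#' @param exprs genes x samples matrix (transformed scale).
#' @param samples data frame with columns `genotype` (`"wt"`/`"mut"`) and
#'   `litter`, rows aligned with the matrix columns.
#' @param moderated whether the primary statistics are the moderated ones.
#' @return a `de_result` data frame: gene_id, effect, t, p, q, direction
#'   (`up`/`down` in mutant), plus t_ord, p_ord, q_ord, t_mod, p_mod,
#'   q_mod, sigma. Attributes `d0` and `s0_2` record the moderation prior.
#' @export
fit_de <- function(exprs, samples, moderated = TRUE) {
  exprs <- as.matrix(exprs)
  if (nrow(samples) != ncol(exprs))
    stop("`samples` must describe the matrix columns", call. = FALSE)
  tab <- table(factor(samples$genotype, levels = c("wt", "mut")))
  if (any(tab < 2))
    stop("need >= 2 samples per genotype", call. = FALSE)
  X <- de_design(samples)
  fit <- ols_genotype(exprs, X)
  mod <- moderate_variances(fit$s2, fit$df)
  t_mod <- fit$effect / sqrt(mod$s2_tilde * fit$v_g)
  df_mod <- min(fit$df + mod$d0, 1e6)
  p_mod <- 2 * stats::pt(-abs(t_mod), df_mod)
  out <- data.frame(
    gene_id = rownames(exprs),
    effect = unname(fit$effect),
    t_ord = unname(fit$t), p_ord = unname(fit$p),
    q_ord = bh_fdr(unname(fit$p)),
    t_mod = unname(t_mod), p_mod = unname(p_mod),
    q_mod = bh_fdr(unname(p_mod)),
    sigma = sqrt(unname(fit$s2)),
    direction = ifelse(fit$effect < 0, "down", "up"),
    stringsAsFactors = FALSE)
  if (moderated) {
    out$t <- out$t_mod; out$p <- out$p_mod; out$q <- out$q_mod
  } else {
    out$t <- out$t_ord; out$p <- out$p_ord; out$q <- out$q_ord
  }
  out <- out[, c("gene_id", "effect", "t", "p", "q", "direction",
                 "t_ord", "p_ord", "q_ord", "t_mod", "p_mod", "q_mod",
                 "sigma")]
  structure(out, d0 = mod$d0, s0_2 = mod$s0_2, df = fit$df,
            class = c("de_result", "data.frame"))
}

#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' `q_i = min over j with p_(j) >= p_(i) of p_(j) * n / j`, capped at 1 and
#' mapped back to the input order.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return numeric vector of q-values, same order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Litter-constrained genotype-label permutation test
#'
#' Enumerates every reassignment of the genotype labels that preserves each
#' litter's genotype counts (so litter effects cannot masquerade as
#' genotype effects under the permutation null), refits the
#' genotype + litter model for each, counts the genes significant at
#' `alpha`, and reports how many permutations reach at least the observed
#' tally. The identity assignment is one of the permutations, so the
#' empirical p-value is at least `1/total`. When the exact enumeration
#' exceeds `max_exact` assignments, a uniform sample of `n_sample`
#' permutations is drawn instead (seeded, reported with a Monte-Carlo CI).
#'
#' @param exprs genes x samples matrix.
#' @param samples data frame with `genotype` and `litter` columns.
#' @param alpha per-gene significance level (default 0.01).
#' @param statistic `"ordinary"` (default; exact-df t) or `"moderated"`.
#' @param max_exact largest enumeration evaluated exhaustively.
#' @param n_sample Monte-Carlo sample size beyond `max_exact`.
#' @param sample_seed RNG seed for the Monte-Carlo branch.
#' @return a `permutation_report`: list with `total` (valid permutations),
#'   `observed` (genes with p < alpha under the true labels),
#'   `count_ge_observed`, `empirical_p`, `alpha`, `tallies` (per
#'   permutation), `exact`, and `mc_ci` (95% CI, Monte-Carlo branch only).
#' @export
litter_permutation_test <- function(exprs, samples, alpha = 0.01,
                                    statistic = c("ordinary", "moderated"),
                                    max_exact = 1e6, n_sample = 1e4,
                                    sample_seed = 1L) {
  statistic <- match.arg(statistic)
  exprs <- as.matrix(exprs)
  X <- de_design(samples)                    # errors if confounded
  litter <- factor(samples$litter)
  idx_by_litter <- split(seq_len(nrow(samples)), litter)
  k_mut <- vapply(idx_by_litter, function(i)
    sum(samples$genotype[i] == "mut"), integer(1))
  per_litter <- mapply(function(idx, k) {
    if (k == 0) list(integer(0)) else utils::combn(idx, k, simplify = FALSE)
  }, idx_by_litter, k_mut, SIMPLIFY = FALSE)
  total <- prod(vapply(per_litter, length, numeric(1)))

  exact <- total <= max_exact
  choose_sets <- function(pick) {
    unlist(mapply(function(opts, j) opts[[j]], per_litter, pick,
                  SIMPLIFY = FALSE), use.names = FALSE)
  }
  if (exact) {
    grid <- expand.grid(lapply(per_litter, seq_along))
    assignments <- lapply(seq_len(nrow(grid)), function(r)
      choose_sets(as.integer(grid[r, ])))
  } else {
    assignments <- with_seed(sample_seed, {
      lapply(seq_len(n_sample), function(i)
        choose_sets(vapply(per_litter, function(o)
          sample.int(length(o), 1), integer(1))))
    })
  }

  tally_for <- function(mut_idx) {
    g <- rep("wt", nrow(samples))
    g[mut_idx] <- "mut"
    Xp <- build_design(factor(g, levels = c("wt", "mut")), litter)
    fit <- ols_genotype(exprs, Xp)
    p <- if (statistic == "ordinary") fit$p else {
      mod <- moderate_variances(fit$s2, fit$df)
      t_mod <- fit$effect / sqrt(mod$s2_tilde * fit$v_g)
      2 * stats::pt(-abs(t_mod), min(fit$df + mod$d0, 1e6))
    }
    sum(p < alpha)
  }

  tallies <- vapply(assignments, tally_for, numeric(1))
  observed <- tally_for(which(samples$genotype == "mut"))
  count <- sum(tallies >= observed)
  if (exact) {
    emp_p <- count / total
    ci <- NULL
  } else {
    emp_p <- count / length(tallies)
    ci <- stats::binom.test(count, length(tallies))$conf.int
  }
  structure(list(total = total, observed = observed,
                 count_ge_observed = count, empirical_p = emp_p,
                 alpha = alpha, tallies = tallies, exact = exact,
                 mc_ci = ci),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf(
    "permutation_report: %d/%s %s permutations reach >= %d genes at p < %g (empirical p = %.3g)\n",
    x$count_ge_observed,
    format(x$total, big.mark = ","),
    if (x$exact) "exactly enumerated" else "sampled",
    x$observed, x$alpha, x$empirical_p))
  invisible(x)
}
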