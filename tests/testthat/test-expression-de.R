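# Expression preprocessing (background correction, glog VST, detection
# filter, outlier QC) and litter-aware differential expression.

test_that("background correction subtracts per-array control means", {
  m <- matrix(1:6, 3, 2, dimnames = list(letters[1:3], c("s1", "s2")))
  expect_equal(background_correct(m, c(0, 0)), m)
  expect_equal(background_correct(m, c(s1 = 100, s2 = 0))[, 1], m[, 1] - 100)
  out <- background_correct(m, c(s1 = 50, s2 = 100))
  expect_equal(out[, 1], m[, 1] - 50)
  expect_equal(out[, 2], m[, 2] - 100)
  expect_error(background_correct(m, 1), "one control mean")
  expect_error(background_correct(m, NULL), "required")
})

test_that("glog has the right limits and flattens the mean-variance trend", {
  expect_equal(glog2(2^20, 1), 20, tolerance = 1e-6)   # ~log2 for large x
  expect_equal(glog2(0, 3), log2(3 / 2))               # closed form at 0
  x <- seq(-50, 1000, by = 1.5)
  expect_true(all(diff(glog2(x, 5)) > 0))              # monotone

  cfg <- small_cfg(n_genes = 4000, de_fraction = 0, detected_fraction = 1,
                   seed = 30)
  sim <- gen_expression(cfg)
  corrected <- background_correct(sim$raw, sim$control_means)
  transformed <- vst_glog(corrected)
  slope <- function(m) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, sd)
    unname(coef(lm(sdv ~ mu))[2])
  }
  expect_gt(abs(slope(corrected)) / abs(slope(transformed)), 5)
  expect_error(vst_glog(matrix(1, 5, 3)), "degenerate")
})

test_that("detection filtering keeps any-sample detections and is idempotent", {
  e <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("g", 1:4), NULL))
  d <- rbind(c(0.96, 0.10),    # detected once: kept
             c(0.94, 0.94),    # never detected: removed
             c(0.95, 0.95),    # boundary: kept (>= 0.95)
             c(0.10, 0.99))
  out <- detection_filter(e, d)
  expect_equal(rownames(out$exprs), c("g1", "g3", "g4"))
  expect_equal(out$removed, "g2")
  again <- detection_filter(out$exprs, out$detection)
  expect_equal(again$exprs, out$exprs)
  expect_error(detection_filter(e, d[1:3, ]), "congruent")
})

test_that("outlier QC flags exactly the planted outlier sample", {
  cfg <- small_cfg(n_genes = 2000, seed = 17)
  sim <- gen_expression(cfg)
  qc0 <- qc_outliers(sim$exprs)
  expect_false(any(qc0$flagged))                     # homogeneous cohort
  bad <- sim$exprs
  bad[, 4] <- withr::with_seed(1, rnorm(nrow(bad), 8, 2))
  qc1 <- qc_outliers(bad)
  expect_equal(qc1$sample_id[qc1$flagged], colnames(bad)[4])
  expect_equal(qc_outliers(bad), qc1)                # deterministic
  expect_error(qc_outliers(sim$exprs[, 1:3]), ">= 4")
})

test_that("fit_de reduces to the two-sample t-test without litter structure", {
  withr::with_seed(12, {
    e <- matrix(rnorm(300), 30, 10)
    rownames(e) <- paste0("g", 1:30)
    samp <- data.frame(genotype = rep(c("wt", "mut"), each = 5),
                       litter = "L1")
    de <- fit_de(e, samp, moderated = FALSE)
    tt <- apply(e, 1, function(x)
      t.test(x[6:10], x[1:5], var.equal = TRUE)$statistic)
    expect_equal(de$t, unname(tt), tolerance = 1e-10)
    expect_equal(de$effect, rowMeans(e[, 6:10]) - rowMeans(e[, 1:5]),
                 ignore_attr = TRUE)
  })
})

test_that("fit_de recovers effects, flags direction, and detects confounding", {
  cfg <- small_cfg(n_genes = 2000, de_fraction = 0.05, detected_fraction = 1,
                   seed = 44)
  sim <- gen_expression(cfg)
  de <- fit_de(sim$exprs, sim$samples)
  expect_true(all(de$q >= de$p))
  merged <- merge(de, sim$truth, by = "gene_id")
  expect_gt(cor(merged$effect.x, merged$effect.y), 0.9)
  expect_true(all(merged$direction[merged$effect.y < 0] == "down"))

  # genotype constant within every litter: not estimable
  samp_conf <- data.frame(genotype = rep(c("wt", "mut"), each = 4),
                          litter = rep(c("L1", "L2"), each = 4))
  expect_error(fit_de(matrix(rnorm(80), 10, 8), samp_conf), "confounded")
  expect_error(fit_de(sim$exprs[, 1:2],
                      sim$samples[1:2, ]), ">= 2 samples")
})

test_that("effect-estimate error shrinks with the noise level", {
  rmse <- vapply(c(1.0, 0.5, 0.1), function(sdv) {
    cfg <- small_cfg(n_genes = 1500, de_fraction = 0.1, expr_noise_sd = sdv,
                     detected_fraction = 1, seed = 60)
    sim <- gen_expression(cfg)
    de <- fit_de(sim$exprs, sim$samples)
    m <- merge(de, sim$truth, by = "gene_id")
    sqrt(mean((m$effect.x - m$effect.y)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("moderated statistics agree with the established reference", {
  cfg <- small_cfg(n_genes = 800, de_fraction = 0.05, detected_fraction = 1,
                   seed = 71)
  sim <- gen_expression(cfg)
  de <- fit_de(sim$exprs, sim$samples)
  design <- model.matrix(~ genotype + litter,
                         transform(sim$samples,
                                   genotype = factor(genotype,
                                                     c("wt", "mut")),
                                   litter = factor(litter)))
  fit <- limma::eBayes(limma::lmFit(sim$exprs, design))
  expect_equal(de$t_mod, fit$t[, 2], tolerance = 0.01, ignore_attr = TRUE)
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 0.05)
  expect_gt(cor(de$p_mod, fit$p.value[, 2]), 0.9999)
})

test_that("BH adjustment matches the literal step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(2, {
    for (i in 1:200) {
      p <- runif(sample(1:50, 1))^sample(1:3, 1)
      q <- bh_fdr(p)
      expect_equal(q, naive_bh(p), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-15))
      o <- order(p)
      expect_true(all(diff(q[o]) >= -1e-15))
    }
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("litter-constrained permutations are enumerated correctly", {
  # litters (2WT/2M) and (1WT/1M): C(4,2) * C(2,1) = 12 valid relabellings
  samp <- data.frame(genotype = c("wt", "wt", "mut", "mut", "wt", "mut"),
                     litter = c("L1", "L1", "L1", "L1", "L2", "L2"))
  withr::with_seed(5, e <- matrix(rnorm(50 * 6), 50, 6,
                                  dimnames = list(paste0("g", 1:50), NULL)))
  rep_ <- litter_permutation_test(e, samp, alpha = 0.05)
  expect_equal(rep_$total, 12)
  expect_true(rep_$exact)
  # the identity assignment is one of the permutations
  expect_gte(rep_$count_ge_observed, 1)
  expect_gte(rep_$empirical_p, 1 / rep_$total)
  expect_equal(length(rep_$tallies), 12)

  # the default study design admits exactly 108 permutations
  cfg <- small_cfg(n_genes = 60, seed = 15, detected_fraction = 1)
  sim <- gen_expression(cfg)
  rep2 <- litter_permutation_test(sim$exprs, sim$samples)
  expect_equal(rep2$total, 108)

  # Monte-Carlo branch engages above the exact budget, with a CI
  rep3 <- litter_permutation_test(e, samp, alpha = 0.05, max_exact = 4,
                                  n_sample = 50, sample_seed = 2)
  expect_false(rep3$exact)
  expect_length(rep3$mc_ci, 2)
})

test_that("a single-genotype litter triggers the degeneracy warning", {
  cfg <- small_cfg(litters = list(c(wt = 2, mut = 2), c(wt = 2, mut = 0)),
                   n_genes = 30, seed = 1)
  expect_warning(gen_expression(cfg), "single genotype")
})
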