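# Null-threshold derivation, promoter calling, gene mapping and the
# null-genotype cross-filter.

test_that("the rank rule guarantees the exclusion fraction", {
  thr <- derive_null_threshold(1:100, 0.99)
  expect_equal(thr$value, 100)
  expect_equal(thr$frac_below, 0.99)

  # non-round n: the guarantee still holds
  withr::with_seed(8, {
    x <- rnorm(10007)
    t2 <- derive_null_threshold(x, 0.99)
    expect_gte(t2$frac_below, 0.99)
    t3 <- derive_null_threshold(x, 0.95)
    expect_gte(t3$frac_below, 0.95)
  })

  expect_warning(t0 <- derive_null_threshold(rep(0, 200)), "degenerate")
  expect_equal(t0$value, 0)
  expect_error(derive_null_threshold(1:50), ">= 100")
  expect_error(derive_null_threshold(1:200, 1), "percentile")

  ti <- derive_null_threshold(1:100, 0.99, method = "interpolate")
  expect_equal(ti$value, unname(quantile(1:100, 0.99)))
})

test_that("promoter calling extracts the peak interval around the argmax", {
  des <- design_from_mids(list(c(100, 300, 500, 700, 900)))
  ws <- c(0, 1.2, 1.6, 1.1, 0)
  calls <- call_enriched_promoters(ws, des, 1.5, tier = "strict")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$max_score, 1.6)
  expect_equal(calls$peak_start, 500)   # single probe reaches 1.5
  expect_equal(calls$peak_end, 500)
  expect_equal(calls$tier, "strict")

  # lower threshold: contiguous run around the maximum
  calls2 <- call_enriched_promoters(ws, des, 1.0)
  expect_equal(calls2$peak_start, 300)
  expect_equal(calls2$peak_end, 700)
  expect_equal(calls2$n_enriched, 3L)

  # nothing above threshold: empty call set
  expect_equal(nrow(call_enriched_promoters(ws, des, 2)), 0)

  # strict calls are a subset of long calls whenever thresholds are nested
  withr::with_seed(31, {
    des2 <- design_from_mids(lapply(1:40, function(i)
      cumsum(c(100, sample(100:300, 7, TRUE)))))
    w <- pmax(rnorm(nrow(des2$probes), 0.4, 0.7), 0)
    long <- call_enriched_promoters(w, des2, 0.5)
    strict <- call_enriched_promoters(w, des2, 1.2, tier = "strict")
    expect_true(all(strict$promoter_id %in% long$promoter_id))
  })
})

test_that("region-to-gene expansion handles multi-gene promoters", {
  des <- design_from_mids(list(c(100, 300, 500), c(1100, 1300, 1500)),
                          bidirectional = c(TRUE, FALSE))
  ws <- c(0, 2, 0, 0, 2, 0)
  calls <- call_enriched_promoters(ws, des, 1, min_enriched_probes = 1)
  genes <- map_regions_to_genes(calls, des)
  expect_equal(nrow(genes), 3)                     # 2 regions, 3 gene rows
  expect_equal(length(unique(genes$gene_id)), 3)

  # without bidirectional regions the counts coincide
  des1 <- design_from_mids(list(c(100, 300, 500), c(1100, 1300, 1500)))
  genes1 <- map_regions_to_genes(calls, des1)
  expect_equal(nrow(genes1), nrow(calls))

  # region with no gene link is retained with a warning
  des_no <- des1
  des_no$genes <- des_no$genes[-1, ]
  expect_warning(g2 <- map_regions_to_genes(calls, des_no), "no gene link")
  expect_equal(sum(g2$gene_id == ""), 1)
})

test_that("null cross-filtering removes genes with hot null probes", {
  des <- design_from_mids(list(c(100, 300, 500), c(1100, 1300, 1500)))
  ws <- c(0, 2, 0, 0, 2, 0)
  calls <- call_enriched_promoters(ws, des, 1)
  genes <- map_regions_to_genes(calls, des)

  # all-zero null track: identity
  res0 <- filter_against_null(genes, rep(0, 6), des, 0.9)
  expect_equal(res0$kept, genes)
  expect_equal(nrow(res0$excluded), 0)

  # one hot null probe in the first promoter: that gene excluded with its
  # null evidence
  null_ws <- c(0, 1.4, 0, 0, 0, 0)
  res <- filter_against_null(genes, null_ws, des, 0.9)
  expect_equal(res$excluded$promoter_id, "PR001")
  expect_equal(res$excluded$null_probe, "PR001_02")
  expect_equal(res$excluded$null_score, 1.4)
  expect_equal(res$kept$promoter_id, "PR002")

  # exclusion is strict: a null score exactly at the threshold is kept
  res_eq <- filter_against_null(genes, null_ws, des, 1.4)
  expect_equal(nrow(res_eq$excluded), 0)

  # idempotent
  res2 <- filter_against_null(res$kept, null_ws, des, 0.9)
  expect_equal(res2$kept, res$kept)
  expect_equal(nrow(res2$excluded), 0)
})

test_that("null calibration holds on synthetic null arrays", {
  cfg <- small_cfg(n_promoters = 300, bound_fraction = 0, seed = 77)
  des <- gen_design(cfg)
  arr <- gen_chip_arrays(des, cfg)
  ws <- window_scores(compute_probe_scores(quantile_normalize(arr$null)),
                      des)
  thr <- derive_null_threshold(ws, 0.99)
  expect_lte(mean(ws >= thr$value), 0.01 + thr$n_ties / thr$n_null)
  expect_gte(thr$frac_below, 0.99)
})
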