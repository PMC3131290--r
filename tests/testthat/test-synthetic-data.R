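# Generator invariants: geometry bounds, ground-truth consistency,
# determinism under a fixed seed.

test_that("design geometry respects the configured span and spacing", {
  cfg <- small_cfg(n_promoters = 40, seed = 7)
  des <- gen_design(cfg)
  expect_equal(sort(unique(des$probes$promoter_id)),
               des$promoters$promoter_id)
  expect_true(all(des$probes$end > des$probes$start))
  mids <- probe_midpoints(des)
  for (pid in des$promoters$promoter_id) {
    sel <- des$probes$promoter_id == pid
    m <- sort(mids[sel])
    gaps <- diff(m)
    expect_true(all(gaps >= cfg$probe_spacing[1] &
                      gaps <= cfg$probe_spacing[2]))
    # probes stay inside the strand-oriented span around the TSS
    g <- des$genes[match(pid, des$genes$promoter_id), ]
    offs <- if (g$strand == "+") m - g$tss else g$tss - m
    expect_true(all(offs >= -cfg$promoter_span[["upstream"]] &
                      offs <= cfg$promoter_span[["downstream"]]))
  }
})

test_that("bidirectional fraction controls multi-gene promoter links", {
  des0 <- gen_design(small_cfg(bidirectional_fraction = 0))
  expect_equal(nrow(des0$genes), nrow(des0$promoters))
  des1 <- gen_design(small_cfg(n_promoters = 200,
                               bidirectional_fraction = 0.5, seed = 9))
  links <- table(des1$genes$promoter_id)
  expect_true(any(links == 2))
  # divergent partners run on the opposite strand
  multi <- names(links)[links == 2]
  strands <- des1$genes$strand[des1$genes$promoter_id %in% multi]
  expect_setequal(unique(strands), c("-", "+"))
})

test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- small_cfg(n_promoters = 100, seed = 7)
  d1 <- gen_design(cfg)
  d2 <- gen_design(cfg)
  expect_identical(d1, d2)
  f1 <- tempfile(); f2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
  write_design(d1, f1, g1)
  write_design(d2, f2, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))
  expect_true(startsWith(readLines(f1, 1), "# nullchip seed=7"))
  expect_identical(gen_chip_arrays(d1, cfg), gen_chip_arrays(d2, cfg))
  expect_identical(gen_expression(cfg), gen_expression(cfg))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_promoters = 0), "positive")
  expect_error(sim_config(bound_fraction = 1.2), "proportions")
  expect_error(sim_config(peak_amplitude = -1), ">= 0")
  expect_error(sim_config(prevalence_target = 0.1,
                          prevalence_background = 0.5), "prevalence")
  expect_error(sim_config(motif = "AAAGQAAA"), "IUPAC")
})

test_that("planted peaks follow the kernel and truth lists bound promoters", {
  # noiseless kernel evaluation: exact amplitude at the site, zero at the
  # halfwidth, linear in between
  expect_equal(peak_kernel(0, 2, 750), 2)
  expect_equal(peak_kernel(c(-750, 750), 2, 750), c(0, 0))
  expect_equal(peak_kernel(375, 2, 750), 1)

  cfg <- small_cfg(noise_sd = 0, bound_fraction = 0.2, seed = 5)
  des <- gen_design(cfg)
  arr <- gen_chip_arrays(des, cfg)
  expect_true(all(arr$truth$promoter_id %in% des$promoters$promoter_id))
  # replicates identical without noise; signal confined to bound promoters
  expect_equal(arr$wt[, 1], arr$wt[, 2])
  expect_true(all(arr$null == 0))
  bound <- des$probes$promoter_id %in% arr$truth$promoter_id
  expect_true(all(arr$wt[!bound, 1] == 0))
  expect_true(all(arr$wt[bound, 1] >= 0))
  # maximal observed value never exceeds the planted amplitude
  expect_lte(max(arr$wt), cfg$peak_amplitude)

  arr0 <- gen_chip_arrays(des, small_cfg(bound_fraction = 0, seed = 5))
  expect_equal(nrow(arr0$truth), 0)
})

test_that("null expression study yields uniform two-group t-test p-values", {
  cfg <- small_cfg(n_genes = 5000, de_fraction = 0, litter_sd = 0,
                   detected_fraction = 1, seed = 21)
  sim <- gen_expression(cfg)
  g <- sim$samples$genotype
  p <- apply(sim$exprs, 1, function(x)
    stats::t.test(x[g == "wt"], x[g == "mut"], var.equal = TRUE)$p.value)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("a planted expression effect is recovered without noise", {
  cfg <- small_cfg(n_genes = 50, de_fraction = 0.02, effect_size = 1,
                   expr_noise_sd = 1e-6, litter_sd = 0,
                   detected_fraction = 1, seed = 3)
  sim <- gen_expression(cfg)
  expect_equal(nrow(sim$truth), 1)
  de <- fit_de(sim$exprs, sim$samples)
  est <- de$effect[de$gene_id == sim$truth$gene_id]
  expect_equal(est, sim$truth$effect, tolerance = 1e-4)
})

test_that("sequence generator plants the motif as recorded in truth", {
  cfg <- small_cfg(prevalence_target = 1, prevalence_background = 0,
                   seq_length = 300, seed = 13)
  seqs <- gen_promoter_sequences(cfg, paste0("T", 1:30), paste0("B", 1:30))
  expect_true(all(scan_motif(cfg$motif, seqs$targets) > 0))
  # nothing was planted in the background (chance occurrences of the 8-mer
  # in random sequence remain possible and are rare)
  bg_truth <- seqs$truth[seqs$truth$set == "background", ]
  expect_true(all(!bg_truth$planted))
  expect_lte(sum(scan_motif(cfg$motif, seqs$background) > 0), 5)
  tr <- seqs$truth[seqs$truth$set == "target", ]
  expect_true(all(tr$planted))
  # the recorded position holds the recorded concrete variant
  chars <- as.character(seqs$targets)
  for (i in seq_len(nrow(tr))) {
    expect_equal(substr(chars[[tr$seq_id[i]]], tr$position[i],
                        tr$position[i] + 7), tr$variant[i])
  }
  expect_error(
    gen_promoter_sequences(small_cfg(seq_length = 5), "T1", "B1"),
    "longer")
})
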