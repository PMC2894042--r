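test_that("largest-remainder apportionment matches the exhaustive oracle", {
  comp <- default_composition()
  counts <- apportion_counts(750, comp)
  expect_equal(sum(counts), 750L)
  expect_identical(unname(counts), apportion_oracle(750, comp))
  expect_equal(unname(counts["egp"]), 278L)
  expect_equal(round(100 * counts[["egp"]] / 750), 37)

  ## conservation under random compositions and sizes
  set.seed(42)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    f <- stats::setNames(as.vector(stats::rgamma(k, 1)), letters[1:k])
    f <- f / sum(f)
    n <- sample(10:500, 1)
    got <- apportion_counts(n, f)
    expect_equal(sum(got), n)
    expect_identical(unname(got), apportion_oracle(n, f))
  }

  expect_error(apportion_counts(10, c(a = 0.6, b = 0.6)), "sum to 1")
})

test_that("array template has the configured composition", {
  tpl <- make_array_template()
  expect_equal(nrow(tpl), 750L)
  expect_false(anyDuplicated(tpl$probe_id) > 0)
  expect_equal(unname(table(tpl$category)[["egp"]]), 278L)

  tpl1 <- make_array_template(10, c(x = 1.0))
  expect_equal(nrow(tpl1), 10L)
  expect_true(all(tpl1$category == "x"))
})

test_that("ground truth planting is deterministic and counts probes", {
  tpl <- make_array_template()
  cfg <- default_effect_config()
  cfg$frac <- c(A = 0, B = 0, C = 0, D = 0.10)
  tr1 <- simulate_ground_truth(tpl, cfg, seed = 7)
  tr2 <- simulate_ground_truth(tpl, cfg, seed = 7)
  expect_identical(tr1, tr2)
  expect_equal(sum(tr1$D != 0), round(0.10 * 750))
  expect_true(all(tr1[, c("A", "B", "C")] == 0))
  expect_true(all(abs(2 * tr1$D[tr1$D != 0]) >= 0.12 - 1e-12))
  expect_true(all(abs(2 * tr1$D[tr1$D != 0]) <= 0.63 + 1e-12))

  cfg$frac[] <- 0
  tr0 <- simulate_ground_truth(tpl, cfg, seed = 7)
  expect_true(all(tr0[, effect_names()] == 0))

  cfg$frac <- c(A = 0, B = 0, C = 0, D = 1.5)
  expect_error(simulate_ground_truth(tpl, cfg, seed = 7), "\\[0, 1\\]")
})

test_that("planted effects pass through exactly at zero noise", {
  f <- canonical_factors()
  tpl <- make_array_template(40, c(unknown = 1))
  nz <- zero_noise_config()
  truth <- null_truth(tpl)
  truth$D[5] <- 0.3   # log-FC 0.6 on factor D

  ## single-factor D contrast: attached (plus) vs detached (minus)
  g <- structure(list(
    samples = data.frame(sample_id = c("LFHA_r1", "LFHD_r1"),
                         treatment = c("LFHA", "LFHD"), replicate = 1L),
    edges = data.frame(array_id = "a1", cy5_sample = "LFHA_r1",
                       cy3_sample = "LFHD_r1")), class = "hyb_graph")
  arr <- simulate_arrays(g, tpl, truth, noise = nz, seed = 1)[[1]]
  ma <- compute_ma(background_correct(arr))
  expect_equal(ma$M[5], 0.6, tolerance = 1e-9)
  expect_equal(ma$M[-5], rep(0, 39), tolerance = 1e-9)

  ## self-self edge: all M zero after background subtraction
  gss <- structure(list(
    samples = data.frame(sample_id = c("LFHA_r1", "LFHA_r2"),
                         treatment = "LFHA", replicate = 1:2),
    edges = data.frame(array_id = "a1", cy5_sample = "LFHA_r1",
                       cy3_sample = "LFHA_r2")), class = "hyb_graph")
  arr0 <- simulate_arrays(gss, tpl, truth, noise = nz, seed = 1)[[1]]
  ma0 <- compute_ma(background_correct(arr0))
  expect_equal(ma0$M, rep(0, 40), tolerance = 1e-9)
})

test_that("dye bias shifts pre-normalization M in extreme deciles", {
  tpl <- make_array_template(750)
  nz <- default_noise_config()
  nz$dye_amplitude <- 0.5
  truth <- null_truth(tpl, noise = nz)
  arrs <- simulate_self_self(tpl, n_arrays = 1, noise = nz, seed = 11)
  ma <- compute_ma(background_correct(arrs[[1]]))
  dec <- cut(ma$A, stats::quantile(ma$A, 0:10 / 10), include.lowest = TRUE)
  med <- tapply(ma$M, dec, stats::median)
  expect_gt(max(abs(med)), 0.2)
})

test_that("self-self simulation respects replication and determinism", {
  tpl <- make_array_template(50, c(unknown = 1))
  ss <- simulate_self_self(tpl, n_arrays = 2, seed = 3)
  expect_length(ss, 2L)
  expect_error(simulate_self_self(tpl, n_arrays = 0), "at least 1")

  nz <- zero_noise_config()
  ss0 <- simulate_self_self(tpl, n_arrays = 2, noise = nz, seed = 3)
  ma <- compute_ma(background_correct(ss0[[1]]))
  expect_equal(ma$M, rep(0, 50), tolerance = 1e-9)

  a <- simulate_self_self(tpl, 2, seed = 9)
  b <- simulate_self_self(tpl, 2, seed = 9)
  expect_identical(a, b)
})

test_that("simulate_* leave the caller's RNG stream untouched", {
  tpl <- make_array_template(30, c(unknown = 1))
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_ground_truth(tpl, seed = 1))
  invisible(simulate_self_self(tpl, 2, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("simulated qPCR Ct tables encode planted ratios", {
  panel <- tissue_panel_truth(foot_ratio = 87)
  rec <- simulate_qpcr(panel, noise_sd = 0, sample_offset_sd = 0, seed = 2)
  expect_true(all(rec$Ct > 0))
  expect_true("18S" %in% rec$gene)
  ## closed form: Ct difference between calibrator and foot = log2(87)
  ct <- tapply(rec$Ct[rec$gene != "18S"],
               rec$sample_label[rec$gene != "18S"], mean)
  expect_equal(unname(ct["ctenidium"] - ct["foot"]), log2(87),
               tolerance = 1e-12)

  rec2 <- simulate_qpcr(panel, noise_sd = 0, sample_offset_sd = 0, seed = 2)
  expect_identical(rec, rec2)

  ## absent transcript sits above the detection cutoff
  panel$rel_expr[panel$sample_label == "mantle"] <- 0
  rec3 <- simulate_qpcr(panel, seed = 2)
  expect_true(all(rec3$Ct[rec3$sample_label == "mantle" &
                            rec3$gene != "18S"] > 36))
})
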