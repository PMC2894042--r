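ct_records <- function(...) {
  ## build a Ct table from sample=list(target=, reference=) pairs
  args <- list(...)
  do.call(rbind, lapply(names(args), function(s) {
    data.frame(sample_label = s,
               gene = rep(c("tgt", "18S"), each = length(args[[s]]$t)),
               replicate = c(seq_along(args[[s]]$t),
                             seq_along(args[[s]]$r)),
               Ct = c(args[[s]]$t, args[[s]]$r))
  }))
}

test_that("detection calls compare mean Ct to the cutoff", {
  expect_true(detection_call(c(23, 25)))
  expect_false(detection_call(c(38, 38)))
  expect_true(detection_call(35.9))
  expect_error(detection_call(numeric(0)), "non-empty")
})

test_that("ddCt folds: calibrator 1, doubling per cycle, planted ratios", {
  rec <- ct_records(s1 = list(t = 25, r = 15),
                    s2 = list(t = 25, r = 15),   # same dCt as calibrator
                    s3 = list(t = 24, r = 15))   # one cycle earlier
  res <- delta_delta_ct(rec, "tgt", "18S", calibrator = "s1")
  expect_equal(res$fold[res$sample_label == "s1"], 1)
  expect_equal(res$fold[res$sample_label == "s2"], 1)
  expect_equal(res$fold[res$sample_label == "s3"], 2)
  expect_identical(attr(res, "calibrator"), "s1")

  ## planted foot:ctenidium ratio 87 recovered exactly at zero noise
  panel <- tissue_panel_truth(foot_ratio = 87)
  rec87 <- simulate_qpcr(panel, noise_sd = 0, sample_offset_sd = 0,
                         seed = 4)
  res87 <- delta_delta_ct(rec87, unique(panel$gene), "18S")
  expect_identical(attr(res87, "calibrator"), "ctenidium")
  expect_equal(res87$fold[res87$sample_label == "foot"], 87,
               tolerance = 1e-9)
  expect_equal(res87$fold[res87$sample_label == "ctenidium"], 1)
  expect_true(all(res87$call == "+"))

  expect_error(delta_delta_ct(rec[rec$gene == "tgt", ], "tgt", "18S"),
               "missing")
})

test_that("folds are invariant to per-sample Ct shifts", {
  panel <- tissue_panel_truth()
  rec <- simulate_qpcr(panel, noise_sd = 0.1, seed = 6)
  res <- delta_delta_ct(rec, unique(panel$gene), "18S")
  shifted <- rec
  shift <- c(foot = 3, ctenidium = -2, muscle = 0.5, mantle = 0,
             hemocyte = -1)
  shifted$Ct <- shifted$Ct + shift[shifted$sample_label]
  res2 <- delta_delta_ct(shifted, unique(panel$gene), "18S")
  expect_equal(res2$fold, res$fold, tolerance = 1e-9)
})

test_that("calibrator picking selects the lowest-expressing detected sample", {
  rec <- ct_records(hi = list(t = 22, r = 15),
                    lo = list(t = 30, r = 15),
                    out = list(t = 39, r = 15))
  expect_identical(pick_calibrator(rec, "tgt", "18S"), "lo")

  one <- ct_records(only = list(t = 25, r = 15))
  expect_identical(pick_calibrator(one, "tgt", "18S"), "only")

  none <- ct_records(a = list(t = 38, r = 15), b = list(t = 39, r = 15))
  expect_error(pick_calibrator(none, "tgt", "18S"), "not detected")

  ## undetected samples are reported (-) with no fold
  res <- delta_delta_ct(rec, "tgt", "18S")
  expect_identical(res$call[res$sample_label == "out"], "-")
  expect_true(is.na(res$fold[res$sample_label == "out"]))
})

test_that("time-course ratios use the detached group as calibrator", {
  truth <- timecourse_truth()
  rec <- simulate_qpcr(truth[, c("sample_label", "gene", "rel_expr")],
                       noise_sd = 0, sample_offset_sd = 0, seed = 8)
  rec$timepoint <- sub("^[a-z]+_", "", rec$sample_label)
  rec$group <- sub("_.*$", "", rec$sample_label)
  tc <- timecourse_ratios(rec, unique(truth$gene), "18S")
  expect_equal(nrow(tc), 5L)
  truth_att <- truth$rel_expr[truth$group == "attached"]
  expect_equal(tc$fold, truth_att[match(tc$timepoint, truth$timepoint)],
               tolerance = 1e-9)
  expect_identical(tc$timepoint[which.max(tc$fold)], "2d")
  expect_equal(tc$fold[tc$timepoint == "0"], 1, tolerance = 1e-9)

  ## identical groups give fold 1 everywhere
  same <- rec
  same$Ct[same$group == "attached" & same$gene != "18S"] <-
    same$Ct[same$group == "detached" & same$gene != "18S"]
  tc1 <- timecourse_ratios(same, unique(truth$gene), "18S")
  expect_equal(tc1$fold, rep(1, 5), tolerance = 1e-9)

  ## a timepoint missing one group is dropped with a warning
  drop3 <- rec[!(rec$timepoint == "3d" & rec$group == "attached"), ]
  expect_warning(tc2 <- timecourse_ratios(drop3, unique(truth$gene),
                                          "18S"),
                 "omitted")
  expect_equal(nrow(tc2), 4L)
})
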