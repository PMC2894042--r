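make_fake_array <- function(F635, B635, F532, B532, flag = 0L,
                            id = "fake") {
  n <- length(F635)
  structure(list(array_id = id,
                 spots = data.frame(
                   probe_id = sprintf("P%03d", seq_len(n)),
                   F635 = F635, B635 = B635, F532 = F532, B532 = B532,
                   flag = rep_len(flag, n))),
            class = "two_color_array")
}

test_that("background subtraction floors at half the smallest positive value", {
  arr <- make_fake_array(F635 = c(100, 10, 500), B635 = c(30, 50, 100),
                         F532 = c(200, 80, 50), B532 = c(40, 20, 25))
  bc <- background_correct(arr)
  expect_equal(bc$R[1], 70)
  ## corrected -40 floored at half the smallest positive (70/2 = 35)
  expect_equal(bc$R[2], 35)
  expect_true(all(bc$R > 0) && all(bc$G > 0))

  none <- background_correct(arr, method = "none")
  expect_equal(none$R, arr$spots$F635)
  expect_equal(none$G, arr$spots$F532)
  expect_error(background_correct(arr, method = "loess"))
})

test_that("M/A transform and flag weights", {
  arr <- make_fake_array(F635 = c(150, 450, 150), B635 = 50,
                         F532 = c(150, 150, 150), B532 = 50,
                         flag = c(0L, 0L, -50L))
  ma <- compute_ma(background_correct(arr))
  expect_equal(ma$M[1], 0)
  expect_equal(ma$A[1], log2(100))
  expect_equal(ma$M[2], 2)            # R = 400, G = 100
  expect_equal(ma$weight, c(1, 1, 0))
  expect_error(compute_ma(arr), "background_correct")
})

test_that("loess normalization removes constants and smooth trends", {
  set.seed(4)
  n <- 200
  A <- sort(runif(n, 6, 14))
  ma <- data.frame(probe_id = sprintf("P%03d", 1:n),
                   M = rep(0.37, n), A = A, weight = 1)
  norm <- within_array_normalize(ma)
  expect_equal(norm$M, rep(0, n), tolerance = 1e-12)

  ## an exact quadratic trend is reproduced by local quadratic fits
  trend <- 0.5 * ((A - 10) / 2)^2 - 0.2 * (A - 10)
  ma$M <- trend
  norm <- within_array_normalize(ma)
  interior <- A > quantile(A, 0.05) & A < quantile(A, 0.95)
  expect_lt(max(abs(norm$M[interior])), 1e-6)

  ## and a second pass changes nothing material
  norm2 <- within_array_normalize(norm)
  expect_lt(max(abs(norm2$M - norm$M)), 1e-8)

  ## weight-0 spots are transformed but do not bend the curve
  ma$M <- trend
  ma$weight[100] <- 0
  ma$M[100] <- 25          # wild flagged outlier
  norm3 <- within_array_normalize(ma)
  keep <- interior & ma$weight > 0
  expect_lt(max(abs(norm3$M[keep])), 1e-6)
  expect_equal(norm3$M[100], 25 - trend[100], tolerance = 1e-6)

  expect_error(within_array_normalize(ma[1:10, ]), "too few")
})

test_that("weighted median M is near zero per intensity decile after loess", {
  tpl <- make_array_template(750)
  truth <- null_truth(tpl, noise = default_noise_config())
  arr <- simulate_self_self(tpl, 1, seed = 21)[[1]]
  ma <- within_array_normalize(compute_ma(background_correct(arr)))
  dec <- cut(ma$A, stats::quantile(ma$A, 0:10 / 10), include.lowest = TRUE)
  med <- tapply(ma$M[ma$weight > 0], dec[ma$weight > 0], stats::median)
  expect_true(all(abs(med) < 0.05))
})

test_that("between-array scale normalization equalizes spread", {
  set.seed(8)
  M <- cbind(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  doubled <- M
  doubled[, "b"] <- 2 * M[, "b"]
  norm <- between_array_normalize(doubled)
  medabs <- apply(norm, 2, function(x) median(abs(x)))
  expect_equal(medabs[["a"]], medabs[["b"]], tolerance = 1e-12)

  ## identical distributions are unchanged up to the common rescale
  same <- cbind(a = M[, 1], b = M[, 1])
  expect_equal(between_array_normalize(same), same, tolerance = 1e-12)
  expect_identical(between_array_normalize(M, "none"), M)
})

test_that("preprocessing is deterministic and masks flagged spots", {
  tpl <- make_array_template(60, c(unknown = 1))
  truth <- null_truth(tpl)
  noise <- default_noise_config()
  noise$bad_spot_rate <- 0.1
  tr2 <- enumerate_treatments(canonical_factors()[1:2, ])
  g <- build_loop_design(tr2, 2L, loop_spec = list(tr2))
  ## encode via full codes: extend 2-letter codes to valid 4-letter ones
  g$samples$treatment <- paste0(g$samples$treatment, "HA")
  arrs <- simulate_arrays(g, tpl, truth, noise = noise, seed = 31)
  p1 <- preprocess_arrays(arrs)
  p2 <- preprocess_arrays(arrs)
  expect_identical(p1, p2)
  flagged <- arrs[[1]]$spots$flag < 0
  expect_true(all(is.na(p1$M[flagged, 1])))
  expect_true(all(p1$weights[flagged, 1] == 0))
  expect_equal(dim(p1$M), c(60L, nrow(g$edges)))
})
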