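#' Empirical false-discovery calibration from self-self slides
#'
#' On a self-self hybridization every probe is null by construction,
#' so any probe called differential is a false positive. The slides
#' are preprocessed exactly like experimental slides, then each probe
#' gets a one-sample t statistic of its M values against 0 across the
#' replicate slides (with only two replicate slides this is the only
#' estimable contrast: df = n_arrays - 1). The calibration reports,
#' for each cutoff, the observed false-positive count next to the
#' binomial expectation `alpha * n_genes`.
#'
#' @param self_arrays List of at least two self-self
#'   `two_color_array`.
#' @param alphas P-value cutoffs to tabulate (default 0.05 and 0.01).
#' @param bg_method,span,between_method,surface Passed to
#'   [preprocess_arrays()].
#' @return Data frame `alpha`, `observed`, `expected`, `n_genes`
#'   (class `null_calibration`), with the per-probe p-values in
#'   attribute `p_values`.
#' @export
calibrate_fdr <- function(self_arrays, alphas = c(0.05, 0.01),
                          bg_method = "subtract", span = 0.3,
                          between_method = "scale", surface = "direct") {
  if (length(self_arrays) < 2L)
    stop("insufficient replication: need at least 2 self-self arrays")
  if (any(alphas <= 0 | alphas >= 1))
    stop("alphas must lie strictly between 0 and 1")
  prep <- preprocess_arrays(self_arrays, bg_method = bg_method,
                            span = span, between_method = between_method,
                            surface = surface)
  p <- self_self_pvalues(prep$M)
  ok <- !is.na(p)
  out <- data.frame(
    alpha = alphas,
    observed = vapply(alphas, function(a) sum(p[ok] < a), integer(1)),
    expected = alphas * sum(ok),
    n_genes = sum(ok))
  attr(out, "p_values") <- p
  class(out) <- c("null_calibration", "data.frame")
  out
}

## per-probe one-sample t test of M against 0 across arrays
self_self_pvalues <- function(M) {
  n <- rowSums(!is.na(M))
  mean_m <- rowMeans(M, na.rm = TRUE)
  sd_m <- apply(M, 1L, stats::sd, na.rm = TRUE)
  t_stat <- mean_m / (sd_m / sqrt(n))
  p <- 2 * stats::pt(abs(t_stat), df = n - 1L, lower.tail = FALSE)
  p[n < 2L | !is.finite(t_stat)] <- NA_real_
  p
}

#' Replicate the self-self calibration across simulated experiments
#'
#' Simulates `n_experiments` independent self-self assays (each with
#' `n_arrays` slides on the given template), runs [calibrate_fdr()] on
#' each and reports the per-experiment and mean false-positive counts
#' at each cutoff — a Monte-Carlo check that raw-p selection behaves
#' binomially on null data.
#'
#' @param template An `array_template`.
#' @param n_experiments Number of independent assays.
#' @param n_arrays Slides per assay (default 2).
#' @param alphas Cutoffs to tabulate.
#' @param noise See [default_noise_config()].
#' @param seed Integer seed; experiment `i` uses `seed + i`.
#' @return List with `counts` (experiments x alphas matrix),
#'   `mean_observed`, `expected`.
#' @export
replicate_null_calibration <- function(template, n_experiments = 100L,
                                       n_arrays = 2L,
                                       alphas = c(0.05, 0.01),
                                       noise = default_noise_config(),
                                       seed = 1L) {
  counts <- matrix(NA_integer_, n_experiments, length(alphas),
                   dimnames = list(NULL, paste0("alpha_", alphas)))
  for (i in seq_len(n_experiments)) {
    arrs <- simulate_self_self(template, n_arrays = n_arrays,
                               noise = noise, seed = seed + i)
    cal <- calibrate_fdr(arrs, alphas = alphas)
    counts[i, ] <- cal$observed
  }
  list(counts = counts,
       mean_observed = colMeans(counts),
       expected = alphas * nrow(template))
}
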