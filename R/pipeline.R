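#' Run the full factorial microarray pipeline on simulated data
#'
#' Convenience wrapper covering the whole analysis path:
#' enumerate the 2x2x2x2 treatments, lay out the loop design, plant
#' ground-truth effects, simulate the slides, preprocess them into a
#' normalized M-value matrix, fit the per-gene factorial model, select
#' significant genes per factor at each cutoff, account for factor
#' overlaps and cluster the effect profiles.
#'
#' @param n_probes Probes on the slide (default 750).
#' @param n_replicates Biological replicates per treatment (default 4;
#'   64 slides with the default loop layout).
#' @param effect_config See [default_effect_config()].
#' @param noise See [default_noise_config()].
#' @param alphas Selection cutoffs (default 0.05 and 0.01).
#' @param k_clusters Clusters to cut the profile tree into (default
#'   10); reduced to the number of significant genes when fewer.
#' @param seed Integer seed for all stochastic stages.
#' @param surface Loess evaluation surface (see
#'   [within_array_normalize()]); `"interpolate"` is recommended for
#'   slides with many thousands of spots.
#' @return List with the intermediate objects: `factors`,
#'   `treatments`, `graph`, `design`, `template`, `truth`, `arrays`,
#'   `prep`, `fit`, `significant` (per alpha, per factor), `overlap`
#'   (per alpha), `clusters` (at the first alpha), `summary`.
#' @export
run_pipeline <- function(n_probes = 750L, n_replicates = 4L,
                         effect_config = default_effect_config(),
                         noise = default_noise_config(),
                         alphas = c(0.05, 0.01), k_clusters = 10L,
                         seed = 1L, surface = "direct") {
  factors <- canonical_factors()
  treatments <- enumerate_treatments(factors)
  graph <- build_loop_design(treatments, n_replicates = n_replicates)
  design <- build_design_matrix(graph, factors)
  template <- make_array_template(n_probes)
  truth <- simulate_ground_truth(template, effect_config, seed = seed,
                                 noise = noise)
  arrays <- simulate_arrays(graph, template, truth, noise = noise,
                            seed = seed + 1L, factors = factors)
  prep <- preprocess_arrays(arrays, surface = surface)
  fit <- fit_factorial(prep, design)

  fl <- factors$name
  significant <- lapply(stats::setNames(alphas, paste0("alpha_", alphas)),
                        function(a)
                          lapply(stats::setNames(fl, fl), function(f)
                            select_significant(fit, alpha = a, factor = f)))
  overlap <- lapply(significant, factor_overlap)

  clusters <- NULL
  prof <- build_profile_matrix(fit, significant[[1L]])
  if (nrow(prof) >= 2L)
    clusters <- cluster_profiles(prof, k = min(k_clusters, nrow(prof)))

  summary <- utils::capture.output(
    summarize_results(fit, n_genes = n_probes, alphas = alphas,
                      factors = fl))
  list(factors = factors, treatments = treatments, graph = graph,
       design = design, template = template, truth = truth,
       arrays = arrays, prep = prep, fit = fit,
       significant = significant, overlap = overlap,
       clusters = clusters, summary = summary)
}
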