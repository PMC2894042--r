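## Ground-truthed simulator for two-color loop-design experiments.
## All simulate_* functions are pure functions of (config, seed): they
## save and restore the caller's RNG state.

with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("a single integer seed is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Default probe-category composition of the byssus cDNA array
#'
#' Fractions of the 750-probe byssus library falling in each annotation
#' class: 3% foot-protein (Dpfp-like) genes, 37% exocrine gland peptide
#' (EGP) genes, 1% host-defense genes, 6% housekeeping genes and 53%
#' genes without known homologue.
#'
#' @return Named numeric vector of fractions summing to 1.
#' @export
default_composition <- function() {
  c(foot_protein = 0.03, egp = 0.37, host_defense = 0.01,
    housekeeping = 0.06, unknown = 0.53)
}

#' Largest-remainder apportionment of probe counts
#'
#' Splits `n` into integer counts proportional to `fractions` using the
#' largest-remainder rule; remainder ties are broken by the declared
#' order of the categories. Counts always sum exactly to `n`.
#'
#' @param n Total count to apportion.
#' @param fractions Named non-negative fractions summing to 1.
#' @return Named integer vector summing to `n`.
#' @examples
#' apportion_counts(750, default_composition())
#' @export
apportion_counts <- function(n, fractions) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("composition fractions must be non-negative and sum to 1")
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    rem <- quota - base
    ## order(-rem) is stable, so declared category order breaks ties
    top <- order(-rem)[seq_len(left)]
    base[top] <- base[top] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Build an array template
#'
#' Generates the probe list of a synthetic spotted array: `n_probes`
#' probes apportioned over annotation categories by the
#' largest-remainder rule, with deterministic category-prefixed probe
#' identifiers and one spot per probe.
#'
#' @param n_probes Number of probes on the slide (default 750).
#' @param composition Named category fractions (default
#'   [default_composition()]).
#' @return Data frame `probe_id`, `category` with class
#'   `array_template`.
#' @export
make_array_template <- function(n_probes = 750L,
                                composition = default_composition()) {
  if (!is.numeric(n_probes) || n_probes < 1)
    stop("n_probes must be a positive integer")
  counts <- apportion_counts(as.integer(n_probes), composition)
  prefix <- c(foot_protein = "DPFP", egp = "EGP", host_defense = "HD",
              housekeeping = "HK", unknown = "NH")
  tpl <- do.call(rbind, lapply(names(counts), function(cat) {
    if (counts[[cat]] == 0L) return(NULL)
    pf <- if (cat %in% names(prefix)) prefix[[cat]] else toupper(cat)
    data.frame(probe_id = sprintf("%s_%04d", pf, seq_len(counts[[cat]])),
               category = cat, stringsAsFactors = FALSE)
  }))
  rownames(tpl) <- NULL
  class(tpl) <- c("array_template", "data.frame")
  tpl
}

#' Default planted-effect configuration
#'
#' Fractions of probes with a nonzero main effect per factor (10% for
#' attachment D, 4% for temperature A and dissolved oxygen C, 1% for
#' agitation B) and the range the planted absolute log2 fold changes
#' are drawn from (0.12-0.63, the scale of the reported hits).
#' Interaction effects default to none.
#'
#' @return List with elements `frac`, `logfc_range`,
#'   `interaction_frac`.
#' @export
default_effect_config <- function() {
  list(frac = c(A = 0.04, B = 0.01, C = 0.04, D = 0.10),
       logfc_range = c(0.12, 0.63),
       interaction_frac = 0)
}

#' Default noise configuration of the array simulator
#'
#' Log-normal spot intensities around a per-probe baseline (mean 10,
#' SD 1.2 on the log2 scale), gene-wise biological replicate SD drawn
#' around `sigma_gene` from a scaled inverse-chi-square-like
#' distribution with `sigma_df` degrees of freedom (`Inf` = constant),
#' multiplicative spot noise (`sigma_spot`, log2 SD per channel),
#' additive measured background (normal, truncated at zero),
#' a smooth intensity-dependent dye bias of amplitude `dye_amplitude`
#' (log2 units added to M at extreme intensities), and a bad-spot
#' flagging rate.
#'
#' @return Named list of simulator parameters.
#' @export
default_noise_config <- function() {
  list(baseline_mean = 10, baseline_sd = 1.2,
       sigma_gene = 0.1, sigma_df = Inf,
       sigma_spot = 0.05,
       bg_mean = 80, bg_sd = 15,
       dye_amplitude = 0.3,
       bad_spot_rate = 0.01)
}

## smooth quadratic dye bias in log2 M as a function of average
## log2-intensity a; z standardized against the baseline distribution
dye_bias_curve <- function(a, noise) {
  z <- (a - noise$baseline_mean) / noise$baseline_sd
  noise$dye_amplitude * (z^2 - 1) / 2
}

#' Plant per-gene ground-truth effects
#'
#' Draws, per factor, a configured fraction of probes (without
#' replacement) and assigns them a main-effect coefficient of
#' `+-logFC/2` with random sign, where |logFC| is uniform over
#' `logfc_range`; interaction coefficients are planted the same way at
#' `interaction_frac` (default none). Baseline log2 expression and the
#' gene-wise biological SD are drawn from the noise configuration.
#'
#' @param template An `array_template`.
#' @param effect_config See [default_effect_config()].
#' @param seed Integer seed; the function is deterministic given it.
#' @param noise Noise configuration, for baselines and gene SDs.
#' @return Data frame with `probe_id`, `baseline`, `sd` and one column
#'   per factorial effect (class `ground_truth`).
#' @export
simulate_ground_truth <- function(template,
                                  effect_config = default_effect_config(),
                                  seed = 1L,
                                  noise = default_noise_config()) {
  frac <- effect_config$frac
  if (any(frac < 0) || any(frac > 1))
    stop("affected fractions must lie in [0, 1]")
  eff <- effect_names()
  n <- nrow(template)
  with_local_seed(seed, {
    baseline <- stats::rnorm(n, noise$baseline_mean, noise$baseline_sd)
    sd_g <- if (is.finite(noise$sigma_df)) {
      noise$sigma_gene * sqrt(noise$sigma_df /
                                stats::rchisq(n, df = noise$sigma_df))
    } else rep(noise$sigma_gene, n)
    coefs <- matrix(0, n, length(eff), dimnames = list(NULL, eff))
    plant <- function(effect, fraction) {
      n_hit <- round(fraction * n)
      if (n_hit == 0) return()
      hit <- sample.int(n, n_hit)
      lfc <- stats::runif(n_hit, effect_config$logfc_range[1],
                          effect_config$logfc_range[2])
      sgn <- sample(c(-1, 1), n_hit, replace = TRUE)
      coefs[hit, effect] <<- sgn * lfc / 2
    }
    for (f in names(frac)) plant(f, frac[[f]])
    if (effect_config$interaction_frac > 0) {
      for (e in setdiff(eff, names(frac)))
        plant(e, effect_config$interaction_frac)
    }
    out <- data.frame(probe_id = template$probe_id, baseline = baseline,
                      sd = sd_g, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(coefs))
    class(out) <- c("ground_truth", "data.frame")
    out
  })
}

## expected log2 expression of every probe in one sample
sample_expression <- function(truth, treatment, factors) {
  ev <- encode_treatment(treatment, factors)
  as.matrix(truth[, names(ev), drop = FALSE]) %*% ev + truth$baseline
}

## render one channel of one slide: foreground = signal + background,
## background column reports the additive component (local estimate)
render_channel <- function(log2_signal, noise) {
  n <- length(log2_signal)
  spot <- if (noise$sigma_spot > 0) stats::rnorm(n, 0, noise$sigma_spot) else 0
  bg <- pmax(stats::rnorm(n, noise$bg_mean, noise$bg_sd), 0)
  list(F = 2^(log2_signal + spot) + bg, B = bg)
}

new_two_color_array <- function(array_id, probe_id, red, grn, flag) {
  structure(list(
    array_id = array_id,
    spots = data.frame(probe_id = probe_id,
                       F635 = red$F, B635 = red$B,
                       F532 = grn$F, B532 = grn$B,
                       flag = flag, stringsAsFactors = FALSE)),
    class = "two_color_array")
}

#' @export
print.two_color_array <- function(x, ...) {
  cat(sprintf("Two-color array %s: %d spots, %d flagged bad\n",
              x$array_id, nrow(x$spots), sum(x$spots$flag < 0)))
  invisible(x)
}

#' Simulate the slides of a loop-design experiment
#'
#' For every sample the expected log2 expression of each probe is its
#' baseline plus the design-implied sum of planted effects; each slide
#' then renders its red (Cy5) and green (Cy3) sample with gene-wise
#' replicate noise (SD `truth$sd`, drawn independently per
#' hybridization channel — it models the labeling/hybridization
#' realization of the replicate and keeps the fitted model's errors
#' independent across slides), an intensity-dependent dye bias applied
#' symmetrically (+bias/2 to red, -bias/2 to green, so M is shifted by
#' the bias), per-channel multiplicative spot noise, additive measured
#' background, and randomly flagged bad spots.
#'
#' @param graph A `hyb_graph`.
#' @param template An `array_template`.
#' @param truth A `ground_truth` for the template.
#' @param noise See [default_noise_config()].
#' @param seed Integer seed.
#' @param factors Factor table the treatment codes refer to.
#' @return List of `two_color_array`, one per edge of the graph, in
#'   array order.
#' @export
simulate_arrays <- function(graph, template, truth,
                            noise = default_noise_config(), seed = 1L,
                            factors = canonical_factors()) {
  stopifnot(identical(template$probe_id, truth$probe_id))
  n <- nrow(template)
  bias <- dye_bias_curve(truth$baseline, noise)
  with_local_seed(seed, {
    mu <- matrix(NA_real_, n, nrow(graph$samples),
                 dimnames = list(NULL, graph$samples$sample_id))
    for (i in seq_len(nrow(graph$samples)))
      mu[, i] <- sample_expression(truth, graph$samples$treatment[i],
                                   factors)
    gene_noise <- function() {
      if (any(truth$sd > 0)) stats::rnorm(n, 0, truth$sd) else 0
    }
    lapply(seq_len(nrow(graph$edges)), function(e) {
      red <- render_channel(mu[, graph$edges$cy5_sample[e]] +
                              gene_noise() + bias / 2, noise)
      grn <- render_channel(mu[, graph$edges$cy3_sample[e]] +
                              gene_noise() - bias / 2, noise)
      flag <- ifelse(stats::runif(n) < noise$bad_spot_rate, -100L, 0L)
      new_two_color_array(graph$edges$array_id[e], template$probe_id,
                          red, grn, flag)
    })
  })
}

#' Simulate self-self hybridizations
#'
#' Both channels of each slide carry cDNA from the same RNA template,
#' so every probe is null by construction: each channel only differs by
#' its own labeling/measurement noise and the dye bias. These slides
#' drive the empirical false-discovery calibration.
#'
#' @param template An `array_template`.
#' @param n_arrays Number of replicate self-self slides (the original
#'   assay used two).
#' @param noise See [default_noise_config()].
#' @param seed Integer seed.
#' @return List of `two_color_array` of length `n_arrays`.
#' @export
simulate_self_self <- function(template, n_arrays = 2L,
                               noise = default_noise_config(), seed = 1L) {
  if (!is.numeric(n_arrays) || n_arrays < 1)
    stop("n_arrays must be at least 1")
  n <- nrow(template)
  with_local_seed(seed, {
    baseline <- stats::rnorm(n, noise$baseline_mean, noise$baseline_sd)
    bias <- dye_bias_curve(baseline, noise)
    gene_noise <- function() {
      if (noise$sigma_gene > 0) stats::rnorm(n, 0, noise$sigma_gene) else 0
    }
    lapply(seq_len(n_arrays), function(a) {
      red <- render_channel(baseline + gene_noise() + bias / 2, noise)
      grn <- render_channel(baseline + gene_noise() - bias / 2, noise)
      flag <- ifelse(stats::runif(n) < noise$bad_spot_rate, -100L, 0L)
      new_two_color_array(sprintf("selfself_%02d", a), template$probe_id,
                          red, grn, flag)
    })
  })
}

#' Simulate a qPCR Ct table
#'
#' Under perfect doubling per cycle, the threshold cycle of a gene is
#' `Ct0 - log2(relative template amount)` plus measurement noise; a
#' per-sample offset (pipetting/loading) shifts target and reference
#' genes alike and cancels in the ddCt analysis. Samples with zero
#' template are reported above the detection cutoff.
#'
#' @param panel Data frame `sample_label`, `gene`, `rel_expr` giving
#'   the relative template amount of each gene in each sample (0 =
#'   absent). Rows for the reference gene are added with `rel_expr = 1`
#'   when missing.
#' @param reference Reference gene name (default `"18S"`).
#' @param n_replicates Technical replicates per sample/gene.
#' @param ct0 Threshold cycle of one relative unit of target template.
#' @param ct_ref Threshold cycle of the reference gene.
#' @param noise_sd SD (cycles) of replicate measurement noise.
#' @param sample_offset_sd SD (cycles) of the per-sample loading offset.
#' @param cutoff Detection cutoff in cycles (default 36); absent genes
#'   get `cutoff + 2`.
#' @param seed Integer seed.
#' @return Data frame `sample_label`, `gene`, `replicate`, `Ct`.
#' @export
simulate_qpcr <- function(panel, reference = "18S", n_replicates = 3L,
                          ct0 = 24, ct_ref = 14, noise_sd = 0.15,
                          sample_offset_sd = 0.5, cutoff = 36, seed = 1L) {
  stopifnot(all(c("sample_label", "gene", "rel_expr") %in% names(panel)))
  labs <- unique(panel$sample_label)
  missing_ref <- labs[!labs %in%
                        panel$sample_label[panel$gene == reference]]
  if (length(missing_ref))
    panel <- rbind(panel, data.frame(sample_label = missing_ref,
                                     gene = reference, rel_expr = 1))
  with_local_seed(seed, {
    offset <- stats::setNames(
      stats::rnorm(length(labs), 0, sample_offset_sd), labs)
    rows <- lapply(seq_len(nrow(panel)), function(i) {
      base <- if (panel$gene[i] == reference) ct_ref else ct0
      ct <- if (panel$rel_expr[i] > 0) {
        base - log2(panel$rel_expr[i]) + offset[[panel$sample_label[i]]] +
          stats::rnorm(n_replicates, 0, noise_sd)
      } else rep(cutoff + 2, n_replicates)
      data.frame(sample_label = panel$sample_label[i],
                 gene = panel$gene[i],
                 replicate = seq_len(n_replicates),
                 Ct = ct, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Ground-truth tissue panel for the validation targets
#'
#' Relative template amounts across the five assayed tissues for a
#' foot-enriched transcript, stated relative to the lowest-expressing
#' detected tissue (ctenidium = 1). The default mirrors the reported
#' foot:ctenidium ratio of 87 for the unannotated foot transcript, with
#' intermediate levels elsewhere.
#'
#' @param gene Target gene name.
#' @param foot_ratio Fold excess of foot over the calibrator tissue.
#' @return Panel data frame for [simulate_qpcr()].
#' @export
tissue_panel_truth <- function(gene = "NH_BG17_C09", foot_ratio = 87) {
  data.frame(
    sample_label = c("foot", "ctenidium", "muscle", "mantle", "hemocyte"),
    gene = gene,
    rel_expr = c(foot_ratio, 1, 6, 3, 10),
    stringsAsFactors = FALSE)
}

#' Ground-truth attachment time course
#'
#' Relative expression of a byssogenesis-induced transcript in attached
#' versus detached mussels at 0, 12 h, 1 d, 2 d and 3 d
#' post-treatment, peaking at day 2 (the Dpfp-like profile).
#'
#' @param gene Target gene name.
#' @return Panel data frame with `timepoint` and `group` columns; feed
#'   to [simulate_qpcr()] after pasting group/timepoint into
#'   `sample_label`.
#' @export
timecourse_truth <- function(gene = "DPFP_BG20_A01") {
  tp <- c("0", "12h", "1d", "2d", "3d")
  fold_attached <- c(1, 1.6, 2.4, 4.1, 1.9)  # vs detached = 1
  out <- rbind(
    data.frame(timepoint = tp, group = "attached",
               rel_expr = fold_attached),
    data.frame(timepoint = tp, group = "detached", rel_expr = 1))
  out$gene <- gene
  out$sample_label <- paste(out$group, out$timepoint, sep = "_")
  out[, c("sample_label", "timepoint", "group", "gene", "rel_expr")]
}
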