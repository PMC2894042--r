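## Independent oracles and small fixtures shared across tests.

## noise configuration with every stochastic component switched off
zero_noise_config <- function() {
  list(baseline_mean = 10, baseline_sd = 1.2,
       sigma_gene = 0, sigma_df = Inf,
       sigma_spot = 0,
       bg_mean = 50, bg_sd = 0,
       dye_amplitude = 0,
       bad_spot_rate = 0)
}

## all-null ground truth for a template
null_truth <- function(template, seed = 1,
                       noise = zero_noise_config()) {
  cfg <- default_effect_config()
  cfg$frac[] <- 0
  simulate_ground_truth(template, cfg, seed = seed, noise = noise)
}

## explicit normal-equations least squares: beta = (X'X)^-1 X'y
ols_oracle <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

## exhaustive largest-remainder oracle: among all floor/ceil roundings
## of the quotas that sum to n, pick the one minimizing total absolute
## deviation, preferring to round earlier-declared categories up
apportion_oracle <- function(n, fractions) {
  q <- n * fractions
  k <- length(q)
  best <- NULL
  best_score <- Inf
  for (mask in 0:(2^k - 1)) {
    up <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    cand <- ifelse(up, ceiling(q), floor(q))
    if (sum(cand) != n) next
    score <- sum(abs(cand - q))
    ## tie-break: lexicographically earliest categories rounded up
    pref <- sum(up * 2^(k - seq_len(k)))
    if (is.null(best) || score < best_score - 1e-12 ||
        (abs(score - best_score) <= 1e-12 && pref > best_pref)) {
      best <- cand
      best_pref <- pref
      best_score <- score
    }
  }
  as.integer(best)
}

## brute-force O(n^3) average-linkage agglomeration on a raw matrix;
## returns merge heights (in merge order) and the partition at each k
average_linkage_oracle <- function(mat) {
  D <- as.matrix(stats::dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      d_ij <- mean(D[clusters[[i]], clusters[[j]]])
      if (d_ij < best_d) { best_d <- d_ij; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    partitions[[length(partitions) + 1L]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

## canonical set representation of a partition for comparison
partition_key <- function(groups) {
  unname(sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                     character(1))))
}

## brute-force factor-overlap accounting by explicit subset enumeration
overlap_oracle <- function(sets) {
  f <- names(sets)
  genes <- unique(unlist(sets))
  subsets <- unlist(lapply(seq_along(f), function(k)
    apply(utils::combn(f, k), 2, paste, collapse = "")), use.names = FALSE)
  counts <- vapply(subsets, function(s) {
    members <- strsplit(s, "")[[1]]
    inside <- Reduce(intersect, sets[members], accumulate = FALSE)
    outside <- unlist(sets[setdiff(f, members)])
    length(setdiff(inside, outside))
  }, integer(1))
  counts[counts > 0]
}

## small two-factor design for cheap fitting tests
small_graph <- function(n_replicates = 2L) {
  f <- canonical_factors()[1:2, ]
  tr <- enumerate_treatments(f)
  build_loop_design(tr, n_replicates = n_replicates,
                    loop_spec = list(tr))
}
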