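#' Canonical two-level factors of the byssogenesis experiment
#'
#' The four factors driving byssal-thread production in *Dreissena
#' polymorpha*: water temperature (A), water agitation (B), dissolved
#' oxygen (C) and attachment status (D). Each factor has exactly two
#' levels, encoded by a single letter in a treatment code. The level
#' coded +1 ("plus") is chosen so that a positive fitted coefficient
#' means up-regulation at low temperature (L), under flow (F), at low
#' dissolved oxygen (H), and in the attached state (A), matching the
#' sign convention used when reporting log fold changes.
#'
#' @return A data frame with one row per factor and columns `name`,
#'   `plus`, `minus`, `description`.
#' @examples
#' canonical_factors()
#' @export
canonical_factors <- function() {
  data.frame(
    name = c("A", "B", "C", "D"),
    plus = c("L", "F", "H", "A"),
    minus = c("R", "S", "N", "D"),
    description = c(
      "temperature: L = low 4C (+1), R = room 22C (-1)",
      "water agitation: F = flow/stirred (+1), S = static (-1)",
      "dissolved oxygen: H = low 5 mg/L (+1), N = normal 10 mg/L (-1)",
      "attachment: A = attached/byssogenic (+1), D = detached (-1)"
    ),
    stringsAsFactors = FALSE
  )
}

validate_factors <- function(factors) {
  req <- c("name", "plus", "minus")
  if (!is.data.frame(factors) || !all(req %in% names(factors)))
    stop("`factors` must be a data frame with columns name, plus, minus")
  if (any(nchar(factors$plus) != 1L) || any(nchar(factors$minus) != 1L))
    stop("invalid design: factor levels must be single characters")
  if (any(factors$plus == factors$minus))
    stop("invalid design: each factor needs two distinct levels")
  if (anyDuplicated(factors$name))
    stop("invalid design: duplicated factor names")
  invisible(factors)
}

#' Names of the 15 factorial effects
#'
#' Main effects, then two-, three- and four-way interactions of factors
#' named in `factors`, in lexicographic order within each interaction
#' order (A, B, C, D, AB, AC, AD, BC, BD, CD, ABC, ABD, ACD, BCD, ABCD
#' for the canonical design).
#'
#' @param factors Factor table as returned by [canonical_factors()].
#' @return Character vector of effect names (length `2^k - 1`).
#' @export
effect_names <- function(factors = canonical_factors()) {
  nm <- factors$name
  unlist(lapply(seq_along(nm), function(ord) {
    cmb <- utils::combn(nm, ord)
    apply(cmb, 2L, paste, collapse = "")
  }), use.names = FALSE)
}

#' Enumerate all treatment combinations of a full factorial design
#'
#' Forms the Cartesian product of the two levels of every factor and
#' returns the treatment codes (one letter per factor) in deterministic
#' lexicographic (C locale) order. The canonical four-factor design
#' yields the sixteen combinations of the 2x2x2x2 experiment.
#'
#' @inheritParams effect_names
#' @return Character vector of `2^k` treatment codes.
#' @examples
#' enumerate_treatments()          # 16 codes, "LFHA" ... "RSND"
#' @export
enumerate_treatments <- function(factors = canonical_factors()) {
  validate_factors(factors)
  levs <- lapply(seq_len(nrow(factors)), function(i)
    c(factors$plus[i], factors$minus[i]))
  grid <- do.call(expand.grid, c(rev(levs), stringsAsFactors = FALSE))
  codes <- do.call(paste0, rev(grid))
  sort(codes, method = "radix")
}

#' Sum-to-zero effect encoding of a treatment combination
#'
#' Encodes a treatment code as the +-1 effect vector of the full
#' factorial model under the sum-to-zero parameterization: each main
#' effect is +1 at the factor's plus level and -1 otherwise, and every
#' interaction entry is the product of its constituent main-effect
#' entries. Over the full set of treatments every effect column sums to
#' zero, which is what makes twice a fitted coefficient the log2 fold
#' change between the two levels.
#'
#' @param code Treatment code, one character per factor (e.g. `"LFHA"`).
#' @inheritParams effect_names
#' @return Named numeric vector over [effect_names()], entries in
#'   `{-1, +1}`.
#' @examples
#' encode_treatment("LFHA")  # all +1
#' encode_treatment("RSNA")["ABCD"]  # -1
#' @export
encode_treatment <- function(code, factors = canonical_factors()) {
  validate_factors(factors)
  k <- nrow(factors)
  if (!is.character(code) || length(code) != 1L || nchar(code) != k)
    stop("treatment code must be a single string with one character per factor")
  chars <- strsplit(code, "")[[1]]
  main <- vapply(seq_len(k), function(i) {
    if (chars[i] == factors$plus[i]) return(1)
    if (chars[i] == factors$minus[i]) return(-1)
    stop(sprintf("encoding error: '%s' is not a level of factor %s",
                 chars[i], factors$name[i]))
  }, numeric(1))
  names(main) <- factors$name
  eff <- effect_names(factors)
  out <- vapply(eff, function(e) {
    prod(main[strsplit(e, "")[[1]]])
  }, numeric(1))
  names(out) <- eff
  out
}

## Default loop layout: treatments in lexicographic order are rotated by
## (replicate - 1) and split into three head-to-tail cycles of sizes
## 6/5/5.  Rotation moves the cycle boundaries between replicates so the
## union of the per-replicate loops is connected over treatments.
default_loop_spec <- function(treatments, n_replicates,
                              sizes = c(6L, 5L, 5L)) {
  n <- length(treatments)
  if (sum(sizes) != n) sizes <- c(n)  # non-canonical designs: one loop
  lapply(seq_len(n_replicates), function(r) {
    rot <- treatments[((seq_len(n) - 1L + (r - 1L)) %% n) + 1L]
    split(rot, rep(seq_along(sizes), sizes))
  })
}

#' Build the loop hybridization graph
#'
#' Lays out a two-color loop design: biological replicates of each
#' treatment are joined head-to-tail in cycles, each arrow (edge) being
#' one hybridization with the arrow start labeled in the red channel
#' (Cy5/635 nm) and the end in the green channel (Cy3/532 nm). Around a
#' cycle every sample is therefore used exactly twice, once per dye.
#' The default layout mirrors a three-loop design over the sixteen
#' treatments with four biological replicates (64 samples, 64 slides);
#' the loop boundaries rotate between replicates so that the union of
#' loops is connected over treatments, which is required for all 15
#' factorial effects to be estimable.
#'
#' @param treatments Character vector of treatment codes, normally
#'   [enumerate_treatments()].
#' @param n_replicates Number of biological replicates per treatment
#'   (default 4).
#' @param loop_spec Either `NULL` (default layout), a list of cycles
#'   (character vectors of treatment codes) applied to every replicate,
#'   or a list with one such list per replicate.
#' @return An object of class `hyb_graph`: a list with `samples`
#'   (sample_id, treatment, replicate) and `edges` (array_id,
#'   cy5_sample, cy3_sample), both in deterministic order.
#' @examples
#' g <- build_loop_design(enumerate_treatments(), n_replicates = 4)
#' nrow(g$edges)   # 64 arrays
#' @export
build_loop_design <- function(treatments, n_replicates = 4L,
                              loop_spec = NULL) {
  if (length(treatments) < 1L || anyDuplicated(treatments))
    stop("invalid design: treatments must be a non-empty set of unique codes")
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L ||
      n_replicates < 1L)
    stop("n_replicates must be a positive integer")
  n_replicates <- as.integer(n_replicates)
  treatments <- sort(treatments, method = "radix")

  if (is.null(loop_spec)) {
    spec <- default_loop_spec(treatments, n_replicates)
  } else if (all(vapply(loop_spec, is.character, logical(1)))) {
    spec <- rep(list(loop_spec), n_replicates)  # same cycles every replicate
  } else {
    if (length(loop_spec) != n_replicates)
      stop("per-replicate loop_spec must have one entry per replicate")
    spec <- loop_spec
  }
  for (rep_spec in spec) {
    tr <- unlist(rep_spec, use.names = FALSE)
    if (!all(tr %in% treatments))
      stop(sprintf("loop_spec references unknown treatment(s): %s",
                   paste(setdiff(tr, treatments), collapse = ", ")))
  }
  covered <- unique(unlist(spec, use.names = FALSE))
  if (!setequal(covered, treatments))
    stop(sprintf("loop_spec does not cover treatment(s): %s",
                 paste(setdiff(treatments, covered), collapse = ", ")))

  samples <- expand.grid(replicate = seq_len(n_replicates),
                         treatment = treatments,
                         stringsAsFactors = FALSE)
  samples <- samples[order(samples$treatment, samples$replicate), 2:1]
  samples$sample_id <- sprintf("%s_r%d", samples$treatment,
                               samples$replicate)
  rownames(samples) <- NULL
  samples <- samples[, c("sample_id", "treatment", "replicate")]

  edges <- list()
  for (r in seq_len(n_replicates)) {
    for (cyc in spec[[r]]) {
      k <- length(cyc)
      if (k < 2L) stop("each loop must contain at least two treatments")
      nxt <- c(cyc[-1L], cyc[1L])
      edges[[length(edges) + 1L]] <- data.frame(
        cy5_sample = sprintf("%s_r%d", cyc, r),
        cy3_sample = sprintf("%s_r%d", nxt, r),
        stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, edges)
  edges <- data.frame(array_id = sprintf("array_%03d", seq_len(nrow(edges))),
                      edges, stringsAsFactors = FALSE)

  if (!all(c(edges$cy5_sample, edges$cy3_sample) %in% samples$sample_id))
    stop("internal error: edge references unknown sample")
  used <- unique(c(edges$cy5_sample, edges$cy3_sample))
  if (!all(samples$sample_id %in% used))
    warning("some samples are not hybridized on any array")

  g <- structure(list(samples = samples, edges = edges),
                 class = "hyb_graph")
  if (!graph_connected(g))
    warning("hybridization graph is not connected over treatments; ",
            "the factorial model will not be estimable")
  g
}

## connectivity of the undirected treatment graph (union over replicates)
graph_connected <- function(graph) {
  trt <- graph$samples$treatment[match(graph$edges$cy5_sample,
                                       graph$samples$sample_id)]
  trt2 <- graph$samples$treatment[match(graph$edges$cy3_sample,
                                        graph$samples$sample_id)]
  nodes <- unique(graph$samples$treatment)
  if (length(nodes) <= 1L) return(TRUE)
  comp <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (e in seq_along(trt)) {
    a <- find(match(trt[e], nodes)); b <- find(match(trt2[e], nodes))
    if (a != b) comp[a] <- b
  }
  length(unique(vapply(seq_along(nodes), find, integer(1)))) == 1L
}

#' @export
print.hyb_graph <- function(x, ...) {
  cat(sprintf("Loop hybridization design: %d samples (%d treatments x %s), %d arrays\n",
              nrow(x$samples), length(unique(x$samples$treatment)),
              paste(range(x$samples$replicate), collapse = "-"),
              nrow(x$edges)))
  invisible(x)
}

#' Log-ratio design matrix of a loop design
#'
#' Each array measures `M = log2(red/green)`, so its design-matrix row
#' is the difference between the sum-to-zero effect encodings of the
#' red (Cy5) and green (Cy3) samples; the overall mean cancels in the
#' ratio and never appears as a column. Entries are in `{-2, 0, +2}`;
#' a self-self slide contributes an all-zero effect row. An optional
#' all-ones dye-intercept column absorbs any residual global dye offset.
#'
#' @param graph A `hyb_graph` from [build_loop_design()].
#' @inheritParams effect_names
#' @param include_dye Add an all-ones `dye` column (default `TRUE`).
#' @return Numeric matrix (arrays x effects) with attributes `rank`
#'   (numerical rank of the effect columns) and `effects`.
#' @export
build_design_matrix <- function(graph, factors = canonical_factors(),
                                include_dye = TRUE) {
  validate_factors(factors)
  eff <- effect_names(factors)
  trt <- unique(graph$samples$treatment)
  enc <- t(vapply(trt, encode_treatment, numeric(length(eff)),
                  factors = factors))
  rownames(enc) <- trt
  t5 <- graph$samples$treatment[match(graph$edges$cy5_sample,
                                      graph$samples$sample_id)]
  t3 <- graph$samples$treatment[match(graph$edges$cy3_sample,
                                      graph$samples$sample_id)]
  X <- enc[t5, , drop = FALSE] - enc[t3, , drop = FALSE]
  rownames(X) <- graph$edges$array_id
  qr_eff <- qr(X)
  rk <- qr_eff$rank
  if (rk < length(eff)) {
    bad <- eff[qr_eff$pivot[-seq_len(rk)]]
    stop(sprintf(
      "estimability error: design rank %d < %d; non-estimable effect(s): %s",
      rk, length(eff), paste(bad, collapse = ", ")))
  }
  if (include_dye) X <- cbind(X, dye = 1)
  attr(X, "rank") <- rk
  attr(X, "effects") <- eff
  X
}

#' Mussels used per treatment
#'
#' Sample-accounting helper: with RNA extracted from pools of
#' `pool_size` animals and `n_replicates` biological replicate pools
#' per treatment, `pool_size * n_replicates` mussels are consumed per
#' treatment (6 x 4 = 24 in the canonical design).
#'
#' @param pool_size Animals pooled per RNA sample.
#' @param n_replicates Biological replicates per treatment.
#' @return Integer count of animals per treatment.
#' @examples
#' mussels_per_treatment(6, 4)  # 24
#' @export
mussels_per_treatment <- function(pool_size, n_replicates) {
  if (!is.numeric(pool_size) || !is.numeric(n_replicates) ||
      length(pool_size) != 1L || length(n_replicates) != 1L ||
      pool_size < 1 || n_replicates < 1)
    stop("pool_size and n_replicates must be positive")
  as.integer(pool_size) * as.integer(n_replicates)
}
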