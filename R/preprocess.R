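#' Background-correct a two-color array
#'
#' Subtracts the measured local background from each channel's
#' foreground. To keep all log-ratios finite, corrected intensities are
#' floored at half the smallest positive corrected value of that
#' channel on that slide (per channel, per array). `method = "none"`
#' leaves foregrounds untouched.
#'
#' @param array A `two_color_array`.
#' @param method `"subtract"` (default) or `"none"`.
#' @return The array with numeric vectors `R` and `G` (corrected red
#'   and green intensities) added.
#' @export
background_correct <- function(array, method = c("subtract", "none")) {
  method <- match.arg(method)
  s <- array$spots
  if (method == "none") {
    array$R <- s$F635
    array$G <- s$F532
    return(array)
  }
  floor_channel <- function(x) {
    pos <- x[x > 0]
    if (!length(pos))
      stop("background correction left no positive intensities")
    pmax(x, min(pos) / 2)
  }
  array$R <- floor_channel(s$F635 - s$B635)
  array$G <- floor_channel(s$F532 - s$B532)
  array
}

#' M/A transform of a corrected array
#'
#' Computes the per-spot log-ratio `M = log2(R/G)` and average
#' log-intensity `A = 0.5 * log2(R * G)`; spots carrying a negative
#' quality flag get weight 0 and are excluded from normalization fits
#' and model fitting downstream.
#'
#' @param array A background-corrected `two_color_array`.
#' @return Data frame `probe_id`, `M`, `A`, `weight`.
#' @export
compute_ma <- function(array) {
  if (is.null(array$R) || is.null(array$G))
    stop("run background_correct() first")
  data.frame(probe_id = array$spots$probe_id,
             M = log2(array$R / array$G),
             A = 0.5 * log2(array$R * array$G),
             weight = ifelse(array$spots$flag < 0, 0, 1),
             stringsAsFactors = FALSE)
}

#' Within-array loess normalization
#'
#' Removes intensity-dependent dye bias by fitting a locally weighted
#' quadratic regression of M on A (tricube weights, robust
#' re-weighting) through the weighted spots and replacing M by the
#' residual. Weight-0 spots never influence the curve but are still
#' transformed via the fitted curve evaluated at their A.
#'
#' @param ma Data frame from [compute_ma()].
#' @param span Loess span (default 0.3).
#' @param surface `"direct"` (exact local fits; default) or
#'   `"interpolate"` (kd-tree approximation, much faster on arrays
#'   with many thousands of spots).
#' @return `ma` with `M` replaced by normalized values.
#' @export
within_array_normalize <- function(ma, span = 0.3,
                                   surface = c("direct", "interpolate")) {
  surface <- match.arg(surface)
  use <- ma$weight > 0
  if (sum(use) < 20L)
    stop("too few weighted spots for loess normalization (need >= 20)")
  if (diff(range(ma$M[use])) < 1e-12) {
    ## constant M (e.g. noise-free self-self): remove it directly; the
    ## robust loess machinery cannot iterate on all-zero residuals
    ma$M <- ma$M - ma$M[use][1L]
    return(ma)
  }
  fit <- stats::loess(M ~ A, data = ma[use, ], span = span, degree = 2,
                      family = "symmetric",
                      control = stats::loess.control(surface = surface,
                                                     iterations = 3L))
  trend <- rep(NA_real_, nrow(ma))
  trend[use] <- stats::fitted(fit)
  if (any(!use))
    trend[!use] <- stats::predict(fit, newdata = ma[!use, , drop = FALSE])
  ## outside the fitted A range prediction is NA; fall back to no shift
  trend[is.na(trend)] <- 0
  ma$M <- ma$M - trend
  ma
}

#' Between-array scale normalization
#'
#' Equalizes the spread of M across slides: each array's M values are
#' divided by the ratio of its median absolute M to the geometric mean
#' of all arrays' median absolute M. `method = "none"` is the
#' identity.
#'
#' @param M Numeric genes x arrays matrix of normalized M values
#'   (`NA` for masked spots).
#' @param method `"scale"` (default) or `"none"`.
#' @return Matrix of the same shape.
#' @export
between_array_normalize <- function(M, method = c("scale", "none")) {
  method <- match.arg(method)
  if (method == "none") return(M)
  medabs <- apply(M, 2L, function(x) stats::median(abs(x), na.rm = TRUE))
  if (any(!is.finite(medabs)) || any(medabs <= 0))
    stop("cannot scale-normalize: an array has non-positive median |M|")
  target <- exp(mean(log(medabs)))
  sweep(M, 2L, medabs / target, "/")
}

#' Preprocess a set of slides into an M-value matrix
#'
#' Runs background correction, within-array loess normalization and
#' between-array scale normalization over a list of slides sharing one
#' template, and assembles the genes x arrays matrices of normalized M
#' and of average intensity A, plus the 0/1 weight mask from the spot
#' flags (masked entries are `NA` in `M`).
#'
#' @param arrays List of `two_color_array`.
#' @param bg_method Background method, see [background_correct()].
#' @param within_method `"loess"` (default) or `"none"` (skip
#'   within-array normalization).
#' @param span Loess span, see [within_array_normalize()].
#' @param between_method See [between_array_normalize()].
#' @param surface Loess evaluation surface, see
#'   [within_array_normalize()].
#' @return List (class `m_matrix`) with `M`, `A`, `weights` (genes x
#'   arrays) and `probe_id`.
#' @export
preprocess_arrays <- function(arrays, bg_method = "subtract",
                              within_method = c("loess", "none"),
                              span = 0.3, between_method = "scale",
                              surface = "direct") {
  within_method <- match.arg(within_method)
  stopifnot(length(arrays) >= 1L)
  ids <- vapply(arrays, function(a) a$array_id, character(1))
  probe_id <- arrays[[1L]]$spots$probe_id
  per <- lapply(arrays, function(a) {
    if (!identical(a$spots$probe_id, probe_id))
      stop("arrays do not share a common spot template")
    ma <- compute_ma(background_correct(a, bg_method))
    if (within_method == "loess")
      ma <- within_array_normalize(ma, span = span, surface = surface)
    ma
  })
  M <- vapply(per, function(x) ifelse(x$weight > 0, x$M, NA_real_),
              numeric(length(probe_id)))
  A <- vapply(per, function(x) x$A, numeric(length(probe_id)))
  W <- vapply(per, function(x) x$weight, numeric(length(probe_id)))
  dimnames(M) <- dimnames(A) <- dimnames(W) <- list(probe_id, ids)
  M <- between_array_normalize(M, between_method)
  structure(list(M = M, A = A, weights = W, probe_id = probe_id),
            class = "m_matrix")
}

#' @export
print.m_matrix <- function(x, ...) {
  cat(sprintf("Normalized M-value matrix: %d probes x %d arrays (%d masked entries)\n",
              nrow(x$M), ncol(x$M), sum(is.na(x$M))))
  invisible(x)
}
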