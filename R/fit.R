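#' Per-gene least-squares fit of the full factorial model
#'
#' Fits, for every probe, ordinary least squares of its normalized
#' log-ratios on the loop design's effect columns (15 effects under
#' sum-to-zero coding, plus the optional dye intercept). Standard
#' errors come from the per-gene residual variance with
#' `residual_df = informative arrays - fitted columns`; t statistics
#' are two-sided tested against that t distribution. The log2 fold
#' change between the two levels of an effect is exactly twice its
#' coefficient. Genes with too few informative (unmasked) arrays are
#' marked unfit and excluded from downstream tables; genes with
#' residual df < 3 are flagged low-confidence.
#'
#' @param m An `m_matrix` from [preprocess_arrays()], or a plain
#'   genes x arrays matrix of M values (`NA` = masked).
#' @param design Design matrix from [build_design_matrix()]; rows must
#'   match the arrays (columns of `m`).
#' @return Object of class `gene_fit`: list of genes x effects
#'   matrices `coefficients`, `se`, `t`, `p`, `log_fc` (2 x
#'   coefficient for the factorial effects), vectors `sigma`,
#'   `residual_df`, `mu` (mean average intensity, reporting only),
#'   logical `fitted`, `low_confidence`, and `effects`.
#' @export
fit_factorial <- function(m, design) {
  if (inherits(m, "m_matrix")) {
    M <- m$M; A <- m$A
  } else {
    M <- as.matrix(m); A <- NULL
  }
  if (ncol(M) != nrow(design))
    stop(sprintf("M has %d arrays but the design has %d rows",
                 ncol(M), nrow(design)))
  if (!is.null(rownames(design)) && !is.null(colnames(M)) &&
      !identical(colnames(M), rownames(design)))
    M <- M[, rownames(design), drop = FALSE]
  probe_id <- rownames(M)
  if (is.null(probe_id))
    probe_id <- sprintf("gene_%05d", seq_len(nrow(M)))
  eff <- attr(design, "effects")
  if (is.null(eff)) eff <- colnames(design)
  X <- unclass(design)
  p <- ncol(X)
  ng <- nrow(M)
  cols <- colnames(X)

  coef_m <- se_m <- t_m <- p_m <-
    matrix(NA_real_, ng, p, dimnames = list(rownames(M), cols))
  sigma <- rep(NA_real_, ng)
  df_res <- rep(NA_integer_, ng)
  complete <- !apply(M, 1L, anyNA)

  solve_block <- function(Xs, Ys) {
    ## Ys: arrays x genes block sharing one mask
    qrX <- qr(Xs)
    if (qrX$rank < ncol(Xs))
      return(NULL)
    beta <- qr.coef(qrX, Ys)
    res <- Ys - Xs %*% beta
    dfr <- nrow(Xs) - ncol(Xs)
    s2 <- colSums(res^2) / dfr
    xtx_inv_diag <- diag(chol2inv(qr.R(qrX)))
    list(beta = beta, s2 = s2, dfr = dfr, d = xtx_inv_diag)
  }

  fill <- function(idx, fit) {
    coef_m[idx, ] <<- t(fit$beta)
    se <- sqrt(outer(fit$s2, fit$d))
    se_m[idx, ] <<- se
    sigma[idx] <<- sqrt(fit$s2)
    df_res[idx] <<- fit$dfr
    tt <- t(fit$beta) / se
    ## exact fits: zero residual variance makes t 0/0; report p = 1 for
    ## (numerically) zero coefficients, p = 0 otherwise
    degen <- sqrt(fit$s2) < 1e-12
    pv <- 2 * stats::pt(abs(tt), df = fit$dfr, lower.tail = FALSE)
    if (any(degen)) {
      cz <- abs(t(fit$beta)[degen, , drop = FALSE]) < 1e-10
      pv[degen, ] <- ifelse(cz, 1, 0)
      tt[degen, ] <- ifelse(cz, 0, Inf) * sign(t(fit$beta)[degen, , drop = FALSE] + cz)
    }
    t_m[idx, ] <<- tt
    p_m[idx, ] <<- pv
  }

  if (any(complete)) {
    fit <- solve_block(X, t(M[complete, , drop = FALSE]))
    if (is.null(fit))
      stop("estimability error: design matrix is rank deficient")
    fill(which(complete), fit)
  }
  for (g in which(!complete)) {
    keep <- !is.na(M[g, ])
    if (sum(keep) <= p) next  # unfit: not enough informative arrays
    fit <- solve_block(X[keep, , drop = FALSE],
                       cbind(M[g, keep]))
    if (is.null(fit)) next    # effects not estimable for this mask
    fill(g, fit)
  }

  fitted_ok <- !is.na(df_res)
  structure(list(
    probe_id = probe_id,
    coefficients = coef_m, se = se_m, t = t_m, p = p_m,
    log_fc = 2 * coef_m[, eff, drop = FALSE],
    sigma = sigma, residual_df = df_res,
    mu = if (is.null(A)) rep(NA_real_, ng) else rowMeans(A),
    fitted = fitted_ok,
    low_confidence = fitted_ok & df_res < 3L,
    effects = eff), class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  cat(sprintf("Factorial fit: %d probes (%d fitted), %d effect columns, residual df %s\n",
              length(x$probe_id), sum(x$fitted), length(x$effects),
              paste(unique(stats::na.omit(x$residual_df)), collapse = "/")))
  invisible(x)
}

#' Log fold change from a sum-to-zero coefficient
#'
#' Under sum-to-zero coding the two levels of an effect sit at
#' `+coef` and `-coef`, so the log2 fold change between levels is
#' double the coefficient.
#'
#' @param coefficient Numeric coefficient(s).
#' @return `2 * coefficient`.
#' @examples
#' logfc_from_coef(0.314)  # 0.628
#' @export
logfc_from_coef <- function(coefficient) 2 * coefficient

#' Select genes significant for one effect
#'
#' Returns the probes whose two-sided p-value for the given effect is
#' below `alpha` (a raw p-value cutoff: selection deliberately uses
#' unadjusted p, calibrated empirically via self-self slides), sorted
#' by ascending p with ties broken by probe id.
#'
#' @param fit A `gene_fit`.
#' @param alpha Significance cutoff in (0, 1), default 0.01.
#' @param factor Effect name (default `"D"`, the attachment effect).
#' @return Data frame `probe_id`, `p_value`, `log_fc` with attribute
#'   `alpha`.
#' @export
select_significant <- function(fit, alpha = 0.01, factor = "D") {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  if (!factor %in% fit$effects)
    stop(sprintf("unknown effect '%s'", factor))
  p <- fit$p[, factor]
  sel <- which(fit$fitted & !is.na(p) & p < alpha)
  out <- data.frame(probe_id = fit$probe_id[sel],
                    p_value = p[sel],
                    log_fc = fit$log_fc[sel, factor],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Test the interaction effects
#'
#' Applies the same raw-p selection to each of the 11 interaction
#' columns of the factorial model.
#'
#' @inheritParams select_significant
#' @return Named list of significance tables, one per interaction.
#' @export
test_interactions <- function(fit, alpha = 0.01) {
  inter <- fit$effects[nchar(fit$effects) > 1L]
  stats::setNames(lapply(inter, function(e)
    select_significant(fit, alpha = alpha, factor = e)), inter)
}
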