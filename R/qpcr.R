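#' Detection call from replicate Ct values
#'
#' A transcript counts as detected (+) in a sample when its mean
#' threshold cycle is below the detection cutoff (default 36 cycles).
#'
#' @param ct_values Numeric replicate Ct values.
#' @param cutoff Detection cutoff in cycles.
#' @return Logical.
#' @export
detection_call <- function(ct_values, cutoff = 36) {
  if (!length(ct_values) || !is.numeric(ct_values))
    stop("ct_values must be a non-empty numeric vector")
  mean(ct_values) < cutoff
}

## replicate-mean and SD of Ct per (sample, gene)
ct_summary <- function(records, gene) {
  sub <- records[records$gene == gene, , drop = FALSE]
  agg_m <- tapply(sub$Ct, sub$sample_label, mean)
  agg_s <- tapply(sub$Ct, sub$sample_label, stats::sd)
  data.frame(sample_label = names(agg_m), mean_ct = as.numeric(agg_m),
             sd_ct = as.numeric(agg_s), stringsAsFactors = FALSE)
}

## per-sample delta-Ct (target minus reference) with propagated SD
delta_ct_table <- function(records, target, reference) {
  req <- c("sample_label", "gene", "Ct")
  if (!all(req %in% names(records)))
    stop("records need columns sample_label, gene, replicate, Ct")
  tg <- ct_summary(records, target)
  rf <- ct_summary(records, reference)
  if (!all(tg$sample_label %in% rf$sample_label))
    stop(sprintf("reference gene '%s' missing for sample(s): %s", reference,
                 paste(setdiff(tg$sample_label, rf$sample_label),
                       collapse = ", ")))
  i <- match(tg$sample_label, rf$sample_label)
  data.frame(sample_label = tg$sample_label,
             mean_ct = tg$mean_ct,
             delta_ct = tg$mean_ct - rf$mean_ct[i],
             ## replicate SDs combine in quadrature in dCt space
             sd_dct = sqrt(ifelse(is.na(tg$sd_ct), 0, tg$sd_ct)^2 +
                             ifelse(is.na(rf$sd_ct[i]), 0, rf$sd_ct[i])^2),
             stringsAsFactors = FALSE)
}

#' Pick the calibrator sample
#'
#' Among samples where the target is detected, returns the one with
#' the largest delta-Ct (i.e. the lowest-expressing detected sample,
#' the "lowest (+)" convention); ties break by label sort order.
#'
#' @param records Ct table (`sample_label`, `gene`, `replicate`,
#'   `Ct`).
#' @param target,reference Gene names.
#' @param cutoff Detection cutoff in cycles.
#' @return The calibrator `sample_label`.
#' @export
pick_calibrator <- function(records, target, reference = "18S",
                            cutoff = 36) {
  d <- delta_ct_table(records, target, reference)
  det <- d$mean_ct < cutoff
  if (!any(det)) stop("target not detected in any sample")
  d <- d[det, , drop = FALSE]
  d <- d[order(-d$delta_ct, d$sample_label), , drop = FALSE]
  d$sample_label[1L]
}

#' 2^-ddCt relative quantification
#'
#' Classic comparative-Ct analysis under perfect doubling: per sample,
#' `dCt = Ct_target - Ct_reference` (replicate means);
#' `ddCt = dCt(sample) - dCt(calibrator)`; fold change =
#' `2^(-ddCt)`. The calibrator's own fold is exactly 1. Replicate SDs
#' are combined in dCt space and propagated to the fold scale by the
#' delta method (`sd_fold = fold * ln2 * sd_dCt`). Samples whose mean
#' target Ct is at or above the cutoff are reported as not detected
#' with no fold change.
#'
#' @param records Ct table (`sample_label`, `gene`, `replicate`,
#'   `Ct`).
#' @param target Target gene name.
#' @param reference Reference gene name (default `"18S"`).
#' @param calibrator Calibrator sample label; `NULL` (default) picks
#'   the lowest-expressing detected sample via [pick_calibrator()].
#' @param cutoff Detection cutoff in cycles.
#' @return Data frame `sample_label`, `detected`, `fold`, `sd_fold`,
#'   `delta_ct`, `call` ("+"/"-"), with attribute `calibrator`.
#' @export
delta_delta_ct <- function(records, target, reference = "18S",
                           calibrator = NULL, cutoff = 36) {
  d <- delta_ct_table(records, target, reference)
  d$detected <- d$mean_ct < cutoff
  if (is.null(calibrator))
    calibrator <- pick_calibrator(records, target, reference, cutoff)
  ci <- match(calibrator, d$sample_label)
  if (is.na(ci)) stop(sprintf("calibrator '%s' has no measurements",
                              calibrator))
  if (!d$detected[ci]) stop("calibrator sample is not detected")
  ddct <- d$delta_ct - d$delta_ct[ci]
  fold <- 2^(-ddct)
  fold[ci] <- 1  # exact by definition
  fold[!d$detected] <- NA_real_
  out <- data.frame(sample_label = d$sample_label,
                    detected = d$detected,
                    fold = fold,
                    sd_fold = ifelse(d$detected,
                                     fold * log(2) * d$sd_dct, NA_real_),
                    delta_ct = d$delta_ct,
                    call = ifelse(d$detected, "+", "-"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample_label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "calibrator") <- calibrator
  out
}

#' Attached-versus-detached fold change per timepoint
#'
#' For each timepoint of the byssogenesis time course, computes the
#' 2^-ddCt fold change of the attached group against the detached
#' group at the same timepoint (detached = calibrator, fold 1).
#' Timepoints missing either group are dropped with a warning.
#'
#' @param records Ct table with additional columns `timepoint` and
#'   `group`.
#' @param target Target gene name.
#' @param reference Reference gene name.
#' @param groups Length-2 named character vector mapping
#'   `c(attached=, detached=)` onto the values of the `group` column.
#' @return Data frame `timepoint`, `fold`, `sd_fold` in input
#'   timepoint order.
#' @export
timecourse_ratios <- function(records, target, reference = "18S",
                              groups = c(attached = "attached",
                                         detached = "detached")) {
  if (!all(c("timepoint", "group") %in% names(records)))
    stop("records need 'timepoint' and 'group' columns")
  tps <- unique(records$timepoint)
  rows <- lapply(tps, function(tp) {
    sub <- records[records$timepoint == tp, , drop = FALSE]
    have <- groups %in% sub$group
    if (!all(have)) {
      warning(sprintf("timepoint '%s' missing group(s): %s — omitted", tp,
                      paste(groups[!have], collapse = ", ")))
      return(NULL)
    }
    sub$sample_label <- sub$group
    res <- delta_delta_ct(sub, target, reference,
                          calibrator = groups[["detached"]])
    i <- match(groups[["attached"]], res$sample_label)
    data.frame(timepoint = tp, fold = res$fold[i],
               sd_fold = res$sd_fold[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(timepoint = character(0), fold = numeric(0),
                      sd_fold = numeric(0))
  rownames(out) <- NULL
  out
}
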