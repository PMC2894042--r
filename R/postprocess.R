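#' Factor-overlap (Venn) accounting of significant genes
#'
#' Classifies every significant gene by the exact subset of factors
#' for which it was selected and counts genes per subset. Per-factor
#' totals are the sums over all subsets containing that factor (e.g.
#' 19 A-only + 1 AB + 1 AC + 6 AD genes give a factor-A total of 27),
#' and the grand total is the number of distinct significant genes.
#'
#' @param sig_tables Named list (names = factor letters) of
#'   significance tables from [select_significant()], or of plain
#'   character vectors of probe ids.
#' @return Object of class `overlap_account`: list with `subsets`
#'   (data frame `subset`, `count`), `factor_totals`, `grand_total`
#'   and `membership` (gene -> subset string).
#' @export
factor_overlap <- function(sig_tables) {
  if (is.null(names(sig_tables)) || any(names(sig_tables) == ""))
    stop("sig_tables must be a named list (one entry per factor)")
  sets <- lapply(sig_tables, function(x)
    if (is.data.frame(x)) x$probe_id else as.character(x))
  genes <- sort(unique(unlist(sets, use.names = FALSE)), method = "radix")
  membership <- vapply(genes, function(g)
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = ""), character(1))
  tab <- table(membership)
  subsets <- data.frame(subset = as.character(names(tab)),
                        count = as.integer(tab),
                        stringsAsFactors = FALSE)
  subsets <- subsets[order(nchar(subsets$subset), subsets$subset), ,
                     drop = FALSE]
  rownames(subsets) <- NULL
  factor_totals <- vapply(names(sets), function(f)
    sum(subsets$count[grepl(f, subsets$subset, fixed = TRUE)]),
    integer(1))
  structure(list(subsets = subsets, factor_totals = factor_totals,
                 grand_total = length(genes), membership = membership),
            class = "overlap_account")
}

#' @export
print.overlap_account <- function(x, ...) {
  cat(sprintf("Factor overlap: %d distinct significant genes\n",
              x$grand_total))
  print(x$subsets, row.names = FALSE)
  cat("Per-factor totals:",
      paste(sprintf("%s=%d", names(x$factor_totals), x$factor_totals),
            collapse = ", "), "\n")
  invisible(x)
}

#' Integer percentage of the array
#'
#' Reports a gene count as a round-half-up integer percentage of the
#' probes on the slide, matching the style "73 genes (10% of the total
#' genes on the slide)".
#'
#' @param k Gene count.
#' @param n_genes Probes on the array.
#' @return Integer percent.
#' @examples
#' percent_of_array(73, 750)  # 10
#' percent_of_array(9, 750)   # 1
#' @export
percent_of_array <- function(k, n_genes) {
  if (n_genes <= 0) stop("n_genes must be positive")
  as.integer(floor(100 * k / n_genes + 0.5))
}

#' Reporting line for a significant-gene count
#'
#' @param k Gene count.
#' @param n_genes Probes on the array.
#' @return Character string, e.g. `"73 genes (10% of the total genes
#'   on the slide)"`.
#' @export
report_line <- function(k, n_genes) {
  sprintf("%d genes (%d%% of the total genes on the slide)", k,
          percent_of_array(k, n_genes))
}

#' Signed effect-profile matrix of the significant genes
#'
#' One row per gene significant for at least one factor; the column of
#' a factor holds the gene's log2 fold change where the gene passed
#' selection for that factor and 0 elsewhere (non-significant entries
#' encode "no significant change"). Setting `raw = TRUE` fills all
#' four columns with the fitted log fold changes instead.
#'
#' @param fit A `gene_fit`.
#' @param sig_tables Named list of per-factor significance tables.
#' @param raw Use raw log fold changes for non-significant entries.
#' @return Numeric matrix (genes x factors), rows ordered by probe id.
#' @export
build_profile_matrix <- function(fit, sig_tables, raw = FALSE) {
  factors <- names(sig_tables)
  acc <- factor_overlap(sig_tables)
  genes <- names(acc$membership)
  mat <- matrix(0, length(genes), length(factors),
                dimnames = list(genes, factors))
  if (!length(genes)) return(mat)
  idx <- match(genes, fit$probe_id)
  if (anyNA(idx)) stop("significance tables name probes absent from the fit")
  for (f in factors) {
    lfc <- fit$log_fc[idx, f]
    if (raw) mat[, f] <- lfc
    else {
      hit <- grepl(f, acc$membership, fixed = TRUE)
      mat[hit, f] <- lfc[hit]
    }
  }
  mat
}

#' Average-linkage clustering of effect profiles
#'
#' Hierarchical agglomerative clustering (average linkage, Euclidean
#' distance) of the signed effect profiles, cut into `k` clusters.
#' Rows are sorted by probe id before clustering so results are
#' deterministic; clusters are relabeled 1..k in order of first
#' appearance.
#'
#' @param mat Profile matrix from [build_profile_matrix()].
#' @param k Number of clusters (default 10).
#' @return List (class `cluster_result`) with `labels` (named integer
#'   vector), `tree` (an `hclust`), `k` and `profiles`.
#' @export
cluster_profiles <- function(mat, k = 10L) {
  if (nrow(mat) < 1L) stop("no genes to cluster")
  if (k > nrow(mat))
    stop(sprintf("k = %d exceeds the number of genes (%d)", k, nrow(mat)))
  mat <- mat[order(rownames(mat), method = "radix"), , drop = FALSE]
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "average")
  raw <- stats::cutree(hc, k = k)
  relabel <- match(raw, unique(raw))
  labels <- stats::setNames(as.integer(relabel), rownames(mat))
  structure(list(labels = labels, tree = hc, k = as.integer(k),
                 profiles = mat), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Average-linkage clustering: %d genes in %d clusters\n",
              length(x$labels), x$k))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Heatmap of clustered effect profiles
#'
#' Renders the signed profile matrix with the byssogenesis study's
#' color convention — green for up-regulation, red for
#' down-regulation, black for no significant change (note this is the
#' reverse of the common red-up convention). Requires the `pheatmap`
#' package.
#'
#' @param cl A `cluster_result`.
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
profile_heatmap <- function(cl, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("profile_heatmap() needs the 'pheatmap' package")
  lim <- max(abs(cl$profiles), 1e-6)
  invisible(pheatmap::pheatmap(
    cl$profiles, cluster_rows = cl$tree, cluster_cols = FALSE,
    color = grDevices::colorRampPalette(c("red", "black", "green"))(101),
    breaks = seq(-lim, lim, length.out = 102), ...))
}

#' Plain-text summary of a factorial analysis
#'
#' Echoes, per factor and cutoff, the count of selected genes as a
#' count-and-percentage line, plus the overlap grand total.
#'
#' @param fit A `gene_fit`.
#' @param n_genes Probes on the slide.
#' @param alphas Cutoffs to report (default 0.05 and 0.01).
#' @param factors Factor letters to report.
#' @return Character vector of report lines (also printed).
#' @export
summarize_results <- function(fit, n_genes = length(fit$probe_id),
                              alphas = c(0.05, 0.01),
                              factors = c("A", "B", "C", "D")) {
  lines <- character(0)
  for (a in alphas) {
    sig <- lapply(stats::setNames(factors, factors), function(f)
      select_significant(fit, alpha = a, factor = f))
    acc <- factor_overlap(sig)
    lines <- c(lines, sprintf("P < %g:", a),
               vapply(factors, function(f)
                 sprintf("  factor %s: %s", f,
                         report_line(nrow(sig[[f]]), n_genes)),
                 character(1)),
               sprintf("  distinct over all factors: %d genes",
                       acc$grand_total))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
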