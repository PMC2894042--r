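## Minimal GenePix-Results (GPR) dialect: ATF-style header followed by a
## tab-delimited spot table. Required data columns: Block, Column, Row,
## Name, ID, "F635 Median", "B635 Median", "F532 Median", "B532 Median",
## Flags. Extra columns in real-world files are preserved as metadata.

gpr_required_cols <- c("Block", "Column", "Row", "Name", "ID",
                       "F635 Median", "B635 Median",
                       "F532 Median", "B532 Median", "Flags")

#' Write a two-color array as a GPR file
#'
#' Serializes a `two_color_array` in a minimal GenePix-Results
#' dialect: an ATF header (`ATF 1.0`, header-line/column counts,
#' quoted `key=value` records including `Type` and `Wavelengths`)
#' followed by the tab-delimited spot table. Intensities are written
#' with 17 significant digits so the file round-trips losslessly
#' through [read_gpr()]. The write is atomic (temp file + rename).
#'
#' @param array A `two_color_array`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gpr <- function(array, path) {
  s <- array$spots
  n <- nrow(s)
  ncols <- 32L
  grid_col <- ((seq_len(n) - 1L) %% ncols) + 1L
  grid_row <- ((seq_len(n) - 1L) %/% ncols) + 1L
  header <- c(sprintf("\"Type=GenePix Results 3\""),
              sprintf("\"Wavelengths=635\t532\""),
              sprintf("\"ArrayId=%s\"", array$array_id),
              sprintf("\"Creator=byssofact %s\"",
                      as.character(utils::packageVersion("byssofact"))))
  num <- function(x) sprintf("%.17g", x)
  body <- paste(1L, grid_col, grid_row, s$probe_id, s$probe_id,
                num(s$F635), num(s$B635), num(s$F532), num(s$B532),
                s$flag, sep = "\t")
  lines <- c("ATF\t1.0",
             sprintf("%d\t%d", length(header), length(gpr_required_cols)),
             header,
             paste(sprintf('"%s"', gpr_required_cols), collapse = "\t"),
             body)
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a GPR spot-intensity file
#'
#' Parses the ATF header and the spot table of a GenePix-Results-like
#' file. The required columns are checked by name (a missing one is a
#' format error naming it); unknown columns are kept in the
#' `extra_columns` attribute. Negative `Flags` values mark bad spots
#' and map to weight 0 downstream.
#'
#' @param path File path.
#' @return A `two_color_array` with the header key-values in attribute
#'   `header`.
#' @export
read_gpr <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !grepl("^ATF", lines[1L]))
    stop(sprintf("format error: '%s' is not an ATF/GPR file", path))
  hd <- strsplit(lines[2L], "\t")[[1L]]
  n_header <- as.integer(hd[1L])
  header_lines <- lines[2L + seq_len(n_header)]
  header_kv <- sub("\"$", "", sub("^\"", "", header_lines))
  tab <- utils::read.delim(text = lines[-seq_len(2L + n_header)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(gpr_required_cols, names(tab))
  if (length(missing))
    stop(sprintf("format error: missing required GPR column(s): %s",
                 paste(missing, collapse = ", ")))
  arr_id <- sub("^ArrayId=", "", grep("^ArrayId=", header_kv, value = TRUE))
  if (!length(arr_id))
    arr_id <- sub("\\.gpr$", "", basename(path))
  out <- new_two_color_array(
    arr_id[1L], as.character(tab$ID),
    red = list(F = tab[["F635 Median"]], B = tab[["B635 Median"]]),
    grn = list(F = tab[["F532 Median"]], B = tab[["B532 Median"]]),
    flag = as.integer(tab$Flags))
  attr(out, "header") <- header_kv
  extra <- setdiff(names(tab), gpr_required_cols)
  if (length(extra))
    attr(out, "extra_columns") <- tab[, extra, drop = FALSE]
  out
}

#' Write / read the hybridization graph and sample sheet
#'
#' The graph file is tab-delimited with columns `array_id`,
#' `cy5_sample`, `cy3_sample`; the sample sheet has `sample_id`,
#' `treatment`, `replicate`. Together they reconstruct a `hyb_graph`.
#'
#' @param graph A `hyb_graph`.
#' @param graph_path,samples_path Output paths.
#' @return Paths, invisibly.
#' @export
write_graph <- function(graph, graph_path, samples_path) {
  utils::write.table(graph$edges, graph_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(graph$samples, samples_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(graph_path, samples_path))
}

#' @rdname write_graph
#' @export
read_graph <- function(graph_path, samples_path) {
  edges <- utils::read.delim(graph_path, stringsAsFactors = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  req_e <- c("array_id", "cy5_sample", "cy3_sample")
  req_s <- c("sample_id", "treatment", "replicate")
  if (!all(req_e %in% names(edges)))
    stop("graph file must have columns array_id, cy5_sample, cy3_sample")
  if (!all(req_s %in% names(samples)))
    stop("sample sheet must have columns sample_id, treatment, replicate")
  bad <- setdiff(c(edges$cy5_sample, edges$cy3_sample), samples$sample_id)
  if (length(bad))
    stop(sprintf("graph references unknown sample(s): %s",
                 paste(unique(bad), collapse = ", ")))
  structure(list(samples = samples[, req_s], edges = edges[, req_e]),
            class = "hyb_graph")
}

#' Write the normalized M-value matrix and its mask
#'
#' @param m An `m_matrix`.
#' @param m_path,mask_path Output TSV paths (probes x arrays).
#' @return Paths, invisibly.
#' @export
write_m_matrix <- function(m, m_path, mask_path) {
  wr <- function(mat, path) {
    df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(m$M, m_path)
  wr(m$weights, mask_path)
  invisible(c(m_path, mask_path))
}

#' Write per-gene factorial fit results
#'
#' One row per probe: coefficients, standard errors, t statistics,
#' p-values and log fold changes for every effect, plus the residual
#' SD, residual df, mean intensity and the low-confidence flag.
#'
#' @param fit A `gene_fit`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fit_results <- function(fit, path) {
  lab <- function(mat, what)
    stats::setNames(as.data.frame(mat),
                    paste(what, colnames(mat), sep = "_"))
  df <- cbind(data.frame(probe_id = fit$probe_id, mu = fit$mu,
                         sigma = fit$sigma,
                         residual_df = fit$residual_df,
                         low_confidence = fit$low_confidence,
                         stringsAsFactors = FALSE),
              lab(fit$coefficients, "coef"), lab(fit$se, "se"),
              lab(fit$t, "t"), lab(fit$p, "p"),
              lab(fit$log_fc, "logfc"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
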