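# Expression matrix input and normalization: TSV parsing, gene symbol
# re-annotation, duplicate collapse, TPM renormalization, and microarray
# preparation (unlog + quantile normalization + probe collapse).

new_expr_matrix <- function(values, platform = "rnaseq", scale = "linear") {
  values <- as.matrix(values)
  attr(values, "platform") <- platform
  attr(values, "scale") <- scale
  values
}

expr_platform <- function(E) attr(E, "platform") %||% "rnaseq"
expr_scale <- function(E) attr(E, "scale") %||% "linear"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file whose header row carries sample IDs,
#' whose first column carries gene symbols, and whose body is numeric
#' (TPM for RNA-seq, normalized intensities for microarrays). For
#' microarray data a log2 scale is suspected when the maximum value is
#' below 50; linear intensities always exceed that.
#'
#' @param path Path to the TSV file.
#' @param platform `"rnaseq"` or `"microarray"`.
#' @return Numeric matrix (genes x samples) with `platform` and `scale`
#'   attributes (`scale` is `"linear"` or `"log2-suspected"`).
#' @export
read_expression_matrix <- function(path, platform = c("rnaseq", "microarray")) {
  platform <- match.arg(platform)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0 || ncol(raw) < 2)
    stop("empty expression matrix in ", path)
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample IDs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  genes <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value '%s' for gene %s in sample %s",
                 body[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
                 samples[bad[1, 2]]))
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric value for gene %s in sample %s",
                 genes[bad[1, 1]], samples[bad[1, 2]]))
  }
  dimnames(num) <- list(genes, samples)
  scale <- if (platform == "microarray" && max(num) < 50)
    "log2-suspected" else "linear"
  new_expr_matrix(num, platform = platform, scale = scale)
}

#' Write an expression or signature matrix to TSV
#'
#' @param E Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the first (gene) column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(E, path, id_col = "GENE") {
  df <- data.frame(rownames(E), E, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column gene alias map
#'
#' @param path TSV with columns old symbol, approved symbol (no header
#'   required; a header line `old<TAB>new` is tolerated).
#' @return Data frame with columns `old` and `new`.
#' @export
read_alias_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("old", "new"))
  if (nrow(df) > 0 && identical(tolower(df$old[1]), "old"))
    df <- df[-1, , drop = FALSE]
  if (any(!nzchar(df$new))) stop("alias map contains empty approved symbols")
  df
}

#' Re-annotate gene symbols and collapse duplicates
#'
#' Maps row names through an alias table (old symbol to approved
#' symbol); symbols without an alias pass through unchanged. Rows
#' sharing a final symbol are replaced by their per-sample median.
#'
#' @param E Expression matrix (genes x samples).
#' @param aliases Data frame with columns `old`, `new`, or `NULL`.
#' @return Expression matrix with unique gene symbols.
#' @export
reannotate_and_collapse <- function(E, aliases = NULL) {
  symbols <- rownames(E)
  if (!is.null(aliases) && nrow(aliases) > 0) {
    idx <- match(symbols, aliases$old)
    hit <- !is.na(idx)
    symbols[hit] <- aliases$new[idx[hit]]
  }
  if (!anyDuplicated(symbols)) {
    out <- E
    rownames(out) <- symbols
    return(new_expr_matrix(out, expr_platform(E), expr_scale(E)))
  }
  keep_order <- !duplicated(symbols)
  uniq <- symbols[keep_order]
  collapsed <- vapply(uniq, function(s) {
    rows <- E[symbols == s, , drop = FALSE]
    apply(rows, 2, stats::median)
  }, numeric(ncol(E)))
  out <- t(collapsed)
  dimnames(out) <- list(uniq, colnames(E))
  new_expr_matrix(out, expr_platform(E), expr_scale(E))
}

#' Renormalize each sample to TPM scale
#'
#' Rescales every column so that it sums to 10^6:
#' `x_gl = TPM_gl * 10^6 / sum_i TPM_il`. Idempotent.
#'
#' @param E Non-negative expression matrix (genes x samples).
#' @return Matrix whose columns each sum to 10^6.
#' @export
renormalize_tpm <- function(E) {
  if (any(E < 0)) stop("expression values must be non-negative")
  cs <- colSums(E)
  zero <- cs <= 0
  if (any(zero))
    stop("all-zero expression column for sample(s): ",
         paste(colnames(E)[zero], collapse = ", "))
  out <- sweep(E, 2, cs, "/") * 1e6
  new_expr_matrix(out, expr_platform(E), "linear")
}

#' Prepare microarray data for deconvolution
#'
#' Transforms suspected log2 data back to the natural scale, quantile
#' normalizes samples onto the mean order-statistic profile (ties
#' averaged), optionally collapses probes to gene symbols keeping the
#' probe with the highest mean expression across samples, and finally
#' renormalizes each sample to the TPM convention.
#'
#' @param E Expression matrix read with `platform = "microarray"`.
#' @param probe_map Optional data frame with columns `probe`, `symbol`.
#' @return Prepared expression matrix (columns sum to 10^6).
#' @export
prepare_microarray <- function(E, probe_map = NULL) {
  if (expr_platform(E) != "microarray")
    stop("prepare_microarray expects a microarray matrix")
  vals <- E
  if (expr_scale(E) == "log2-suspected") vals <- 2^vals
  vals <- limma::normalizeQuantiles(as.matrix(vals), ties = TRUE)
  if (!is.null(probe_map)) {
    missing <- setdiff(probe_map$probe, rownames(vals))
    if (length(missing) > 0)
      warning("probe map names absent probes: ",
              paste(utils::head(missing, 5), collapse = ", "))
    pm <- probe_map[probe_map$probe %in% rownames(vals), , drop = FALSE]
    sym <- rownames(vals)
    sym[match(pm$probe, rownames(vals))] <- pm$symbol
    means <- rowMeans(vals)
    # keep, per symbol, the probe with the highest mean across samples
    ord <- order(sym, -means)
    keep <- ord[!duplicated(sym[ord])]
    vals <- vals[sort(keep), , drop = FALSE]
    rownames(vals) <- sym[sort(keep)]
  }
  renormalize_tpm(new_expr_matrix(vals, "microarray", "linear"))
}
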