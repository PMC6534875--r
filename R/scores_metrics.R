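# Deconvolution-derived aggregate scores (lymphocyte fraction,
# immunoscore and TB-score classes) and benchmarking metrics.

#' Total lymphocyte fraction per sample
#'
#' Sum of the B cell, NK cell, non-regulatory CD4+ T cell, CD8+ T cell,
#' and Treg fractions.
#'
#' @param F Fraction table from [deconvolute()].
#' @return Named numeric vector (one value per sample).
#' @export
lymphocyte_fraction <- function(F) {
  needed <- c("B.cells", "NK.cells", "T.cells.CD4", "T.cells.CD8", "Tregs")
  missing <- setdiff(needed, colnames(F))
  if (length(missing) > 0)
    stop("missing cell-type columns: ", paste(missing, collapse = ", "))
  stats::setNames(rowSums(F[, needed, drop = FALSE]), F$Sample)
}

# Shared dichotomization: Hi-Hi iff both markers strictly above their
# medians, Lo-Lo iff both at or below; anything mixed is unclassified.
# Medians are computed within groups when a grouping vector is given.
dichotomize_two <- function(a, b, group = NULL) {
  n <- length(a)
  if (is.null(group)) group <- rep("all", n)
  cls <- rep("unclassified", n)
  for (g in unique(group)) {
    i <- group == g
    ma <- stats::median(a[i])
    mb <- stats::median(b[i])
    hi <- i & a > ma & b > mb
    lo <- i & a <= ma & b <= mb
    cls[hi] <- "Hi-Hi"
    cls[lo] <- "Lo-Lo"
  }
  cls
}

#' Deconvolution-based immunoscore classes
#'
#' CD3+ T cell fractions are the sum of CD8+, non-regulatory CD4+, and
#' Treg fractions. CD3 and CD8 fractions are dichotomized at their
#' medians across patients (computed per group when `group` is given):
#' `Hi-Hi` patients have both fractions strictly above the medians,
#' `Lo-Lo` patients both at or below, all others are `unclassified`.
#'
#' @param F Fraction table with at least two samples.
#' @param group Optional grouping vector (e.g. cancer type), one entry
#'   per sample; medians are computed within groups.
#' @return Data frame with `Sample`, `CD3`, `CD8`, and `class`.
#' @export
immunoscore_classes <- function(F, group = NULL) {
  if (nrow(F) < 2) stop("need at least two samples to dichotomize")
  cd3 <- rowSums(F[, c("T.cells.CD8", "T.cells.CD4", "Tregs"),
                   drop = FALSE])
  cd8 <- F[["T.cells.CD8"]]
  if (stats::sd(cd3) == 0 && stats::sd(cd8) == 0)
    warning("all fractions identical; every sample is Lo-Lo")
  data.frame(Sample = F$Sample, CD3 = unname(cd3), CD8 = cd8,
             class = dichotomize_two(cd3, cd8, group),
             stringsAsFactors = FALSE)
}

#' Deconvolution-based T and B cell (TB) score classes
#'
#' As [immunoscore_classes()], with B cell and CD8+ T cell fractions as
#' the two markers.
#'
#' @inheritParams immunoscore_classes
#' @return Data frame with `Sample`, `B`, `CD8`, and `class`.
#' @export
tb_score_classes <- function(F, group = NULL) {
  if (nrow(F) < 2) stop("need at least two samples to dichotomize")
  b <- F[["B.cells"]]
  cd8 <- F[["T.cells.CD8"]]
  data.frame(Sample = F$Sample, B = b, CD8 = cd8,
             class = dichotomize_two(b, cd8, group),
             stringsAsFactors = FALSE)
}

#' Benchmarking metrics: Pearson correlation and RMSE
#'
#' `RMSE = sqrt(mean((est - truth)^2))`; Pearson r is `NA` (reported as
#' missing) when the truth is constant.
#'
#' @param est,truth Equal-length numeric vectors (length >= 2).
#' @return List with `pearson_r` and `RMSE`.
#' @export
metrics <- function(est, truth) {
  stopifnot(length(est) == length(truth), length(est) >= 2)
  r <- if (stats::sd(truth) == 0 || stats::sd(est) == 0) NA_real_
       else stats::cor(est, truth)
  list(pearson_r = r, RMSE = sqrt(mean((est - truth)^2)))
}
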