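# Deconvolution of cell fractions: constrained least squares per
# sample, Treg dropout heuristic, mRNA-content correction, "Other"
# fraction estimation, and scaling to cell densities.

#' Regulatory T cell dropout heuristic
#'
#' Treg and non-regulatory CD4+ T cell signatures are nearly collinear,
#' which can drive low-abundance Treg estimates to zero. When the
#' initial Treg fraction falls below `threshold`, the regression is
#' re-solved with the CD4 column removed; the final Treg fraction is the
#' mean of both estimates, the CD4 fraction is reduced by that amount
#' (floored at zero), and the adjusted immune fractions are rescaled so
#' their sum matches the pre-adjustment immune sum.
#'
#' @param S Signature matrix restricted to the shared genes.
#' @param m Mixture vector over the same genes.
#' @param F1 Raw fractions from [solve_constrained_lsq()] with full `S`.
#' @param threshold Trigger threshold on the initial Treg fraction
#'   (default 0.02).
#' @return List with `fractions` (adjusted raw fractions), `adjusted`
#'   (logical), and the audit fields `F1_reg`, `F2_reg`, `F_reg`,
#'   `F_CD4` (NA when not triggered).
#' @export
apply_treg_heuristic <- function(S, m, F1, threshold = 0.02) {
  out <- list(fractions = F1, adjusted = FALSE, F1_reg = NA_real_,
              F2_reg = NA_real_, F_reg = NA_real_, F_CD4 = NA_real_)
  if (!all(c("Tregs", "T.cells.CD4") %in% colnames(S))) {
    warning("Treg heuristic skipped: Tregs or T.cells.CD4 column absent")
    return(out)
  }
  F1_reg <- F1[["Tregs"]]
  out$F1_reg <- F1_reg
  if (F1_reg >= threshold) return(out)
  S2 <- S[, colnames(S) != "T.cells.CD4", drop = FALSE]
  F2 <- solve_constrained_lsq(S2, m)
  F2_reg <- F2[["Tregs"]]
  F_reg <- mean(c(F1_reg, F2_reg))
  F_CD4 <- max(F1[["T.cells.CD4"]] - F_reg, 0)
  adj <- F1
  adj[["Tregs"]] <- F_reg
  adj[["T.cells.CD4"]] <- F_CD4
  s1 <- sum(F1)
  s2 <- sum(adj)
  if (s2 > 0) adj <- adj * s1 / s2
  out$fractions <- adj
  out$adjusted <- TRUE
  out$F2_reg <- F2_reg
  out$F_reg <- F_reg
  out$F_CD4 <- F_CD4
  out
}

#' Correct cell fractions for per-type mRNA content
#'
#' Cells differ in average mRNA content, so regression fractions
#' estimated from mRNA mixtures are biased as estimates of cell
#' fractions. Each fraction is divided by its scaling factor,
#' `F'_c = F_c / n_c`, then the corrected fractions are rescaled to
#' preserve the total immune fraction: `F''_c = F'_c * f / f'` with
#' `f = sum(F_c)` and `f' = sum(F'_c)`.
#'
#' @param F Named non-negative raw fractions.
#' @param n Named positive scaling factors (matched by cell type; types
#'   missing from `n` get factor 1).
#' @return Corrected fractions `F''` with `sum(F'') == sum(F)`.
#' @export
normalize_mrna_content <- function(F, n) {
  if (any(F < 0)) stop("fractions must be non-negative")
  nc <- rep(1, length(F))
  names(nc) <- names(F)
  if (!is.null(names(n))) {
    shared <- intersect(names(F), names(n))
    nc[shared] <- n[shared]
  } else {
    stopifnot(length(n) == length(F))
    nc[] <- n
  }
  if (any(nc <= 0)) stop("scaling factors must be positive")
  Fp <- F / nc
  f <- sum(F)
  fp <- sum(Fp)
  if (fp == 0) return(F * 0)
  Fp * f / fp
}

#' Fraction of uncharacterized ("Other") cells
#'
#' The remainder of the sample not attributed to any signature cell
#' type: `F_other = 1 - sum(F'')`, clipped at zero against roundoff.
#' These estimates are deliberately not mRNA-rescaled, as the
#' uncharacterized population has unknown mRNA content.
#'
#' @param F_corrected Corrected fractions `F''`.
#' @return Scalar `F_other >= 0`.
#' @export
estimate_other_fraction <- function(F_corrected) {
  max(1 - sum(F_corrected), 0)
}

#' Default mRNA scaling factors
#'
#' Per-cell-type scaling factors shipped with the package, derived from
#' the median expression of the PSMB2 housekeeping gene per cell type in
#' the bundled synthetic compendium (see [make_fixtures()]). These are
#' synthetic stand-in values; for real analyses supply factors computed
#' from a suitable compendium with [mrna_scaling_factors()].
#'
#' @return Named numeric vector over [immune_cell_types()].
#' @export
default_mrna_scaling <- function() {
  path <- system.file("extdata", "mrna_scaling_synthetic.tsv",
                      package = "immunofrac")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(df$scaling, df$cell_type)
}

#' mRNA scaling factors from a compendium housekeeping gene
#'
#' Computes `n_c` as the median expression of a housekeeping gene
#' (PSMB2 by default) across the libraries of each immune cell type,
#' normalized to mean 1 across types.
#'
#' @param C A [labeled_compendium()] containing the housekeeping gene.
#' @param gene Housekeeping gene symbol.
#' @return Named numeric vector of positive scaling factors.
#' @export
mrna_scaling_factors <- function(C, gene = "PSMB2") {
  if (!(gene %in% rownames(C$expr)))
    stop("housekeeping gene ", gene, " absent from compendium")
  types <- intersect(immune_cell_types(), unique(C$cell_type))
  n <- vapply(types, function(ct)
    stats::median(C$expr[gene, C$cell_type == ct]), numeric(1))
  n / mean(n)
}

#' Deconvolute immune cell fractions from a mixture matrix
#'
#' Per sample: the signature (after blacklists) is restricted to the
#' genes present in the mixture matrix (`G*`), the constrained
#' least-squares system is solved, the Treg heuristic applied, fractions
#' are corrected for mRNA content (unless disabled), and the remainder
#' is reported as `Other`.
#'
#' @param M Mixture expression matrix (genes x samples), prepared with
#'   the io layer. With `arrays = TRUE` the matrix is first
#'   quantile-normalized (and unlogged when a log2 scale is suspected).
#' @param S Signature matrix; defaults to the bundled synthetic
#'   TIL10-style matrix.
#' @param tumor Apply the tumor gene blacklist (recommended for bulk
#'   tumor RNA-seq).
#' @param arrays Input is microarray data.
#' @param rmgenes `"default"`, `"none"`, or a path; when `NULL` the
#'   platform default is used (`"default"` for RNA-seq, `"none"` for
#'   arrays, which often lack signature genes).
#' @param mrna_scale Correct for mRNA content per cell type.
#' @param scaling Named scaling factors `n_c`; defaults to
#'   [default_mrna_scaling()] when `mrna_scale` is `TRUE`.
#' @param aliases Optional alias map applied to `M` before matching.
#' @return A fraction table: data frame with `Sample`, one column per
#'   cell type, and `Other`; rows sum to 1. Audit fields (raw fractions
#'   and Treg adjustment) are attached as attribute `audit`.
#' @export
deconvolute <- function(M, S = til10_synthetic(), tumor = FALSE,
                        arrays = FALSE, rmgenes = NULL, mrna_scale = TRUE,
                        scaling = NULL, aliases = NULL) {
  if (is.null(rmgenes)) rmgenes <- if (arrays) "none" else "default"
  if (arrays) {
    M <- new_expr_matrix(M, "microarray",
                         if (max(M) < 50) "log2-suspected" else "linear")
    M <- prepare_microarray(M)
  }
  M <- reannotate_and_collapse(M, aliases)
  M <- renormalize_tpm(M)
  S <- apply_gene_blacklists(S, rmgenes = rmgenes, tumor = tumor)
  shared <- intersect(rownames(S), rownames(M))
  if (length(shared) < ncol(S))
    stop("insufficient signature coverage: only ", length(shared),
         " signature genes present in the mixture matrix")
  if (length(shared) < 0.8 * nrow(S))
    warning("only ", length(shared), " of ", nrow(S),
            " signature genes present in the mixture matrix")
  Sg <- S[shared, , drop = FALSE]
  types <- colnames(S)
  if (is.null(scaling) && mrna_scale) scaling <- default_mrna_scaling()
  if (!mrna_scale) scaling <- stats::setNames(rep(1, length(types)), types)
  samples <- colnames(M)
  rows <- vector("list", length(samples))
  audit <- vector("list", length(samples))
  ok <- logical(length(samples))
  for (j in seq_along(samples)) {
    res <- tryCatch({
      m <- M[shared, j]
      F1 <- solve_constrained_lsq(Sg, m)
      th <- apply_treg_heuristic(Sg, m, F1)
      Fpp <- normalize_mrna_content(th$fractions, scaling)
      other <- estimate_other_fraction(Fpp)
      tot <- sum(Fpp) + other
      list(fractions = c(Fpp, Other = other) / tot,
           audit = c(list(raw = F1), th[c("adjusted", "F1_reg", "F2_reg",
                                          "F_reg", "F_CD4")]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("sample ", samples[j], " failed: ", conditionMessage(res))
    } else {
      rows[[j]] <- res$fractions
      audit[[j]] <- res$audit
      ok[j] <- TRUE
    }
  }
  if (!any(ok)) stop("deconvolution failed for every sample")
  tab <- do.call(rbind, rows[ok])
  out <- data.frame(Sample = samples[ok], tab, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(audit) <- samples
  attr(out, "audit") <- audit[ok]
  out
}

#' Scale deconvoluted fractions to cell densities
#'
#' Multiplies each sample's fractions (including `Other`) by its total
#' cell density (cells per square millimetre), typically the median
#' number of nuclei per mm^2 across tissue images of the sample.
#'
#' @param F Fraction table from [deconvolute()].
#' @param total_cells Named numeric vector (sample -> total cells/mm^2)
#'   or data frame with columns `Sample`, `total`.
#' @return Data frame of densities; samples without a density are
#'   excluded with a warning.
#' @export
scale_to_densities <- function(F, total_cells) {
  if (is.data.frame(total_cells))
    total_cells <- stats::setNames(total_cells$total, total_cells$Sample)
  if (any(total_cells < 0, na.rm = TRUE))
    stop("total cell densities must be non-negative")
  have <- F$Sample %in% names(total_cells)
  if (any(!have))
    warning("samples without a total density excluded: ",
            paste(F$Sample[!have], collapse = ", "))
  F <- F[have, , drop = FALSE]
  tot <- total_cells[F$Sample]
  out <- F
  num <- setdiff(colnames(F), "Sample")
  out[num] <- F[num] * tot
  out$total_density <- unname(tot)
  out
}
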