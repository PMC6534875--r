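# Signature matrix construction: a labeled expression compendium is
# distilled into a genes x cell-types matrix of median expression
# profiles through a cascade of marker-selection filters, followed by
# curated/tumor gene blacklists.

#' Construct a labeled expression compendium
#'
#' Bundles a prepared (TPM-normalized) expression matrix with one
#' cell-type label and one dataset-of-origin label per library.
#'
#' @param expr Expression matrix (genes x libraries).
#' @param cell_type Character vector, one label per library; the ten
#'   immune labels of [immune_cell_types()] plus optionally `"Tumor"`.
#' @param dataset Optional character vector of dataset IDs per library.
#' @return List of class `labeled_compendium`.
#' @export
labeled_compendium <- function(expr, cell_type,
                               dataset = rep("d1", ncol(expr))) {
  expr <- as.matrix(expr)
  stopifnot(length(cell_type) == ncol(expr),
            length(dataset) == ncol(expr))
  structure(list(expr = expr, cell_type = as.character(cell_type),
                 dataset = as.character(dataset)),
            class = "labeled_compendium")
}

immune_libs <- function(C) C$cell_type %in% immune_cell_types()

#' Three-bin quantization of gene expression
#'
#' Per gene, assigns every library to a low/medium/high bin by an
#' exhaustive search for the two thresholds that minimize the total
#' within-bin sum of squares of `log2(x + 1)` values. Bins are monotone
#' in expression by construction; genes with (near-)constant expression
#' are assigned all-low.
#'
#' @param C A [labeled_compendium()] (or a plain matrix).
#' @return Integer matrix of the same shape, values 1 (low), 2 (medium),
#'   3 (high).
#' @export
quantize_expression <- function(C) {
  X <- if (inherits(C, "labeled_compendium")) C$expr else as.matrix(C)
  L <- log2(X + 1)
  bins <- matrix(1L, nrow(L), ncol(L), dimnames = dimnames(L))
  n <- ncol(L)
  if (n < 3) return(bins)
  for (g in seq_len(nrow(L))) {
    v <- L[g, ]
    if (max(v) - min(v) < 1e-9) next  # constant: all low
    ord <- order(v)
    s <- v[ord]
    cs <- cumsum(s)
    cs2 <- cumsum(s^2)
    # within-bin SS for s[(a+1)..b]
    ss <- function(a, b) {
      sum_ <- cs[b] - if (a > 0) cs[a] else 0
      sum2 <- cs2[b] - if (a > 0) cs2[a] else 0
      sum2 - sum_^2 / (b - a)
    }
    best <- Inf
    bi <- 1L
    bj <- 2L
    for (i in 1L:(n - 2L)) {
      for (j in (i + 1L):(n - 1L)) {
        tot <- ss(0L, i) + ss(i, j) + ss(j, n)
        if (tot < best - 1e-12) {
          best <- tot
          bi <- i
          bj <- j
        }
      }
    }
    b <- integer(n)
    b[ord[seq_len(bi)]] <- 1L
    b[ord[(bi + 1L):bj]] <- 2L
    b[ord[(bj + 1L):n]] <- 3L
    bins[g, ] <- b
  }
  bins
}

#' Select cell-type-specific candidate marker genes
#'
#' A gene is a candidate marker for cell type `c` iff its quantized
#' expression is high in every library of `c` and low or medium in every
#' other library (immune or tumor). This criterion is exclusive: a gene
#' can own at most one cell type.
#'
#' @param bins Integer bin matrix from [quantize_expression()].
#' @param cell_type Character vector of per-library labels.
#' @return Named character vector: names are candidate genes, values the
#'   owner cell type.
#' @export
select_cell_specific_genes <- function(bins, cell_type) {
  types <- intersect(immune_cell_types(), unique(cell_type))
  owner <- character(0)
  for (ct in types) {
    in_ct <- cell_type == ct
    cand <- rownames(bins)[
      rowSums(bins[, in_ct, drop = FALSE] == 3L) == sum(in_ct) &
      rowSums(bins[, !in_ct, drop = FALSE] >= 3L) == 0L]
    if (length(cand) > 0) {
      o <- rep(ct, length(cand))
      names(o) <- cand
      owner <- c(owner, o)
    }
  }
  if (anyDuplicated(names(owner)))
    stop("a gene was selected for more than one cell type; ",
         "the exclusivity criterion should forbid this")
  owner
}

#' Remove genes detected in fewer than two immune libraries
#'
#' Detection means expression strictly greater than zero.
#'
#' @param C A [labeled_compendium()].
#' @return Compendium restricted to detected genes.
#' @export
filter_detected <- function(C) {
  imm <- C$expr[, immune_libs(C), drop = FALSE]
  keep <- rowSums(imm > 0) >= 2
  labeled_compendium(C$expr[keep, , drop = FALSE], C$cell_type, C$dataset)
}

#' Filter candidates by expression in tumors
#'
#' Removes genes with median log2 expression above 7 in all provided
#' cancer cell lines, and genes with mean bulk-tumor expression below
#' 1 TPM (too little support for deconvolution of tumor tissue).
#'
#' @param genes Character vector (or named owner vector) of candidates.
#' @param ccle_summary Matrix or data frame of per-gene (rows), per-line
#'   (columns) median log2 expression; rownames are gene symbols.
#' @param tcga_summary Named numeric vector of per-gene mean TPM across
#'   bulk tumors.
#' @return The filtered gene vector (names/owners preserved).
#' @export
filter_tumor_expression <- function(genes, ccle_summary, tcga_summary) {
  sym <- if (is.null(names(genes))) genes else names(genes)
  ccle <- as.matrix(ccle_summary)
  drop <- logical(length(sym))
  miss_c <- !(sym %in% rownames(ccle))
  miss_t <- !(sym %in% names(tcga_summary))
  if (any(miss_c | miss_t))
    warning("genes missing from tumor summaries retained: ",
            paste(utils::head(sym[miss_c | miss_t], 5), collapse = ", "))
  in_c <- which(!miss_c)
  if (length(in_c) > 0) {
    cc <- ccle[sym[in_c], , drop = FALSE]
    drop[in_c] <- drop[in_c] | (rowSums(cc > 7) == ncol(cc))
  }
  in_t <- which(!miss_t)
  drop[in_t] <- drop[in_t] | (tcga_summary[sym[in_t]] < 1)
  genes[!drop]
}

#' Filter candidates against a gene-set compendium
#'
#' A candidate is removed when it appears in a gene set tagged with a
#' different cell type. Gene sets tagged `T.cells.CD4` are not used to
#' filter `Tregs` candidates, because bona fide Treg markers (FOXP3 and
#' the like) also occur in CD4+ T cell sets.
#'
#' @param owner Named character vector: gene -> owner cell type.
#' @param gene_sets Data frame with columns `set`, `cell_type`, `gene`
#'   (long format; see [read_gene_sets()]).
#' @return Filtered owner vector.
#' @export
filter_specificity <- function(owner, gene_sets) {
  if (length(owner) == 0 || nrow(gene_sets) == 0) return(owner)
  drop <- vapply(seq_along(owner), function(i) {
    g <- names(owner)[i]
    ct <- owner[i]
    hits <- gene_sets[gene_sets$gene == g, , drop = FALSE]
    if (nrow(hits) == 0) return(FALSE)
    other <- hits$cell_type != ct
    if (ct == "Tregs") other <- other & hits$cell_type != "T.cells.CD4"
    any(other)
  }, logical(1))
  owner[!drop]
}

#' Read a gene-set compendium from a GMT-like TSV
#'
#' Each line: set name, cell-type tag, then one gene symbol per field.
#'
#' @param path Path to the file.
#' @return Long-format data frame with columns `set`, `cell_type`,
#'   `gene`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("gene set line with no genes: ", f[1])
    data.frame(set = f[1], cell_type = f[2], gene = f[-(1:2)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Filter candidates by expression range
#'
#' Highly expressed genes dominate the least-squares objective; genes
#' whose expression exceeds 700 TPM in any library are removed (strict
#' inequality: a peak of exactly 700 survives).
#'
#' @param owner Named owner vector.
#' @param C A [labeled_compendium()].
#' @return Filtered owner vector.
#' @export
filter_range <- function(owner, C) {
  if (length(owner) == 0) return(owner)
  mx <- apply(C$expr[names(owner), , drop = FALSE], 1, max)
  owner[mx <= 700]
}

#' Filter candidates by correlation with true cell fractions
#'
#' Using simulated mixtures with known composition, keeps a candidate of
#' type `c` iff the Pearson correlation between its expression across
#' mixtures and the true fraction of `c` is at least 0.6. Genes with
#' zero expression variance across mixtures are removed with a warning.
#'
#' @param owner Named owner vector.
#' @param mix_expr Expression matrix (genes x mixtures).
#' @param mix_fractions True fraction matrix (cell types x mixtures).
#' @param min_r Correlation threshold (default 0.6).
#' @return Filtered owner vector.
#' @export
filter_fraction_correlation <- function(owner, mix_expr, mix_fractions,
                                        min_r = 0.6) {
  if (length(owner) == 0) return(owner)
  keep <- vapply(seq_along(owner), function(i) {
    g <- names(owner)[i]
    if (!(g %in% rownames(mix_expr))) return(FALSE)
    x <- mix_expr[g, ]
    f <- mix_fractions[owner[i], ]
    if (stats::sd(x) == 0) {
      warning("zero-variance expression across mixtures: ", g)
      return(FALSE)
    }
    stats::cor(x, f) >= min_r
  }, logical(1))
  owner[keep]
}

#' Filter candidates by restricted expression in external data sets
#'
#' For each gene `g` with owner type `c` and each external labeled data
#' set `d`, computes `R_gd`: the median expression over libraries of `c`
#' divided by the median over libraries not of `c` (a zero denominator
#' yields +Inf). Genes are ranked per cell type by `median_d(R_gd)`; the
#' top `top_n` with a median ratio of at least `min_ratio` survive. Ties
#' at the boundary break lexicographically by gene symbol. For Treg
#' candidates, CD4+ T cell libraries are excluded from the denominator,
#' and an additional Treg-versus-CD4 pass (ratio of Treg median over CD4
#' median, threshold `treg_min_ratio`) is applied in data sets carrying
#' both types.
#'
#' @param owner Named owner vector.
#' @param external List of [labeled_compendium()] objects.
#' @param top_n Per-type cap on retained genes (default 30).
#' @param min_ratio Threshold on the median ratio (default 2).
#' @param treg_min_ratio Threshold for the Treg-vs-CD4 pass (default 1).
#' @return Filtered owner vector.
#' @export
filter_restricted_expression <- function(owner, external, top_n = 30,
                                         min_ratio = 2, treg_min_ratio = 1) {
  if (length(owner) == 0) return(owner)
  ratio_in_dataset <- function(g, ct, D, exclude_cd4 = FALSE) {
    if (!(g %in% rownames(D$expr))) return(NA_real_)
    in_ct <- D$cell_type == ct
    out_ct <- !in_ct
    if (exclude_cd4) out_ct <- out_ct & D$cell_type != "T.cells.CD4"
    if (!any(in_ct) || !any(out_ct)) return(NA_real_)
    num <- stats::median(D$expr[g, in_ct])
    den <- stats::median(D$expr[g, out_ct])
    if (den == 0) return(Inf)
    num / den
  }
  med_ratio <- vapply(seq_along(owner), function(i) {
    g <- names(owner)[i]
    ct <- owner[i]
    rs <- vapply(external, ratio_in_dataset, numeric(1), g = g, ct = ct,
                 exclude_cd4 = identical(ct, "Tregs"))
    rs <- rs[!is.na(rs)]
    if (length(rs) == 0) return(NA_real_)
    stats::median(rs)
  }, numeric(1))
  keep <- rep(FALSE, length(owner))
  for (ct in unique(owner)) {
    idx <- which(owner == ct & !is.na(med_ratio) & med_ratio >= min_ratio)
    if (length(idx) == 0) next
    ord <- idx[order(-med_ratio[idx], names(owner)[idx])]
    keep[utils::head(ord, top_n)] <- TRUE
  }
  out <- owner[keep]
  # extra Treg-vs-CD4 pass
  treg <- which(out == "Tregs")
  if (length(treg) > 0) {
    ok <- vapply(treg, function(i) {
      g <- names(out)[i]
      rs <- vapply(external, function(D) {
        tr <- D$cell_type == "Tregs"
        cd4 <- D$cell_type == "T.cells.CD4"
        if (!(g %in% rownames(D$expr)) || !any(tr) || !any(cd4))
          return(NA_real_)
        den <- stats::median(D$expr[g, cd4])
        if (den == 0) return(Inf)
        stats::median(D$expr[g, tr]) / den
      }, numeric(1))
      rs <- rs[!is.na(rs)]
      length(rs) == 0 || stats::median(rs) >= treg_min_ratio
    }, logical(1))
    if (any(!ok)) out <- out[-treg[!ok]]
  }
  out
}

#' Aggregate median expression profiles into a signature matrix
#'
#' For every selected gene and immune cell type, the signature entry is
#' the median of the (TPM-normalized) expression values over all
#' libraries of that type.
#'
#' @param C A [labeled_compendium()].
#' @param genes Selected signature genes (character or named owner
#'   vector).
#' @return Numeric signature matrix (genes x cell types present in `C`).
#' @export
build_signature_profiles <- function(C, genes) {
  sym <- if (is.null(names(genes))) genes else names(genes)
  types <- intersect(immune_cell_types(), unique(C$cell_type))
  S <- vapply(types, function(ct) {
    libs <- C$cell_type == ct
    apply(C$expr[sym, libs, drop = FALSE], 1, stats::median)
  }, numeric(length(sym)))
  S <- matrix(S, nrow = length(sym),
              dimnames = list(sym, types))
  S
}

#' Apply curated and tumor gene blacklists to a signature matrix
#'
#' `rmgenes = "default"` removes the curated 17 variable-expression
#' genes; `rmgenes = "none"` leaves the matrix untouched; a file path
#' reads a custom one-symbol-per-line list. `tumor = TRUE` additionally
#' removes the 17 genes over-expressed in bulk tumor RNA-seq.
#' Blacklisted genes absent from the matrix are silently skipped.
#'
#' @param S Signature matrix (genes x cell types).
#' @param rmgenes `"default"`, `"none"`, or a file path.
#' @param tumor Logical; apply the tumor blacklist as well.
#' @return Reduced signature matrix.
#' @export
apply_gene_blacklists <- function(S, rmgenes = "default", tumor = FALSE) {
  black <- character(0)
  if (identical(rmgenes, "default")) {
    black <- .rmgenes_default
  } else if (!identical(rmgenes, "none")) {
    black <- readLines(rmgenes)
    black <- trimws(black[nzchar(trimws(black))])
  }
  if (isTRUE(tumor)) black <- union(black, .rmgenes_tumor)
  S[!(rownames(S) %in% black), , drop = FALSE]
}

#' Condition number of a signature matrix
#'
#' Ratio of the largest to the smallest singular value of the
#' linear-scale matrix; lower values indicate a better-posed
#' deconvolution. Rank-deficient matrices report +Inf with a warning.
#'
#' @param S Signature matrix with at least as many genes as cell types.
#' @return Positive real (possibly `Inf`).
#' @export
condition_number <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) < ncol(S))
    stop("signature needs at least as many genes as cell types")
  d <- svd(S, nu = 0, nv = 0)$d
  if (min(d) <= 1e-12 * max(d)) {
    warning("rank-deficient signature matrix; condition number is Inf")
    return(Inf)
  }
  max(d) / min(d)
}

#' Full signature construction pipeline
#'
#' Runs the complete filter cascade on a labeled compendium: detection
#' prefilter, three-bin quantization, cell-specific selection, tumor
#' expression filter, gene-set specificity filter, expression-range
#' filter, fraction-correlation filter (when simulated mixtures are
#' supplied), restricted-expression filter (when external data sets are
#' supplied), then median profile aggregation.
#'
#' @param C A [labeled_compendium()].
#' @param ccle_summary,tcga_summary Tumor expression summaries (see
#'   [filter_tumor_expression()]); `NULL` skips the filter.
#' @param gene_sets Gene-set compendium data frame; `NULL` skips.
#' @param mixtures List with `expr` and `fractions` for the correlation
#'   filter; `NULL` skips.
#' @param external List of labeled external data sets for the
#'   restricted-expression filter; `NULL` skips.
#' @return List with `signature` (the matrix), `owner` (gene -> type),
#'   and `report` (per-gene per-stage survival flags).
#' @export
build_signature <- function(C, ccle_summary = NULL, tcga_summary = NULL,
                            gene_sets = NULL, mixtures = NULL,
                            external = NULL) {
  C <- filter_detected(C)
  bins <- quantize_expression(C)
  owner <- select_cell_specific_genes(bins, C$cell_type)
  report <- data.frame(gene = names(owner), owner = unname(owner),
                       candidate = TRUE, stringsAsFactors = FALSE)
  stage <- function(owner, nm) {
    report[[nm]] <<- report$gene %in% names(owner)
    owner
  }
  if (!is.null(ccle_summary) && !is.null(tcga_summary))
    owner <- stage(filter_tumor_expression(owner, ccle_summary,
                                           tcga_summary), "tumor_expr")
  if (!is.null(gene_sets))
    owner <- stage(filter_specificity(owner, gene_sets), "specificity")
  owner <- stage(filter_range(owner, C), "range")
  if (!is.null(mixtures))
    owner <- stage(filter_fraction_correlation(owner, mixtures$expr,
                                               mixtures$fractions),
                   "fraction_cor")
  if (!is.null(external))
    owner <- stage(filter_restricted_expression(owner, external),
                   "restricted")
  list(signature = build_signature_profiles(C, owner),
       owner = owner, report = report)
}

#' Read a signature matrix from TSV
#'
#' First column `GENE`, remaining columns one per cell type.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix (genes x cell types).
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  S <- as.matrix(df[, -1, drop = FALSE])
  rownames(S) <- df[[1]]
  storage.mode(S) <- "double"
  S
}
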