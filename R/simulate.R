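# In-silico mixture simulation: known cell fractions, tumor purity,
# sequencing-depth effects, and the leave-K-out validation design.

#' Draw a random immune cell composition at a given tumor purity
#'
#' Immune fractions are sampled uniformly on [0, 1] and renormalized so
#' they sum to `1 - purity`; the tumor fraction equals the purity.
#'
#' @param n_types Number of immune cell types.
#' @param purity Tumor fraction in [0, 1].
#' @param type_names Optional names for the immune fractions.
#' @return Named numeric vector of `n_types` immune fractions plus
#'   `Tumor`; sums to 1.
#' @export
simulate_fractions <- function(n_types = 10, purity = 0,
                               type_names = immune_cell_types()) {
  stopifnot(purity >= 0, purity <= 1)
  u <- stats::runif(n_types)
  f <- if (purity < 1) u / sum(u) * (1 - purity) else numeric(n_types)
  names(f) <- type_names[seq_len(n_types)]
  c(f, Tumor = purity)
}

#' Simulate a bulk mixture expression profile
#'
#' The expected profile is the fraction-weighted sum of per-type
#' expression profiles, `sum_c truth_c * profile_c`. Finite sequencing
#' depth is emulated by resampling gene counts from a multinomial with
#' `depth` trials over the expected profile, then converting back to
#' TPM; `depth = Inf` returns the exact linear mixture.
#'
#' @param profiles Expression matrix (genes x cell types, TPM scale);
#'   column names must cover the names of `truth`.
#' @param truth Named fraction vector (see [simulate_fractions()]).
#' @param depth Read pairs (> 0) or `Inf`.
#' @return Named numeric vector of TPM values (sums to 10^6).
#' @export
simulate_mixture <- function(profiles, truth, depth = Inf) {
  stopifnot(all(names(truth) %in% colnames(profiles)))
  if (!is.infinite(depth) && depth <= 0) stop("depth must be positive")
  mix <- drop(as.matrix(profiles[, names(truth), drop = FALSE]) %*% truth)
  mix <- mix / sum(mix) * 1e6
  if (is.infinite(depth)) return(mix)
  counts <- stats::rmultinom(1, size = depth, prob = mix)[, 1]
  counts / depth * 1e6
}

#' Enumerate the simulation benchmark design
#'
#' Every mixture is simulated at each purity with the base depth, and
#' additionally at each non-base depth at the anchor purity. With the
#' default settings (100 mixtures, purities 0 to 1 in steps of 0.1,
#' depths 1, 2, 5, 10, 20, 50, 100 million read pairs, anchor purity
#' 0.6) this enumerates 1700 data sets.
#'
#' @param n_mixtures Number of random immune compositions.
#' @param purities Tumor purity grid.
#' @param depths Sequencing-depth grid (read pairs); the smallest is the
#'   base depth used across the purity grid.
#' @param anchor_purity Purity at which the depth series is simulated;
#'   must belong to `purities`.
#' @return Data frame with columns `mixture`, `purity`, `depth`.
#' @export
generate_design <- function(n_mixtures = 100,
                            purities = seq(0, 1, by = 0.1),
                            depths = c(1, 2, 5, 10, 20, 50, 100) * 1e6,
                            anchor_purity = 0.6) {
  stopifnot(all(purities >= 0 & purities <= 1), all(depths > 0))
  if (!any(abs(purities - anchor_purity) < 1e-12))
    stop("anchor purity is not in the purity grid")
  base_depth <- min(depths)
  grid1 <- expand.grid(mixture = seq_len(n_mixtures), purity = purities,
                       KEEP.OUT.ATTRS = FALSE)
  grid1$depth <- rep(base_depth, nrow(grid1))
  extra <- setdiff(depths, base_depth)
  if (length(extra) > 0) {
    grid2 <- expand.grid(mixture = seq_len(n_mixtures), depth = extra,
                         KEEP.OUT.ATTRS = FALSE)
    grid2$purity <- anchor_purity
    out <- rbind(grid1[, c("mixture", "purity", "depth")],
                 grid2[, c("mixture", "purity", "depth")])
  } else {
    out <- grid1[, c("mixture", "purity", "depth")]
  }
  rownames(out) <- NULL
  out
}

#' Leave-K-out validation on a labeled compendium
#'
#' For each simulated mixture, one library per cell type (plus the
#' tumor library, when present) is drawn to compose the mixture; the
#' signature matrix is then rebuilt from the remaining libraries only
#' (detection prefilter, quantization, cell-specific selection, range
#' filter, median profiles), so the mixture's libraries never inform the
#' signature. Deconvolution runs without mRNA scaling because the true
#' fractions are mRNA (TPM-mixing) fractions.
#'
#' @param C A [labeled_compendium()] with at least two libraries per
#'   immune type; a `"Tumor"` library provides the tumor profile.
#' @param design Data frame from [generate_design()] (columns `mixture`,
#'   `purity`, `depth`).
#' @return List with `estimates` and `truth` (cell types x runs) and
#'   `by_type`: per-type Pearson r and RMSE across runs.
#' @export
leave_k_out_validate <- function(C, design) {
  types <- intersect(immune_cell_types(), unique(C$cell_type))
  if (nrow(design) == 0) {
    empty <- matrix(numeric(0), nrow = length(types), ncol = 0,
                    dimnames = list(types, NULL))
    return(list(estimates = empty, truth = empty,
                by_type = data.frame(cell_type = character(0),
                                     r = numeric(0), RMSE = numeric(0))))
  }
  tumor_libs <- which(C$cell_type == "Tumor")
  mixtures <- sort(unique(design$mixture))
  # per-mixture library draw, reused across the rows of that mixture
  picks <- lapply(mixtures, function(i) {
    vapply(types, function(ct) sample(which(C$cell_type == ct), 1L),
           integer(1))
  })
  names(picks) <- as.character(mixtures)
  fracs <- lapply(mixtures, function(i)
    simulate_fractions(length(types), 0, types))
  names(fracs) <- as.character(mixtures)
  est <- matrix(NA_real_, length(types), nrow(design),
                dimnames = list(types, NULL))
  tru <- est
  for (k in seq_len(nrow(design))) {
    mi <- as.character(design$mixture[k])
    pick <- picks[[mi]]
    imm <- fracs[[mi]][types] * (1 - design$purity[k])
    profiles <- C$expr[, pick, drop = FALSE]
    colnames(profiles) <- types
    truth <- imm
    if (length(tumor_libs) > 0 && design$purity[k] > 0) {
      tpick <- tumor_libs[1]
      profiles <- cbind(profiles, Tumor = C$expr[, tpick])
      truth <- c(imm, Tumor = design$purity[k])
    }
    mix <- simulate_mixture(profiles, truth, design$depth[k])
    held_out <- c(pick, if (length(tumor_libs) > 0) tumor_libs[1])
    keep <- setdiff(seq_along(C$cell_type), held_out)
    Ck <- labeled_compendium(C$expr[, keep, drop = FALSE],
                             C$cell_type[keep], C$dataset[keep])
    if (!all(types %in% Ck$cell_type)) {
      warning("mixture ", mi, " skipped: exclusion empties a cell type")
      next
    }
    Ck <- filter_detected(Ck)
    owner <- select_cell_specific_genes(quantize_expression(Ck),
                                        Ck$cell_type)
    owner <- filter_range(owner, Ck)
    S <- build_signature_profiles(Ck, owner)
    M <- matrix(mix, ncol = 1, dimnames = list(names(mix), "mix"))
    F <- deconvolute(M, S, rmgenes = "none", mrna_scale = FALSE)
    est[, k] <- unlist(F[1, types])
    tru[, k] <- imm
  }
  done <- colSums(is.na(est)) == 0
  est <- est[, done, drop = FALSE]
  tru <- tru[, done, drop = FALSE]
  by_type <- do.call(rbind, lapply(types, function(ct) {
    m <- metrics(est[ct, ], tru[ct, ])
    data.frame(cell_type = ct, r = m$pearson_r, RMSE = m$RMSE,
               stringsAsFactors = FALSE)
  }))
  rownames(by_type) <- NULL
  list(estimates = est, truth = tru, by_type = by_type)
}

#' Embed a signature matrix into full TPM profiles
#'
#' Builds per-cell-type expression profiles on the TPM scale whose
#' restriction to the signature genes equals the signature columns: a
#' single filler gene absorbs the non-signature transcriptome mass so
#' that every column sums to 10^6. An extra all-filler `Tumor` column
#' models an uncharacterized cell population orthogonal to the
#' signature. Mixtures simulated from these profiles are exactly
#' consistent with the deconvolution model, making them a noiseless
#' recovery benchmark.
#'
#' @param S Signature matrix (genes x cell types), linear TPM scale
#'   with column sums below 10^6.
#' @param filler_gene Name of the filler row.
#' @return Expression matrix ((genes + 1) x (cell types + 1)).
#' @export
signature_to_profiles <- function(S, filler_gene = "NONSIG") {
  cs <- colSums(S)
  if (any(cs >= 1e6))
    stop("signature columns must sum to less than 10^6")
  P <- rbind(S, matrix(1e6 - cs, 1, ncol(S),
                       dimnames = list(filler_gene, colnames(S))))
  cbind(P, Tumor = c(numeric(nrow(S)), 1e6))
}
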