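# Brute-force reference for 3-bin quantization: minimal within-bin sum
# of squares over all ordered two-threshold partitions of log2(x + 1).
brute_quantize <- function(v) {
  l <- log2(v + 1)
  n <- length(l)
  ord <- order(l)
  s <- l[ord]
  best <- Inf
  best_bins <- rep(1L, n)
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      parts <- list(s[1:i], s[(i + 1):j], s[(j + 1):n])
      tot <- sum(vapply(parts, function(p) sum((p - mean(p))^2),
                        numeric(1)))
      if (tot < best - 1e-12) {
        best <- tot
        b <- integer(n)
        b[ord[1:i]] <- 1L
        b[ord[(i + 1):j]] <- 2L
        b[ord[(j + 1):n]] <- 3L
        best_bins <- b
      }
    }
  }
  best_bins
}

test_that("three-bin quantization separates clustered expression levels", {
  v <- c(0.1, 0.2, 10, 12, 500, 600)
  bins <- quantize_expression(matrix(v, 1, dimnames = list("g", NULL)))
  expect_equal(unname(bins[1, ]), c(1, 1, 2, 2, 3, 3))
  expect_equal(unname(bins[1, ]), brute_quantize(v))

  set.seed(77)
  for (i in 1:25) {
    v <- rexp(sample(5:30, 1), 1 / 50)
    bins <- quantize_expression(matrix(v, 1, dimnames = list("g", NULL)))
    expect_equal(unname(bins[1, ]), brute_quantize(v))
    # monotone in expression
    expect_true(all(diff(bins[1, order(v)]) >= 0))
  }

  const <- quantize_expression(matrix(5, 1, 8, dimnames = list("g", NULL)))
  expect_true(all(const == 1L))
})

test_that("cell-specific selection requires high in all own libraries and none elsewhere", {
  labels <- c("B.cells", "B.cells", "B.cells", "NK.cells", "NK.cells",
              "Tumor")
  bins <- rbind(
    good_b  = c(3, 3, 3, 1, 2, 1),
    both    = c(3, 3, 3, 3, 3, 1),   # high in B and NK: candidate for neither
    partial = c(3, 3, 2, 1, 1, 1),   # high in only 2 of 3 B libraries
    nk      = c(1, 2, 1, 3, 3, 1),
    tumor_hi = c(1, 1, 1, 1, 1, 3)
  )
  owner <- select_cell_specific_genes(bins, labels)
  expect_equal(owner, c(good_b = "B.cells", nk = "NK.cells"))
})

test_that("tumor-expression filter applies the all-lines and low-support rules", {
  ccle <- rbind(allhigh = c(8, 9, 10), onehigh = c(8, 3, 10),
                low = c(2, 2, 2))
  tcga <- c(allhigh = 10, onehigh = 10, low = 0.5)
  genes <- c("allhigh", "onehigh", "low")
  out <- filter_tumor_expression(genes, ccle, tcga)
  expect_equal(out, "onehigh")
  expect_warning(filter_tumor_expression(c("onehigh", "ghost"), ccle, tcga),
                 "missing")
})

test_that("gene-set specificity filter respects the Treg/CD4 exemption", {
  owner <- c(NKG1 = "NK.cells", TRG1 = "Tregs", FREE = "B.cells")
  gs <- data.frame(set = c("mono_set", "cd4_set"),
                   cell_type = c("Monocytes", "T.cells.CD4"),
                   gene = c("NKG1", "TRG1"))
  out <- filter_specificity(owner, gs)
  expect_equal(out, c(TRG1 = "Tregs", FREE = "B.cells"))
  # a Treg gene in a non-CD4 foreign set is still removed
  gs2 <- data.frame(set = "nk_set", cell_type = "NK.cells", gene = "TRG1")
  expect_equal(names(filter_specificity(owner, gs2)), c("NKG1", "FREE"))
})

test_that("expression-range filter removes only genes strictly above 700", {
  C <- labeled_compendium(
    rbind(peak800 = c(800, 1, 1), peak700 = c(700, 1, 1),
          low = c(5, 5, 5)),
    rep("B.cells", 3))
  owner <- c(peak800 = "B.cells", peak700 = "B.cells", low = "B.cells")
  expect_equal(names(filter_range(owner, C)), c("peak700", "low"))
})

test_that("fraction-correlation filter keeps informative genes at the threshold", {
  f <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  fr <- rbind(B.cells = f)
  expr <- rbind(lin = 10 * f + 2,          # exact linear function, r = 1
                flat = rep(3, 5))
  owner <- c(lin = "B.cells", flat = "B.cells")
  expect_warning(out <- filter_fraction_correlation(owner, expr, fr),
                 "zero-variance")
  expect_equal(names(out), "lin")

  set.seed(13)
  noise <- rbind(rnd = sample(10 * f))     # permuted: uncorrelated
  expect_length(filter_fraction_correlation(c(rnd = "B.cells"), noise, fr),
                0)

  # boundary is inclusive: a gene exactly at the threshold survives
  x <- 3 * scale(f)[, 1] + 4 * scale(c(1, -2, 1, 1, -1))[, 1]
  x <- x - min(x)
  r_x <- cor(x, f)
  out <- filter_fraction_correlation(c(g = "B.cells"),
                                     rbind(g = x), fr, min_r = r_x)
  expect_equal(names(out), "g")
})

test_that("restricted-expression filter ranks by median ratio with a top-30 cap", {
  types <- c(rep("B.cells", 2), rep("NK.cells", 2))
  mk <- function(vals) labeled_compendium(vals, types)
  # 40 B-cell candidates, ratios 41:2 (all >= 2): exactly 30 survive,
  # and the lowest-ratio genes are the ones dropped
  genes <- sprintf("g%02d", 1:40)
  vals <- matrix(1, 40, 4, dimnames = list(genes, NULL))
  vals[, 1:2] <- (41:2)   # in-type medians; out-type median 1
  ext <- list(mk(vals), mk(vals))
  owner <- setNames(rep("B.cells", 40), genes)
  out <- filter_restricted_expression(owner, ext)
  expect_length(out, 30)
  expect_setequal(names(out), genes[1:30])

  # ratio below 2 is removed even when slots remain
  vals2 <- matrix(1, 2, 4, dimnames = list(c("hi", "lo"), NULL))
  vals2["hi", 1:2] <- 10; vals2["hi", 3:4] <- 2      # R = 5
  vals2["lo", 1:2] <- 1.5                            # R = 1.5
  out2 <- filter_restricted_expression(
    setNames(rep("B.cells", 2), c("hi", "lo")),
    list(mk(vals2)))
  expect_equal(names(out2), "hi")

  # zero out-of-type median yields an infinite ratio (kept)
  vals3 <- matrix(0, 1, 4, dimnames = list("z", NULL))
  vals3["z", 1:2] <- 4
  expect_equal(names(filter_restricted_expression(
    setNames("B.cells", "z"), list(mk(vals3)))), "z")
})

test_that("Treg restricted-expression handling excludes CD4 and applies the extra pass", {
  types <- c("Tregs", "Tregs", "T.cells.CD4", "T.cells.CD4",
             "B.cells", "B.cells")
  # shared with CD4 (ratio vs CD4 < 1) but clean vs B cells
  vals <- rbind(shared = c(10, 10, 20, 20, 1, 1),
                clean  = c(10, 10, 4, 4, 1, 1))
  ext <- list(labeled_compendium(vals, types))
  owner <- setNames(rep("Tregs", 2), c("shared", "clean"))
  out <- filter_restricted_expression(owner, ext)
  # both pass the main ratio (CD4 excluded from the denominator), but
  # the Treg-vs-CD4 pass removes the gene dominated by CD4 expression
  expect_equal(names(out), "clean")
})

test_that("median profiles aggregate libraries per cell type", {
  C <- labeled_compendium(
    rbind(g1 = c(1, 3, 5, 9), g2 = c(2, 2, 2, 7)),
    c("B.cells", "B.cells", "B.cells", "NK.cells"))
  S <- build_signature_profiles(C, c("g1", "g2"))
  expect_equal(S["g1", "B.cells"], 3)
  expect_equal(S["g1", "NK.cells"], 9)  # single-library type
  expect_equal(S["g2", "B.cells"], 2)
})

test_that("blacklists remove exactly the listed, present genes", {
  S <- til10_synthetic()
  expect_equal(nrow(S), 170L)
  expect_equal(nrow(apply_gene_blacklists(S, "default")), 153L)
  expect_equal(apply_gene_blacklists(S, "none"), S)
  path <- tempfile()
  writeLines(c(rownames(S)[1], "NOT_A_GENE"), path)
  expect_equal(nrow(apply_gene_blacklists(S, path)), 169L)
  # tumor list overlaps the curated list in two symbols
  expect_equal(nrow(apply_gene_blacklists(S, "default", tumor = TRUE)),
               170L - length(union(gene_blacklist("default"),
                                   gene_blacklist("tumor"))))
})

test_that("condition number is the singular-value ratio", {
  expect_equal(condition_number(diag(10)), 1)
  expect_equal(condition_number(diag(c(1, 2))), 2)
  expect_warning(k <- condition_number(cbind(1:3, 2 * (1:3))),
                 "rank-deficient")
  expect_equal(k, Inf)
})

test_that("independent filters commute", {
  fx <- get_fixtures()
  C <- filter_detected(fx$compendium)
  owner <- select_cell_specific_genes(quantize_expression(C), C$cell_type)
  a <- filter_range(
    suppressWarnings(filter_tumor_expression(owner, fx$ccle_summary,
                                             fx$tcga_summary)), C)
  b <- suppressWarnings(filter_tumor_expression(
    filter_range(owner, C), fx$ccle_summary, fx$tcga_summary))
  expect_equal(a, b)
})

test_that("the full pipeline recovers planted markers with high precision", {
  fx <- get_fixtures()
  sig <- build_signature(fx$compendium, fx$ccle_summary, fx$tcga_summary,
                         fx$gene_sets, fx$mixtures, fx$external)
  sel <- names(sig$owner)
  planted <- names(fx$planted)
  expect_gte(mean(sel %in% planted), 0.9)
  expect_gte(mean(planted %in% sel), 0.9)
  # every signature gene has exactly one owner
  expect_false(anyDuplicated(sel) > 0)
  expect_setequal(rownames(sig$signature), sel)
})
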