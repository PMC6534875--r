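test_that("mRNA-content correction follows the two-step scaling equations", {
  # F' = F / n; F'' = F' * f / f' with f = sum(F), f' = sum(F')
  F <- c(A = 0.2, B = 0.2)
  n <- c(A = 1, B = 2)
  Fpp <- normalize_mrna_content(F, n)
  expect_equal(unname(Fpp), c(0.2 * 0.4 / 0.3, 0.1 * 0.4 / 0.3),
               tolerance = 1e-9)
  expect_equal(sum(Fpp), sum(F), tolerance = 1e-9)

  # unit factors are the identity; zero fractions pass through
  expect_equal(normalize_mrna_content(F, c(A = 1, B = 1)), F)
  expect_equal(unname(normalize_mrna_content(c(A = 0, B = 0), n)), c(0, 0))
  expect_error(normalize_mrna_content(F, c(A = 0, B = 1)), "positive")
})

test_that("the Other fraction is the clipped complement", {
  expect_equal(estimate_other_fraction(c(0.1, 0.3)), 0.6)
  expect_equal(estimate_other_fraction(c(0.5, 0.5)), 0)
  expect_equal(estimate_other_fraction(c(0.5, 0.5 + 1e-12)), 0)
})

test_that("the Treg heuristic triggers exactly below the 0.02 threshold", {
  S <- til10_synthetic()
  types <- immune_cell_types()

  # high-Treg mixture: untouched
  f_hi <- setNames(rep(0.08, 10), types)
  f_hi["Tregs"] <- 0.05
  m <- drop(S %*% f_hi)
  F1 <- solve_constrained_lsq(S, m)
  th <- apply_treg_heuristic(S, m, F1)
  expect_false(th$adjusted)
  expect_equal(th$fractions, F1)

  # low-Treg mixture: re-solve without CD4, average, and rescale
  f_lo <- f_hi
  f_lo["Tregs"] <- 0.005
  m <- drop(S %*% f_lo)
  F1 <- solve_constrained_lsq(S, m)
  expect_lt(F1[["Tregs"]], 0.02)
  th <- apply_treg_heuristic(S, m, F1)
  expect_true(th$adjusted)
  F2 <- solve_constrained_lsq(S[, colnames(S) != "T.cells.CD4"], m)
  expect_equal(th$F2_reg, F2[["Tregs"]])
  expect_equal(th$F_reg, mean(c(F1[["Tregs"]], F2[["Tregs"]])))
  expect_equal(th$F_CD4, max(F1[["T.cells.CD4"]] - th$F_reg, 0))
  # the adjusted immune sum is preserved
  expect_equal(sum(th$fractions), sum(F1), tolerance = 1e-9)

  # constructed audit arithmetic: mean and floored difference
  expect_equal(mean(c(0.01, 0.03)), 0.02)
  expect_equal(max(0.015 - 0.02, 0), 0)

  expect_warning(out <- apply_treg_heuristic(S[, 1:3], m[1:3] * 0,
                                             c(0, 0, 0)), "skipped")
  expect_false(out$adjusted)
})

test_that("deconvolute separates immune content from an orthogonal tumor mass", {
  set.seed(202)
  S <- apply_gene_blacklists(til10_synthetic(), "default")
  types <- immune_cell_types()
  P <- signature_to_profiles(S)
  Fstar <- runif(10)
  Fstar <- Fstar / sum(Fstar)          # immune composition
  truth <- c(setNames(0.4 * Fstar, types), Tumor = 0.6)
  mix <- simulate_mixture(P, truth, Inf)
  M <- matrix(mix, ncol = 1, dimnames = list(names(mix), "s1"))
  out <- deconvolute(M, S, rmgenes = "none", mrna_scale = FALSE)
  est <- unlist(out[1, types])
  expect_equal(unname(est), unname(truth[types]), tolerance = 0.02)
  expect_equal(out$Other, 0.6, tolerance = 0.02)
  expect_equal(sum(unlist(out[1, c(types, "Other")])), 1, tolerance = 1e-6)
})

test_that("disabling mRNA scaling equals unit scaling factors", {
  set.seed(203)
  S <- til10_synthetic()
  P <- signature_to_profiles(S)
  truth <- simulate_fractions(10, 0.3)
  mix <- simulate_mixture(P, truth, Inf)
  M <- matrix(mix, ncol = 1, dimnames = list(names(mix), "s1"))
  a <- deconvolute(M, S, rmgenes = "none", mrna_scale = FALSE,
                   scaling = runif(10, 0.5, 2))
  b <- deconvolute(M, S, rmgenes = "none", mrna_scale = TRUE,
                   scaling = setNames(rep(1, 10), immune_cell_types()))
  expect_equal(a, b, ignore_attr = TRUE)
  # and non-unit factors do change the result
  d <- deconvolute(M, S, rmgenes = "none", mrna_scale = TRUE,
                   scaling = setNames(seq(0.5, 2, length.out = 10),
                                      immune_cell_types()))
  expect_false(isTRUE(all.equal(a$B.cells, d$B.cells)))
})

test_that("deconvolute runs on partial signature coverage and flags it", {
  set.seed(204)
  S <- til10_synthetic()
  P <- signature_to_profiles(S)
  truth <- simulate_fractions(10, 0.2)
  mix <- simulate_mixture(P, truth, Inf)
  keep <- c(sample(rownames(S), 100), "NONSIG")
  M <- matrix(mix[keep], ncol = 1, dimnames = list(keep, "s1"))
  expect_warning(out <- deconvolute(M, S, rmgenes = "none",
                                    mrna_scale = FALSE),
                 "100 of 170")
  expect_equal(sum(unlist(out[1, -1])), 1, tolerance = 1e-6)

  M_small <- M[1:5, , drop = FALSE]
  expect_error(suppressWarnings(deconvolute(M_small, S, rmgenes = "none")),
               "insufficient signature coverage|every sample")
})

test_that("fraction tables always close to one across random mixtures", {
  set.seed(205)
  S <- til10_synthetic()
  P <- signature_to_profiles(S)
  mixes <- vapply(1:10, function(i)
    simulate_mixture(P, simulate_fractions(10, runif(1)), 1e6),
    numeric(nrow(P)))
  rownames(mixes) <- rownames(P)
  colnames(mixes) <- paste0("s", 1:10)
  out <- deconvolute(mixes, S, rmgenes = "default", mrna_scale = TRUE)
  sums <- rowSums(out[, -1])
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(out[, -1] >= 0))
})

test_that("density scaling multiplies fractions by total cells per mm2", {
  F <- data.frame(Sample = c("a", "b"),
                  T.cells.CD8 = c(0.1, 0.2), Other = c(0.9, 0.8))
  D <- scale_to_densities(F, c(a = 2000, b = 0))
  expect_equal(D$T.cells.CD8, c(200, 0))
  expect_equal(D$Other, c(1800, 0))
  # densities divided by totals reproduce the fractions
  expect_equal(D$T.cells.CD8[1] / D$total_density[1], 0.1)
  expect_warning(scale_to_densities(F, c(a = 100)), "excluded")
})
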