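# Constrained least-squares machinery: Lawson-Hanson NNLS, least
# distance programming (LDP), and least squares with linear inequality
# constraints (LSI). This is the numerical core of the deconvolution
# model: minimize ||S F - m||^2 subject to F >= 0 and sum(F) <= 1.

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Minimizes `||A x - b||^2` subject to `x >= 0` with the classical
#' active-set algorithm. Deterministic; no random initialization.
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric vector of length m.
#' @param tol Dual-feasibility tolerance; defaults to a multiple of
#'   machine epsilon scaled by `A`.
#' @return List with `x` (solution), `residual` (b - A x), and
#'   `objective` (squared residual norm).
#' @export
nnls_solve <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  if (is.null(tol)) tol <- 100 * .Machine$double.eps * max(abs(A)) * max(n, 1)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))
  iter <- 0L
  max_iter <- 30L * max(n, 1L)
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      P <- which(passive)
      # least squares on the passive set
      zP <- tryCatch(qr.coef(qr(A[, P, drop = FALSE]), b),
                     error = function(e) rep(NA_real_, length(P)))
      zP[is.na(zP)] <- 0
      z[P] <- zP
      if (all(z[P] > tol)) {
        x <- z
        break
      }
      # step toward z until the first passive variable hits zero
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[x <= tol] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) break
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  r <- b - drop(A %*% x)
  list(x = x, residual = r, objective = sum(r^2))
}

# Least distance programming: minimize ||x|| subject to G x >= h.
# Solved through the NNLS dual construction of Lawson & Hanson.
ldp_solve <- function(G, h, tol = 1e-12) {
  G <- as.matrix(G)
  h <- as.numeric(h)
  n <- ncol(G)
  E <- rbind(t(G), h)
  f <- c(numeric(n), 1)
  fit <- nnls_solve(E, f)
  r <- fit$residual
  rnorm2 <- sqrt(sum(r^2))
  if (rnorm2 < tol) stop("LDP constraints are incompatible (infeasible)")
  x <- -r[seq_len(n)] / r[n + 1L]
  x
}

# LSI: minimize ||A x - b|| subject to G x >= h, via SVD reduction to LDP.
# Near-zero singular values are truncated (with a warning) so that
# rank-deficient designs still return a feasible minimum-norm solution.
lsi_solve <- function(A, b, G, h, rank_tol = 1e-12) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  sv <- svd(A)
  keep <- sv$d > rank_tol * max(sv$d, 0)
  if (!any(keep)) {
    # A is numerically zero; any feasible point minimizes. Return the
    # minimum-norm feasible point.
    return(ldp_solve(G, h))
  }
  if (!all(keep)) {
    warning("design matrix is rank-deficient; truncating ",
            sum(!keep), " singular value(s)")
  }
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  d <- sv$d[keep]
  cvec <- drop(crossprod(U, b))
  Gt <- G %*% V %*% diag(1 / d, length(d))
  ht <- h - drop(Gt %*% cvec)
  y <- ldp_solve(Gt, ht)
  drop(V %*% ((y + cvec) / d))
}

#' Constrained least-squares deconvolution of a single mixture
#'
#' Solves `min ||S F - m||^2` subject to `F_c >= 0` and `sum_c F_c <= 1`,
#' the regression at the heart of the deconvolution model. Genes are the
#' rows of `S`; `m` must be the matching mixture column restricted to the
#' same genes.
#'
#' @param S Signature matrix (signature genes x cell types), linear
#'   scale.
#' @param m Numeric mixture vector with one entry per row of `S`.
#' @return Named numeric vector of raw cell fractions `F_c` (one per
#'   column of `S`); non-negative, summing to at most 1.
#' @export
#' @examples
#' S <- cbind(A = c(10, 0), B = c(0, 10))
#' solve_constrained_lsq(S, c(7, 2))
solve_constrained_lsq <- function(S, m) {
  S <- as.matrix(S)
  m <- as.numeric(m)
  if (length(m) != nrow(S))
    stop("mixture vector length does not match signature gene count")
  if (nrow(S) < ncol(S))
    stop("insufficient signature coverage: fewer genes than cell types")
  if (any(m < 0)) stop("mixture values must be non-negative")
  C <- ncol(S)
  if (all(m == 0)) {
    F <- numeric(C)
    names(F) <- colnames(S)
    return(F)
  }
  G <- rbind(diag(C), rep(-1, C))
  h <- c(numeric(C), -1)
  F <- lsi_solve(S, m, G, h)
  # clean tiny constraint violations from floating point
  F[F < 0] <- 0
  s <- sum(F)
  if (s > 1) F <- F / s
  names(F) <- colnames(S)
  F
}
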