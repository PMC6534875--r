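# Independent oracle for the constrained least-squares problem
# min ||S F - m||^2 s.t. F >= 0, sum(F) <= 1, solved by accelerated
# projected gradient (FISTA). Shares no code with the package's
# active-set solver.

# Euclidean projection onto {x >= 0, sum(x) <= 1}
project_capped_simplex <- function(x) {
  p <- pmax(x, 0)
  if (sum(p) <= 1) return(p)
  u <- sort(x, decreasing = TRUE)
  css <- cumsum(u)
  j <- seq_along(u)
  rho <- max(j[u - (css - 1) / j > 0])
  theta <- (css[rho] - 1) / rho
  pmax(x - theta, 0)
}

qp_oracle <- function(S, m, iters = 5000) {
  StS <- crossprod(S)
  Stm <- drop(crossprod(S, m))
  L <- 2 * max(eigen(StS, symmetric = TRUE, only.values = TRUE)$values)
  x <- rep(0, ncol(S))
  y <- x
  t_k <- 1
  for (i in seq_len(iters)) {
    grad <- 2 * (StS %*% y - Stm)
    x_new <- project_capped_simplex(drop(y - grad / L))
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    y <- x_new + (t_k - 1) / t_new * (x_new - x)
    x <- x_new
    t_k <- t_new
  }
  x
}

qp_objective <- function(S, F, m) sum((drop(S %*% F) - m)^2)
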