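# Internal numerical helpers shared across modules.

# Inverse of a symmetric PSD matrix via Cholesky, escalating a diagonal
# jitter (relative to mean(diag)) when the factorization fails. Near-singular
# kinships (duplicated individuals, Kronecker products of low-rank panels)
# are routine inputs, so this is policy, not a band-aid.
solve_psd <- function(M, jitter = 1e-6, label = "matrix") {
  d <- mean(diag(M))
  if (!is.finite(d) || d <= 0) d <- 1
  for (k in 0:4) {
    eps <- if (k == 0) 0 else jitter * 10^(k - 1) * d
    ch <- tryCatch(chol(M + diag(eps, nrow(M))), error = function(e) NULL)
    if (!is.null(ch)) {
      inv <- chol2inv(ch)
      dimnames(inv) <- dimnames(M)
      return(inv)
    }
  }
  stop(sprintf("%s is numerically singular even after jitter (condition number %.3g)",
               label, kappa(M)))
}

# Cholesky with the same escalating jitter; returns the upper factor.
chol_jitter <- function(M, jitter = 1e-6, label = "matrix") {
  d <- mean(diag(M))
  if (!is.finite(d) || d <= 0) d <- 1
  for (k in 0:4) {
    eps <- if (k == 0) 0 else jitter * 10^(k - 1) * d
    ch <- tryCatch(chol(M + diag(eps, nrow(M))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop(sprintf("%s is not positive definite (condition number %.3g)", label, kappa(M)))
}

# Ensure a covariance structure is invertible: if its Cholesky fails, add
# escalating diagonal jitter (starting at 1e-6 * mean(diag)) and report once.
# Applied at model assembly so the MME, the marginal covariance V and the
# spectral EMMA path all see the same effective structure.
jitter_psd <- function(K, jitter = 1e-6, label = "K") {
  d <- mean(diag(K))
  if (!is.finite(d) || d <= 0) d <- 1
  for (k in 0:4) {
    eps <- if (k == 0) 0 else jitter * 10^(k - 1) * d
    Kj <- K + diag(eps, nrow(K))
    ev <- eigen(Kj, symmetric = TRUE, only.values = TRUE)$values
    # a Cholesky can "succeed" on a numerically singular matrix, so gate on
    # the eigenvalue spread instead
    if (min(ev) > 1e-8 * max(ev)) {
      if (eps > 0)
        message(sprintf("structure %s near-singular: added diagonal jitter %.3g", label, eps))
      return(Kj)
    }
  }
  stop(sprintf("structure %s is numerically singular even after jitter (condition number %.3g)",
               label, kappa(K)))
}

# Dense rank, descending, ties share a rank (1 = best).
dense_rank_desc <- function(x) {
  match(-x, sort(unique(-x)))
}

# Draw from MVN(0, K * s2) for a PSD K (eigen route, tolerant of semidefiniteness).
rmvn_psd <- function(K, s2 = 1) {
  ed <- eigen(K, symmetric = TRUE)
  vals <- pmax(ed$values, 0)
  as.vector(ed$vectors %*% (sqrt(vals * s2) * stats::rnorm(length(vals))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
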