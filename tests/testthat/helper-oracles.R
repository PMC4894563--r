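# Independent oracles used across tests. These deliberately avoid the
# package's own linear-algebra paths: scalar loops, dense V-inverse GLS,
# and closed forms.

# VanRaden A by explicit scalar loops over individuals and markers.
A_oracle <- function(M, p) {
  n <- nrow(M)
  Z <- M
  for (j in seq_len(ncol(M))) Z[, j] <- M[, j] - (2 * p[j] - 1)
  denom <- 0
  for (j in seq_along(p)) denom <- denom + 2 * p[j] * (1 - p[j])
  A <- matrix(0, n, n)
  for (i in 1:n) for (k in 1:n) A[i, k] <- sum(Z[i, ] * Z[k, ]) / denom
  dimnames(A) <- list(rownames(M), rownames(M))
  A
}

# Su dominance D by scalar loops (default denominator).
D_oracle <- function(M, p) {
  H <- 1 - abs(M)
  q <- 1 - p
  n <- nrow(M)
  W <- H
  for (j in seq_len(ncol(M))) W[, j] <- H[, j] - 2 * p[j] * q[j]
  denom <- 0
  for (j in seq_along(p)) denom <- denom + 2 * p[j] * q[j] * (1 - 2 * p[j] * q[j])
  D <- matrix(0, n, n)
  for (i in 1:n) for (k in 1:n) D[i, k] <- sum(W[i, ] * W[k, ]) / denom
  dimnames(D) <- list(rownames(M), rownames(M))
  D
}

# Dense V-inverse GLS evaluation of BLUEs and BLUPs for an mm_spec at
# fixed variance components: beta = (X'V^-1X)^-1 X'V^-1 y,
# u_i = s2_i K_i Z_i' V^-1 (y - X beta).
gls_oracle <- function(spec, vc) {
  obs <- spec$observed
  y <- spec$y[obs]
  X <- spec$X[obs, , drop = FALSE]
  V <- diag(vc[["residual"]], length(y))
  for (nm in names(spec$random)) {
    Z <- spec$random[[nm]]$Z[obs, , drop = FALSE]
    V <- V + vc[[nm]] * Z %*% unclass(spec$random[[nm]]$K) %*% t(Z)
  }
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  resid <- y - X %*% beta
  u <- lapply(names(spec$random), function(nm) {
    Z <- spec$random[[nm]]$Z[obs, , drop = FALSE]
    drop(vc[[nm]] * unclass(spec$random[[nm]]$K) %*% t(Z) %*% Vi %*% resid)
  })
  names(u) <- names(spec$random)
  list(beta = drop(beta), u = u)
}

# REML log-likelihood by direct small-matrix inversion (same basis-invariant
# convention as the package documents, evaluated independently).
loglik_oracle <- function(y, X, V) {
  n <- length(y); p <- ncol(X)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * ((n - p) * log(2 * pi) + as.numeric(determinant(V)$modulus) +
            log(det(XtViX)) - log(det(t(X) %*% X)) + drop(t(y) %*% P %*% y))
}

# Balanced one-way ANOVA-REML closed form: s2e = MSE, s2u = (MSB - MSE)/r.
anova_reml <- function(y, g) {
  a <- nlevels(g); r <- length(y) / a
  gm <- tapply(y, g, mean)
  MSB <- r * sum((gm - mean(y))^2) / (a - 1)
  MSE <- sum((y - gm[as.integer(g)])^2) / (length(y) - a)
  c(s2u = (MSB - MSE) / r, s2e = MSE)
}

# Balanced one-way layout generator.
make_oneway <- function(a, r, s2u = 2, s2e = 1, mu = 5) {
  g <- factor(rep(paste0("g", seq_len(a)), each = r))
  u <- rnorm(a, 0, sqrt(s2u))
  y <- mu + u[as.integer(g)] + rnorm(a * r, 0, sqrt(s2e))
  data.frame(grp = g, y = y)
}

# Draw one MVN(0, K) vector through an eigen square root (PSD-tolerant).
rmvn_psd_oracle <- function(K, s2 = 1) {
  ed <- eigen(K, symmetric = TRUE)
  as.vector(ed$vectors %*% (sqrt(pmax(ed$values, 0) * s2) * rnorm(nrow(K))))
}

# A small random single-kernel GBLUP problem.
make_gblup <- function(n = 60, m = 150, var_add = 1, var_e = 1, seed = NULL) {
  mk <- simulate_markers(n, m, seed = seed)
  sim <- simulate_phenotype(mk, var_add = var_add, var_e = var_e,
                            n_qtl = min(40, m), seed = if (is.null(seed)) NULL else seed + 1)
  d <- sim$phenotypes
  d$g <- d$id
  list(markers = mk, data = d, sim = sim,
       spec = mm_spec(d, "y", random = list(g = additive_A(mk))))
}
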