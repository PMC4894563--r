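# Variance-component estimation: spectral single-kernel REML (EMMA-style),
# direct average-information REML on the n x n marginal covariance, and
# EM-REML through the mixed-model-equation inverse blocks.

vc_floor <- function(spec) 1e-10 * stats::var(spec$y[spec$observed])

# Package a fit: BLUEs/BLUPs at the optimum plus likelihood bookkeeping.
finish_fit <- function(spec, vc, method, trace, converged, n_iter, boundary) {
  sol <- solve_mme(spec, vc)
  ll <- reml_loglik(spec, vc)
  ic <- information_criteria(ll, n_params = length(vc), n_obs = spec$n_obs)
  structure(list(vc = vc, solution = sol, loglik = ll,
                 aic = ic[["AIC"]], bic = ic[["BIC"]], method = method,
                 trace = trace, converged = converged, n_iter = n_iter,
                 boundary = boundary, spec = spec),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("mm_fit (%s REML): logLik = %.4f, AIC = %.2f, BIC = %.2f\n",
              x$method, x$loglik, x$aic, x$bic))
  cat("variance components:\n")
  for (nm in names(x$vc))
    cat(sprintf("  %-12s %.6g%s\n", nm, x$vc[[nm]],
                if (isTRUE(x$boundary[[nm]])) " (boundary)" else ""))
  if (!x$converged) cat("NOTE: did not converge\n")
  invisible(x)
}

#' Single-kernel REML via spectral decomposition (EMMA)
#'
#' For a model with exactly one random term, rotates the data into the
#' eigenbasis of the kernel projected onto the orthogonal complement of the
#' fixed-effect column space. The restricted likelihood then depends on the
#' single ratio `delta = sigma2_e / sigma2_u`, which is maximized by a
#' 100-point log-scale grid over `[1e-9, 1e9]` followed by local
#' `optimize()` refinement; the variance scale is profiled out in closed
#' form. BLUEs/BLUPs come from [solve_mme()] at the optimum.
#'
#' @param spec an [mm_spec] with exactly one random term.
#' @param n_grid grid resolution for the ratio search.
#' @return an object of class `mm_fit` (see [fit()]).
#' @export
fit_emma <- function(spec, n_grid = 100) {
  stopifnot(inherits(spec, "mm_spec"))
  if (length(spec$random) != 1)
    stop("EMMA estimates a single variance component besides the error; use AI or EM for multiple random terms")
  obs <- spec$observed
  y <- spec$y[obs]
  if (stats::var(y) == 0) stop("zero phenotypic variance")
  X <- spec$X[obs, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  nm <- names(spec$random)

  Z <- spec$random[[1]]$Z[obs, , drop = FALSE]
  G <- Z %*% unclass(spec$random[[1]]$K) %*% t(Z)
  # orthonormal basis of the complement of col(X)
  Q <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  M <- crossprod(Q, G %*% Q)
  ed <- eigen((M + t(M)) / 2, symmetric = TRUE)
  xi <- pmax(ed$values, 0)
  eta2 <- drop(crossprod(ed$vectors, crossprod(Q, y)))^2
  df <- n - p

  prof <- function(logd) {
    d <- exp(logd)
    s <- sum(eta2 / (xi + d))
    0.5 * (df * log(df / (2 * pi)) - df - df * log(s) - sum(log(xi + d)))
  }
  grid <- seq(log(1e-9), log(1e9), length.out = n_grid)
  vals <- vapply(grid, prof, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-10)
  delta <- exp(opt$maximum)
  at_boundary <- i %in% c(1, n_grid) &&
    abs(opt$maximum - grid[i]) < 1e-6 * abs(grid[i])

  s <- sum(eta2 / (xi + delta))
  floor_v <- vc_floor(spec)
  s2u <- max(s / df, floor_v)
  s2e <- max(delta * s2u, floor_v)
  vc <- stats::setNames(c(s2u, s2e), c(nm, "residual"))
  boundary <- stats::setNames(c(s2u <= floor_v || at_boundary && delta >= 1e8,
                                s2e <= floor_v || at_boundary && delta <= 1e-8),
                              c(nm, "residual"))
  trace <- data.frame(iter = 1, loglik = opt$objective, t(vc))
  finish_fit(spec, vc, "EMMA", trace, converged = TRUE, n_iter = 1,
             boundary = boundary)
}

# One EM-REML sweep: MME solve at current vc, closed-form updates
#   s2_ui <- (u_i' Kinv_i u_i + tr(Kinv_i C^ii)) / q_i     [C^ii in cov units]
#   s2_e  <- (y'y - b'W'y) / (n - p)
em_update <- function(spec, vc) {
  sol <- solve_mme(spec, vc)
  obs <- spec$observed
  y <- spec$y[obs]
  p <- ncol(spec$X)
  new_vc <- vc
  for (nm in names(spec$random)) {
    Kinv <- sol$K_inv[[nm]]
    u <- sol$u[[nm]]
    q <- length(u)
    new_vc[[nm]] <- (drop(crossprod(u, Kinv %*% u)) +
                       sum(Kinv * sol$C_inv[[nm]])) / q
  }
  Xb <- drop(spec$X[obs, , drop = FALSE] %*% sol$beta)
  uy <- sum(vapply(names(spec$random), function(nm)
    sum(drop(spec$random[[nm]]$Z[obs, , drop = FALSE] %*% sol$u[[nm]]) * y),
    numeric(1)))
  new_vc[["residual"]] <- (sum(y^2) - sum(Xb * y) - uy) / (spec$n_obs - p)
  floor_v <- vc_floor(spec)
  pmax(new_vc, c(rep(floor_v, length(new_vc) - 1), floor_v))
}

# P matrix pieces at given vc: returns list(P, Py, loglik-relevant scalars).
projection_pieces <- function(spec, vc) {
  obs <- spec$observed
  y <- spec$y[obs]
  X <- spec$X[obs, , drop = FALSE]
  V <- build_V(spec, vc)
  chV <- chol(V)
  Vinv <- chol2inv(chV)
  VinvX <- Vinv %*% X
  XtViX_inv <- solve_psd(crossprod(X, VinvX), label = "X'V^-1X")
  P <- Vinv - VinvX %*% XtViX_inv %*% t(VinvX)
  P <- (P + t(P)) / 2
  list(P = P, Py = drop(P %*% y))
}

#' Multi-kernel REML by direct average information
#'
#' Newton-type iterations on `theta = (sigma2_u1..., sigma2_e)` using the
#' average-information matrix `AI_ij = 0.5 * y'P Vdot_i P Vdot_j P y` and
#' score `s_i = -0.5 * [tr(P Vdot_i) - y'P Vdot_i P y]`, with
#' `Vdot_i = Z_i K_i Z_i'` (identity for the residual) and the projection
#' `P` computed on the dense n x n marginal covariance (direct inversion).
#' Steps that would decrease the restricted likelihood are halved up to 10
#' times, after which one EM sweep replaces the Newton step; components are
#' clamped at a small non-negativity floor.
#'
#' @param spec an [mm_spec].
#' @param init optional starting variance components (default: equal split
#'   of the observed phenotypic variance).
#' @param max_iter,tol_loglik,tol_theta convergence controls: stop when the
#'   log-likelihood change is below `tol_loglik` and the largest relative
#'   parameter change is below `tol_theta`.
#' @return an object of class `mm_fit`.
#' @export
fit_ai <- function(spec, init = NULL, max_iter = 100,
                   tol_loglik = 1e-8, tol_theta = 1e-6) {
  stopifnot(inherits(spec, "mm_spec"))
  obs <- spec$observed
  y <- spec$y[obs]
  if (stats::var(y) == 0) stop("zero phenotypic variance")
  j <- length(spec$random)
  nms <- c(names(spec$random), "residual")
  floor_v <- vc_floor(spec)
  theta <- init %||% stats::setNames(rep(stats::var(y) / (j + 1), j + 1), nms)
  theta <- check_vc(spec, theta)

  Vdots <- c(lapply(spec$random, function(tr) {
    Z <- tr$Z[obs, , drop = FALSE]
    Z %*% unclass(tr$K) %*% t(Z)
  }), list(residual = diag(length(y))))

  ll <- reml_loglik(spec, theta)
  trace <- data.frame(iter = 0, loglik = ll, t(theta), step = NA_character_)
  converged <- FALSE
  used_em <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    pp <- projection_pieces(spec, theta)
    Py <- pp$Py
    tvecs <- lapply(Vdots, function(Vd) drop(Vd %*% Py))
    score <- vapply(seq_along(Vdots), function(i)
      -0.5 * (sum(pp$P * Vdots[[i]]) - sum(Py * tvecs[[i]])), numeric(1))
    AI <- matrix(0, j + 1, j + 1)
    Pt <- lapply(tvecs, function(tv) drop(pp$P %*% tv))
    for (a in seq_len(j + 1)) for (b in a:(j + 1))
      AI[a, b] <- AI[b, a] <- 0.5 * sum(tvecs[[a]] * Pt[[b]])

    delta <- tryCatch(solve(AI, score), error = function(e) NULL)
    step_kind <- "AI"
    new_theta <- NULL; new_ll <- -Inf
    if (!is.null(delta)) {
      h <- 1
      for (half in 0:10) {
        cand <- pmax(theta + h * delta, floor_v)
        cand_ll <- tryCatch(reml_loglik(spec, cand), error = function(e) -Inf)
        if (cand_ll >= ll - 1e-10) { new_theta <- cand; new_ll <- cand_ll; break }
        h <- h / 2
      }
    }
    if (is.null(new_theta)) {   # singular AI or persistent decrease: EM sweep
      step_kind <- "EM"
      used_em <- TRUE
      new_theta <- em_update(spec, theta)
      new_ll <- reml_loglik(spec, new_theta)
    }

    rel_change <- max(abs(new_theta - theta) / pmax(abs(theta), floor_v))
    dll <- new_ll - ll
    theta <- new_theta; ll <- new_ll
    trace <- rbind(trace, data.frame(iter = it, loglik = ll, t(theta), step = step_kind))
    if (abs(dll) < tol_loglik && rel_change < tol_theta) { converged <- TRUE; break }
  }

  boundary <- stats::setNames(theta <= floor_v * (1 + 1e-12), nms)
  fit <- finish_fit(spec, theta, "AI", trace, converged, it, boundary)
  fit$em_fallback <- used_em
  fit
}

#' Multi-kernel REML by expectation-maximization
#'
#' Classic EM-REML: at each iteration Henderson's equations are solved at
#' the current components and the closed-form updates
#' `sigma2_ui <- (u_i' K_i^-1 u_i + tr(K_i^-1 C^ii)) / q_i` (with `C^ii`
#' the BLUP block of the inverse coefficient matrix in covariance units)
#' and `sigma2_e <- (y'y - b'W'y) / (n - p)` are applied. The restricted
#' likelihood is non-decreasing along the iteration; convergence uses the
#' same criteria as [fit_ai()] with a larger default iteration budget.
#'
#' @inheritParams fit_ai
#' @return an object of class `mm_fit`.
#' @export
fit_em <- function(spec, init = NULL, max_iter = 5000,
                   tol_loglik = 1e-8, tol_theta = 1e-6) {
  stopifnot(inherits(spec, "mm_spec"))
  y <- spec$y[spec$observed]
  if (stats::var(y) == 0) stop("zero phenotypic variance")
  j <- length(spec$random)
  nms <- c(names(spec$random), "residual")
  floor_v <- vc_floor(spec)
  theta <- init %||% stats::setNames(rep(stats::var(y) / (j + 1), j + 1), nms)
  theta <- check_vc(spec, theta)

  ll <- reml_loglik(spec, theta)
  trace <- data.frame(iter = 0, loglik = ll, t(theta))
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    new_theta <- em_update(spec, theta)
    new_ll <- reml_loglik(spec, new_theta)
    rel_change <- max(abs(new_theta - theta) / pmax(abs(theta), floor_v))
    dll <- new_ll - ll
    theta <- new_theta; ll <- new_ll
    trace <- rbind(trace, data.frame(iter = it, loglik = ll, t(theta)))
    if (abs(dll) < tol_loglik && rel_change < tol_theta) { converged <- TRUE; break }
  }
  boundary <- stats::setNames(theta <= floor_v * (1 + 1e-12), nms)
  finish_fit(spec, theta, "EM", trace, converged, it, boundary)
}

#' Fit a mixed model, dispatching on the number of random terms
#'
#' `method = "auto"` selects the spectral EMMA path when the model has a
#' single random term and average-information REML otherwise.
#'
#' @param spec an [mm_spec].
#' @param method `"auto"`, `"EMMA"`, `"AI"` or `"EM"`.
#' @param ... passed to the selected algorithm.
#' @return an object of class `mm_fit`: variance components `vc`, the MME
#'   `solution` (BLUEs, BLUPs, fitted, residuals), restricted `loglik`,
#'   `aic`/`bic`, convergence `trace`, `converged`, `n_iter`, `boundary`
#'   flags and the `method` used.
#' @export
fit <- function(spec, method = c("auto", "EMMA", "AI", "EM"), ...) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (length(spec$random) == 1) "EMMA" else "AI"
  switch(method,
         EMMA = fit_emma(spec, ...),
         AI = fit_ai(spec, ...),
         EM = fit_em(spec, ...))
}
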