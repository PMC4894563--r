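#' Assemble a mixed model specification
#'
#' Builds the response, fixed-effect incidence `X` and one incidence/structure
#' pair `(Z_i, K_i)` per random term from a phenotype table. Records with a
#' missing response are dropped from the estimation rows, but **all** levels
#' of every random term (the columns of `Z_i`, i.e. the labels of `K_i`) are
#' retained, so levels without phenotypes receive BLUPs through their
#' covariance with observed levels — this is the mechanism by which
#' unrealized crosses and unobserved hybrids are predicted.
#'
#' @param data data.frame of phenotype records.
#' @param response name of the response column.
#' @param fixed one-sided formula for fixed effects (default `~ 1`),
#'   evaluated on `data`.
#' @param random named list of random terms. Each element is one of:
#'   a [relationship_matrix] (the term's factor column in `data` is then
#'   the element's name); a list `list(column = <col>, K = <matrix>)`;
#'   or a list `list(Z = <incidence matrix>, K = <matrix>)` supplying the
#'   incidence directly (one row per record of `data`, columns labeled by
#'   the levels of `K`) — the route for designs whose incidence is not a
#'   one-factor indicator, e.g. half diallels where each record carries
#'   two parents. Terms with `K = NULL` get an identity structure over
#'   the observed factor levels (or the `Z` columns).
#' @return an object of class `mm_spec` holding `y` (with missing mask),
#'   full-row `X` and `Z_i`, structures, and the source `data`.
#' @export
mm_spec <- function(data, response, fixed = ~1, random) {
  stopifnot(is.data.frame(data))
  if (!response %in% names(data)) stop(sprintf("response column '%s' not found", response))
  y <- as.numeric(data[[response]])
  observed <- !is.na(y)
  if (!any(observed)) stop("all responses are missing")

  mf <- stats::model.frame(fixed, data, na.action = stats::na.pass)
  X <- stats::model.matrix(fixed, mf)
  if (nrow(X) != nrow(data)) stop("fixed-effect covariates contain missing values")

  # full column rank on the observed rows; drop aliased columns (pivoted QR)
  qx <- qr(X[observed, , drop = FALSE])
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    warning(sprintf("fixed-effect matrix rank deficient; dropping %d aliased column(s): %s",
                    ncol(X) - qx$rank,
                    paste(colnames(X)[-keep], collapse = ", ")))
    X <- X[, sort(keep), drop = FALSE]
  }

  if (missing(random) || length(random) == 0) stop("at least one random term is required")
  if (is.null(names(random)) || any(names(random) == ""))
    stop("random terms must be named")

  terms <- list()
  for (nm in names(random)) {
    el <- random[[nm]]
    if (is.list(el) && !is.matrix(el) && !is.null(el$Z)) {
      # user-supplied incidence: rows follow data records, columns follow K
      Z <- as.matrix(el$Z)
      if (nrow(Z) != nrow(data))
        stop(sprintf("random term '%s': incidence Z has %d rows but data has %d records",
                     nm, nrow(Z), nrow(data)))
      K <- el$K
      if (is.null(K)) {
        labs <- colnames(Z) %||% paste0(nm, seq_len(ncol(Z)))
        K <- relationship_matrix(diag(ncol(Z)) + 0, kind = "identity",
                                 check_psd = FALSE)
        dimnames(K) <- list(labs, labs)
      }
      if (is.null(colnames(Z))) {
        if (ncol(Z) != nrow(K))
          stop(sprintf("random term '%s': Z has %d columns but K has %d levels",
                       nm, ncol(Z), nrow(K)))
        colnames(Z) <- rownames(K)
      }
      miss <- setdiff(colnames(Z), rownames(K))
      if (length(miss))
        stop(sprintf("random term '%s': level '%s' absent from its structure's labels",
                     nm, miss[1]))
      Z <- Z[, rownames(K), drop = FALSE]   # align columns to K label order
      column <- NA_character_
    } else {
      if (is.list(el) && !is.matrix(el)) {
        column <- el$column %||% nm
        K <- el$K
      } else {
        column <- nm
        K <- el
      }
      if (!column %in% names(data))
        stop(sprintf("random term '%s': column '%s' not found in data", nm, column))
      lev <- as.character(data[[column]])
      if (is.null(K)) {
        labs <- sort(unique(lev))
        K <- relationship_matrix(diag(length(labs)) + 0, kind = "identity",
                                 check_psd = FALSE)
        dimnames(K) <- list(labs, labs)
      }
      labs <- rownames(K)
      miss <- setdiff(unique(lev[observed]), labs)
      if (length(miss))
        stop(sprintf("random term '%s': level '%s' absent from its structure's labels",
                     nm, miss[1]))
      f <- factor(lev, levels = labs)
      Z <- stats::model.matrix(~ f - 1)
      Z <- matrix(Z, nrow(Z), ncol(Z), dimnames = list(NULL, labs))
    }
    Kj <- jitter_psd(unclass(K), label = sprintf("'%s'", nm))
    dimnames(Kj) <- dimnames(K)
    terms[[nm]] <- list(column = column, Z = Z, K = Kj)
  }

  n_obs <- sum(observed)
  if (n_obs <= ncol(X))
    stop("model not estimable: observed records must exceed fixed-effect columns")

  structure(list(y = y, observed = observed, X = X, random = terms,
                 response = response, fixed = fixed, data = data,
                 n_obs = n_obs, cache = new.env(parent = emptyenv())),
            class = "mm_spec")
}

#' @export
print.mm_spec <- function(x, ...) {
  cat(sprintf("mm_spec: %d records (%d observed), %d fixed column(s), %d random term(s)\n",
              length(x$y), x$n_obs, ncol(x$X), length(x$random)))
  for (nm in names(x$random))
    cat(sprintf("  %s: %d levels (structure %s)\n", nm, ncol(x$random[[nm]]$Z),
                attr(x$random[[nm]]$K, "kind") %||% "custom"))
  invisible(x)
}

#' Solve Henderson's mixed model equations at fixed variance components
#'
#' With `R = I * sigma2_e` and `G_i = K_i * sigma2_u[i]` the coefficient
#' system is the classic Henderson form; the solution gives the BLUEs
#' `beta`, per-term BLUPs `u_i` (for every level of `K_i`, observed or
#' not), and the BLUP-block rows of the inverse coefficient matrix scaled
#' to covariance units (needed by EM-REML updates and standard errors).
#'
#' @param spec an [mm_spec].
#' @param vc named numeric vector of variance components: one entry per
#'   random term (matching `names(spec$random)`) plus `"residual"`.
#' @return object of class `mme_solution` with `beta`, `u` (named list of
#'   labeled vectors), `fitted`, `residuals` (observed rows), `fitted_full`
#'   (all records), and `C_inv` blocks per term.
#' @export
solve_mme <- function(spec, vc) {
  stopifnot(inherits(spec, "mm_spec"))
  vc <- check_vc(spec, vc)
  obs <- spec$observed
  y <- spec$y[obs]
  X <- spec$X[obs, , drop = FALSE]
  p <- ncol(X)
  s2e <- vc[["residual"]]

  Zs <- lapply(spec$random, function(tr) tr$Z[obs, , drop = FALSE])
  qs <- vapply(Zs, ncol, integer(1))
  W <- cbind(X, do.call(cbind, Zs))

  C <- crossprod(W)
  off <- p
  Kinvs <- list()
  for (i in seq_along(Zs)) {
    nm <- names(spec$random)[i]
    Kinv <- get0(paste0("Kinv_", nm), envir = spec$cache, inherits = FALSE)
    if (is.null(Kinv)) {
      Kinv <- solve_psd(unclass(spec$random[[i]]$K),
                        label = sprintf("structure K for term '%s'", nm))
      assign(paste0("Kinv_", nm), Kinv, envir = spec$cache)
    }
    Kinvs[[nm]] <- Kinv
    idx <- off + seq_len(qs[i])
    # boundary components (0) are treated as effectively zero variance
    lam <- s2e / max(vc[[nm]], 1e-12 * s2e)
    C[idx, idx] <- C[idx, idx] + Kinv * lam
    off <- off + qs[i]
  }

  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch))
    stop(sprintf("singular mixed-model coefficient matrix (condition number %.3g)",
                 kappa(C)))
  Cinv <- chol2inv(ch)
  b <- drop(Cinv %*% crossprod(W, y))

  beta <- b[seq_len(p)]
  names(beta) <- colnames(X)
  u <- list(); C_blocks <- list()
  off <- p
  for (i in seq_along(Zs)) {
    nm <- names(spec$random)[i]
    idx <- off + seq_len(qs[i])
    ui <- b[idx]
    names(ui) <- colnames(Zs[[i]])
    u[[nm]] <- ui
    C_blocks[[nm]] <- Cinv[idx, idx, drop = FALSE] * s2e
    off <- off + qs[i]
  }

  fitted_obs <- unname(drop(W %*% b))
  fitted_full <- drop(spec$X %*% beta) +
    Reduce(`+`, Map(function(tr, ui) drop(tr$Z %*% ui), spec$random, u))

  structure(list(beta = beta, u = u, fitted = fitted_obs,
                 residuals = y - fitted_obs, fitted_full = unname(fitted_full),
                 C_inv = C_blocks, K_inv = Kinvs, vc = vc),
            class = "mme_solution")
}

# Validate/normalize a variance-component vector against a spec.
check_vc <- function(spec, vc) {
  nms <- c(names(spec$random), "residual")
  if (is.null(names(vc))) {
    if (length(vc) != length(nms)) stop("unnamed vc must have one entry per term plus residual")
    names(vc) <- nms
  }
  if (!all(nms %in% names(vc)))
    stop(sprintf("vc must contain components: %s", paste(nms, collapse = ", ")))
  vc <- vc[nms]
  if (vc[["residual"]] <= 0) stop("residual variance must be strictly positive")
  if (any(vc < 0)) stop("variance components must be non-negative")
  vc
}

# Marginal covariance V = sum_i Z_i K_i Z_i' s2_i + I s2_e on observed rows.
build_V <- function(spec, vc) {
  obs <- spec$observed
  n <- sum(obs)
  V <- diag(vc[["residual"]], n)
  for (nm in names(spec$random)) {
    Z <- spec$random[[nm]]$Z[obs, , drop = FALSE]
    V <- V + vc[[nm]] * Z %*% unclass(spec$random[[nm]]$K) %*% t(Z)
  }
  (V + t(V)) / 2
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the REML log-likelihood
#' `-0.5 * [(n-p) log 2pi + log|V| + log|X'V^-1 X| - log|X'X| + y'Py]`
#' with `P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1`. The `log|X'X|` term makes
#' the value invariant to the choice of basis spanning the fixed-effect
#' column space. Determinants go through Cholesky log-determinants, so
#' large `n` does not overflow.
#'
#' @param spec an [mm_spec].
#' @param vc named variance components as in [solve_mme()].
#' @return a finite scalar.
#' @export
reml_loglik <- function(spec, vc) {
  vc <- check_vc(spec, vc)
  obs <- spec$observed
  y <- spec$y[obs]
  X <- spec$X[obs, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  V <- build_V(spec, vc)
  chV <- tryCatch(chol(V), error = function(e)
    stop("V is not positive definite at the supplied variance components"))
  logdetV <- 2 * sum(log(diag(chV)))
  Vinv_y <- backsolve(chV, forwardsolve(t(chV), y))
  Vinv_X <- backsolve(chV, forwardsolve(t(chV), X))
  XtViX <- crossprod(X, Vinv_X)
  chXX <- chol(XtViX)
  logdetXtViX <- 2 * sum(log(diag(chXX)))
  logdetXtX <- 2 * sum(log(diag(chol(crossprod(X)))))
  beta <- backsolve(chXX, forwardsolve(t(chXX), crossprod(X, Vinv_y)))
  yPy <- sum(y * Vinv_y) - sum(crossprod(X, Vinv_y) * beta)
  -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetXtViX - logdetXtX + yPy)
}

#' Information criteria from a restricted log-likelihood
#'
#' `AIC = -2 loglik + 2 k`, `BIC = -2 loglik + k log(n_obs)`. Under REML the
#' fixed effects are profiled out, so `k` counts estimated variance
#' components only.
#'
#' @param loglik restricted log-likelihood.
#' @param n_params number of estimated variance components `k`.
#' @param n_obs number of observations used.
#' @return named vector `c(AIC = , BIC = )`.
#' @export
information_criteria <- function(loglik, n_params, n_obs) {
  if (n_obs <= n_params) stop("n_obs must exceed n_params")
  c(AIC = -2 * loglik + 2 * n_params,
    BIC = -2 * loglik + n_params * log(n_obs))
}
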