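#' Single-marker mixed-model association scan (diploid)
#'
#' Controls polygenic background with a kinship random effect: the
#' variance components are estimated once on the marker-free null model
#' with the spectral single-kernel algorithm, then held fixed while each
#' marker in turn enters the fixed effects (the P3D /
#' population-parameters-previously-determined scheme). After whitening by
#' the Cholesky factor of the null-model covariance, each marker's effect
#' is a generalized-least-squares coefficient with a Wald t-test.
#'
#' Monomorphic markers and markers aliased with the fixed effects are
#' recorded as missing. With `K = I` and no polygenic variance the
#' per-marker p-value reduces to the ordinary regression t-test.
#'
#' @param data phenotype data.frame; column `id` links records to marker rows.
#' @param response response column name.
#' @param markers a [marker_matrix] in additive coding, rownames matching
#'   `data[[id]]` values.
#' @param K kinship [relationship_matrix] (default: [additive_A()] of
#'   `markers`).
#' @param fixed one-sided fixed-effect formula (default `~ 1`).
#' @param id genotype identifier column (default `"id"`).
#' @return a `gwas_scan` data.frame with per-marker `effect`, `se`,
#'   `p_value`, `score` (`-log10 p`); attributes `vc` (null-model
#'   components) and `bonferroni` (the `-log10(0.05/m)` threshold);
#'   metadata attribute `method = "P3D"`.
#' @export
mm_scan <- function(data, response, markers, K = NULL, fixed = ~1, id = "id") {
  stopifnot(inherits(markers, "marker_matrix"))
  if (markers$coding != "additive") stop("mm_scan requires additive-coded markers")
  if (!id %in% names(data)) stop(sprintf("id column '%s' not found", id))
  K <- K %||% additive_A(markers)
  if (!all(rownames(markers$values) %in% rownames(K)))
    stop("marker/kinship label mismatch: individuals missing from K")

  random <- stats::setNames(list(list(column = id, K = K)), "kinship")
  spec <- mm_spec(data, response, fixed = fixed, random = random)
  null_fit <- fit_emma(spec)

  obs <- spec$observed
  y <- spec$y[obs]
  X <- spec$X[obs, , drop = FALSE]
  ids <- as.character(data[[id]])[obs]
  M <- markers$values[match(ids, rownames(markers$values)), , drop = FALSE]
  if (anyNA(match(ids, rownames(markers$values))))
    stop("marker/kinship label mismatch: phenotype id absent from marker rows")
  M <- impute_marker_means(M)

  # whiten by the null-model covariance, then partitioned OLS per marker
  V <- build_V(spec, null_fit$vc)
  Lt <- t(chol(V))
  yw <- forwardsolve(Lt, y)
  Xw <- forwardsolve(Lt, X)
  Mw <- forwardsolve(Lt, M)

  qx <- qr(Xw)
  yr <- qr.resid(qx, yw)
  Mr <- qr.resid(qx, Mw)
  df <- length(y) - ncol(X) - 1

  mono <- markers$allele_freqs <= 0 | markers$allele_freqs >= 1
  mm2 <- colSums(Mr^2)
  aliased <- mm2 < 1e-8 * pmax(colSums(Mw^2), 1e-300)
  bad <- mono | aliased

  eff <- colSums(Mr * yr) / mm2
  rss <- sum(yr^2) - eff^2 * mm2
  se <- sqrt(pmax(rss, 0) / df / mm2)
  tstat <- eff / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  eff[bad] <- se[bad] <- pval[bad] <- NA_real_

  out <- data.frame(marker = colnames(markers$values), effect = eff, se = se,
                    p_value = pval, score = -log10(pval),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("gwas_scan", class(out)),
            vc = null_fit$vc,
            bonferroni = -log10(0.05 / sum(!bad)),
            method = "P3D")
}
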