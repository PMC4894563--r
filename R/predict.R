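#' Extract genomic estimated breeding values (BLUPs) for a random term
#'
#' The BLUP vector of a marker-kinship random effect equals the genomic
#' estimated breeding values of the genotypes; levels without any
#' phenotype record are included (predicted through their covariance in
#' `K` with observed levels).
#'
#' @param fit an `mm_fit` from [fit()].
#' @param term name of a random term of the fit (default: the first).
#' @return named numeric vector over all levels of the term's structure.
#' @export
gebv <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "mm_fit"))
  term <- term %||% names(fit$solution$u)[1]
  if (!term %in% names(fit$solution$u))
    stop(sprintf("unknown term '%s'; available: %s", term,
                 paste(names(fit$solution$u), collapse = ", ")))
  fit$solution$u[[term]]
}

#' Predict unrealized crosses as mid-parent breeding values
#'
#' The predicted genetic value of the cross i x j is the average of the
#' parental breeding values, `(GEBV_i + GEBV_j) / 2` — appropriate for
#' species with null or small heterotic effects. `pairs = "all"` enumerates
#' every unordered pair excluding selfs.
#'
#' @param gebvs named numeric vector of parental breeding values.
#' @param pairs `"all"`, or a 2-column matrix / data.frame of parent pairs.
#' @return a `cross_table` data.frame with `parent1`, `parent2`,
#'   `predicted_value` and dense `rank` (1 = best; ties share a rank, rows
#'   of equal value ordered by parent labels).
#' @export
predict_crosses <- function(gebvs, pairs = "all") {
  if (is.null(names(gebvs))) stop("gebvs must be a named vector")
  parents <- names(gebvs)
  if (identical(pairs, "all")) {
    if (length(parents) < 2) stop("need at least two parents")
    idx <- utils::combn(length(parents), 2)
    p1 <- parents[idx[1, ]]; p2 <- parents[idx[2, ]]
  } else {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2) stop("pairs must have two columns")
    unknown <- setdiff(unique(c(pairs)), parents)
    if (length(unknown))
      stop(sprintf("unknown parent '%s'", unknown[1]))
    p1 <- as.character(pairs[, 1]); p2 <- as.character(pairs[, 2])
  }
  val <- (gebvs[p1] + gebvs[p2]) / 2
  out <- data.frame(parent1 = p1, parent2 = p2, predicted_value = unname(val),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$predicted_value, out$parent1, out$parent2), ]
  out$rank <- dense_rank_desc(out$predicted_value)
  rownames(out) <- NULL
  class(out) <- c("cross_table", class(out))
  out
}

#' Kronecker SCA kernel for single-cross hybrids
#'
#' The covariance structure of specific combining ability among all
#' female x male hybrids is the Kronecker product of the parental genomic
#' relationship matrices, `K3 = K1 (x) K2`. Labels are composites
#' `female:male` in female-outer (row-major) order, the same order
#' produced by `kronecker()` and matching [mm_spec()] incidence columns
#' when the hybrid factor uses those labels.
#'
#' @param K1,K2 parental [relationship_matrix] objects (females, males).
#' @param sep label separator (default `":"`).
#' @return a [relationship_matrix] of kind `"epistatic"` sized
#'   `q1*q2 x q1*q2`.
#' @export
sca_kernel <- function(K1, K2, sep = ":") {
  K3 <- kronecker(unclass(K1), unclass(K2))
  labs <- as.vector(t(outer(rownames(K1), rownames(K2), paste, sep = sep)))
  dimnames(K3) <- list(labs, labs)
  relationship_matrix(K3, kind = "epistatic", check_psd = FALSE)
}

#' Predict single-cross hybrids from GCA and SCA BLUPs
#'
#' The predicted genetic value of the hybrid female f x male m is the sum
#' of the parental general combining abilities and the cross-specific
#' combining ability, `u_GCA1[f] + u_GCA2[m] + u_SCA[f:m]`, covering
#' observed and unobserved crosses alike. With `include_fixed = TRUE` the
#' mean fixed-effect value (the fitted `X beta` averaged over records) is
#' added so predictions are on the trait scale.
#'
#' @param fit an `mm_fit` containing the three terms.
#' @param gca1,gca2,sca names of the corresponding random terms.
#' @param sep separator used in the SCA labels.
#' @param include_fixed add the mean fixed-effect contribution.
#' @return a `cross_table` with `female`, `male`, `predicted_value`, `rank`.
#' @export
predict_hybrids <- function(fit, gca1 = "GCA1", gca2 = "GCA2", sca = "SCA",
                            sep = ":", include_fixed = FALSE) {
  stopifnot(inherits(fit, "mm_fit"))
  for (tm in c(gca1, gca2, sca))
    if (!tm %in% names(fit$solution$u))
      stop(sprintf("term '%s' not found in fit; available: %s", tm,
                   paste(names(fit$solution$u), collapse = ", ")))
  u1 <- fit$solution$u[[gca1]]; u2 <- fit$solution$u[[gca2]]
  u3 <- fit$solution$u[[sca]]
  parts <- strsplit(names(u3), sep, fixed = TRUE)
  fem <- vapply(parts, `[`, character(1), 1)
  mal <- vapply(parts, `[`, character(1), 2)
  if (anyNA(mal)) stop("SCA labels must be 'female", sep, "male' composites")
  val <- u1[fem] + u2[mal] + u3
  if (include_fixed) {
    obs <- fit$spec$observed
    val <- val + mean(drop(fit$spec$X[obs, , drop = FALSE] %*% fit$solution$beta))
  }
  out <- data.frame(female = fem, male = mal, predicted_value = unname(val),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$predicted_value, out$female, out$male), ]
  out$rank <- dense_rank_desc(out$predicted_value)
  rownames(out) <- NULL
  class(out) <- c("cross_table", class(out))
  out
}

#' Narrow-sense heritability from variance components
#'
#' Single-kernel design: `h2 = sigma2_u / (sigma2_u + sigma2_e)`. Hybrid
#' (GCA/SCA) design: `h2 = (sigma2_GCA1 + sigma2_GCA2) /
#' (sigma2_GCA1 + sigma2_GCA2 + sigma2_e)` — the SCA component enters
#' neither numerator nor denominator.
#'
#' @param vc an `mm_fit` or a named variance-component vector with a
#'   `"residual"` entry.
#' @param design `"single"` or `"hybrid"`.
#' @param gca_terms for the hybrid design, names of the GCA components
#'   (default: the first two non-residual components).
#' @return scalar in `[0, 1]`.
#' @export
heritability <- function(vc, design = c("single", "hybrid"), gca_terms = NULL) {
  design <- match.arg(design)
  if (inherits(vc, "mm_fit")) vc <- vc$vc
  if (is.null(names(vc)) || !"residual" %in% names(vc))
    stop("vc must be named and include a 'residual' component")
  gen <- vc[setdiff(names(vc), "residual")]
  if (all(c(gen, vc[["residual"]]) == 0)) stop("undefined heritability: all components zero")
  if (design == "single") {
    num <- sum(gen)
  } else {
    gca_terms <- gca_terms %||% names(gen)[seq_len(min(2, length(gen)))]
    if (length(gca_terms) < 2) stop("hybrid design requires at least two GCA components")
    num <- sum(vc[gca_terms])
  }
  unname(num / (num + vc[["residual"]]))
}

#' Upper bound on prediction accuracy
#'
#' Selection theory bounds the correlation between predicted and realized
#' genetic values by the square root of the heritability.
#'
#' @param h2 heritability in `[0, 1]`.
#' @return `sqrt(h2)`.
#' @export
accuracy_upper_bound <- function(h2) {
  if (!is.numeric(h2) || any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]")
  sqrt(h2)
}

#' Half-diallel incidence matrix
#'
#' Rows are unordered crosses, columns are parents; each row carries a 1
#' for both participating parents. Self-crosses are rejected.
#'
#' @param parents character vector of parent labels.
#' @param crosses `NULL` (all unordered pairs) or a 2-column matrix /
#'   data.frame of parent pairs.
#' @return numeric incidence matrix with cross rownames `p1:p2`.
#' @export
half_diallel_incidence <- function(parents, crosses = NULL) {
  parents <- as.character(parents)
  if (is.null(crosses)) {
    idx <- utils::combn(length(parents), 2)
    crosses <- cbind(parents[idx[1, ]], parents[idx[2, ]])
  } else {
    crosses <- as.matrix(crosses)
  }
  if (any(crosses[, 1] == crosses[, 2]))
    stop("self-cross supplied; half diallels exclude selfs")
  unknown <- setdiff(unique(c(crosses)), parents)
  if (length(unknown)) stop(sprintf("unknown parent '%s'", unknown[1]))
  Z <- matrix(0, nrow(crosses), length(parents),
              dimnames = list(paste(crosses[, 1], crosses[, 2], sep = ":"), parents))
  for (i in seq_len(nrow(crosses))) Z[i, crosses[i, ]] <- 1
  Z
}
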