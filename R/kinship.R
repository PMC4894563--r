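#' Relationship (kinship) matrix constructor
#'
#' Validates and labels a symmetric positive-semidefinite covariance
#' structure for one random effect. Symmetry is required to a 1e-10
#' relative tolerance and eigenvalues may dip no lower than
#' `-1e-8 * max(eigenvalue)` (numerical jitter allowance).
#'
#' @param values square numeric matrix with matching row/column labels.
#' @param kind one of `"additive"`, `"dominance"`, `"epistatic"`,
#'   `"identity"`, `"custom"`.
#' @param check_psd verify positive-semidefiniteness (eigen decomposition;
#'   skip for large matrices you already trust).
#' @return the matrix with class `relationship_matrix` and a `kind` attribute.
#' @export
relationship_matrix <- function(values, kind = c("custom", "additive", "dominance",
                                                 "epistatic", "identity"),
                                check_psd = TRUE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  if (is.null(rownames(values)) && is.null(colnames(values)))
    rownames(values) <- colnames(values) <- paste0("G", seq_len(nrow(values)))
  if (is.null(rownames(values))) rownames(values) <- colnames(values)
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  if (anyDuplicated(rownames(values))) stop("relationship matrix labels must be unique")
  if (!identical(rownames(values), colnames(values)))
    stop("row and column labels must agree")
  sc <- max(abs(values), 1e-300)
  if (max(abs(values - t(values))) > 1e-10 * sc)
    stop("relationship matrix is not symmetric")
  values <- (values + t(values)) / 2
  if (check_psd) {
    ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1e-300))
      stop("relationship matrix is not positive semidefinite")
  }
  structure(values, class = c("relationship_matrix", class(values)),
            kind = kind)
}

#' Additive genomic relationship matrix (VanRaden)
#'
#' Computes `A = Z Z' / (2 * sum_j p_j (1 - p_j))` where `Z` is the
#' -1/0/+1 marker grid column-centered by `2 p_j - 1`. Missing cells are
#' imputed to the per-marker mean of the coded values before centering.
#' Monomorphic markers contribute nothing to either numerator or
#' denominator and are excluded with a message.
#'
#' @param markers a [marker_matrix] in additive coding.
#' @param allele_freqs optional user-supplied frequencies of the +1 allele
#'   (defaults to the frequencies observed in `markers`).
#' @return a [relationship_matrix] of kind `"additive"`.
#' @export
additive_A <- function(markers, allele_freqs = NULL) {
  stopifnot(inherits(markers, "marker_matrix"))
  if (markers$coding != "additive")
    stop("additive_A requires additive (-1/0/1) coding; see letters_to_numeric()")
  p <- allele_freqs %||% markers$allele_freqs
  if (length(p) != ncol(markers$values)) stop("allele_freqs length mismatch")
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("zero denominator: all markers are monomorphic")
  if (any(!poly))
    message(sprintf("excluding %d monomorphic marker(s) from A", sum(!poly)))
  M <- impute_marker_means(markers$values[, poly, drop = FALSE])
  p <- p[poly]
  Z <- sweep(M, 2, 2 * p - 1)
  denom <- 2 * sum(p * (1 - p))
  A <- tcrossprod(Z) / denom
  relationship_matrix(A, kind = "additive", check_psd = FALSE)
}

#' Dominance genomic relationship matrix (Su)
#'
#' Codes each call 0/1 for homozygote/heterozygote, centers marker `j` by
#' its expected heterozygosity `2 p_j q_j`, and scales:
#' `D = W W' / sum_j 2 p_j q_j (1 - 2 p_j q_j)` (default, Su et al.'s
#' normalization). `denominator = "simple"` divides by `sum_j 2 p_j q_j`
#' instead.
#'
#' @param markers a [marker_matrix] in additive or dominance coding
#'   (additive is recoded: homozygotes to 0, heterozygote to 1).
#' @param denominator `"su"` (default) or `"simple"`.
#' @param allele_freqs optional frequencies of the +1 allele.
#' @return a [relationship_matrix] of kind `"dominance"`.
#' @export
dominance_D <- function(markers, denominator = c("su", "simple"),
                        allele_freqs = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(markers, "marker_matrix"))
  if (!markers$coding %in% c("additive", "dominance"))
    stop("dominance_D requires additive or dominance coding")
  H <- if (markers$coding == "additive") 1 - abs(markers$values) else markers$values
  if (sum(H, na.rm = TRUE) == 0)
    stop("dominance structure undefined: no heterozygous calls in the panel")
  p <- allele_freqs %||% markers$allele_freqs
  q <- 1 - p
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("zero denominator: all markers are monomorphic")
  H <- impute_marker_means(H[, poly, drop = FALSE])
  pq2 <- 2 * p[poly] * q[poly]
  W <- sweep(H, 2, pq2)
  denom <- switch(denominator,
                  su = sum(pq2 * (1 - pq2)),
                  simple = sum(pq2))
  D <- tcrossprod(W) / denom
  relationship_matrix(D, kind = "dominance", check_psd = FALSE)
}

#' Epistatic relationship matrices (Hadamard products)
#'
#' Element-wise (Hadamard) products of relationship matrices:
#' additive-by-additive `A#A`, dominance-by-dominance `D#D`, and
#' additive-by-dominance `A#D`. By the Schur product theorem the result is
#' again positive semidefinite.
#'
#' @param Ka,Kb [relationship_matrix] objects sharing the same label order
#'   (`Kb` defaults to `Ka`).
#' @param kind `"aa"`, `"dd"` or `"ad"` (recorded, not used in the algebra).
#' @return a [relationship_matrix] of kind `"epistatic"`.
#' @export
epistatic <- function(Ka, Kb = Ka, kind = c("aa", "dd", "ad")) {
  kind <- match.arg(kind)
  if (!identical(rownames(Ka), rownames(Kb))) {
    bad <- which(rownames(Ka) != rownames(Kb))[1]
    stop(sprintf("label mismatch between kernels at position %d: '%s' vs '%s'",
                 bad, rownames(Ka)[bad], rownames(Kb)[bad]))
  }
  E <- unclass(Ka) * unclass(Kb)
  relationship_matrix(E, kind = "epistatic", check_psd = FALSE)
}
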