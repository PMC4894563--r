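#' Marker matrix container
#'
#' A labeled individuals-by-markers genotype table in a declared coding.
#' Additive coding stores genotypes as -1/0/+1 (reference homozygote,
#' heterozygote, alternate homozygote); dominance coding stores 0/1
#' (homozygote / heterozygote); `raw_letters` stores two-letter diploid
#' calls such as `"AG"` awaiting conversion with [letters_to_numeric()].
#'
#' Per-marker allele frequencies `p_j` refer to the allele coded +1. When
#' not supplied they are computed from the observed calls (for additive
#' coding, the mean of `(x+1)/2`; for dominance coding, solved from the
#' heterozygote frequency under Hardy-Weinberg equilibrium).
#'
#' @param values numeric (or character for `raw_letters`) matrix with
#'   individual IDs as rownames and marker IDs as colnames.
#' @param coding one of `"additive"`, `"dominance"`, `"raw_letters"`.
#' @param allele_freqs optional numeric vector of per-marker frequencies of
#'   the +1 allele, length `ncol(values)`, each in `[0, 1]`.
#' @return an object of class `marker_matrix`: a list with elements
#'   `values`, `coding`, `allele_freqs`.
#' @export
marker_matrix <- function(values, coding = c("additive", "dominance", "raw_letters"),
                          allele_freqs = NULL) {
  coding <- match.arg(coding)
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- paste0("G", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("M", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("individual IDs must be unique")
  if (anyDuplicated(colnames(values))) stop("marker IDs must be unique")

  if (coding == "additive") {
    ok <- values %in% c(-1, 0, 1) | is.na(values)
    if (!all(ok)) stop("additive coding requires values in {-1, 0, 1, NA}")
    storage.mode(values) <- "double"
  } else if (coding == "dominance") {
    ok <- values %in% c(0, 1) | is.na(values)
    if (!all(ok)) stop("dominance coding requires values in {0, 1, NA}")
    storage.mode(values) <- "double"
  }

  if (is.null(allele_freqs)) {
    allele_freqs <- switch(coding,
      additive = colMeans((values + 1) / 2, na.rm = TRUE),
      dominance = {
        # under HWE het frequency h = 2pq; take the minor root p <= 0.5
        h <- pmin(colMeans(values, na.rm = TRUE), 0.5)
        (1 - sqrt(pmax(1 - 2 * h, 0))) / 2
      },
      raw_letters = rep(NA_real_, ncol(values)))
  }
  if (length(allele_freqs) != ncol(values))
    stop("allele_freqs length must equal the marker count")
  if (coding != "raw_letters" &&
      any(!is.finite(allele_freqs) | allele_freqs < 0 | allele_freqs > 1))
    stop("allele frequencies must lie in [0, 1]")
  names(allele_freqs) <- colnames(values)

  structure(list(values = values, coding = coding, allele_freqs = allele_freqs),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d individuals x %d markers (%s coding)\n",
              nrow(x$values), ncol(x$values), x$coding))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$values)

#' Convert letter genotypes to additive numeric coding
#'
#' Identifies the two alleles observed at each marker, maps the two
#' homozygotes to -1 and +1 and the heterozygote to 0. By default the minor
#' allele is coded +1 (`reference_rule = "minor_positive"`); frequency ties
#' are broken by taking the lexicographically later allele letter as +1 so
#' the conversion is deterministic.
#'
#' Markers with more than two observed alleles, no observed calls, or a
#' single observed allele (monomorphic) are dropped with a warning; the
#' per-marker reasons are returned in the `dropped` attribute.
#'
#' @param raw a [marker_matrix] with `raw_letters` coding; cells are
#'   two-letter calls (`"AG"`, `"A/G"` and `"A|G"` all accepted) or `NA`.
#' @param reference_rule `"minor_positive"` (default) or `"major_positive"`.
#' @return a [marker_matrix] with additive coding and observed allele
#'   frequencies; attribute `dropped` is a data.frame of removed markers.
#' @export
letters_to_numeric <- function(raw, reference_rule = c("minor_positive", "major_positive")) {
  reference_rule <- match.arg(reference_rule)
  if (!inherits(raw, "marker_matrix") || raw$coding != "raw_letters")
    stop("letters_to_numeric expects a marker_matrix with raw_letters coding")
  vals <- raw$values
  n <- nrow(vals)
  out <- matrix(NA_real_, n, ncol(vals), dimnames = dimnames(vals))
  freqs <- numeric(ncol(vals))
  drop_reason <- character(0); drop_id <- character(0)

  for (j in seq_len(ncol(vals))) {
    calls <- gsub("[/|]", "", vals[, j])
    calls[calls %in% c("", "NN", "--")] <- NA
    obs <- calls[!is.na(calls)]
    if (length(obs) == 0) {
      drop_id <- c(drop_id, colnames(vals)[j]); drop_reason <- c(drop_reason, "all_missing")
      freqs[j] <- NA; next
    }
    if (any(nchar(obs) != 2)) stop(sprintf(
      "marker %s: genotype calls must be two-letter diploid calls", colnames(vals)[j]))
    alleles <- sort(table(unlist(strsplit(obs, ""))), decreasing = TRUE)
    if (length(alleles) > 2) {
      warning(sprintf("marker %s has >2 alleles; dropped", colnames(vals)[j]))
      drop_id <- c(drop_id, colnames(vals)[j]); drop_reason <- c(drop_reason, "multiallelic")
      freqs[j] <- NA; next
    }
    if (length(alleles) == 1) {
      drop_id <- c(drop_id, colnames(vals)[j]); drop_reason <- c(drop_reason, "monomorphic")
      freqs[j] <- NA; next
    }
    counts <- as.vector(alleles); letters2 <- names(alleles)
    # pick the +1 allele
    if (counts[1] == counts[2]) {
      pos <- max(letters2)               # tie: lexicographically later letter
    } else if (reference_rule == "minor_positive") {
      pos <- letters2[which.min(counts)]
    } else {
      pos <- letters2[which.max(counts)]
    }
    ndose <- vapply(strsplit(calls, ""), function(a)
      if (anyNA(a) || length(a) == 0) NA_real_ else sum(a == pos), numeric(1))
    out[, j] <- ndose - 1
    freqs[j] <- mean(ndose, na.rm = TRUE) / 2
  }

  keep <- !(colnames(vals) %in% drop_id)
  if (length(drop_id))
    warning(sprintf("%d marker(s) dropped during conversion (%s)",
                    length(drop_id), paste(unique(drop_reason), collapse = ", ")))
  if (!any(keep)) stop("empty marker matrix: all markers dropped during conversion")
  mm <- marker_matrix(out[, keep, drop = FALSE], coding = "additive",
                      allele_freqs = freqs[keep])
  attr(mm, "dropped") <- data.frame(marker = drop_id, reason = drop_reason,
                                    stringsAsFactors = FALSE)
  mm
}

#' Filter markers by minor allele frequency and missingness
#'
#' @param markers a [marker_matrix] (additive or dominance coding).
#' @param min_maf minimum minor allele frequency in `[0, 0.5]`.
#' @param max_missing maximum tolerated missing fraction in `[0, 1]`.
#' @return the filtered [marker_matrix]; attribute `removed` reports counts.
#' @export
filter_markers <- function(markers, min_maf = 0, max_missing = 1) {
  stopifnot(inherits(markers, "marker_matrix"))
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must lie in [0, 0.5]")
  if (max_missing < 0 || max_missing > 1) stop("max_missing must lie in [0, 1]")
  p <- markers$allele_freqs
  maf <- pmin(p, 1 - p)
  missf <- colMeans(is.na(markers$values))
  low_maf <- maf < min_maf
  high_miss <- missf > max_missing
  keep <- !(low_maf | high_miss)
  if (!any(keep)) stop("empty marker matrix: all markers removed by filtering")
  out <- marker_matrix(markers$values[, keep, drop = FALSE], coding = markers$coding,
                       allele_freqs = p[keep])
  attr(out, "removed") <- c(low_maf = sum(low_maf),
                            high_missing = sum(high_miss & !low_maf))
  out
}

# Impute missing cells to the per-marker mean of the coded values (internal).
impute_marker_means <- function(M) {
  if (!anyNA(M)) return(M)
  mu <- colMeans(M, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(M), arr.ind = TRUE)
  M[idx] <- mu[idx[, 2]]
  M
}
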