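# Delimited-text readers/writers. All matrices are row/column labeled and
# alignment downstream is by label, never by position; missing token "NA".

sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a phenotype table
#'
#' Delimited text (TSV, or CSV by extension): one row per record, a
#' genotype ID column, optional fixed-effect columns, one or more trait
#' columns; missing values coded `NA`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = sep_for(path), na.strings = "NA",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a phenotype table
#' @param data data.frame of records.
#' @param path file path (TSV, or CSV by extension).
#' @export
write_phenotypes <- function(data, path) {
  utils::write.table(data, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Read a marker matrix
#'
#' First column holds individual IDs, header row holds marker IDs.
#'
#' @param path file path.
#' @param coding marker coding of the file contents.
#' @return a [marker_matrix].
#' @export
read_markers <- function(path, coding = "additive") {
  d <- utils::read.table(path, header = TRUE, sep = sep_for(path), na.strings = "NA",
                         check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(d[, -1, drop = FALSE])
  rownames(M) <- as.character(d[[1]])
  if (coding != "raw_letters") storage.mode(M) <- "double"
  marker_matrix(M, coding = coding)
}

#' Write a marker matrix
#' @param markers a [marker_matrix].
#' @param path file path.
#' @export
write_markers <- function(markers, path) {
  d <- data.frame(id = rownames(markers$values), markers$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Read a labeled square relationship matrix
#'
#' @param path file path (ID header row and ID first column; row and
#'   column labels must agree).
#' @param kind recorded matrix kind.
#' @return a [relationship_matrix].
#' @export
read_kinship <- function(path, kind = "custom") {
  d <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                         check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(d[, -1, drop = FALSE])
  rownames(M) <- as.character(d[[1]])
  if (!identical(rownames(M), colnames(M)))
    stop(sprintf("kinship file %s: row/column labels disagree (first: '%s' vs '%s')",
                 path, rownames(M)[1], colnames(M)[1]))
  storage.mode(M) <- "double"
  relationship_matrix(M, kind = kind, check_psd = FALSE)
}

#' Write a labeled square relationship matrix
#'
#' Values are written with 12 significant digits, so a write/read
#' round-trip is stable to well below 1e-10.
#'
#' @param K a [relationship_matrix] (or labeled square matrix).
#' @param path file path.
#' @export
write_kinship <- function(K, path) {
  vals <- apply(unclass(K), 2, function(col) sprintf("%.12g", col))
  d <- data.frame(id = rownames(K), vals, check.names = FALSE,
                  stringsAsFactors = FALSE)
  colnames(d) <- c("id", colnames(K))
  utils::write.table(d, path, sep = sep_for(path), quote = FALSE, row.names = FALSE)
}

#' Import diploid genotypes from a VCF file
#'
#' Converts biallelic GT calls to additive coding with the ALT allele as
#' +1 (`0/0` -> -1, `0/1` -> 0, `1/1` -> +1; `./.` -> `NA`). Multiallelic
#' sites are dropped with a warning. Requires the `vcfR` package.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return a [marker_matrix] in additive coding.
#' @export
read_vcf_markers <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi)) {
    warning(sprintf("%d multiallelic site(s) dropped", sum(!bi)))
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  if (is.null(ids)) ids <- paste0("M", seq_len(nrow(gt)))
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g == "0/0"] <- -1
    out[g %in% c("0/1", "1/0")] <- 0
    out[g == "1/1"] <- 1
    out
  }
  M <- apply(gt, 2, code)
  M <- t(M)                      # individuals x markers
  colnames(M) <- ids
  marker_matrix(M, coding = "additive")
}

#' Write a fitted model to delimited files
#'
#' Writes `<prefix>_vc.tsv` (variance components and boundary flags),
#' `<prefix>_blues.tsv`, one `<prefix>_blup_<term>.tsv` per random term,
#' `<prefix>_residuals.tsv`, and `<prefix>_summary.tsv` (log-likelihood,
#' AIC, BIC, method, convergence).
#'
#' @param fit an `mm_fit`.
#' @param prefix output path prefix.
#' @return invisibly, the written file paths.
#' @export
write_fit <- function(fit, prefix) {
  stopifnot(inherits(fit, "mm_fit"))
  paths <- character(0)
  w <- function(d, suffix) {
    p <- paste0(prefix, "_", suffix, ".tsv")
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    paths <<- c(paths, p)
  }
  w(data.frame(component = names(fit$vc), variance = unname(fit$vc),
               boundary = unname(fit$boundary[names(fit$vc)])), "vc")
  w(data.frame(effect = names(fit$solution$beta),
               estimate = unname(fit$solution$beta)), "blues")
  for (nm in names(fit$solution$u))
    w(data.frame(level = names(fit$solution$u[[nm]]),
                 blup = unname(fit$solution$u[[nm]])), paste0("blup_", nm))
  obs <- which(fit$spec$observed)
  w(data.frame(record = obs, fitted = fit$solution$fitted,
               residual = fit$solution$residuals), "residuals")
  w(data.frame(loglik = fit$loglik, AIC = fit$aic, BIC = fit$bic,
               method = fit$method, converged = fit$converged,
               n_iter = fit$n_iter), "summary")
  invisible(paths)
}
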