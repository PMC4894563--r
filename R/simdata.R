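#' Simulate a marker matrix under Hardy-Weinberg equilibrium
#'
#' Per-marker allele frequencies are drawn uniformly over `maf_range`;
#' each individual's genotype is the sum of two independent Bernoulli
#' allele draws, coded -1/0/+1. Labels are `G1..Gn` / `M1..Mm`.
#'
#' @param n,m numbers of individuals and markers.
#' @param maf_range frequency range for the +1 allele, inside `(0, 0.5]`.
#' @param seed integer seed (`NULL` leaves the RNG stream untouched).
#' @return a [marker_matrix] in additive coding.
#' @export
simulate_markers <- function(n, m, maf_range = c(0.05, 0.5), seed = NULL) {
  stopifnot(n >= 1, m >= 1)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(m, maf_range[1], maf_range[2])
  g <- matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m) - 1
  dimnames(g) <- list(paste0("G", seq_len(n)), paste0("M", seq_len(m)))
  marker_matrix(g, coding = "additive")
}

#' Simulate phenotypes with controlled additive/dominance architecture
#'
#' Draws additive effects for `n_qtl` randomly chosen markers (and, when
#' `var_dom > 0`, dominance effects acting on the heterozygosity codes of
#' the same QTL), then rescales each genetic-value column so its realized
#' sample variance equals `var_add` / `var_dom` exactly — sharp small-n
#' behavior, unlike expectation-scaled simulators. Residual noise is drawn
#' `N(0, var_e)`. The seed is split deterministically across the QTL
#' choice, effect draws and noise so that changing one stage's size does
#' not perturb the others.
#'
#' @param markers a [marker_matrix] in additive coding.
#' @param var_add,var_dom,var_e additive, dominance and residual variances
#'   (non-negative, not all zero).
#' @param n_qtl number of causal markers (<= m).
#' @param seed integer seed.
#' @param mu intercept.
#' @return list with `phenotypes` (data.frame `id`, `y`), `true_bv`
#'   (additive breeding values), `true_gv` (total genetic values), and
#'   `qtl` (marker ids used).
#' @export
simulate_phenotype <- function(markers, var_add = 1, var_dom = 0, var_e = 1,
                               n_qtl = min(100L, ncol(markers$values)),
                               seed = NULL, mu = 0) {
  stopifnot(inherits(markers, "marker_matrix"))
  if (any(c(var_add, var_dom, var_e) < 0) || all(c(var_add, var_dom, var_e) == 0))
    stop("variances must be non-negative and not all zero")
  M <- markers$values
  if (n_qtl > ncol(M)) stop("n_qtl cannot exceed the marker count")
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 3)

  # center and rescale to an exact realized sample variance
  rescale <- function(x, v) {
    s <- stats::var(x)
    if (s == 0) return(NULL)
    (x - mean(x)) * sqrt(v / s)
  }

  g_a <- NULL
  for (attempt in 1:10) {
    set.seed(sub_seeds[1] + attempt)
    qtl <- sample(ncol(M), n_qtl)
    set.seed(sub_seeds[2] + attempt)
    a <- stats::rnorm(n_qtl)
    raw_a <- drop(impute_marker_means(M[, qtl, drop = FALSE]) %*% a)
    g_a <- if (var_add > 0) rescale(raw_a, var_add) else rep(0, nrow(M))
    g_d <- rep(0, nrow(M))
    if (var_dom > 0) {
      d <- stats::rnorm(n_qtl)
      H <- 1 - abs(impute_marker_means(M[, qtl, drop = FALSE]))
      g_d <- rescale(drop(H %*% d), var_dom)
    }
    if (!is.null(g_a) && !is.null(g_d)) break
    g_a <- NULL
  }
  if (is.null(g_a)) stop("zero-variance genetic score after 10 QTL resampling attempts")

  set.seed(sub_seeds[3])
  e <- stats::rnorm(nrow(M), 0, sqrt(var_e))
  gv <- g_a + g_d
  y <- mu + gv + e
  list(phenotypes = data.frame(id = rownames(M), y = y, stringsAsFactors = FALSE),
       true_bv = stats::setNames(g_a, rownames(M)),
       true_gv = stats::setNames(gv, rownames(M)),
       qtl = colnames(M)[qtl])
}

#' Simulate a two-heterotic-group hybrid system
#'
#' Emulates a factorial single-cross design between two parental panels:
#' simulates a marker panel per heterotic group, builds the parental
#' genomic relationship matrices `K1`, `K2` and the hybrid SCA kernel
#' `K3 = K1 (x) K2`, draws `u_GCA1 ~ N(0, K1 s2)`, `u_GCA2 ~ N(0, K2 s2)`,
#' `u_SCA ~ N(0, K3 s2)`, and composes hybrid phenotypes over locations
#' with residual noise. A random subset of hybrids is observed (default
#' 25%); unobserved hybrids appear with `NA` responses so model assembly
#' retains their levels for prediction.
#'
#' @param n_f,n_m numbers of female and male parents.
#' @param m markers per parental panel.
#' @param var_gca1,var_gca2,var_sca,var_e variance components.
#' @param n_locations number of locations (fixed location effects drawn
#'   `N(0, 1)` once). The default of 4 replicates each observed hybrid
#'   enough for the SCA and residual variances to be separable.
#' @param prop_observed fraction of hybrids with phenotypes.
#' @param seed integer seed.
#' @return list with `data` (records for all hybrids x locations: columns
#'   `GCA1`, `GCA2`, `SCA`, `Location`, `y`), structures `K1`, `K2`, `K3`,
#'   true effect vectors `u_gca1`, `u_gca2`, `u_sca`, and `true_hybrid`
#'   (total genetic value per hybrid).
#' @export
simulate_hybrid_system <- function(n_f = 20, n_m = 20, m = 511,
                                   var_gca1 = 1, var_gca2 = 1, var_sca = 1,
                                   var_e = 1, n_locations = 4,
                                   prop_observed = 0.25, seed = NULL) {
  stopifnot(n_f >= 2, n_m >= 2)
  if (!is.null(seed)) set.seed(seed)
  females <- simulate_markers(n_f, m)
  rownames(females$values) <- paste0("F", seq_len(n_f))
  males <- simulate_markers(n_m, m)
  rownames(males$values) <- paste0("M", seq_len(n_m))
  K1 <- additive_A(females); K2 <- additive_A(males)
  K3 <- sca_kernel(K1, K2)

  u1 <- stats::setNames(rmvn_psd(unclass(K1), var_gca1), rownames(K1))
  u2 <- stats::setNames(rmvn_psd(unclass(K2), var_gca2), rownames(K2))
  u3 <- stats::setNames(rmvn_psd(unclass(K3), var_sca), rownames(K3))

  hyb <- rownames(K3)
  fem <- rep(rownames(K1), each = n_m)
  mal <- rep(rownames(K2), times = n_f)
  true_hybrid <- u1[fem] + u2[mal] + u3
  names(true_hybrid) <- hyb

  n_obs <- max(1, round(prop_observed * length(hyb)))
  observed <- sample(hyb, n_obs)
  loc_eff <- stats::rnorm(n_locations)

  recs <- expand.grid(hyb_i = seq_along(hyb), loc = seq_len(n_locations))
  dat <- data.frame(GCA1 = fem[recs$hyb_i], GCA2 = mal[recs$hyb_i],
                    SCA = hyb[recs$hyb_i],
                    Location = factor(paste0("L", recs$loc)),
                    stringsAsFactors = FALSE)
  y <- true_hybrid[recs$hyb_i] + loc_eff[recs$loc] +
    stats::rnorm(nrow(dat), 0, sqrt(var_e))
  y[!(dat$SCA %in% observed)] <- NA
  dat$y <- as.numeric(y)

  list(data = dat, K1 = K1, K2 = K2, K3 = K3,
       u_gca1 = u1, u_gca2 = u2, u_sca = u3,
       true_hybrid = true_hybrid, observed = observed)
}
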