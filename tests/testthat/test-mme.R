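test_that("assemble builds indicator incidences and retains unobserved levels", {
  # one factor, no missing data: plain 0/1 indicators with unit row sums
  set.seed(21)
  dat <- make_oneway(5, 3)
  spec <- mm_spec(dat, "y", random = list(grp = NULL))
  Z <- spec$random$grp$Z
  expect_true(all(Z %in% c(0, 1)))
  expect_equal(unname(rowSums(Z)), rep(1, nrow(dat)))
  expect_equal(colnames(Z), sort(unique(as.character(dat$grp))))

  # hand-built toy: shuffled records still map to the right columns
  d2 <- data.frame(g = c("b", "a", "b", "c"), y = 1:4)
  K <- relationship_matrix(diag(3), check_psd = FALSE)
  dimnames(K) <- list(c("a", "b", "c"), c("a", "b", "c"))
  s2 <- mm_spec(d2, "y", random = list(g = K))
  expect_equal(unname(s2$random$g$Z),
               matrix(c(0, 1, 0, 0,  1, 0, 1, 0,  0, 0, 0, 1), 4, 3))

  # 400 hybrid levels, 100 observed: all columns retained, rows = records
  sim <- simulate_hybrid_system(seed = 5, n_locations = 2)
  spec3 <- mm_spec(sim$data, "y", fixed = ~Location,
                   random = list(GCA1 = sim$K1, GCA2 = sim$K2, SCA = sim$K3))
  expect_equal(ncol(spec3$random$SCA$Z), 400)
  expect_equal(spec3$n_obs, 100 * 2)

  # errors: unknown level, all-missing response
  expect_error(mm_spec(data.frame(g = "zz", y = 1), "y", random = list(g = K)),
               "absent.*labels")
  d2$y <- NA
  expect_error(mm_spec(d2, "y", random = list(g = K)), "all responses are missing")
})

test_that("solve_mme equals dense-GLS on random instances (property, n <= 50)", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(15:50, 1)
    q <- sample(4:12, 1)
    labs <- paste0("L", seq_len(q))
    B <- matrix(rnorm(q * q), q)
    K <- relationship_matrix(crossprod(B) / q + diag(q) * 0.1, check_psd = FALSE)
    dimnames(K) <- list(labs, labs)
    dat <- data.frame(g = sample(labs, n, replace = TRUE),
                      x = rnorm(n))
    dat$y <- 1 + 0.5 * dat$x + rnorm(n)
    spec <- mm_spec(dat, "y", fixed = ~x, random = list(g = K))
    vc <- c(g = runif(1, 0.2, 3), residual = runif(1, 0.2, 3))
    sol <- solve_mme(spec, vc)
    ora <- gls_oracle(spec, vc)
    expect_equal(unname(sol$beta), unname(ora$beta), tolerance = 1e-6)
    expect_equal(unname(sol$u$g), unname(ora$u$g), tolerance = 1e-6)
    expect_equal(sol$fitted + sol$residuals, spec$y[spec$observed], tolerance = 1e-8)
  }
})

test_that("solve_mme reduces to OLS in the zero-variance limit", {
  set.seed(32)
  dat <- make_oneway(6, 4)
  spec <- mm_spec(dat, "y", random = list(grp = NULL))
  sol <- solve_mme(spec, c(grp = 1e-12, residual = 1))
  expect_lt(max(abs(sol$u$grp)), 1e-9)
  expect_equal(unname(sol$beta), mean(dat$y), tolerance = 1e-8)
})

test_that("balanced one-way BLUPs equal the classical shrinkage estimator", {
  set.seed(33)
  a <- 7; r <- 5
  dat <- make_oneway(a, r)
  spec <- mm_spec(dat, "y", random = list(grp = NULL))
  vc <- c(grp = 1.7, residual = 0.9)
  sol <- solve_mme(spec, vc)
  gm <- tapply(dat$y, dat$grp, mean)
  shrink <- r * vc[["grp"]] / (r * vc[["grp"]] + vc[["residual"]])
  expect_equal(unname(sol$u$grp), as.numeric(shrink * (gm - mean(dat$y))),
               tolerance = 1e-8)
})

test_that("three-term GCA/SCA toy solves match dense GLS", {
  sim <- simulate_hybrid_system(n_f = 4, n_m = 4, m = 60, seed = 41,
                                n_locations = 2, prop_observed = 0.6)
  spec <- mm_spec(sim$data, "y", fixed = ~Location,
                  random = list(GCA1 = sim$K1, GCA2 = sim$K2, SCA = sim$K3))
  vc <- c(GCA1 = 1.2, GCA2 = 0.7, SCA = 0.9, residual = 1.1)
  sol <- solve_mme(spec, vc)
  ora <- gls_oracle(spec, vc)
  expect_equal(unname(sol$beta), unname(ora$beta), tolerance = 1e-6)
  for (nm in names(spec$random))
    expect_equal(unname(sol$u[[nm]]), unname(ora$u[[nm]]), tolerance = 1e-6)
})

test_that("response scaling scales solutions and rescaled vc consistently", {
  set.seed(34)
  dat <- make_oneway(6, 3)
  spec <- mm_spec(dat, "y", random = list(grp = NULL))
  vc <- c(grp = 1.4, residual = 0.6)
  sol <- solve_mme(spec, vc)
  cst <- 3.7
  dat2 <- dat; dat2$y <- cst * dat2$y
  spec2 <- mm_spec(dat2, "y", random = list(grp = NULL))
  sol2 <- solve_mme(spec2, vc * cst^2)
  expect_equal(sol2$beta, cst * sol$beta, tolerance = 1e-8)
  expect_equal(sol2$u$grp, cst * sol$u$grp, tolerance = 1e-8)
  expect_equal(sol2$residuals / sqrt(cst^2 * vc[["residual"]]),
               sol$residuals / sqrt(vc[["residual"]]), tolerance = 1e-8)
})

test_that("independent unobserved levels do not perturb observed BLUPs", {
  set.seed(35)
  dat <- make_oneway(5, 3)
  labs <- levels(dat$grp)
  K5 <- relationship_matrix(diag(5), check_psd = FALSE)
  dimnames(K5) <- list(labs, labs)
  spec5 <- mm_spec(dat, "y", random = list(grp = K5))
  # add a sixth level, block-independent in K, never observed
  K6 <- relationship_matrix(diag(6), check_psd = FALSE)
  dimnames(K6) <- list(c(labs, "g6"), c(labs, "g6"))
  spec6 <- mm_spec(dat, "y", random = list(grp = list(column = "grp", K = K6)))
  vc <- c(grp = 1.1, residual = 0.7)
  s5 <- solve_mme(spec5, vc); s6 <- solve_mme(spec6, vc)
  expect_equal(s5$u$grp, s6$u$grp[labs], tolerance = 1e-10)
  expect_equal(unname(s6$u$grp[["g6"]]), 0, tolerance = 1e-10)
})

test_that("reml_loglik matches direct inversion and is basis invariant", {
  # tiny problem evaluated by hand-rolled 3x3 algebra
  y <- c(1.2, -0.4, 2.1)
  dat <- data.frame(g = c("a", "b", "c"), y = y)
  K <- relationship_matrix(diag(3), check_psd = FALSE)
  dimnames(K) <- list(c("a", "b", "c"), c("a", "b", "c"))
  spec <- mm_spec(dat, "y", random = list(g = K))
  vc <- c(g = 0.8, residual = 1.3)
  V <- 0.8 * diag(3) + 1.3 * diag(3)
  X <- matrix(1, 3, 1)
  expect_equal(reml_loglik(spec, vc), drop(loglik_oracle(y, X, V)),
               tolerance = 1e-10)

  # replacing X by X B (invertible B) leaves the value unchanged
  set.seed(36)
  dat2 <- make_oneway(5, 3)
  dat2$x <- rnorm(nrow(dat2))
  dat2$x2 <- dat2$x * 2.5 + 1   # same column space as (1, x)
  sA <- mm_spec(dat2, "y", fixed = ~x, random = list(grp = NULL))
  sB <- mm_spec(dat2, "y", fixed = ~x2, random = list(grp = NULL))
  vc2 <- c(grp = 1.2, residual = 0.5)
  expect_equal(reml_loglik(sA, vc2), reml_loglik(sB, vc2), tolerance = 1e-9)
})

test_that("rank-deficient fixed effects are reduced with a warning", {
  set.seed(37)
  dat <- make_oneway(4, 3)
  dat$x <- rnorm(nrow(dat))
  dat$xdup <- dat$x
  expect_warning(spec <- mm_spec(dat, "y", fixed = ~x + xdup,
                                 random = list(grp = NULL)),
                 "rank deficient")
  expect_equal(ncol(spec$X), 2)
})

test_that("information criteria follow the documented REML convention", {
  expect_equal(unname(information_criteria(0, 1, exp(2))), c(2, 2))
  expect_equal(unname(information_criteria(-10, 2, 100)),
               c(24, 2 * log(100) + 20))
  expect_error(information_criteria(0, 5, 4), "exceed")

  set.seed(38)
  dat <- make_oneway(5, 3)
  f <- fit(mm_spec(dat, "y", random = list(grp = NULL)))
  ic <- information_criteria(f$loglik, length(f$vc), sum(!is.na(dat$y)))
  expect_equal(f$aic, ic[["AIC"]])
  expect_equal(f$bic, ic[["BIC"]])
})
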