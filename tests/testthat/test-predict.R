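test_that("gebv returns labeled BLUPs, including unphenotyped levels", {
  set.seed(61)
  prob <- make_gblup(n = 50, m = 100)
  # mask a quarter of the phenotypes: those genotypes must still get GEBVs
  d <- prob$data
  masked <- sample(d$id, 12)
  d$y[d$id %in% masked] <- NA
  spec <- mm_spec(d, "y", random = list(g = additive_A(prob$markers)))
  f <- fit_emma(spec)
  g <- gebv(f, "g")
  expect_equal(length(g), 50)
  expect_true(all(masked %in% names(g)))
  expect_false(anyNA(g))
  expect_error(gebv(f, "nope"), "unknown term.*available")

  # GLS identity: u = s2u K Z' V^-1 (y - X beta)
  ora <- gls_oracle(spec, f$vc)
  expect_equal(unname(g), unname(ora$u$g), tolerance = 1e-6)
  # shrinkage centering: balanced Z, intercept-only X -> mean near zero
  expect_lt(abs(mean(g)), 0.05 * sd(spec$y[spec$observed]))
})

test_that("an unobserved level independent in K has GEBV exactly zero", {
  set.seed(62)
  dat <- make_oneway(4, 3)
  labs <- c(levels(dat$grp), "lone")
  K <- diag(5); dimnames(K) <- list(labs, labs)
  spec <- mm_spec(dat, "y",
                  random = list(grp = list(column = "grp",
                                           K = relationship_matrix(K, check_psd = FALSE))))
  f <- fit_emma(spec)
  expect_equal(unname(gebv(f)[["lone"]]), 0, tolerance = 1e-12)
})

test_that("predict_crosses enumerates mid-parent values correctly", {
  g <- c(p1 = 1, p2 = 2, p3 = 3, p4 = 4)
  ct <- predict_crosses(g)
  expect_equal(nrow(ct), 6)
  expect_equal(ct$predicted_value[1], 3.5)             # best: p3 x p4
  expect_equal(ct[1, c("parent1", "parent2")], data.frame(parent1 = "p3", parent2 = "p4"),
               ignore_attr = TRUE)
  expect_equal(ct$predicted_value[6], 1.5)             # worst: p1 x p2
  # (1,4) and (2,3) tie at 2.5: dense ranks share the value
  expect_equal(ct$rank, c(1, 2, 3, 3, 4, 5))

  # all-zero GEBVs -> all predictions zero, single shared rank
  z <- predict_crosses(c(a = 0, b = 0, c = 0))
  expect_true(all(z$predicted_value == 0))
  expect_true(all(z$rank == 1))

  # shift invariance: adding a constant shifts predictions by that constant
  ct2 <- predict_crosses(g + 10)
  expect_equal(ct2$predicted_value, ct$predicted_value + 10)
  expect_equal(ct2$rank, ct$rank)

  expect_error(predict_crosses(g, pairs = cbind("p1", "p9")), "unknown parent 'p9'")
})

test_that("cross enumeration size is exactly choose(n, 2)", {
  for (n in c(2, 5, 30)) {
    g <- setNames(rnorm(n), paste0("P", seq_len(n)))
    expect_equal(nrow(predict_crosses(g)), choose(n, 2))
  }
})

test_that("sca_kernel is the Kronecker product with female-outer labels", {
  I2 <- relationship_matrix(diag(2), check_psd = FALSE)
  dimnames(I2) <- list(c("f1", "f2"), c("f1", "f2"))
  I3 <- relationship_matrix(diag(3), check_psd = FALSE)
  dimnames(I3) <- list(paste0("m", 1:3), paste0("m", 1:3))
  K3 <- sca_kernel(I2, I3)
  expect_equal(unclass(K3), diag(6), ignore_attr = TRUE)
  expect_equal(rownames(K3)[1:3], c("f1:m1", "f1:m2", "f1:m3"))

  # 2x2 scalar Kronecker definition
  K1 <- relationship_matrix(matrix(c(2, 1, 1, 3), 2,
                                   dimnames = list(c("a", "b"), c("a", "b"))))
  K2 <- relationship_matrix(matrix(c(1, 0.5, 0.5, 2), 2,
                                   dimnames = list(c("x", "y"), c("x", "y"))))
  K <- sca_kernel(K1, K2)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2)
    expect_equal(K[paste(rownames(K1)[i], rownames(K2)[k], sep = ":"),
                   paste(rownames(K1)[j], rownames(K2)[l], sep = ":")],
                 K1[i, j] * K2[k, l])

  # label order consistent with assemble's Z3 column order (round trip)
  sim <- simulate_hybrid_system(n_f = 3, n_m = 3, m = 40, seed = 63,
                                n_locations = 2, prop_observed = 1)
  spec <- mm_spec(sim$data, "y", fixed = ~Location,
                  random = list(SCA = sim$K3))
  expect_equal(colnames(spec$random$SCA$Z), rownames(sim$K3))
})

test_that("20x20 parent groups give a 400 x 400 SCA kernel", {
  sim <- simulate_hybrid_system(n_f = 20, n_m = 20, m = 60, seed = 64,
                                n_locations = 1)
  expect_equal(dim(unclass(sim$K3)), c(400, 400))
})

test_that("predict_hybrids adds GCA and SCA components", {
  # hand-set BLUPs on a synthetic fit skeleton
  fake <- structure(list(solution = list(
    u = list(GCA1 = c(f1 = 1, f2 = 2),
             GCA2 = c(m1 = 10, m2 = 20),
             SCA = c("f1:m1" = 0, "f1:m2" = 0, "f2:m1" = 0, "f2:m2" = 0)))),
    class = "mm_fit")
  ct <- predict_hybrids(fake)
  got <- setNames(ct$predicted_value, paste(ct$female, ct$male, sep = ":"))
  expect_equal(got[c("f1:m1", "f1:m2", "f2:m1", "f2:m2")],
               c("f1:m1" = 11, "f1:m2" = 21, "f2:m1" = 12, "f2:m2" = 22))
  expect_error(predict_hybrids(fake, sca = "missing"), "not found")

  # all-zero BLUPs -> every hybrid predicted at the intercept
  sim <- simulate_hybrid_system(n_f = 3, n_m = 3, m = 40, seed = 65,
                                n_locations = 2, prop_observed = 1)
  spec <- mm_spec(sim$data, "y",
                  random = list(GCA1 = sim$K1, GCA2 = sim$K2, SCA = sim$K3))
  f <- fit_ai(spec, max_iter = 5)
  f$solution$u <- lapply(f$solution$u, function(u) u * 0)
  ct0 <- predict_hybrids(f, include_fixed = TRUE)
  expect_equal(ct0$predicted_value,
               rep(mean(spec$X[spec$observed, , drop = FALSE] %*% f$solution$beta), 9))
})

test_that("a GCA+SCA model out-predicts GCA-only when SCA variance is real", {
  sim <- simulate_hybrid_system(n_f = 10, n_m = 10, m = 150, var_sca = 2,
                                n_locations = 2, prop_observed = 0.5, seed = 66)
  spec3 <- mm_spec(sim$data, "y", fixed = ~Location,
                   random = list(GCA1 = sim$K1, GCA2 = sim$K2, SCA = sim$K3))
  f3 <- fit_ai(spec3)
  pred3 <- predict_hybrids(f3)
  v3 <- setNames(pred3$predicted_value, paste(pred3$female, pred3$male, sep = ":"))

  spec2 <- mm_spec(sim$data, "y", fixed = ~Location,
                   random = list(GCA1 = sim$K1, GCA2 = sim$K2))
  f2 <- fit_ai(spec2)
  v2 <- f2$solution$u$GCA1[sub(":.*", "", names(v3))] +
    f2$solution$u$GCA2[sub(".*:", "", names(v3))]
  truth <- sim$true_hybrid[names(v3)]
  expect_gt(cor(v3, truth), cor(v2, truth))
})

test_that("heritability follows the single and hybrid design formulas", {
  expect_equal(heritability(c(g = 1, residual = 1)), 0.5)
  expect_equal(heritability(c(GCA1 = 1, GCA2 = 1, SCA = 5, residual = 2),
                            design = "hybrid"), 0.5)
  expect_equal(heritability(c(g = 0.21, residual = 0.79)), 0.21)
  expect_error(heritability(c(g = 0, residual = 0)), "undefined heritability")
  expect_error(heritability(c(GCA1 = 1, residual = 1), design = "hybrid"),
               "at least two GCA")
})

test_that("accuracy upper bound is the square root of heritability", {
  expect_equal(accuracy_upper_bound(0.18), sqrt(0.18))
  # the printed two-decimal bounds for the corn traits
  expect_lt(abs(accuracy_upper_bound(0.18) - 0.43), 0.01)
  expect_lt(abs(accuracy_upper_bound(0.62) - 0.79), 0.01)
  expect_equal(accuracy_upper_bound(1), 1)
  expect_equal(accuracy_upper_bound(0), 0)
  expect_error(accuracy_upper_bound(1.2), "\\[0, 1\\]")
})

test_that("half-diallel incidence has two parents per cross", {
  Z <- half_diallel_incidence(paste0("p", 1:4))
  expect_equal(dim(Z), c(6, 4))
  expect_true(all(rowSums(Z) == 2))
  expect_true(all(colSums(Z) == 3))
  expect_equal(unname(half_diallel_incidence(c("a", "b"))), matrix(1, 1, 2))
  expect_error(half_diallel_incidence(c("a", "b"), cbind("a", "a")), "self-cross")
})
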