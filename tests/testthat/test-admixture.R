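# Maximum-likelihood admixture model: likelihood, EM updates, fitting, CV.

test_that("the log-likelihood matches hand arithmetic and a brute-force oracle", {
  # one individual, one SNP, k = 1, g = 1, f = 0.5
  g <- toy_genotypes(matrix(1L, 1, 1))
  ll <- admixture_loglik(g, matrix(1, 1, 1), matrix(0.5, 1, 1))
  expect_equal(ll, log(0.5) + log(0.5), tolerance = 1e-9)
  # certain outcome: g = 2 everywhere, f = 1 (up to the numeric floor)
  g2 <- toy_genotypes(matrix(2L, 3, 4))
  ll2 <- admixture_loglik(g2, matrix(c(0.3, 0.7, 0.5, 0.5, 0.9, 0.1),
                                     3, 2, byrow = TRUE),
                          matrix(1, 2, 4))
  expect_equal(ll2, 0, tolerance = 1e-4)
  # brute-force per-entry oracle on a random small instance with missing
  set.seed(61)
  d <- matrix(sample(c(0:2, NA), 12, replace = TRUE), 3, 4)
  g3 <- toy_genotypes(d)
  q <- .rdirichlet_test(3, 2)
  f <- matrix(runif(8, 0.1, 0.9), 2, 4)
  oracle <- 0
  for (i in 1:3) for (j in 1:4) {
    if (is.na(d[i, j])) next
    pi1 <- sum(q[i, ] * f[, j]); pi2 <- sum(q[i, ] * (1 - f[, j]))
    oracle <- oracle + d[i, j] * log(pi1) + (2 - d[i, j]) * log(pi2)
  }
  expect_equal(admixture_loglik(g3, q, f), oracle, tolerance = 1e-9)
})

test_that("the EM step has the single-population closed form as a fixed point", {
  set.seed(62)
  d <- matrix(rbinom(60, 2, 0.35), 15, 4)
  g <- toy_genotypes(d)
  st <- em_step(g, matrix(1, 15, 1), matrix(0.5, 1, 4))
  expect_equal(as.vector(st$q), rep(1, 15))
  expect_equal(as.vector(st$f), colMeans(d) / 2, tolerance = 1e-9)
  st2 <- em_step(g, st$q, st$f)
  expect_equal(st2$f, st$f, tolerance = 1e-9)     # fixed point
})

test_that("EM never decreases the likelihood and keeps parameters feasible", {
  set.seed(63)
  fx <- two_breed_fixture(200, 10, 10, seed = 63)
  g <- fx$genotypes
  for (r in 1:8) {
    q <- .rdirichlet_test(n_samples(g), 2)
    f <- matrix(runif(2 * 200, 0.05, 0.95), 2, 200)
    ll0 <- admixture_loglik(g, q, f)
    st <- em_step(g, q, f)
    expect_gte(admixture_loglik(g, st$q, st$f), ll0 - 1e-9)
    expect_true(all(abs(rowSums(st$q) - 1) < 1e-8))
    expect_true(all(st$f >= 1e-6 & st$f <= 1 - 1e-6))
  }
})

test_that("EM is nearly stationary at the generating parameters of a large cohort", {
  fx <- two_breed_fixture(10000, 0, 200, fst = 0.1, seed = 64)
  st <- em_step(fx$genotypes, fx$q, fx$freqs)
  # ancestry rows barely move when J is large
  expect_lt(max(abs(st$q - fx$q)), 0.01)
  # frequency updates move within their per-SNP sampling scale
  # (each f_kj is re-estimated from ~I attributed copies)
  expect_lt(mean(abs(st$f - fx$freqs)), 0.03)
})

test_that("fitting recovers ancestry on a small two-breed cohort", {
  fx <- two_breed_fixture(1500, 40, 40, fst = 0.1, seed = 65)
  fit <- fit_admixture(fx$genotypes, 2, tol = 1e-5, max_iter = 300,
                       n_starts = 2, seed = 66)
  expect_lt(aligned_q_error(fit$Q, fx$q), 0.08)
  expect_true(all(diff(fit$loglik_trace) > -1e-9))
  expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-8))
  # determinism
  fit2 <- fit_admixture(fx$genotypes, 2, tol = 1e-5, max_iter = 300,
                        n_starts = 2, seed = 66)
  expect_identical(fit$Q, fit2$Q)
  expect_identical(fit$loglik, fit2$loglik)
})

test_that("k = 1 fits reduce to sample frequencies in closed form", {
  fx <- two_breed_fixture(100, 5, 5, seed = 67)
  fit <- fit_admixture(fx$genotypes, 1)
  expect_true(all(fit$Q == 1))
  f_hat <- allele_frequencies(fx$genotypes)
  expect_equal(as.vector(fit$F), unname(pmin(pmax(f_hat, 1e-6), 1 - 1e-6)),
               tolerance = 1e-12)
})

test_that("supervised references improve or match unsupervised recovery", {
  fx <- two_breed_fixture(1200, 30, 30, fst = 0.1, seed = 68)
  un <- fit_admixture(fx$genotypes, 2, tol = 1e-5, max_iter = 250,
                      n_starts = 2, seed = 69)
  su <- fit_admixture(fx$genotypes, 2, tol = 1e-5, max_iter = 250,
                      n_starts = 2, seed = 69, supervised = c("NE", "CH"))
  expect_lte(aligned_q_error(su$Q, fx$q), aligned_q_error(un$Q, fx$q) + 1e-9)
})

test_that("model methods are coherent", {
  fx <- two_breed_fixture(300, 10, 10, seed = 70)
  fit <- fit_admixture(fx$genotypes, 2, tol = 1e-4, max_iter = 100,
                       n_starts = 1, seed = 71)
  expect_identical(coef(fit), fit$Q)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(dim(fitted(fit)), dim(fx$genotypes$dosage))
  expect_true(all(fitted(fit) >= 0 & fitted(fit) <= 2))
  res <- residuals(fit, genotypes = fx$genotypes)
  expect_equal(dim(res), dim(fx$genotypes$dosage))
  # projection of the training purebreds under fixed F recovers their q
  pred <- predict(fit, fx$genotypes)
  expect_lt(mean(abs(pred - fit$Q)), 0.05)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_true(all(sims[[1]] %in% 0:2))
  expect_output(print(summary(fit)), "Mean ancestry")
})

test_that("cross-validation is flat for single-population data", {
  set.seed(72)
  d <- matrix(rbinom(80 * 400, 2, rep(runif(400, 0.2, 0.8), each = 80)),
              80, 400)
  g <- toy_genotypes(d)
  cv <- cross_validate_k(g, k_range = 1:2, folds = 5, tol = 1e-3,
                         max_iter = 60, seed = 73)
  s <- attr(cv, "summary")
  # no strong spurious minimum: errors within a small relative band
  expect_lt(abs(diff(s$error)) / s$error[1], 0.03)
  expect_equal(nrow(cv), 10L)
})

test_that("inferred-population Fst is symmetric with exact boundary behaviour", {
  f <- rbind(a = c(0.2, 0.5, 0.7), b = c(0.2, 0.5, 0.7))
  tab <- inferred_pop_fst(f)
  expect_equal(tab["a", "b"], 0)
  expect_identical(tab, t(tab))
  # supervised k = 2 fit: inferred gene pools are the breed panels and the
  # divergence estimate recovers the simulated value (small upward noise
  # from the finite reference panels, ~1/(2n) per locus)
  fx <- two_breed_fixture(4000, 80, 0, fst = 0.1, seed = 74)
  fit <- fit_admixture(fx$genotypes, 2, tol = 1e-5, max_iter = 200,
                       n_starts = 1, seed = 75, supervised = c("NE", "CH"))
  est <- inferred_pop_fst(fit$F, method = "hudson")[1, 2]
  expect_lt(abs(est - 0.1), 0.02)
  # unsupervised ML sharpens the inferred pools, so its divergence runs
  # higher; it must stay on the same scale
  fit_u <- fit_admixture(fx$genotypes, 2, tol = 1e-5, max_iter = 200,
                         n_starts = 2, seed = 76)
  est_u <- inferred_pop_fst(fit_u$F, method = "hudson")[1, 2]
  expect_gt(est_u, 0.05)
  expect_lt(est_u, 0.2)
})
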