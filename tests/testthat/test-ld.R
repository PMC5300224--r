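# LD statistics: haplotype EM, r2, pruning, decay binning, Sved Ne.

test_that("haplotype EM is exact when no double heterozygotes exist", {
  da <- c(2L, 0L, 1L, 2L, 0L)
  db <- c(2L, 0L, 0L, 1L, 0L)
  em <- two_locus_haplotype_em(da, db)
  # direct gamete count: i1 -> 2x(1,1); i2,i5 -> 2x(0,0); i3 -> (1,0),(0,0);
  # i4 -> (1,1),(1,0)  =>  p11 = 3/10
  expect_equal(em$p_ij, 0.3)
  expect_lte(em$iterations, 1L)
  expect_equal(em$p_i, mean(da) / 2)
  expect_equal(em$p_j, mean(db) / 2)
})

test_that("EM haplotype frequencies match phased truth on collapsed genotypes", {
  sim <- simulate_ld_haplotypes(4000, p = 0.4, n_loci = 12,
                                copy_prob = 0.7, seed = 51)
  h <- sim$haplotypes
  g <- sim$genotypes$dosage
  for (pair in list(c(1, 2), c(3, 5), c(7, 8))) {
    a <- pair[1]; b <- pair[2]
    true_p11 <- mean(h[, a] == 1 & h[, b] == 1)
    em <- two_locus_haplotype_em(g[, a], g[, b])
    se <- sqrt(true_p11 * (1 - true_p11) / 4000)
    expect_lt(abs(em$p_ij - true_p11), 4 * se + 1e-3)
    # r2 from EM close to r2 from the phased haplotypes
    r2_true <- cor(h[, a], h[, b])^2
    r2_em <- r2_pair(em$p_ij, em$p_i, em$p_j)
    expect_lt(abs(r2_em - r2_true), 0.02)
  }
})

test_that("independent loci give p_ij near the product of margins", {
  sim <- simulate_ld_haplotypes(3000, p = 0.5, n_loci = 4,
                                copy_prob = 0, seed = 52)
  g <- sim$genotypes$dosage
  em <- two_locus_haplotype_em(g[, 1], g[, 3])
  expect_lt(abs(em$p_ij - em$p_i * em$p_j), 0.02)
})

test_that("r2 closed form matches hand arithmetic and boundaries", {
  expect_equal(r2_pair(0.25, 0.5, 0.5), 0)       # p_ij = p_i p_j
  expect_equal(r2_pair(0.5, 0.5, 0.5), 1)        # perfect association
  expect_equal(r2_pair(0.2, 0.3, 0.4), 0.0064 / 0.0504, tolerance = 1e-12)
  expect_error(r2_pair(0.2, 0, 0.5), "undefined")
})

test_that("LD records respect Frechet bounds on simulated data", {
  sim <- simulate_ld_haplotypes(400, p = 0.45, n_loci = 25,
                                copy_prob = 0.75, seed = 53)
  rec <- ld_pairs(sim$genotypes, max_bp = 100000, method = "em")
  expect_true(all(rec$r2 >= 0 & rec$r2 <= 1, na.rm = TRUE))
  expect_true(all(rec$p_ij <= pmin(rec$p_i, rec$p_j) + 1e-9))
  expect_true(all(rec$p_ij >= pmax(0, rec$p_i + rec$p_j - 1) - 1e-9))
  expect_true(all(rec$dist_bp > 0))
})

test_that("pruning matches a brute-force oracle on toy windows", {
  set.seed(54)
  d <- matrix(rbinom(40 * 5, 2, 0.5), 40, 5)
  d[, 2] <- d[, 1]; flip <- sample(40, 3); d[flip, 2] <- 2L - d[flip, 2]
  g <- toy_genotypes(d)
  kept <- ld_prune(g, window = 50, step = 10, r2_threshold = 0.1)
  expect_identical(kept, brute_prune(g, 0.1))
  expect_equal(length(kept), 4L)          # exactly one of the pair removed
  expect_true(!all(c("s1", "s2") %in% kept))
  # several random toys
  for (r in 1:5) {
    dd <- matrix(rbinom(30 * 8, 2, runif(1, 0.3, 0.7)), 30, 8)
    dd[, 4] <- dd[, 3]
    gg <- toy_genotypes(dd)
    expect_identical(ld_prune(gg, 50, 10, r2_threshold = 0.2),
                     brute_prune(gg, 0.2))
  }
})

test_that("pruning keeps everything below threshold and is monotone in threshold", {
  sim <- simulate_ld_haplotypes(300, p = 0.5, n_loci = 120,
                                copy_prob = 0.6, seed = 55)
  g <- sim$genotypes
  k10 <- length(ld_prune(g, 50, 10, r2_threshold = 0.10))
  k05 <- length(ld_prune(g, 50, 10, r2_threshold = 0.05))
  k01 <- length(ld_prune(g, 50, 10, r2_threshold = 0.01))
  expect_lte(k01, k05)
  expect_lte(k05, k10)
  # uncorrelated loci: identity
  sim0 <- simulate_ld_haplotypes(300, p = 0.5, n_loci = 30,
                                 copy_prob = 0, seed = 56)
  kept0 <- ld_prune(sim0$genotypes, 50, 10, r2_threshold = 0.99)
  expect_equal(length(kept0), 30L)
})

test_that("decay binning uses half-open intervals and flags empty bins", {
  rec <- data.frame(dist_bp = c(30000, 20000), r2 = c(0.2, 0.5))
  prof <- ld_decay_profile(rec)
  expect_equal(prof$mean_r2[2], 0.35)     # both records in [0.02, 0.04)
  expect_true(is.na(prof$mean_r2[1]))     # empty bin undefined, not 0
  expect_equal(prof$n_pairs[1], 0L)
  # Markov fixture: mean r2 non-increasing across populated bins
  sim <- simulate_ld_haplotypes(500, p = 0.5, n_loci = 150,
                                copy_prob = 0.9, seed = 57)
  rec2 <- ld_pairs(sim$genotypes, max_bp = 5e5, method = "composite")
  prof2 <- ld_decay_profile(rec2)
  m <- prof2$mean_r2[!is.na(prof2$mean_r2)]
  expect_true(all(diff(m) <= 0.01))       # monotone decay (small slack)
})

test_that("Sved Ne reproduces hand arithmetic and its algebraic inverse", {
  # r2 = 1 at any distance -> Ne = 0
  rec1 <- data.frame(dist_bp = 5e5, r2 = 1)
  ne1 <- ne_trajectory(rec1, generations = 100)
  expect_equal(ne1$ne, 0)
  # c = 0.005 M (t = 100), r2 = 0.04 -> Ne = 50 * 24 = 1200
  rec2 <- data.frame(dist_bp = 5e5, r2 = 0.04)
  ne2 <- ne_trajectory(rec2, generations = 100)
  expect_equal(ne2$ne, 1200)
  # exact round trip: r2 = 1 / (4 c Ne + 1) recovers Ne at every horizon
  gens <- c(1, 5, 10, 20, 50, 100, 200)
  ne_true <- c(100, 220, 300, 420, 730, 1160, 1760)
  cs <- 1 / (2 * gens)
  rec3 <- data.frame(dist_bp = cs * 1e8, r2 = 1 / (4 * cs * ne_true + 1))
  out <- ne_trajectory(rec3, generations = gens)
  expect_equal(out$ne, ne_true, tolerance = 1e-9)
  # r2 = 0 flagged as infinite
  rec4 <- data.frame(dist_bp = 5e5, r2 = 0)
  expect_equal(ne_trajectory(rec4, generations = 100)$ne, Inf)
  expect_error(ne_trajectory(data.frame(dist_bp = 1, r2 = 1.5), 1), "above 1")
})

test_that("a shrinking-population LD profile yields decreasing recent Ne", {
  # construct records from a Sved curve whose implied Ne declines toward
  # the present, then check the recovered trajectory preserves the pattern
  gens <- c(1, 5, 10, 20, 50, 100, 200)
  ne_true <- c(90, 200, 280, 400, 700, 1100, 1700)
  cs <- 1 / (2 * gens)
  set.seed(58)
  rec <- do.call(rbind, lapply(seq_along(gens), function(i) {
    d <- cs[i] * 1e8 * runif(40, 0.92, 1.08)
    data.frame(dist_bp = d,
               r2 = pmin(1, pmax(1e-6,
                 1 / (4 * cs[i] * ne_true[i] + 1) + rnorm(40, 0, 0.002))))
  }))
  out <- ne_trajectory(rec, generations = gens)
  expect_true(all(diff(out$ne) > 0))      # older horizons, larger Ne
})
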