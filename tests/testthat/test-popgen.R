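# Heterozygosity, exact HWE test, Fst, GRM, PCA and outlier exclusion.

test_that("heterozygosity matches closed forms and binomial sampling", {
  # p = 0.5 -> expected het 0.5; monomorphic -> 0
  d <- cbind(c(0L, 1L, 2L, 1L), c(0L, 0L, 0L, 0L))
  h <- heterozygosity(toy_genotypes(d), by_group = FALSE)
  expect_equal(h$per_snp$all$exp_het, c(0.5, 0))
  expect_equal(h$per_snp$all$obs_het, c(0.5, 0))
  # HWE cohort at p = 0.3: observed het within 3 SE of 0.42
  set.seed(41)
  g <- toy_genotypes(matrix(rbinom(500, 2, 0.3), 500, 1))
  h2 <- heterozygosity(g, by_group = FALSE)
  se <- sqrt(0.42 * 0.58 / 500)
  expect_lt(abs(h2$per_snp$all$obs_het - 0.42), 3 * se)
})

# independent enumeration oracle: conditional probability of every
# heterozygote count via the Levene distribution computed by recurrence
hwe_oracle <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  n1 <- 2 * n11 + n12; n2 <- 2 * n22 + n12
  if (n1 == 0 || n2 == 0) return(1)
  rare <- min(n1, n2)
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalised probabilities by upward recurrence:
  # P(h+2)/P(h) = (n1-h)(n2-h) / ((h+2)(h+1)) * ... derived from factorials
  pr <- numeric(length(hets))
  pr[1] <- 1
  if (length(hets) > 1) {
    for (i in 2:length(hets)) {
      h <- hets[i - 1]
      m1 <- (n1 - h) / 2; m2 <- (n2 - h) / 2
      pr[i] <- pr[i - 1] * 4 * m1 * m2 / ((h + 2) * (h + 1))
    }
  }
  pr <- pr / sum(pr)
  obs <- match(n12, hets)
  sum(pr[pr <= pr[obs] * (1 + 1e-12)])
}

test_that("exact HWE p-values match the enumeration oracle to 1e-12", {
  cases <- list(c(1, 0, 1), c(25, 50, 25), c(10, 2, 10), c(0, 10, 0),
                c(3, 7, 90), c(40, 20, 40), c(57, 14, 29))
  set.seed(42)
  for (r in 1:40) {
    n <- sample(3:100, 1)
    cnt <- as.vector(rmultinom(1, n, prob = runif(3, 0.05, 1)))
    cases[[length(cases) + 1]] <- cnt
  }
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  }
  expect_equal(hwe_exact_test(17, 0, 0), 1)    # monomorphic
  expect_gt(hwe_exact_test(25, 50, 25), 0.9)   # perfect HWE proportions
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("pairwise Fst reproduces closed forms and boundary cases", {
  expect_equal(pairwise_fst(0.2, 0.8), 0.36)   # (0.36/4)/0.25
  f <- runif(50, 0.1, 0.9)
  expect_equal(pairwise_fst(f, f), 0)
  expect_equal(pairwise_fst(rep(0, 20), rep(1, 20)), 1)
  # symmetry over random inputs
  set.seed(43)
  for (r in 1:5) {
    a <- runif(30); b <- runif(30)
    expect_equal(pairwise_fst(a, b), pairwise_fst(b, a))
    expect_equal(pairwise_fst(a, b, method = "hudson"),
                 pairwise_fst(b, a, method = "hudson"))
  }
  expect_error(pairwise_fst(rep(0, 5), rep(0, 5)), "polymorphic")
})

test_that("Hudson Fst recovers the generator divergence from breed panels", {
  fx <- two_breed_fixture(8000, 60, 0, fst = 0.1, seed = 44)
  f_by <- allele_frequencies(fx$genotypes, by_group = TRUE)
  est <- pairwise_fst(f_by["NE", ], f_by["CH", ], method = "hudson")
  # sample-frequency noise inflates the numerator slightly; the estimate
  # must still sit near the simulated divergence
  expect_lt(abs(est - 0.1), 0.025)
})

test_that("GRM is symmetric and reflects identity and breed structure", {
  fx <- two_breed_fixture(1500, 25, 0, fst = 0.15, seed = 45)
  g <- fx$genotypes
  # duplicate a sample
  g2 <- genotype_matrix(rbind(g$dosage, g$dosage[1, , drop = FALSE]),
                        g$map,
                        rbind(g$samples,
                              data.frame(id = "dup", group = "NE")))
  G <- grm(g2)
  n <- nrow(G)
  expect_equal(max(abs(G - t(G))), 0)
  expect_lt(abs(G[1, n] - G[1, 1]), 1e-10)
  expect_lt(abs(G[1, n] - G[n, n]), 1e-10)
  # within-breed relationships exceed between-breed
  ne <- which(g$samples$group == "NE"); ch <- which(g$samples$group == "CH")
  G0 <- grm(g)
  within <- c(G0[ne, ne][upper.tri(G0[ne, ne])],
              G0[ch, ch][upper.tri(G0[ch, ch])])
  between <- as.vector(G0[ne, ch])
  expect_gt(mean(within), mean(between))
})

test_that("PCA separates simulated breeds and satisfies spectral contracts", {
  fx <- two_breed_fixture(4000, 30, 0, fst = 0.15, seed = 46)
  pc <- pca_project(grm(fx$genotypes), 2)
  expect_true(all(diff(pc$values) < 1e-8))          # non-increasing
  expect_true(all(pc$values > -1e-8))               # PSD up to tolerance
  ne <- fx$genotypes$samples$group == "NE"
  # zero overlap on PC1
  expect_true(max(pc$coords[ne, 1]) < min(pc$coords[!ne, 1]) ||
              min(pc$coords[ne, 1]) > max(pc$coords[!ne, 1]))
  # rank-1 case: all-equal relationship matrix
  pc1 <- pca_project(matrix(1, 5, 5), 2)
  expect_equal(sum(abs(pc1$values) > 1e-8), 1L)
  expect_error(pca_project(matrix(1:6, 2, 3), 1), "symmetric")
})

test_that("two-lineage four-breed structure is laid out as expected on PC1", {
  # hierarchical divergence: two lineages, two indicine breeds close
  # together, composite between its parental lineages
  set.seed(47)
  J <- 3000
  p <- runif(J, 0.1, 0.9)
  bn <- function(p, fst) {
    s <- (1 - fst) / fst
    pmin(pmax(rbeta(length(p), p * s, (1 - p) * s), 1e-6), 1 - 1e-6)
  }
  p_ind <- bn(p, 0.08); p_tau <- bn(p, 0.08)       # lineages
  fr <- rbind(NE = bn(p_ind, 0.02), IB = bn(p_ind, 0.02),
              CH = bn(p_tau, 0.02))
  colnames(fr) <- paste0("snp", 1:J)
  q <- rbind(diag(3)[rep(1:3, each = 20), ],
             matrix(rep(c(0.1875, 0.1875, 0.625), 20), ncol = 3,
                    byrow = TRUE))
  labels <- rep(c("NE", "IB", "CH", "CAN"), each = 20)
  sim <- simulate_admixed_cohort(fr, q, seed = 48, group_labels = labels)
  pc <- pca_project(grm(sim$genotypes), 2)
  cent <- tapply(pc$coords[, 1], sim$genotypes$samples$group, mean)
  # composite sits between its parental lineages; indicine breeds adjacent
  expect_true((cent["CAN"] > min(cent["CH"], cent["NE"])) &&
              (cent["CAN"] < max(cent["CH"], cent["NE"])))
  expect_lt(abs(cent["NE"] - cent["IB"]),
            abs(cent["NE"] - cent["CH"]) / 2)
  expect_lt(abs(cent["CAN"] - cent["CH"]), abs(cent["CAN"] - cent["NE"]))
})

test_that("planted PCA outliers are removed and tight clusters are kept", {
  set.seed(49)
  coords <- rbind(matrix(rnorm(200 * 2), 200, 2),
                  c(30, 30))                        # ~10+ SD outlier
  rownames(coords) <- paste0("a", 1:201)
  pc <- structure(list(values = c(2, 1), coords = coords,
                       n_components = 2L), class = "pca_result")
  labels <- rep("G", 201)
  res <- pca_outlier_filter(pc, labels, n_sd = 6)
  expect_equal(res$removed, "a201")
  # homogeneous cluster at n_sd = 3: at most a small tail removed
  res2 <- pca_outlier_filter(pc, labels, n_sd = 3)
  expect_lt(length(res2$removed) / 201, 0.03)
  # infinite threshold: identity
  res3 <- pca_outlier_filter(pc, labels, n_sd = Inf)
  expect_equal(length(res3$removed), 0L)
  # tiny groups are skipped with a warning
  expect_warning(pca_outlier_filter(pc, c(rep("G", 199), "H", "H"), 3),
                 "fewer than 3")
})
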