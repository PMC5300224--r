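# Shared fixture builders.  Everything is generated in code at fixed seeds;
# no data files.

# hand-built genotype matrix from a dosage matrix
toy_genotypes <- function(dosage, chr = NULL, pos = NULL, groups = NULL) {
  dosage <- as.matrix(dosage)
  j <- ncol(dosage)
  if (is.null(chr)) chr <- rep(1L, j)
  if (is.null(pos)) pos <- stats::ave(seq_len(j), chr, FUN = seq_along) * 1000L
  if (is.null(groups)) groups <- rep("g1", nrow(dosage))
  genotype_matrix(dosage,
                  data.frame(snp_id = sprintf("s%d", seq_len(j)), chr = chr,
                             pos = pos, allele1 = rep("A", j),
                             allele2 = rep("B", j),
                             stringsAsFactors = FALSE),
                  data.frame(id = paste0("i", seq_len(nrow(dosage))),
                             group = groups, stringsAsFactors = FALSE))
}

# two purebred reference panels plus admixed samples with known q
two_breed_fixture <- function(n_snps, n_pure, n_admixed, fst = 0.1,
                              seed = 1, missing_rate = 0,
                              breed_names = c("NE", "CH"),
                              q_admixed = NULL) {
  f <- simulate_breed_frequencies(n_snps, 2, fst, seed = seed,
                                  breed_names = breed_names)
  if (is.null(q_admixed)) {
    set.seed(seed + 1)
    q1 <- stats::runif(n_admixed, 0.2, 0.8)
    q_admixed <- cbind(q1, 1 - q1)
  }
  q <- rbind(diag(2)[rep(1:2, each = n_pure), , drop = FALSE], q_admixed)
  labels <- c(rep(breed_names, each = n_pure),
              rep("admixed", nrow(q_admixed)))
  sim <- simulate_admixed_cohort(f, q, missing_rate = missing_rate,
                                 seed = seed + 2, group_labels = labels)
  list(freqs = f, q = q, genotypes = sim$genotypes, truth = sim$truth)
}

# subset a genotype_matrix by sample / SNP index
.subset_panel <- function(g, samples = NULL, snps = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(g$dosage))
  if (is.null(snps)) snps <- seq_len(ncol(g$dosage))
  map <- g$map[snps, , drop = FALSE]; rownames(map) <- NULL
  sm <- g$samples[samples, , drop = FALSE]; rownames(sm) <- NULL
  genotype_matrix(g$dosage[samples, snps, drop = FALSE], map, sm)
}

# uniform-simplex draws for test cohorts
.rdirichlet_test <- function(n, k, alpha = 1) {
  x <- matrix(stats::rgamma(n * k, alpha), n, k)
  x / rowSums(x)
}

# q-recovery error after label alignment
aligned_q_error <- function(q_hat, q_true, stat = c("rmse", "mae")) {
  stat <- match.arg(stat)
  perm <- align_labels(q_true, q_hat)
  d <- q_hat[, perm, drop = FALSE] - q_true
  if (stat == "rmse") sqrt(mean(d^2)) else mean(abs(d))
}

# independent single-window brute-force pruner implementing the documented
# rule: repeatedly find the first offending pair in position order and drop
# the lower-MAF member (tie: later position)
brute_prune <- function(g, threshold) {
  f <- allele_frequencies(g)
  maf <- pmin(f, 1 - f)
  live <- seq_len(ncol(g$dosage))
  repeat {
    worst <- NULL
    for (a in seq_along(live)) {
      for (b in seq_along(live)) {
        if (b <= a) next
        ok <- !is.na(g$dosage[, live[a]]) & !is.na(g$dosage[, live[b]])
        r2 <- suppressWarnings(cor(g$dosage[ok, live[a]],
                                   g$dosage[ok, live[b]])^2)
        if (!is.na(r2) && r2 > threshold) { worst <- c(live[a], live[b]); break }
      }
      if (!is.null(worst)) break
    }
    if (is.null(worst)) break
    drop <- if (maf[worst[1]] < maf[worst[2]]) worst[1]
            else if (maf[worst[2]] < maf[worst[1]]) worst[2]
            else worst[2]          # equal MAF: later position goes
    live <- setdiff(live, drop)
  }
  g$map$snp_id[live]
}

# constructed QC panel with a hand-countable removal per filter:
# 25 samples x 20 SNPs; s19, s20 on chromosome 30; sample i25 missing 3/18
# autosomal entries (call rate 0.833); s7 missing in 2 remaining samples
# (8.3% > 5%); s8 all heterozygous (HWE exact p << 1e-5)
build_qc_toy <- function() {
  set.seed(99)
  n <- 25; j <- 20
  d <- matrix(rbinom(n * j, 2, 0.4), n, j)
  d[, 8] <- 1L                                   # all-het SNP
  d[25, c(1, 2, 3)] <- NA_integer_               # low call-rate sample
  d[c(1, 2), 7] <- NA_integer_                   # low call-rate SNP
  toy_genotypes(d, chr = c(rep(1L, 18), 30L, 30L))
}
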