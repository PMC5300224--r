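#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional exact test on genotype counts: given the allele counts, the
#' p-value is the summed probability of all heterozygote counts (necessarily
#' of the same parity as the observed one) whose conditional probability
#' does not exceed that of the observed count.  The standard exact test
#' without mid-p correction.
#'
#' @param n_hom1 count of allele-1 homozygotes.
#' @param n_het count of heterozygotes.
#' @param n_hom2 count of allele-2 homozygotes.
#' @return the exact p-value.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  .stop_if(any(c(n_hom1, n_het, n_hom2) < 0), "genotype counts must be >= 0")
  n <- n_hom1 + n_het + n_hom2
  .stop_if(n == 0, "all genotype counts are zero: test undefined")
  n1 <- 2L * n_hom1 + n_het              # copies of allele 1
  n2 <- 2L * n_hom2 + n_het
  if (n1 == 0L || n2 == 0L) return(1)    # monomorphic: single configuration
  rare <- min(n1, n2)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(n_het = h | n, n1) = log[ n! / (n11! h! n22!) * 2^h ] - log[ (2n)! / (n1! n2!) ]
  logp <- vapply(hets, function(h) {
    m1 <- (n1 - h) / 2; m2 <- (n2 - h) / 2
    lgamma(n + 1) - lgamma(m1 + 1) - lgamma(h + 1) - lgamma(m2 + 1) +
      h * log(2) + lgamma(n1 + 1) + lgamma(n2 + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  .stop_if(is.na(obs), "observed heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

# vectorised over SNPs: columns of a dosage matrix
.hwe_pvalues <- function(dosage) {
  apply(dosage, 2L, function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0L) return(NA_real_)
    hwe_exact_test(sum(d == 2L), sum(d == 1L), sum(d == 0L))
  })
}
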