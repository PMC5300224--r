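#' Two-locus haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood estimate of the four two-locus haplotype frequencies
#' by EM over the double-heterozygote phase ambiguity (all other genotype
#' pairs have unambiguous gametes).  Marginal allele frequencies equal the
#' observed ones at every iteration.
#'
#' @param ga,gb allele-1 dosage vectors at the two SNPs (same samples);
#'   pairs with a missing value are dropped.
#' @param tol EM convergence tolerance on the haplotype-frequency change.
#' @param max_iter iteration cap.
#' @return list with `p_ij` (frequency of the allele1-allele1 haplotype),
#'   `p_i`, `p_j` (marginal allele-1 frequencies), `n` (samples used),
#'   `iterations`, `converged`.
#' @export
two_locus_haplotype_em <- function(ga, gb, tol = 1e-10, max_iter = 1000L) {
  ok <- !is.na(ga) & !is.na(gb)
  da <- ga[ok]; db <- gb[ok]
  n <- length(da)
  .stop_if(n < 2, "need at least two samples with both SNPs called")
  cnt <- function(a, b) sum(da == a & db == b)
  # unambiguous gamete counts (haplotype written as allele-at-i, allele-at-j)
  c11 <- 2 * cnt(2, 2) + cnt(2, 1) + cnt(1, 2)
  c10 <- 2 * cnt(2, 0) + cnt(2, 1) + cnt(1, 0)
  c01 <- 2 * cnt(0, 2) + cnt(0, 1) + cnt(1, 2)
  c00 <- 2 * cnt(0, 0) + cnt(0, 1) + cnt(1, 0)
  dh <- cnt(1, 1)                       # double heterozygotes
  ntot <- 2 * n
  w <- 0.5                               # P(cis | double het)
  p <- c(c11 + w * dh, c10 + (1 - w) * dh,
         c01 + (1 - w) * dh, c00 + w * dh) / ntot
  it <- 0L; converged <- (dh == 0L)
  while (!converged && it < max_iter) {
    it <- it + 1L
    cis <- p[1] * p[4]; trans <- p[2] * p[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    pn <- c(c11 + w * dh, c10 + (1 - w) * dh,
            c01 + (1 - w) * dh, c00 + w * dh) / ntot
    converged <- max(abs(pn - p)) < tol
    p <- pn
  }
  list(p_ij = p[1], p_i = p[1] + p[2], p_j = p[1] + p[3],
       n = n, iterations = it, converged = converged || dh == 0L)
}

#' Squared correlation between two loci
#'
#' Hill-Robertson r-squared from haplotype and marginal frequencies:
#' `r2 = (p_ij - p_i p_j)^2 / (p_i (1 - p_i) p_j (1 - p_j))`.
#'
#' @param p_ij frequency of the haplotype carrying allele 1 at both loci.
#' @param p_i,p_j marginal allele-1 frequencies, strictly inside (0, 1).
#' @return r-squared in `[0, 1]`.
#' @examples
#' r2_pair(0.2, 0.3, 0.4)  # 0.0064 / 0.0504
#' @export
r2_pair <- function(p_ij, p_i, p_j) {
  .stop_if(p_i <= 0 || p_i >= 1 || p_j <= 0 || p_j >= 1,
           "marginal frequency fixed at 0 or 1: r2 undefined")
  d <- p_ij - p_i * p_j
  min(1, d^2 / (p_i * (1 - p_i) * p_j * (1 - p_j)))
}

# r2 between two dosage columns
.pair_r2 <- function(da, db, method) {
  if (method == "composite") {
    ok <- !is.na(da) & !is.na(db)
    if (sum(ok) < 2 || stats::sd(da[ok]) == 0 || stats::sd(db[ok]) == 0)
      return(NA_real_)
    stats::cor(da[ok], db[ok])^2
  } else {
    em <- two_locus_haplotype_em(da, db)
    if (em$p_i <= 0 || em$p_i >= 1 || em$p_j <= 0 || em$p_j >= 1)
      return(NA_real_)
    r2_pair(em$p_ij, em$p_i, em$p_j)
  }
}

#' Pairwise LD records within chromosomes
#'
#' Computes r-squared for every within-chromosome SNP pair up to `max_bp`
#' apart.  `method = "em"` (default) estimates haplotype frequencies by
#' [two_locus_haplotype_em()] and applies [r2_pair()]; `method =
#' "composite"` uses the squared Pearson correlation of dosages (the fast
#' genotype-correlation r-squared, matching sliding-window pruning tools).
#'
#' @param g a [genotype_matrix]; SNP map must be position-sorted within
#'   chromosome.
#' @param max_bp maximum pair distance in base pairs (default 0.5 Mb).
#' @param method `"em"` or `"composite"`.
#' @return data.frame with columns `chr`, `snp_i`, `snp_j`, `dist_bp`,
#'   `r2`, and (for `"em"`) `p_ij`, `p_i`, `p_j`.
#' @export
ld_pairs <- function(g, max_bp = 5e5, method = c("em", "composite")) {
  method <- match.arg(method)
  rows <- list()
  for (ch in unique(g$map$chr)) {
    idx <- which(g$map$chr == ch)
    pos <- g$map$pos[idx]
    .stop_if(is.unsorted(pos), sprintf("chromosome %s map is not position-sorted", ch))
    for (a in seq_along(idx)) {
      b <- a + 1L
      while (b <= length(idx) && pos[b] - pos[a] <= max_bp) {
        da <- g$dosage[, idx[a]]; db <- g$dosage[, idx[b]]
        if (method == "em") {
          em <- two_locus_haplotype_em(da, db)
          r2 <- if (em$p_i > 0 && em$p_i < 1 && em$p_j > 0 && em$p_j < 1)
            r2_pair(em$p_ij, em$p_i, em$p_j) else NA_real_
          rows[[length(rows) + 1L]] <-
            data.frame(chr = ch, snp_i = g$map$snp_id[idx[a]],
                       snp_j = g$map$snp_id[idx[b]],
                       dist_bp = pos[b] - pos[a], r2 = r2,
                       p_ij = em$p_ij, p_i = em$p_i, p_j = em$p_j,
                       stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <-
            data.frame(chr = ch, snp_i = g$map$snp_id[idx[a]],
                       snp_j = g$map$snp_id[idx[b]],
                       dist_bp = pos[b] - pos[a],
                       r2 = .pair_r2(da, db, "composite"),
                       stringsAsFactors = FALSE)
        }
        b <- b + 1L
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Sliding-window LD pruning
#'
#' PLINK-style `--indep-pairwise` pruning: windows of `window` SNPs
#' advancing by `step` SNPs along each chromosome; within a window, while
#' any kept pair exceeds `r2_threshold`, the member of the first offending
#' pair (in position order) with the lower minor allele frequency is
#' removed (MAF tie: the later map position goes).  Deterministic given
#' this tie rule.
#'
#' @param g a [genotype_matrix], position-sorted within chromosome.
#' @param window window size in SNPs.
#' @param step window shift in SNPs.
#' @param r2_threshold pruning threshold (e.g. 0.10, 0.05, 0.01).
#' @param method r-squared flavour passed to the pairwise computation
#'   (`"composite"` dosage-correlation, the pruning default, or `"em"`).
#' @return character vector of kept SNP identifiers, in map order.
#' @export
ld_prune <- function(g, window = 50L, step = 10L, r2_threshold,
                     method = c("composite", "em")) {
  method <- match.arg(method)
  .stop_if(missing(r2_threshold), "r2_threshold is required")
  f <- allele_frequencies(g)
  maf <- pmin(f, 1 - f)
  keep <- rep(TRUE, n_snps(g))
  for (ch in unique(g$map$chr)) {
    idx <- which(g$map$chr == ch)
    .stop_if(is.unsorted(g$map$pos[idx]),
             sprintf("chromosome %s map is not position-sorted", ch))
    starts <- seq(1L, max(1L, length(idx)), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      repeat {
        live <- win[keep[win]]
        if (length(live) < 2L) break
        removed <- FALSE
        for (a in seq_len(length(live) - 1L)) {
          if (removed) break
          for (b in (a + 1L):length(live)) {
            r2 <- .pair_r2(g$dosage[, live[a]], g$dosage[, live[b]], method)
            if (!is.na(r2) && r2 > r2_threshold) {
              pair <- c(live[a], live[b])
              drop <- if (isTRUE(maf[pair[1]] < maf[pair[2]])) pair[1]
                      else if (isTRUE(maf[pair[2]] < maf[pair[1]])) pair[2]
                      else pair[which.max(g$map$pos[pair])]
              keep[drop] <- FALSE
              removed <- TRUE
              break
            }
          }
        }
        if (!removed) break
      }
      if (s + window - 1L >= length(idx)) break
    }
  }
  g$map$snp_id[keep]
}

#' LD-decay profile over distance bins
#'
#' Mean r-squared per half-open physical-distance bin `[lo, hi)`.  The
#' default bins are the conventional short-range cattle-panel intervals:
#' 0-0.02, 0.02-0.04, ..., 0.08-0.10, then 0.10-0.20, 0.20-0.30,
#' 0.30-0.40, 0.40-0.50 Mb.
#'
#' @param records data.frame of LD records with columns `dist_bp` and `r2`
#'   (as from [ld_pairs()]).
#' @param breaks_mb bin boundaries in megabase pairs.
#' @return data.frame with `bin`, `lo_mb`, `hi_mb`, `n_pairs`, `mean_r2`
#'   (`NA` for empty bins, never 0).
#' @export
ld_decay_profile <- function(records,
                             breaks_mb = c(0, 0.02, 0.04, 0.06, 0.08,
                                           0.10, 0.20, 0.30, 0.40, 0.50)) {
  d_mb <- records$dist_bp / 1e6
  bin <- findInterval(d_mb, breaks_mb)       # [lo, hi) half-open
  nb <- length(breaks_mb) - 1L
  out <- data.frame(
    bin = sprintf("%.2f to %.2f", breaks_mb[-length(breaks_mb)],
                  breaks_mb[-1]),
    lo_mb = breaks_mb[-length(breaks_mb)],
    hi_mb = breaks_mb[-1],
    n_pairs = 0L, mean_r2 = NA_real_, stringsAsFactors = FALSE)
  for (bidx in seq_len(nb)) {
    sel <- bin == bidx & !is.na(records$r2)
    out$n_pairs[bidx] <- sum(sel)
    if (any(sel)) out$mean_r2[bidx] <- mean(records$r2[sel])
  }
  out
}

#' Effective population size from LD at matched distances
#'
#' Sved's relation `Ne = (1 / (4c)) (1 / r2 - 1)` links expected r-squared
#' to effective size at genetic distance `c` Morgans, and the estimate at
#' distance `c` refers to the population `1 / (2c)` generations ago.  For
#' each requested generation horizon `t`, r-squared is averaged over pairs
#' whose physical distance lies within a relative `band` of the target
#' distance `c = 1 / (2t)` (converted at `bp_per_morgan`, default 100 Mbp
#' per Morgan).
#'
#' @param records data.frame with `dist_bp` and `r2` (as from
#'   [ld_pairs()]).
#' @param generations generation horizons (default 1, 5, 10, 20, 50, 100,
#'   200 generations ago).
#' @param bp_per_morgan base pairs per Morgan.
#' @param band relative half-width of the distance window around the
#'   target (default 0.10).
#' @return data.frame with `generations_ago`, `c_morgan`, `target_bp`,
#'   `n_pairs`, `mean_r2`, `ne` (`Inf` flagged when mean r-squared is 0;
#'   `NA` when no pairs fall in the window).
#' @export
ne_trajectory <- function(records,
                          generations = c(1, 5, 10, 20, 50, 100, 200),
                          bp_per_morgan = 1e8, band = 0.10) {
  .stop_if(any(records$r2 > 1 + 1e-9, na.rm = TRUE),
           "r2 above 1: invalid LD records")
  out <- data.frame(generations_ago = generations,
                    c_morgan = 1 / (2 * generations),
                    target_bp = bp_per_morgan / (2 * generations),
                    n_pairs = 0L, mean_r2 = NA_real_, ne = NA_real_)
  for (r in seq_len(nrow(out))) {
    tgt <- out$target_bp[r]
    sel <- !is.na(records$r2) &
      records$dist_bp >= tgt * (1 - band) &
      records$dist_bp <= tgt * (1 + band)
    out$n_pairs[r] <- sum(sel)
    if (!any(sel)) next
    r2 <- mean(records$r2[sel])
    out$mean_r2[r] <- r2
    cc <- out$c_morgan[r]
    out$ne[r] <- if (r2 == 0) Inf else (1 / (4 * cc)) * (1 / r2 - 1)
  }
  out
}
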