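#' Expected and observed heterozygosity
#'
#' Per SNP and per sample group: expected heterozygosity 2p(1-p) with p the
#' group allele-1 frequency, and observed heterozygosity as the fraction of
#' heterozygous calls among non-missing calls.  SNPs with no call in a group
#' are excluded from that group's summaries.
#'
#' @param g a [genotype_matrix].
#' @param by_group if `FALSE`, all samples are pooled into one group.
#' @return a `het_summary`: list with `per_snp` (per group, data.frame of
#'   `exp_het`/`obs_het` per SNP) and `summary` (per group mean, SD, median
#'   of both).
#' @export
heterozygosity <- function(g, by_group = TRUE) {
  groups <- if (by_group) unique(g$samples$group) else "all"
  per_snp <- list()
  rows <- list()
  for (gr in groups) {
    d <- if (by_group) g$dosage[g$samples$group == gr, , drop = FALSE]
         else g$dosage
    .stop_if(nrow(d) == 0, sprintf("group '%s' is empty", gr))
    n <- colSums(!is.na(d))
    p <- colSums(d, na.rm = TRUE) / (2 * n)
    exp_het <- 2 * p * (1 - p)
    obs_het <- colSums(d == 1L, na.rm = TRUE) / n
    exp_het[n == 0] <- NA_real_
    obs_het[n == 0] <- NA_real_
    per_snp[[gr]] <- data.frame(snp_id = g$map$snp_id, exp_het = exp_het,
                                obs_het = obs_het, n_called = n,
                                stringsAsFactors = FALSE)
    rows[[gr]] <- data.frame(
      group = gr,
      exp_mean = mean(exp_het, na.rm = TRUE),
      exp_sd = stats::sd(exp_het, na.rm = TRUE),
      exp_median = stats::median(exp_het, na.rm = TRUE),
      obs_mean = mean(obs_het, na.rm = TRUE),
      obs_sd = stats::sd(obs_het, na.rm = TRUE),
      obs_median = stats::median(obs_het, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  structure(list(per_snp = per_snp,
                 summary = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "het_summary")
}

#' @export
print.het_summary <- function(x, ...) {
  cat("Heterozygosity summary (expected / observed)\n")
  s <- x$summary
  for (r in seq_len(nrow(s)))
    cat(sprintf("  %-12s exp %.2f (%.2f), median %.2f | obs %.2f (%.2f), median %.2f\n",
                s$group[r], s$exp_mean[r], s$exp_sd[r], s$exp_median[r],
                s$obs_mean[r], s$obs_sd[r], s$obs_median[r]))
  invisible(x)
}

#' Pairwise Fst between two populations
#'
#' Ratio-of-averages estimators from per-SNP allele frequencies.  The
#' default (`"wright"`) form is the across-population variance over the
#' limiting heterozygosity,
#' `sum_j (p_aj - p_bj)^2 / 4  /  sum_j pbar_j (1 - pbar_j)`,
#' clamped to `[0, 1]`.  The `"hudson"` form,
#' `sum_j (p_aj - p_bj)^2 / sum_j [p_aj (1 - p_bj) + p_bj (1 - p_aj)]`,
#' is unbiased for the per-population drift parameter of the
#' Balding-Nichols model when each population has diverged independently
#' from a common ancestor, and is the form used in the package's
#' divergence-recovery checks.  Loci with undefined frequency in either
#' population are dropped.
#'
#' @param freqs_a,freqs_b per-SNP allele-1 frequency vectors over the same
#'   SNPs.
#' @param weights optional per-SNP weights.
#' @param method `"wright"` (default) or `"hudson"`.
#' @return Fst scalar in `[0, 1]`.
#' @examples
#' pairwise_fst(0.2, 0.8)  # single locus: (0.36/4)/0.25 = 0.36
#' @export
pairwise_fst <- function(freqs_a, freqs_b, weights = NULL,
                         method = c("wright", "hudson")) {
  method <- match.arg(method)
  .stop_if(length(freqs_a) != length(freqs_b),
           "frequency vectors differ in length")
  ok <- !is.na(freqs_a) & !is.na(freqs_b)
  a <- freqs_a[ok]; b <- freqs_b[ok]
  w <- if (is.null(weights)) rep(1, sum(ok)) else weights[ok]
  pbar <- (a + b) / 2
  poly <- pbar > 0 & pbar < 1
  .stop_if(!any(poly), "no polymorphic loci: Fst undefined")
  if (method == "wright") {
    num <- sum(w * (a - b)^2 / 4)
    den <- sum(w * pbar * (1 - pbar))
  } else {
    num <- sum(w * (a - b)^2)
    den <- sum(w * (a * (1 - b) + b * (1 - a)))
  }
  min(1, max(0, num / den))
}

#' Genomic relationship matrix
#'
#' VanRaden method-1 GRM: dosages centred by twice the allele frequency,
#' cross-product scaled by `2 * sum_j p_j (1 - p_j)`.  Missing dosages are
#' mean-imputed per SNP (equivalently, contribute zero after centring).
#'
#' @param g a [genotype_matrix] with at least two samples and one
#'   polymorphic SNP.
#' @return symmetric samples-by-samples relationship matrix.
#' @export
grm <- function(g) {
  .stop_if(n_samples(g) < 2, "need at least two samples")
  p <- allele_frequencies(g)
  poly <- !is.na(p) & p > 0 & p < 1
  .stop_if(!any(poly), "no polymorphic SNPs: GRM undefined")
  d <- g$dosage[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(d, 2L, 2 * p)
  z[is.na(z)] <- 0
  gmat <- tcrossprod(z) / (2 * sum(p * (1 - p)))
  dimnames(gmat) <- list(g$samples$id, g$samples$id)
  gmat
}

#' Principal components of a relationship matrix
#'
#' Eigendecomposition of a symmetric (genomic) relationship matrix.
#' Sample coordinates are eigenvectors scaled by the square root of their
#' (non-negative-truncated) eigenvalues, ordered by decreasing eigenvalue.
#' Sign convention: the loading of largest magnitude on each component is
#' positive.
#'
#' @param G symmetric relationship matrix (e.g. from [grm()]).
#' @param n_components number of leading components to return.
#' @return a `pca_result`: list with `values` (all eigenvalues,
#'   non-increasing), `coords` (samples by `n_components` score matrix) and
#'   `n_components`.
#' @export
pca_project <- function(G, n_components = 2L) {
  .stop_if(!isSymmetric(unname(G), tol = 1e-8),
           "relationship matrix must be symmetric")
  .stop_if(n_components > nrow(G), "more components than samples")
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  vals <- e$values
  vecs <- e$vectors[, seq_len(n_components), drop = FALSE]
  for (cc in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, cc]))
    if (vecs[i, cc] < 0) vecs[, cc] <- -vecs[, cc]
  }
  coords <- sweep(vecs, 2L, sqrt(pmax(vals[seq_len(n_components)], 0)), `*`)
  rownames(coords) <- rownames(G)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  structure(list(values = vals, coords = coords,
                 n_components = n_components),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  tot <- sum(pmax(x$values, 0))
  pct <- 100 * pmax(x$values[seq_len(x$n_components)], 0) / tot
  cat(sprintf("PCA: %d samples, %d components (%% variance: %s)\n",
              nrow(x$coords), x$n_components,
              paste(sprintf("%.1f", pct), collapse = ", ")))
  invisible(x)
}

#' Exclude samples outside their group's main cluster
#'
#' A reproducible replacement for visual out-of-cluster exclusion: within
#' each group, a sample is flagged when, on any of the first `components`
#' principal components, it lies more than `n_sd` robust standard
#' deviations (MAD) from the group median.  Single pass; groups with fewer
#' than three samples are skipped with a warning.
#'
#' @param pca a `pca_result` from [pca_project()].
#' @param labels per-sample group labels, in the row order of the PCA
#'   coordinates.
#' @param n_sd flagging threshold in robust SDs (default 3).
#' @param components number of leading components examined (default 2).
#' @return list with `kept` and `removed` sample-identifier vectors and a
#'   per-sample `details` data.frame.
#' @export
pca_outlier_filter <- function(pca, labels, n_sd = 3, components = 2L) {
  co <- pca$coords[, seq_len(min(components, ncol(pca$coords))),
                   drop = FALSE]
  ids <- rownames(co)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(co)))
  out <- logical(nrow(co))
  skipped <- character(0)
  for (gr in unique(labels)) {
    rows <- which(labels == gr)
    if (length(rows) < 3L) {
      skipped <- c(skipped, gr)
      next
    }
    x <- co[rows, , drop = FALSE]
    ctr <- apply(x, 2L, stats::median)
    sc <- apply(x, 2L, stats::mad)
    sc[sc == 0] <- 1e-12
    z <- abs(sweep(sweep(x, 2L, ctr), 2L, sc, `/`))
    out[rows] <- apply(z, 1L, max) > n_sd
  }
  if (length(skipped))
    warning("groups with fewer than 3 samples skipped: ",
            paste(skipped, collapse = ", "))
  list(kept = ids[!out], removed = ids[out],
       details = data.frame(id = ids, group = labels, outlier = out,
                            stringsAsFactors = FALSE))
}
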