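# Maximum-likelihood admixture model.
#
# Model: individual i draws, independently at each SNP j, two allele copies
# from a mixture of k population gene pools; population k contributes a
# fraction q_ik of i's genome and carries allele 1 at frequency f_kj.  The
# allele-1 dosage g_ij is then Binomial(2, sum_k q_ik f_kj), and the sample
# log-likelihood is
#   L(Q,F) = sum_ij { g_ij log(sum_k q_ik f_kj)
#                     + (2 - g_ij) log(sum_k q_ik (1 - f_kj)) }
# over non-missing entries.  Fitting is by EM block ascent, which is
# monotone in L.

# masked matrices used by the likelihood and the EM update
.admix_parts <- function(g) {
  G <- g$dosage
  M <- !is.na(G)
  G1 <- ifelse(M, G, 0)          # allele-1 copy counts
  G2 <- ifelse(M, 2L - G, 0)     # allele-2 copy counts
  list(G1 = G1, G2 = G2, M = M, Ji = rowSums(M))
}

#' Admixture model log-likelihood
#'
#' Evaluates the binomial-mixture log-likelihood of a genotype matrix at
#' ancestry matrix `q` (rows sum to 1) and population allele frequencies
#' `f`, skipping missing genotypes.  Mixture dosage probabilities are
#' floored at 1e-6 so boundary evaluations stay finite.
#'
#' @param g a [genotype_matrix].
#' @param q individuals-by-populations ancestry matrix.
#' @param f populations-by-SNPs allele-1 frequency matrix.
#' @return the log-likelihood (scalar).
#' @export
admixture_loglik <- function(g, q, f) {
  q <- as.matrix(q); f <- as.matrix(f)
  .stop_if(ncol(q) != nrow(f), "q and f disagree on the number of populations")
  .stop_if(nrow(q) != nrow(g$dosage) || ncol(f) != ncol(g$dosage),
           "dimensions of q/f do not match the genotype matrix")
  parts <- .admix_parts(g)
  d1 <- .clamp(q %*% f, .EPS, 1)
  d2 <- .clamp(q %*% (1 - f), .EPS, 1)
  sum(parts$G1 * log(d1) + parts$G2 * log(d2))
}

#' One EM block-ascent step
#'
#' The E-step attributes each allele copy to a population of origin
#' (responsibilities proportional to `q_ik f_kj` for allele-1 copies and
#' `q_ik (1 - f_kj)` for allele-2 copies); the M-step re-estimates `q` as
#' each individual's mean responsibility over its non-missing allele
#' copies and `f` as the attributed allele-1 fraction per population and
#' SNP.  The update never decreases the log-likelihood.
#'
#' @param g a [genotype_matrix].
#' @param q current ancestry matrix (rows on the open simplex).
#' @param f current frequency matrix (entries inside (0, 1)).
#' @param fixed_rows optional integer vector of sample rows whose `q` is
#'   held fixed (supervised reference animals).
#' @return list with updated `q` and `f`.
#' @export
em_step <- function(g, q, f, fixed_rows = NULL) {
  q <- as.matrix(q); f <- as.matrix(f)
  parts <- .admix_parts(g)
  .em_update(parts, q, f, fixed_rows)
}

# fused E+M update from precomputed masked parts; the per-population sums
# rowSums(r1 * outer(q_k, f_k)) and colSums(...) collapse to matrix
# products, so the whole step is a handful of BLAS calls
.em_update <- function(parts, q, f, fixed_rows = NULL, loglik = FALSE) {
  k <- ncol(q)
  d1 <- .clamp(q %*% f, .EPS, 1)
  d2 <- .clamp(q %*% (1 - f), .EPS, 1)
  ll <- if (loglik) sum(parts$G1 * log(d1) + parts$G2 * log(d2)) else NULL
  r1 <- parts$G1 / d1                  # I x J weights
  r2 <- parts$G2 / d2
  a_row <- r1 %*% t(f)                 # I x k: sum_j r1_ij f_kj
  b_row <- r2 %*% (1 - t(f))
  qn <- q * (a_row + b_row)
  qn <- qn / pmax(2 * parts$Ji, 1)
  qn <- qn / rowSums(qn)
  a_col <- crossprod(r1, q)            # J x k: sum_i r1_ij q_ik
  b_col <- crossprod(r2, q)
  fn <- f * t(a_col)
  fd <- fn + (1 - f) * t(b_col)
  # empty population guard: undefined frequency updates keep previous value
  fnew <- ifelse(fd <= 0, f, fn / pmax(fd, .Machine$double.xmin))
  fnew <- .clamp(fnew)
  if (!is.null(fixed_rows) && length(fixed_rows))
    qn[fixed_rows, ] <- q[fixed_rows, , drop = FALSE]
  list(q = qn, f = fnew, loglik = ll)
}

.admix_init <- function(g, k, supervised_rows = NULL, supervised_pop = NULL) {
  n <- n_samples(g); j <- n_snps(g)
  q <- .rdirichlet(n, rep(1, k))
  fobs <- allele_frequencies(g)
  fobs[is.na(fobs)] <- 0.5
  f <- matrix(rep(fobs, each = k), k, j) +
    matrix(stats::runif(k * j, -0.05, 0.05), k, j)
  f <- .clamp(f)
  if (!is.null(supervised_rows) && length(supervised_rows)) {
    q[supervised_rows, ] <- .EPS / (k - 1 + .EPS)
    q[cbind(supervised_rows, supervised_pop)] <- 1 - .EPS
    q <- q / rowSums(q)
  }
  list(q = q, f = f)
}

#' Fit the admixture model by EM
#'
#' Maximum-likelihood estimation of ancestry fractions `Q` and population
#' allele frequencies `F` for a given number of populations `k`.  Runs
#' `n_starts` random restarts and keeps the best final log-likelihood;
#' convergence is declared when the absolute change in log-likelihood
#' between successive iterations falls below `tol` (default 1e-6).
#'
#' In supervised mode, samples whose group label appears in `supervised`
#' have their ancestry row pinned to the corresponding population (unit
#' vector up to the numerical floor) and only the remaining rows are
#' estimated; population `k` is then identified with `supervised[k]`.
#'
#' @param g a [genotype_matrix] (post-QC).
#' @param k number of ancestral populations (>= 1).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap per start; a capped run is returned with
#'   `converged = FALSE`.
#' @param n_starts number of random restarts.
#' @param seed integer seed; the fit is deterministic given data and seed.
#' @param supervised optional character vector of group labels (length
#'   `k`): samples with those labels are treated as purebred references.
#' @return an object of class `admix_fit`: list with `Q`, `F`, `loglik`,
#'   `loglik_trace` (best start), `converged`, `iterations`, `k`,
#'   `pop_names`, and bookkeeping fields.
#' @seealso [cross_validate_k()], [align_labels()], [inferred_pop_fst()]
#' @export
fit_admixture <- function(g, k, tol = 1e-6, max_iter = 2000L,
                          n_starts = 5L, seed = 1L, supervised = NULL) {
  .stop_if(k < 1, "k must be >= 1")
  sup_rows <- NULL; sup_pop <- NULL; pop_names <- paste0("pop", seq_len(k))
  if (!is.null(supervised)) {
    .stop_if(length(supervised) != k,
             "supervised labels must have length k")
    sup_rows <- which(g$samples$group %in% supervised)
    sup_pop <- match(g$samples$group[sup_rows], supervised)
    pop_names <- supervised
  }
  if (k == 1L) {
    f <- matrix(allele_frequencies(g), 1L)
    f[is.na(f)] <- 0.5
    f <- .clamp(f)
    q <- matrix(1, n_samples(g), 1L)
    ll <- admixture_loglik(g, q, f)
    return(structure(list(Q = q, F = f, loglik = ll, loglik_trace = ll,
                          converged = TRUE, iterations = 1L, k = 1L,
                          pop_names = pop_names,
                          sample_ids = g$samples$id,
                          groups = g$samples$group,
                          snp_ids = g$map$snp_id,
                          supervised = supervised, n_starts = 1L,
                          call = match.call()),
                     class = "admix_fit"))
  }
  seeds <- .child_seeds(seed, n_starts)
  parts <- .admix_parts(g)
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(seeds[s])
    st <- .admix_init(g, k, sup_rows, sup_pop)
    trace <- numeric(0)
    prev_ll <- -Inf
    converged <- FALSE
    it <- 0L
    repeat {
      upd <- .em_update(parts, st$q, st$f, fixed_rows = sup_rows,
                        loglik = TRUE)
      trace <- c(trace, upd$loglik)
      if (abs(upd$loglik - prev_ll) < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
      prev_ll <- upd$loglik
      st <- list(q = upd$q, f = upd$f)
      it <- it + 1L
    }
    ll <- trace[length(trace)]
    if (is.null(best) || ll > best$loglik)
      best <- list(q = st$q, f = st$f, loglik = ll, trace = trace,
                   converged = converged, iterations = it)
  }
  rownames(best$q) <- g$samples$id
  colnames(best$q) <- pop_names
  rownames(best$f) <- pop_names
  colnames(best$f) <- g$map$snp_id
  structure(list(Q = best$q, F = best$f, loglik = best$loglik,
                 loglik_trace = best$trace, converged = best$converged,
                 iterations = best$iterations, k = k,
                 pop_names = pop_names, sample_ids = g$samples$id,
                 groups = g$samples$group, snp_ids = g$map$snp_id,
                 supervised = supervised, n_starts = n_starts,
                 call = match.call()),
            class = "admix_fit")
}

#' Cross-validation over the number of populations
#'
#' ADMIXTURE-style v-fold cross-validation: the non-missing genotype
#' entries are partitioned at random into `folds` folds; each fold in turn
#' is masked (set missing), the model is refitted, and the masked entries
#' are scored by their average negative binomial log-likelihood under the
#' refit's predicted dosage probability `sum_k q_ik f_kj`.  A good `k`
#' shows low cross-validation error relative to the other values.
#'
#' @param g a [genotype_matrix].
#' @param k_range values of `k` to compare (default 1 to 5).
#' @param folds number of folds (default 5).
#' @param tol,max_iter,n_starts fitting controls passed to
#'   [fit_admixture()].
#' @param seed integer seed controlling the partition and the refits.
#' @return data.frame with one row per (`k`, `fold`) and columns `k`,
#'   `fold`, `error`, plus a `summary` attribute with the per-k mean.
#' @export
cross_validate_k <- function(g, k_range = 1:5, folds = 5L, tol = 1e-4,
                             max_iter = 500L, n_starts = 1L, seed = 1L) {
  parts <- which(!is.na(g$dosage))
  .stop_if(length(parts) < folds, "not enough non-missing entries")
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), length(parts)))
  seeds <- .child_seeds(seed + 1L, length(k_range) * folds)
  rows <- list()
  si <- 0L
  for (k in k_range) {
    for (fo in seq_len(folds)) {
      si <- si + 1L
      mask <- parts[fold_id == fo]
      gt <- g
      gt$dosage[mask] <- NA_integer_
      fit <- fit_admixture(gt, k, tol = tol, max_iter = max_iter,
                           n_starts = n_starts, seed = seeds[si])
      pi_hat <- .clamp(fit$Q %*% fit$F, .EPS, 1 - .EPS)
      gv <- g$dosage[mask]
      pv <- pi_hat[mask]
      err <- -mean(gv * log(pv) + (2 - gv) * log(1 - pv))
      rows[[length(rows) + 1L]] <- data.frame(k = k, fold = fo, error = err)
    }
  }
  out <- do.call(rbind, rows)
  summ <- stats::aggregate(error ~ k, out, mean)
  attr(out, "summary") <- summ
  out
}

#' Pairwise Fst between inferred populations
#'
#' Applies [pairwise_fst()] to every pair of inferred population frequency
#' vectors, giving the ancestry-divergence table among the fitted gene
#' pools.
#'
#' @param f_hat populations-by-SNPs frequency matrix (e.g. `fit$F`).
#' @param method estimator passed to [pairwise_fst()].
#' @return symmetric k-by-k matrix of pairwise Fst.
#' @export
inferred_pop_fst <- function(f_hat, method = "wright") {
  f_hat <- as.matrix(f_hat)
  k <- nrow(f_hat)
  .stop_if(k < 2, "need at least two populations")
  out <- matrix(0, k, k, dimnames = list(rownames(f_hat), rownames(f_hat)))
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    out[a, b] <- out[b, a] <- pairwise_fst(f_hat[a, ], f_hat[b, ],
                                           method = method)
  }
  out
}
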