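# Bayesian admixture model fitted by Gibbs sampling.
#
# Model (the admixture model with independent loci): each of individual i's
# two allele copies at locus l has a latent population of origin
# z_l^(i,a) ~ Categorical(q^(i)); given z = k, the copy carries allele 1
# with probability p_kl.  Priors: q^(i) ~ Dirichlet(alpha, ..., alpha) and
# p_kl ~ Beta(lambda, lambda).  All full conditionals are conjugate, so the
# sampler cycles z | p, q  ->  p | z  ->  q | z.
#
# The latent assignment is carried in count form: per population k, the
# number of individual i's allele-1 (and allele-2) copies at locus j
# assigned to k.  Because allele copies are exchangeable given the
# genotype, sampling these counts from the appropriate multinomial (via
# sequential binomial decomposition) is an exact draw of Z.

# multinomial counts over k populations for each cell of `sizes` (I x J),
# with unnormalised weight matrices w[[k]] (I x J)
.sample_assignment_counts <- function(sizes, w) {
  k <- length(w)
  total <- Reduce(`+`, w)
  out <- vector("list", k)
  rem <- sizes
  wrem <- total
  for (kk in seq_len(k)) {
    if (kk == k) { out[[kk]] <- rem; break }
    pk <- w[[kk]] / pmax(wrem, .Machine$double.xmin)
    pk <- pmin(pmax(pk, 0), 1)
    draw <- stats::rbinom(length(rem), rem, pk)
    dim(draw) <- dim(rem)
    out[[kk]] <- draw
    rem <- rem - draw
    wrem <- wrem - w[[kk]]
  }
  out
}

#' One Gibbs full-conditional update cycle
#'
#' Updates, in order: the latent population-of-origin assignments of every
#' non-missing allele copy (multinomially, with probability proportional
#' to `q_ik p_kj` for allele-1 copies and `q_ik (1 - p_kj)` for allele-2
#' copies), the population allele frequencies (`Beta(lambda + n1,
#' lambda + n2)` from the assigned copy counts), and the individual
#' ancestry vectors (`Dirichlet(alpha + per-population copy counts)`).
#' Frequencies are floored away from 0/1 so no full conditional ever
#' degenerates.
#'
#' @param g a [genotype_matrix].
#' @param state list with `p` (k-by-J frequencies) and `q` (I-by-k
#'   ancestry); the assignment counts are regenerated each cycle.
#' @param alpha Dirichlet concentration of the ancestry prior (> 0).
#' @param lambda Beta parameter of the frequency prior (> 0).
#' @return updated state: list with `p`, `q`, `z` (per-population lists
#'   `n1`, `n2` of assigned copy counts) and `loglik` of the new state.
#' @export
gibbs_sweep <- function(g, state, alpha = 1, lambda = 1) {
  .stop_if(alpha <= 0 || lambda <= 0, "alpha and lambda must be positive")
  p <- state$p; q <- state$q
  k <- nrow(p)
  parts <- .admix_parts(g)
  w1 <- lapply(seq_len(k), function(kk) outer(q[, kk], p[kk, ]))
  w2 <- lapply(seq_len(k), function(kk) outer(q[, kk], 1 - p[kk, ]))
  n1 <- .sample_assignment_counts(parts$G1, w1)
  n2 <- .sample_assignment_counts(parts$G2, w2)
  for (kk in seq_len(k)) {
    a <- lambda + colSums(n1[[kk]])
    b <- lambda + colSums(n2[[kk]])
    p[kk, ] <- .clamp(stats::rbeta(ncol(p), a, b))
  }
  cnt <- sapply(seq_len(k), function(kk)
    rowSums(n1[[kk]]) + rowSums(n2[[kk]]))
  cnt <- matrix(cnt, nrow = nrow(q))
  gdraw <- matrix(stats::rgamma(length(cnt), shape = alpha + cnt),
                  nrow = nrow(cnt))
  q <- gdraw / rowSums(gdraw)
  d1 <- .clamp(q %*% p, .EPS, 1)
  d2 <- .clamp(q %*% (1 - p), .EPS, 1)
  ll <- sum(parts$G1 * log(d1) + parts$G2 * log(d2))
  list(p = p, q = q, z = list(n1 = n1, n2 = n2), loglik = ll)
}

#' Fit the Bayesian admixture model by Gibbs sampling
#'
#' Runs [gibbs_sweep()] for `n_iter` cycles, discards the first `burn_in`,
#' and reports posterior means of the ancestry matrix and population
#' frequencies over the retained sweeps (no thinning by default).  The
#' reference analysis settings are 30,000 iterations with a 10,000-cycle
#' burn-in; smaller chains are adequate for the simulated-cohort scales
#' used in the package's own validation.
#'
#' @param g a [genotype_matrix] (post-QC).
#' @param k number of populations.
#' @param n_iter total Gibbs cycles.
#' @param burn_in cycles discarded (< `n_iter`).
#' @param alpha,lambda prior parameters (see [gibbs_sweep()]).
#' @param seed integer seed; chains are reproducible given the seed.
#' @param thin keep every `thin`-th retained sweep in the posterior mean.
#' @return an object of class `structure_fit`: `Q` (posterior-mean
#'   ancestry), `P` (posterior-mean frequencies), `loglik_trace` (all
#'   sweeps), `n_iter`, `burn_in`, `n_retained`.
#' @export
fit_structure <- function(g, k, n_iter = 30000L, burn_in = 10000L,
                          alpha = 1, lambda = 1, seed = 1L, thin = 1L) {
  .stop_if(k < 1, "k must be >= 1")
  .stop_if(n_iter <= burn_in, "n_iter must exceed burn_in")
  set.seed(seed)
  n <- n_samples(g); j <- n_snps(g)
  fobs <- allele_frequencies(g)
  fobs[is.na(fobs)] <- 0.5
  p <- .clamp(matrix(rep(fobs, each = k), k, j) +
              matrix(stats::runif(k * j, -0.05, 0.05), k, j))
  q <- .rdirichlet(n, rep(1, k))
  state <- list(p = p, q = q)
  q_acc <- matrix(0, n, k)
  p_acc <- matrix(0, k, j)
  trace <- numeric(n_iter)
  n_used <- 0L
  for (it in seq_len(n_iter)) {
    state <- gibbs_sweep(g, state, alpha = alpha, lambda = lambda)
    trace[it] <- state$loglik
    if (it > burn_in && (it - burn_in - 1L) %% thin == 0L) {
      q_acc <- q_acc + state$q
      p_acc <- p_acc + state$p
      n_used <- n_used + 1L
    }
  }
  Q <- q_acc / n_used
  P <- p_acc / n_used
  rownames(Q) <- g$samples$id
  colnames(Q) <- paste0("pop", seq_len(k))
  rownames(P) <- colnames(Q)
  colnames(P) <- g$map$snp_id
  structure(list(Q = Q, P = P, loglik_trace = trace, n_iter = n_iter,
                 burn_in = burn_in, n_retained = n_iter - burn_in,
                 n_used = n_used, alpha = alpha, lambda = lambda, k = k,
                 sample_ids = g$samples$id, groups = g$samples$group,
                 call = match.call()),
            class = "structure_fit")
}

#' @export
print.structure_fit <- function(x, ...) {
  cat(sprintf("Bayesian admixture fit (Gibbs sampling): k = %d\n", x$k))
  cat(sprintf("  %d samples, %d SNPs; %d iterations, %d burn-in (%d retained)\n",
              nrow(x$Q), ncol(x$P), x$n_iter, x$burn_in, x$n_retained))
  cat(sprintf("  priors: alpha = %g, lambda = %g\n", x$alpha, x$lambda))
  invisible(x)
}

#' @export
summary.structure_fit <- function(object, ...) {
  by_group <- stats::aggregate(object$Q, list(group = object$groups), mean)
  structure(list(fit = object, group_means = by_group),
            class = "summary.structure_fit")
}

#' @export
print.summary.structure_fit <- function(x, ...) {
  print(x$fit)
  cat("Posterior-mean ancestry by sample group:\n")
  gm <- x$group_means
  gm[-1] <- round(gm[-1], 3)
  print(gm, row.names = FALSE)
  invisible(x)
}

#' @export
coef.structure_fit <- function(object, ...) object$Q

#' @export
plot.structure_fit <- function(x, ...) {
  ord <- order(x$groups, -x$Q[, 1])
  graphics::barplot(t(x$Q[ord, , drop = FALSE]), col = seq_len(x$k) + 1,
                    border = NA, space = 0, names.arg = rep("", nrow(x$Q)),
                    ylab = "posterior mean ancestry",
                    main = sprintf("Ancestry (Bayesian, k = %d)", x$k), ...)
  invisible(x)
}

#' Align population labels between two ancestry matrices
#'
#' Admixture likelihoods are invariant to permuting population labels, so
#' estimates from different runs or methods must be aligned before
#' comparison.  Finds, by exhaustive search over permutations (k <= 8),
#' the column permutation of `q_b` maximizing the total agreement
#' `sum_i sum_k q_a[i,k] * q_b[i, perm[k]]`.
#'
#' @param q_a reference ancestry matrix (I-by-k).
#' @param q_b ancestry matrix to align, or a character vector of per-sample
#'   reference labels (converted to a 0/1 membership matrix whose columns
#'   follow the label order of first appearance).
#' @return integer permutation `perm` such that `q_b[, perm]` matches the
#'   columns of `q_a`; the achieved agreement score is attached as
#'   attribute `score`.
#' @export
align_labels <- function(q_a, q_b) {
  q_a <- as.matrix(q_a)
  if (is.character(q_b)) {
    labs <- unique(q_b)
    q_b <- sapply(labs, function(l) as.numeric(q_b == l))
  }
  q_b <- as.matrix(q_b)
  .stop_if(ncol(q_a) != ncol(q_b), "ancestry matrices disagree on k")
  .stop_if(nrow(q_a) != nrow(q_b), "ancestry matrices disagree on samples")
  k <- ncol(q_a)
  .stop_if(k > 8, "exhaustive alignment supported for k <= 8")
  perms <- .permutations(k)
  scores <- apply(perms, 1L, function(pp) sum(q_a * q_b[, pp, drop = FALSE]))
  best <- perms[which.max(scores), ]
  attr(best, "score") <- max(scores)
  best
}
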