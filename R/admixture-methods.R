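# S3 methods for admix_fit objects.

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("Admixture model fit (maximum likelihood, EM): k = %d\n", x$k))
  cat(sprintf("  %d samples, %d SNPs; log-likelihood %.2f\n",
              nrow(x$Q), ncol(x$F), x$loglik))
  cat(sprintf("  %s after %d iterations (best of %d start%s)\n",
              if (x$converged) "converged" else "iteration cap reached",
              x$iterations, x$n_starts, if (x$n_starts > 1) "s" else ""))
  if (!is.null(x$supervised))
    cat("  supervised references:", paste(x$supervised, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.admix_fit <- function(object, ...) {
  by_group <- stats::aggregate(object$Q, list(group = object$groups), mean)
  structure(list(fit = object, group_means = by_group),
            class = "summary.admix_fit")
}

#' @export
print.summary.admix_fit <- function(x, ...) {
  print(x$fit)
  cat("Mean ancestry by sample group:\n")
  gm <- x$group_means
  gm[-1] <- round(gm[-1], 3)
  print(gm, row.names = FALSE)
  invisible(x)
}

#' @export
coef.admix_fit <- function(object, ...) object$Q

#' @export
logLik.admix_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- object$k * (nrow(object$Q) + ncol(object$F))
  class(val) <- "logLik"
  val
}

#' @export
fitted.admix_fit <- function(object, ...) {
  2 * object$Q %*% object$F
}

#' @export
residuals.admix_fit <- function(object, genotypes = NULL, ...) {
  .stop_if(is.null(genotypes),
           "supply the genotype_matrix the model was fitted to")
  genotypes$dosage - fitted(object)
}

#' Predict ancestry for new samples under fixed population frequencies
#'
#' Projects new genotypes onto the fitted population gene pools: the
#' frequency matrix `F` is held fixed and only the new samples' ancestry
#' rows are estimated by EM.
#'
#' @param object an `admix_fit`.
#' @param newdata a [genotype_matrix] over the same SNPs.
#' @param tol,max_iter EM controls.
#' @param ... unused.
#' @return ancestry matrix for the new samples.
#' @export
predict.admix_fit <- function(object, newdata, tol = 1e-6,
                              max_iter = 1000L, ...) {
  .stop_if(!identical(object$snp_ids, newdata$map$snp_id),
           "newdata must cover the fitted SNPs in the same order")
  parts <- .admix_parts(newdata)
  f <- object$F
  q <- matrix(1 / object$k, n_samples(newdata), object$k)
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- .clamp(q %*% f, .EPS, 1)
    d2 <- .clamp(q %*% (1 - f), .EPS, 1)
    qn <- matrix(0, nrow(q), object$k)
    for (kk in seq_len(object$k)) {
      qn[, kk] <- rowSums((parts$G1 / d1) * outer(q[, kk], f[kk, ])) +
        rowSums((parts$G2 / d2) * outer(q[, kk], 1 - f[kk, ]))
    }
    q <- qn / pmax(2 * parts$Ji, 1)
    q <- q / rowSums(q)
    ll_new <- sum(parts$G1 * log(.clamp(q %*% f, .EPS, 1)) +
                  parts$G2 * log(.clamp(q %*% (1 - f), .EPS, 1)))
    if (abs(ll_new - ll) < tol) break
    ll <- ll_new
  }
  rownames(q) <- newdata$samples$id
  colnames(q) <- object$pop_names
  q
}

#' @export
plot.admix_fit <- function(x, sort_by = NULL, ...) {
  q <- x$Q
  ord <- order(x$groups, -q[, 1])
  if (!is.null(sort_by)) ord <- order(x$groups, -q[, sort_by])
  graphics::barplot(t(q[ord, , drop = FALSE]), col = seq_len(x$k) + 1,
                    border = NA, space = 0, las = 2,
                    names.arg = rep("", nrow(q)),
                    ylab = "ancestry fraction",
                    main = sprintf("Ancestry (k = %d)", x$k), ...)
  invisible(x)
}

#' Simulate genotypes from a fitted admixture model
#'
#' Draws cohorts from the fitted `(Q, F)` under the model's own generative
#' law (dosage Binomial with mixture probability), e.g. for posterior
#' predictive checks.
#'
#' @param object an `admix_fit`.
#' @param nsim number of replicate cohorts.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of dosage matrices of the fitted dimensions.
#' @export
simulate.admix_fit <- function(object, nsim = 1, seed = 1L, ...) {
  set.seed(seed)
  pi_hat <- .clamp(object$Q %*% object$F, 0, 1)
  n <- nrow(pi_hat); j <- ncol(pi_hat)
  lapply(seq_len(nsim), function(s)
    matrix(stats::rbinom(n * j, 2L, pi_hat), n, j,
           dimnames = dimnames(pi_hat)))
}
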