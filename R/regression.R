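# Single-regression breed-composition method.
#
# Each animal's transformed genotype vector y (allele-1 dosage / 2, values
# 0, 0.5, 1) is regressed on reference-breed allele-frequency vectors; the
# regression coefficients are read as the breeds' percentage contributions,
# clipped to [0, 1] and renormalized to sum to 1.

#' Estimate breed composition by regression on reference frequencies
#'
#' Two fitting modes.  `"joint"` (default): one multiple least-squares
#' regression of the animal's transformed genotypes on all breed
#' frequency columns, without intercept.  This is the consistent reading
#' of the method: under the admixture model the expected transformed
#' genotype is exactly the ancestry-weighted sum of breed frequencies, so
#' the joint coefficients estimate the ancestry fractions directly.
#' `"per-breed"`: a separate simple regression (with intercept) on each
#' breed's frequency vector, the slope taken as that breed's raw
#' coefficient; note that because breed frequencies share ancestral
#' polymorphism they are strongly correlated, and the per-breed slopes
#' absorb part of the other breeds' signal (purebreds are then attributed
#' well under 1 to their own breed) — the mode is retained for
#' comparison, not as the default.  In both modes raw coefficients are
#' then clipped (negative values to 0, values above 1 to 1) and
#' renormalized by their sum so the composition sums to 1.  Missing
#' genotypes are dropped pairwise per regression.  An animal whose
#' coefficients all clip to 0 gets an undefined (all-`NA`) composition and
#' is flagged, never silently set uniform.
#'
#' @param g a [genotype_matrix] under minor-allele coding, or a numeric
#'   samples-by-SNPs matrix of already-transformed values in
#'   `{0, 0.5, 1, NA}`.
#' @param breed_freqs breeds-by-SNPs allele-1 frequency matrix over the
#'   same SNPs (e.g. per-breed [allele_frequencies()] of reference panels,
#'   or the generator's frequency matrix).
#' @param mode `"joint"` (default) or `"per-breed"`.
#' @return an object of class `composition_fit`: list with `raw_beta`,
#'   `clipped_beta`, `composition` (all samples-by-breeds), `undefined`
#'   (logical per sample), `breeds_used`, `mode`, `n_snps_used`.
#' @examples
#' f <- simulate_breed_frequencies(500, 2, fst = 0.15, seed = 1,
#'                                 breed_names = c("NE", "CH"))
#' sim <- simulate_admixed_cohort(f, rbind(c(0.375, 0.625)), seed = 2)
#' fit <- fit_breed_composition(sim$genotypes, f)
#' coef(fit)
#' @export
fit_breed_composition <- function(g, breed_freqs,
                                  mode = c("joint", "per-breed")) {
  mode <- match.arg(mode)
  y_mat <- if (inherits(g, "genotype_matrix")) transform_genotypes(g)
           else as.matrix(g)
  x <- t(as.matrix(breed_freqs))          # J x k
  .stop_if(ncol(y_mat) != nrow(x),
           "genotypes and breed frequencies cover different SNP sets")
  n <- nrow(y_mat); k <- ncol(x)
  breeds <- colnames(x)
  if (is.null(breeds)) breeds <- paste0("breed", seq_len(k))
  raw <- matrix(NA_real_, n, k, dimnames = list(rownames(y_mat), breeds))
  n_used <- integer(n)
  xa_ok <- !apply(x, 1L, anyNA)
  if (mode == "per-breed") {
    for (b in seq_len(k)) {
      xb <- x[, b]
      for (i in seq_len(n)) {
        ok <- !is.na(y_mat[i, ]) & !is.na(xb)
        n_used[i] <- sum(ok)
        vx <- stats::var(xb[ok])
        raw[i, b] <- if (isTRUE(vx > 0))
          stats::cov(xb[ok], y_mat[i, ok]) / vx else NA_real_
      }
    }
  } else {
    for (i in seq_len(n)) {
      ok <- !is.na(y_mat[i, ]) & xa_ok
      n_used[i] <- sum(ok)
      fit <- stats::lm.fit(x[ok, , drop = FALSE], y_mat[i, ok])
      raw[i, ] <- fit$coefficients
    }
  }
  clipped <- pmin(pmax(raw, 0), 1)
  clipped[is.na(raw)] <- NA_real_
  tot <- rowSums(clipped, na.rm = TRUE)
  undefined <- tot == 0 | apply(is.na(clipped), 1L, all)
  comp <- clipped / tot
  comp[undefined, ] <- NA_real_
  structure(list(raw_beta = raw, clipped_beta = clipped,
                 composition = comp, undefined = undefined,
                 breeds_used = breeds, mode = mode, n_snps_used = n_used,
                 groups = if (inherits(g, "genotype_matrix"))
                   g$samples$group else rownames(y_mat),
                 call = match.call()),
            class = "composition_fit")
}

#' @export
print.composition_fit <- function(x, ...) {
  cat(sprintf("Breed composition by single regression (%s mode)\n", x$mode))
  cat(sprintf("  %d samples, references: %s\n", nrow(x$composition),
              paste(x$breeds_used, collapse = ", ")))
  if (any(x$undefined))
    cat(sprintf("  %d sample(s) with undefined composition (all coefficients clipped to 0)\n",
                sum(x$undefined)))
  invisible(x)
}

#' @export
summary.composition_fit <- function(object, ...) {
  gm <- stats::aggregate(object$composition,
                         list(group = object$groups), mean, na.rm = TRUE)
  structure(list(fit = object, group_means = gm),
            class = "summary.composition_fit")
}

#' @export
print.summary.composition_fit <- function(x, ...) {
  print(x$fit)
  cat("Mean composition by sample group:\n")
  gm <- x$group_means
  gm[-1] <- round(gm[-1], 3)
  print(gm, row.names = FALSE)
  invisible(x)
}

#' @export
coef.composition_fit <- function(object, ...) object$composition

#' @export
plot.composition_fit <- function(x, ...) {
  comp <- x$composition
  ok <- !x$undefined
  ord <- order(x$groups[ok], -comp[ok, 1])
  graphics::barplot(t(comp[ok, , drop = FALSE][ord, , drop = FALSE]),
                    col = seq_along(x$breeds_used) + 1, border = NA,
                    space = 0, names.arg = rep("", sum(ok)),
                    ylab = "breed fraction",
                    main = "Breed composition (regression)", ...)
  invisible(x)
}
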