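#' SNP genotype matrix
#'
#' The central genotype container: an individuals-by-SNPs table of allele-1
#' dosages (number of copies of allele 1, coded 0/1/2, `NA` for missing
#' calls), together with a SNP map (identifier, autosome, base-pair position,
#' allele pair) and a sample table (identifier, breed/group label).  By
#' convention allele 1 is the minor allele; [recode_minor()] establishes that
#' coding and is applied automatically when panels are read or merged.
#'
#' @param dosage integer matrix, samples in rows and SNPs in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param map data.frame with columns `snp_id`, `chr` (integer chromosome),
#'   `pos` (1-based base pairs), `allele1`, `allele2`; one row per column of
#'   `dosage`, sorted by position within chromosome.
#' @param samples data.frame with columns `id` and `group`; one row per row
#'   of `dosage`.
#' @return an object of class `genotype_matrix`.
#' @examples
#' g <- genotype_matrix(
#'   dosage = rbind(a1 = c(0, 1, 2), a2 = c(2, NA, 0)),
#'   map = data.frame(snp_id = c("s1", "s2", "s3"), chr = 1L,
#'                    pos = c(100L, 200L, 300L),
#'                    allele1 = "A", allele2 = "B"),
#'   samples = data.frame(id = c("a1", "a2"), group = "demo"))
#' g
#' @export
genotype_matrix <- function(dosage, map, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  .stop_if(!all(dosage %in% c(0L, 1L, 2L, NA)),
           "dosage values must be 0, 1, 2 or NA")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("snp_id", "chr", "pos", "allele1", "allele2")
  .stop_if(!all(need %in% names(map)),
           paste("map must have columns:", paste(need, collapse = ", ")))
  .stop_if(!all(c("id", "group") %in% names(samples)),
           "samples must have columns 'id' and 'group'")
  .stop_if(nrow(map) != ncol(dosage), "map rows must match dosage columns")
  .stop_if(nrow(samples) != nrow(dosage),
           "sample rows must match dosage rows")
  .stop_if(anyDuplicated(map$snp_id) > 0, "snp_id must be unique")
  .stop_if(any(map$pos < 0), "positions must be non-negative")
  rownames(dosage) <- samples$id
  colnames(dosage) <- map$snp_id
  structure(list(dosage = dosage, map = map, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  gr <- table(x$samples$group)
  cat("  groups:", paste(sprintf("%s (%d)", names(gr), gr), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  chromosomes: %s; missing calls: %.2f%%\n",
              paste(range(x$map$chr), collapse = "-"), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Number of samples / SNPs
#' @param g a [genotype_matrix]
#' @return integer count.
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname n_samples
#' @export
n_snps <- function(g) ncol(g$dosage)

# subset helper used throughout: keep given sample/SNP indices
.subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  d <- g$dosage
  map <- g$map
  sm <- g$samples
  if (!is.null(snps)) {
    d <- d[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
    rownames(map) <- NULL
  }
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    sm <- sm[samples, , drop = FALSE]
    rownames(sm) <- NULL
  }
  genotype_matrix(d, map, sm)
}

#' Establish minor-allele dosage coding
#'
#' Recodes each SNP so that allele 1 is the minor allele (allele-1 frequency
#' at most 0.5 among non-missing calls).  Where the frequency is exactly 0.5
#' the lexicographically smaller allele name is kept as allele 1, so the
#' coding is deterministic.
#'
#' @param g a [genotype_matrix]
#' @return a [genotype_matrix] with allele-1 frequency <= 0.5 at every SNP.
#' @export
recode_minor <- function(g) {
  f <- colMeans(g$dosage, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0                     # all-missing SNPs: leave coding alone
  flip <- f > 0.5 |
    (abs(f - 0.5) < 1e-12 & g$map$allele2 < g$map$allele1)
  if (any(flip)) {
    g$dosage[, flip] <- 2L - g$dosage[, flip]
    a1 <- g$map$allele1[flip]
    g$map$allele1[flip] <- g$map$allele2[flip]
    g$map$allele2[flip] <- a1
  }
  g
}

#' Per-SNP allele-1 frequencies
#'
#' Frequency of allele 1 among non-missing allele copies, overall or per
#' group.  SNPs with no non-missing call in a group get `NA` (undefined),
#' never a silent 0.
#'
#' @param g a [genotype_matrix]
#' @param by_group if `TRUE`, one frequency row per sample group.
#' @return named numeric vector (overall) or groups-by-SNPs matrix.
#' @export
allele_frequencies <- function(g, by_group = FALSE) {
  if (!by_group) {
    n <- colSums(!is.na(g$dosage))
    f <- colSums(g$dosage, na.rm = TRUE) / (2 * n)
    f[n == 0] <- NA_real_
    return(f)
  }
  groups <- unique(g$samples$group)
  out <- matrix(NA_real_, length(groups), n_snps(g),
                dimnames = list(groups, g$map$snp_id))
  for (gr in groups) {
    rows <- g$samples$group == gr
    d <- g$dosage[rows, , drop = FALSE]
    n <- colSums(!is.na(d))
    f <- colSums(d, na.rm = TRUE) / (2 * n)
    f[n == 0] <- NA_real_
    out[gr, ] <- f
  }
  out
}

#' Transform dosages to regression scale
#'
#' Divides allele-1 dosage by 2, giving per-SNP values 0, 0.5 or 1 (missing
#' stays missing).  This is the response scale of the single-regression
#' breed-composition method.
#'
#' @param g a [genotype_matrix]
#' @return numeric samples-by-SNPs matrix with values in `{0, 0.5, 1, NA}`.
#' @export
transform_genotypes <- function(g) {
  g$dosage / 2
}
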