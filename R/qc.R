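#' Genotype quality control
#'
#' Applies the standard chip-genotype quality-control sequence, in a fixed,
#' documented order: (1) keep only the requested autosomes, (2) remove
#' samples with per-sample missingness above `mind` (call rate below
#' 1 - mind), (3) remove SNPs with per-SNP missingness above `geno`, (4)
#' remove SNPs whose exact Hardy-Weinberg test p-value falls below `hwe_p`
#' (computed on the pooled data by default), and (5) optionally remove SNPs
#' with minor allele frequency below `maf`.  The defaults are the usual
#' cattle-panel thresholds (mind 0.10, geno 0.05, HWE 1e-5, autosomes 1-29);
#' the MAF filter defaults to off and is switched on (0.05) for LD analyses.
#'
#' @param g a [genotype_matrix].
#' @param mind maximum per-sample missing fraction.
#' @param geno maximum per-SNP missing fraction.
#' @param hwe_p Hardy-Weinberg exact-test p-value threshold (`NULL` skips).
#' @param maf minor-allele-frequency threshold (`NULL` skips).
#' @param chromosomes chromosomes to retain.
#' @param hwe_by_group if `TRUE`, the HWE test is run within each sample
#'   group and a SNP is removed when any group falls below `hwe_p`; default
#'   is the pooled test.
#' @return list with `genotypes` (the filtered [genotype_matrix]) and
#'   `report` (a `qc_report`: per-sample and per-SNP removals with reasons,
#'   plus the thresholds used).
#' @export
qc_filter <- function(g, mind = 0.10, geno = 0.05, hwe_p = 1e-5,
                      maf = NULL, chromosomes = 1:29,
                      hwe_by_group = FALSE) {
  for (th in c(mind, geno, hwe_p, maf))
    .stop_if(!is.null(th) && (th < 0 || th > 1), "thresholds must be in [0,1]")
  snps_removed <- data.frame(snp_id = character(0), reason = character(0),
                             value = numeric(0), stringsAsFactors = FALSE)
  samples_removed <- data.frame(id = character(0), reason = character(0),
                                call_rate = numeric(0),
                                stringsAsFactors = FALSE)
  note_snps <- function(ids, reason, value) {
    if (length(ids))
      snps_removed <<- rbind(snps_removed,
                             data.frame(snp_id = ids, reason = reason,
                                        value = value,
                                        stringsAsFactors = FALSE))
  }

  # 1. chromosome filter
  drop <- !(g$map$chr %in% chromosomes)
  note_snps(g$map$snp_id[drop], "chromosome", g$map$chr[drop])
  g <- .subset_genotypes(g, snps = which(!drop))

  # 2. per-sample call rate
  if (n_snps(g) > 0) {
    miss_i <- rowMeans(is.na(g$dosage))
    bad <- miss_i > mind
    if (any(bad))
      samples_removed <- data.frame(id = g$samples$id[bad],
                                    reason = "sample call rate",
                                    call_rate = 1 - miss_i[bad],
                                    stringsAsFactors = FALSE)
    g <- .subset_genotypes(g, samples = which(!bad))
  }

  # 3. per-SNP call rate
  miss_j <- colMeans(is.na(g$dosage))
  bad <- miss_j > geno
  note_snps(g$map$snp_id[bad], "snp call rate", miss_j[bad])
  g <- .subset_genotypes(g, snps = which(!bad))

  # 4. Hardy-Weinberg exact test
  if (!is.null(hwe_p) && n_snps(g) > 0) {
    if (hwe_by_group) {
      groups <- unique(g$samples$group)
      pmat <- sapply(groups, function(gr)
        .hwe_pvalues(g$dosage[g$samples$group == gr, , drop = FALSE]))
      pv <- apply(as.matrix(pmat), 1L, min, na.rm = TRUE)
    } else {
      pv <- .hwe_pvalues(g$dosage)
    }
    bad <- !is.na(pv) & pv < hwe_p
    note_snps(g$map$snp_id[bad], "hwe", pv[bad])
    g <- .subset_genotypes(g, snps = which(!bad))
  }

  # 5. minor allele frequency
  if (!is.null(maf) && n_snps(g) > 0) {
    f <- allele_frequencies(g)
    fm <- pmin(f, 1 - f)
    bad <- !is.na(fm) & fm < maf
    note_snps(g$map$snp_id[bad], "maf", fm[bad])
    g <- .subset_genotypes(g, snps = which(!bad))
  }

  report <- structure(list(samples_removed = samples_removed,
                           snps_removed = snps_removed,
                           thresholds = list(mind = mind, geno = geno,
                                             hwe_p = hwe_p, maf = maf,
                                             chromosomes = chromosomes)),
                      class = "qc_report")
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  th <- x$thresholds
  cat(sprintf("  thresholds: mind %s, geno %s, hwe %s, maf %s, chr %s\n",
              th$mind, th$geno,
              ifelse(is.null(th$hwe_p), "-", th$hwe_p),
              ifelse(is.null(th$maf), "-", th$maf),
              paste(range(th$chromosomes), collapse = "-")))
  cat(sprintf("  samples removed: %d\n", nrow(x$samples_removed)))
  if (nrow(x$snps_removed)) {
    tab <- table(x$snps_removed$reason)
    cat("  SNPs removed:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  } else cat("  SNPs removed: 0\n")
  invisible(x)
}
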