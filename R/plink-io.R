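# PLINK text (PED/MAP) and binary (BED/BIM/FAM) input/output.
#
# Binary layout: 3 magic bytes 0x6c 0x1b 0x01, then SNP-major blocks of
# ceiling(N/4) bytes per SNP; each sample occupies 2 bits, least significant
# pair first, with 00 = homozygous A1 (dosage 2), 01 = missing, 10 =
# heterozygous, 11 = homozygous A2 (dosage 0).

.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

# dosage (copies of A1) -> 2-bit code and back
.DOSAGE_TO_CODE <- c(`0` = 3L, `1` = 2L, `2` = 0L)   # NA -> 1L
.CODE_TO_DOSAGE <- c(2L, NA_integer_, 1L, 0L)        # index = code + 1

#' Read genotypes from PLINK files
#'
#' Reads a text (`.ped`/`.map`) or binary (`.bed`/`.bim`/`.fam`) file set.
#' For binary input the BIM file's A1 column defines allele 1 and dosages
#' round-trip exactly.  Text PED files carry no allele-order information, so
#' allele 1 is assigned by the minor-allele rule (frequency <= 0.5; ties and
#' monomorphic SNPs keep the lexicographically smaller observed allele),
#' which reproduces the input exactly whenever it was written under
#' minor-allele coding.
#'
#' @param prefix file path without extension.
#' @param dialect `"binary"` or `"text"`.
#' @return a [genotype_matrix]; sample and SNP order follow the source files.
#' @export
read_plink <- function(prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  if (dialect == "binary") .read_bed(prefix) else .read_ped(prefix)
}

#' Write genotypes to PLINK files
#'
#' Writes `g` as `.ped` + `.map` (text) or `.bed` + `.bim` + `.fam`
#' (binary).  Output is byte-stable for fixed input.
#'
#' @param g a [genotype_matrix].
#' @param prefix output path without extension.
#' @param dialect `"binary"` or `"text"`.
#' @return character vector of files written, invisibly.
#' @export
write_plink <- function(g, prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  dir <- dirname(prefix)
  .stop_if(!dir.exists(dir), sprintf("directory '%s' does not exist", dir))
  if (dialect == "binary") .write_bed(g, prefix) else .write_ped(g, prefix)
}

.fam_table <- function(g) {
  data.frame(fid = g$samples$group, iid = g$samples$id,
             pat = "0", mat = "0", sex = "0", pheno = "-9",
             stringsAsFactors = FALSE)
}

.map_table <- function(g) {
  data.frame(chr = g$map$chr, snp_id = g$map$snp_id,
             cm = rep(0, nrow(g$map)),
             pos = g$map$pos, stringsAsFactors = FALSE)
}

.write_tsv_nohdr <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

.write_ped <- function(g, prefix) {
  n <- n_samples(g); j <- n_snps(g)
  a1 <- g$map$allele1; a2 <- g$map$allele2
  # allele characters per (sample, snp): two columns per SNP
  ped_geno <- matrix("0", n, 2L * j)
  if (j > 0) {
    d <- g$dosage
    for (col in seq_len(j)) {
      dc <- d[, col]
      first <- ifelse(is.na(dc), "0", ifelse(dc >= 1L, a1[col], a2[col]))
      second <- ifelse(is.na(dc), "0", ifelse(dc == 2L, a1[col], a2[col]))
      ped_geno[, 2L * col - 1L] <- first
      ped_geno[, 2L * col] <- second
    }
  }
  fam <- .fam_table(g)
  lines <- do.call(paste, c(as.list(fam), lapply(seq_len(ncol(ped_geno)),
                                                 function(cc) ped_geno[, cc])))
  writeLines(lines, paste0(prefix, ".ped"))
  .write_tsv_nohdr(.map_table(g), paste0(prefix, ".map"))
  invisible(paste0(prefix, c(".ped", ".map")))
}

.read_ped <- function(prefix) {
  ped_file <- paste0(prefix, ".ped"); map_file <- paste0(prefix, ".map")
  .stop_if(!file.exists(ped_file), sprintf("missing file '%s'", ped_file))
  .stop_if(!file.exists(map_file), sprintf("missing file '%s'", map_file))
  map <- utils::read.table(map_file, header = FALSE,
                           col.names = c("chr", "snp_id", "cm", "pos"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer"))
  j <- nrow(map)
  lines <- readLines(ped_file)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n_tok <- lengths(toks)
  bad <- which(n_tok != 6L + 2L * j)
  .stop_if(length(bad) > 0,
           sprintf("PED/MAP length mismatch in '%s': record %d has %d fields, expected %d",
                   ped_file, bad[1], n_tok[bad[1]], 6L + 2L * j))
  tok <- do.call(rbind, toks)
  samples <- data.frame(id = tok[, 2L], group = tok[, 1L],
                        stringsAsFactors = FALSE)
  n <- nrow(tok)
  dosage <- matrix(NA_integer_, n, j)
  allele1 <- character(j); allele2 <- character(j)
  for (col in seq_len(j)) {
    x1 <- tok[, 6L + 2L * col - 1L]; x2 <- tok[, 6L + 2L * col]
    obs <- c(x1, x2)
    miss <- x1 == "0" | x2 == "0"
    alleles <- sort(unique(obs[obs != "0"]))
    .stop_if(length(alleles) > 2L,
             sprintf("SNP %s has more than two alleles in '%s'",
                     map$snp_id[col], ped_file))
    if (length(alleles) == 0L) { allele1[col] <- "0"; allele2[col] <- "0"; next }
    if (length(alleles) == 1L) alleles <- c("0", alleles)
    # provisional coding on the first allele; minor-allele rule applied below
    d <- (x1 == alleles[2L]) + (x2 == alleles[2L])
    d[miss] <- NA_integer_
    # count copies of alleles[1] (could be "0" placeholder for monomorphic)
    cnt1 <- 2L - d
    f1 <- mean(cnt1, na.rm = TRUE) / 2
    if (alleles[1L] == "0") {              # monomorphic: observed allele major
      allele1[col] <- "0"; allele2[col] <- alleles[2L]
      dosage[, col] <- 0L
      dosage[miss, col] <- NA_integer_
    } else if (f1 > 0.5 || (abs(f1 - 0.5) < 1e-12 &&
                            alleles[1L] > alleles[2L])) {
      allele1[col] <- alleles[2L]; allele2[col] <- alleles[1L]
      dosage[, col] <- as.integer(d)
    } else {
      allele1[col] <- alleles[1L]; allele2[col] <- alleles[2L]
      dosage[, col] <- as.integer(2L - d)
      dosage[miss, col] <- NA_integer_
    }
  }
  genotype_matrix(dosage,
                  data.frame(snp_id = map$snp_id, chr = map$chr,
                             pos = map$pos, allele1 = allele1,
                             allele2 = allele2, stringsAsFactors = FALSE),
                  samples)
}

.write_bed <- function(g, prefix) {
  n <- n_samples(g); j <- n_snps(g)
  codes <- matrix(1L, ifelse(n %% 4L == 0L, n, n + 4L - n %% 4L), j)
  if (n > 0 && j > 0) {
    d <- g$dosage
    cd <- matrix(1L, n, j)                      # default missing
    cd[!is.na(d) & d == 0L] <- 3L
    cd[!is.na(d) & d == 1L] <- 2L
    cd[!is.na(d) & d == 2L] <- 0L
    codes[seq_len(n), ] <- cd
  }
  codes[-seq_len(n), ] <- 0L                    # padding bits are zero
  np4 <- nrow(codes) / 4L
  arr <- array(codes, dim = c(4L, np4, j))
  bytes <- arr[1L, , , drop = FALSE] + 4L * arr[2L, , , drop = FALSE] +
    16L * arr[3L, , , drop = FALSE] + 64L * arr[4L, , , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.BED_MAGIC, con)
  writeBin(as.raw(bytes), con)
  bim <- data.frame(chr = g$map$chr, snp_id = g$map$snp_id,
                    cm = rep(0, nrow(g$map)),
                    pos = g$map$pos, a1 = g$map$allele1, a2 = g$map$allele2,
                    stringsAsFactors = FALSE)
  .write_tsv_nohdr(bim, paste0(prefix, ".bim"))
  .write_tsv_nohdr(.fam_table(g), paste0(prefix, ".fam"))
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

.read_bed <- function(prefix) {
  bed_file <- paste0(prefix, ".bed")
  bim_file <- paste0(prefix, ".bim")
  fam_file <- paste0(prefix, ".fam")
  for (fl in c(bed_file, bim_file, fam_file))
    .stop_if(!file.exists(fl), sprintf("missing file '%s'", fl))
  bim <- utils::read.table(bim_file, header = FALSE,
                           col.names = c("chr", "snp_id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character",
                                          "character"))
  fam <- utils::read.table(fam_file, header = FALSE,
                           colClasses = "character")
  n <- nrow(fam); j <- nrow(bim)
  raw <- readBin(bed_file, "raw", n = file.size(bed_file))
  .stop_if(length(raw) < 3L || !identical(raw[1:3], .BED_MAGIC),
           sprintf("'%s' is not a SNP-major PLINK BED file (magic-byte mismatch)",
                   bed_file))
  bpj <- ceiling(n / 4L)
  .stop_if(length(raw) - 3L != bpj * j,
           sprintf("'%s' is truncated: %d data bytes, expected %d",
                   bed_file, length(raw) - 3L, bpj * j))
  bytes <- as.integer(raw[-(1:3)])
  dim(bytes) <- c(bpj, j)
  codes <- matrix(0L, 4L * bpj, j)
  codes[seq(1L, 4L * bpj, by = 4L), ] <- bytes %% 4L
  codes[seq(2L, 4L * bpj, by = 4L), ] <- (bytes %/% 4L) %% 4L
  codes[seq(3L, 4L * bpj, by = 4L), ] <- (bytes %/% 16L) %% 4L
  codes[seq(4L, 4L * bpj, by = 4L), ] <- (bytes %/% 64L) %% 4L
  dosage <- matrix(.CODE_TO_DOSAGE[codes[seq_len(n), , drop = FALSE] + 1L],
                   n, j)
  genotype_matrix(dosage,
                  data.frame(snp_id = bim$snp_id, chr = bim$chr,
                             pos = bim$pos, allele1 = bim$a1,
                             allele2 = bim$a2, stringsAsFactors = FALSE),
                  data.frame(id = fam[[2]], group = fam[[1]],
                             stringsAsFactors = FALSE))
}

#' Merge genotype panels
#'
#' Takes the intersection of SNP sets and the union of samples across
#' panels.  Allele codings are reconciled by allele-pair matching: a panel
#' whose allele pair at a SNP is swapped relative to the first panel has its
#' dosages flipped to the common coding; any other allele pair raises a
#' merge conflict naming the SNP.  Minor-allele coding is recomputed on the
#' merged data, so the result is invariant (up to sample order) to the
#' order of the input panels.
#'
#' @param panels list of [genotype_matrix] objects.
#' @return merged [genotype_matrix].
#' @export
merge_panels <- function(panels) {
  .stop_if(length(panels) < 1L, "no panels to merge")
  if (length(panels) == 1L) return(recode_minor(panels[[1L]]))
  common <- Reduce(intersect, lapply(panels, function(p) p$map$snp_id))
  ref <- panels[[1L]]
  ref_idx <- match(common, ref$map$snp_id)
  ref_map <- ref$map[ref_idx, , drop = FALSE]
  pieces <- vector("list", length(panels))
  sample_tabs <- vector("list", length(panels))
  for (i in seq_along(panels)) {
    p <- panels[[i]]
    idx <- match(common, p$map$snp_id)
    d <- p$dosage[, idx, drop = FALSE]
    a1 <- p$map$allele1[idx]; a2 <- p$map$allele2[idx]
    same <- a1 == ref_map$allele1 & a2 == ref_map$allele2
    swapped <- a1 == ref_map$allele2 & a2 == ref_map$allele1
    # "0" placeholder alleles (monomorphic source SNP) match anything
    wild <- a1 == "0" | ref_map$allele1 == "0"
    bad <- !(same | swapped | wild)
    .stop_if(any(bad),
             sprintf("irreconcilable allele pairs at SNP(s): %s",
                     paste(utils::head(common[bad], 5L), collapse = ", ")))
    flip <- swapped & !wild
    d[, flip] <- 2L - d[, flip]
    pieces[[i]] <- d
    sample_tabs[[i]] <- p$samples
  }
  merged <- genotype_matrix(do.call(rbind, pieces), ref_map,
                            do.call(rbind, sample_tabs))
  recode_minor(merged)
}

#' Extract a subset of SNPs by identifier
#'
#' Retains only SNPs named in `keep_ids`, in map order — the generic
#' equivalent of extracting a high-density panel down to a lower-density
#' chip list.  Identifiers absent from the map are silently dropped and
#' counted in the `n_requested_missing` attribute.
#'
#' @param g a [genotype_matrix].
#' @param keep_ids character vector of SNP identifiers to keep.
#' @return a [genotype_matrix] restricted to the requested SNPs.
#' @export
extract_snp_subset <- function(g, keep_ids) {
  keep <- which(g$map$snp_id %in% keep_ids)
  out <- .subset_genotypes(g, snps = keep)
  attr(out, "n_requested_missing") <-
    sum(!(keep_ids %in% g$map$snp_id))
  out
}
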