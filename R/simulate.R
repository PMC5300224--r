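#' Simulate breed-differentiated allele frequencies
#'
#' Draws per-breed allele frequencies under the Balding-Nichols model:
#' ancestral frequencies p_j are drawn uniform on `p_range`, and each breed's
#' frequency at SNP j is Beta-distributed with mean p_j and variance
#' p_j(1-p_j)*F, where F is that breed's divergence (drift) parameter.  This
#' is the standard Fst-indexed divergence model and makes the admixture
#' likelihood correctly specified on cohorts simulated from the result.
#'
#' @param n_snps number of SNPs (>= 1).
#' @param n_breeds number of breeds (>= 1).
#' @param fst per-breed divergence in (0,1); recycled to `n_breeds`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param p_range range of the uniform ancestral-frequency draw.
#' @param breed_names optional breed labels (default B1, B2, ...).
#' @param snps_per_chr SNPs are laid out on autosomes 1..29 in blocks of this
#'   size, spaced `spacing_bp` apart, to give the map realistic structure.
#' @param spacing_bp base-pair spacing of consecutive SNPs on a chromosome.
#' @return a breeds-by-SNPs frequency matrix with attributes `ancestral`
#'   (the p_j vector), `fst`, and `map` (a SNP map data.frame).
#' @examples
#' f <- simulate_breed_frequencies(100, 2, fst = 0.1, seed = 1)
#' dim(f)
#' @export
simulate_breed_frequencies <- function(n_snps, n_breeds, fst, seed,
                                       p_range = c(0.05, 0.95),
                                       breed_names = NULL,
                                       snps_per_chr = 2000L,
                                       spacing_bp = 50000L) {
  .stop_if(n_snps < 1, "n_snps must be >= 1")
  .stop_if(n_breeds < 1, "n_breeds must be >= 1")
  fst <- rep_len(fst, n_breeds)
  .stop_if(any(fst <= 0 | fst >= 1), "fst must be strictly inside (0,1)")
  if (is.null(breed_names)) breed_names <- paste0("B", seq_len(n_breeds))
  set.seed(seed)
  p <- stats::runif(n_snps, p_range[1], p_range[2])
  f <- matrix(NA_real_, n_breeds, n_snps,
              dimnames = list(breed_names, paste0("snp", seq_len(n_snps))))
  for (b in seq_len(n_breeds)) {
    # Beta(a, b) with mean p and variance p(1-p)F: a = p(1-F)/F, b = (1-p)(1-F)/F
    scale <- (1 - fst[b]) / fst[b]
    f[b, ] <- stats::rbeta(n_snps, p * scale, (1 - p) * scale)
  }
  # keep frequencies strictly polymorphic so downstream likelihoods are finite
  f <- .clamp(f)
  chr <- 1L + (seq_len(n_snps) - 1L) %/% snps_per_chr
  chr <- ((chr - 1L) %% 29L) + 1L
  within <- stats::ave(seq_len(n_snps), chr, FUN = seq_along)
  map <- data.frame(snp_id = colnames(f), chr = chr,
                    pos = as.integer(within) * spacing_bp,
                    allele1 = "A", allele2 = "B",
                    stringsAsFactors = FALSE)
  attr(f, "ancestral") <- p
  attr(f, "fst") <- fst
  attr(f, "map") <- map
  f
}

#' Simulate an admixed cohort with known ancestry
#'
#' Genotypes are drawn from the admixture model's own generative law: for
#' individual i with ancestry vector q_i and breed frequencies f_kj, the
#' allele-1 dosage at SNP j is Binomial(2, sum_k q_ik f_kj) — the random
#' union of gametes with loci in linkage equilibrium.  Entries are then
#' masked missing independently at `missing_rate`.
#'
#' @param freqs breeds-by-SNPs frequency matrix
#'   (from [simulate_breed_frequencies()]).
#' @param q_matrix individuals-by-breeds ancestry matrix; rows must sum to 1.
#' @param missing_rate per-entry missingness probability.
#' @param seed integer seed.
#' @param group_labels optional per-individual group labels (default: the
#'   breed of maximum ancestry, or "admixed" if no entry exceeds 0.95).
#' @param id_prefix sample-identifier prefix.
#' @return list with `genotypes` (a [genotype_matrix]) and `truth`
#'   (data.frame: sample_id, group, one `q_<breed>` column per breed).
#' @examples
#' f <- simulate_breed_frequencies(200, 2, fst = 0.1, seed = 1)
#' q <- rbind(c(1, 0), c(0.5, 0.5))
#' sim <- simulate_admixed_cohort(f, q, seed = 2)
#' sim$genotypes
#' @export
simulate_admixed_cohort <- function(freqs, q_matrix, missing_rate = 0,
                                    seed = 1, group_labels = NULL,
                                    id_prefix = "ind") {
  q_matrix <- as.matrix(q_matrix)
  .stop_if(ncol(q_matrix) != nrow(freqs),
           "q_matrix columns must match the number of breeds in freqs")
  .stop_if(any(abs(rowSums(q_matrix) - 1) > 1e-8),
           "q_matrix rows must sum to 1")
  .stop_if(missing_rate < 0 || missing_rate >= 1,
           "missing_rate must be in [0,1)")
  n <- nrow(q_matrix)
  j <- ncol(freqs)
  set.seed(seed)
  pi_mat <- q_matrix %*% freqs              # I x J mixture dosage probability
  d <- matrix(stats::rbinom(n * j, 2L, pi_mat), n, j)
  if (missing_rate > 0) {
    d[stats::runif(n * j) < missing_rate] <- NA_integer_
  }
  breeds <- rownames(freqs)
  if (is.null(group_labels)) {
    top <- max.col(q_matrix)
    group_labels <- ifelse(q_matrix[cbind(seq_len(n), top)] > 0.95,
                           breeds[top], "admixed")
  }
  ids <- sprintf("%s%03d", id_prefix, seq_len(n))
  map <- attr(freqs, "map")
  if (is.null(map)) {
    map <- data.frame(snp_id = colnames(freqs), chr = 1L,
                      pos = seq_len(j) * 50000L,
                      allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  }
  g <- genotype_matrix(d, map, data.frame(id = ids, group = group_labels,
                                          stringsAsFactors = FALSE))
  truth <- data.frame(sample_id = ids, group = group_labels,
                      stringsAsFactors = FALSE)
  qt <- as.data.frame(q_matrix)
  names(qt) <- paste0("q_", breeds)
  list(genotypes = g, truth = cbind(truth, qt))
}

#' Simulate a crossing scheme with per-locus breed-of-origin tracking
#'
#' Founder animals are purebreds drawn from their breed's allele
#' frequencies; each cross transmits, independently at every locus, one of
#' the parent's two allele copies together with its breed-of-origin tag.
#' The realized ancestry of an animal is the fraction of its 2 * n_loci
#' allele copies originating from each breed; its expectation is the exact
#' parental mean, so realized fractions converge to the pedigree expectation
#' as n_loci grows (variance proportional to 1/n_loci).
#'
#' @param scheme data.frame with columns `node`, `sire`, `dam`: founders name
#'   a breed of `freqs` in `sire`/`dam` set to `NA` and carry the breed name
#'   in `node` (or see [canchim_scheme()] for the built-in Canchim design).
#'   `sire`/`dam` entries must reference earlier-declared nodes or breed
#'   names; the mating graph must be acyclic.
#' @param freqs breeds-by-SNPs frequency matrix; founder breeds must appear
#'   in its rownames.
#' @param n_loci number of loci simulated (uses the first `n_loci` SNPs).
#' @param n_per_node animals simulated per node.
#' @param seed integer seed.
#' @return list with `genotypes` (a [genotype_matrix], group = node name)
#'   and `truth` (sample_id, group, realized `q_<breed>` columns, expected
#'   `eq_<breed>` columns).
#' @export
simulate_crossing_scheme <- function(scheme, freqs, n_loci,
                                     n_per_node = 25L, seed = 1) {
  scheme <- as.data.frame(scheme, stringsAsFactors = FALSE)
  .stop_if(!all(c("node", "sire", "dam") %in% names(scheme)),
           "scheme needs columns node, sire, dam")
  breeds <- rownames(freqs)
  k <- length(breeds)
  .stop_if(n_loci > ncol(freqs), "n_loci exceeds SNPs available in freqs")
  f <- freqs[, seq_len(n_loci), drop = FALSE]

  # topological order; a parent reference must resolve to an earlier node or
  # to a founder breed name, otherwise the graph is cyclic/ill-formed
  seen <- character(0)
  for (r in seq_len(nrow(scheme))) {
    nd <- scheme$node[r]
    .stop_if(nd %in% seen, sprintf("node '%s' declared twice", nd))
    for (p in c(scheme$sire[r], scheme$dam[r])) {
      if (!is.na(p) && !(p %in% seen) && !(p %in% breeds))
        stop(sprintf(
          "parent '%s' of node '%s' is neither an earlier node nor a breed (cyclic or ill-formed scheme)",
          p, nd), call. = FALSE)
    }
    seen <- c(seen, nd)
  }

  set.seed(seed)
  # pools[[node]]: list of animals; each animal: list(al = 2 x J 0/1 alleles,
  # or = 2 x J breed index)
  pools <- list()
  make_founder <- function(breed) {
    bi <- match(breed, breeds)
    al <- matrix(stats::rbinom(2L * n_loci, 1L, rep(f[bi, ], each = 2L)),
                 2L, n_loci)
    list(al = al, or = matrix(bi, 2L, n_loci))
  }
  founder_pool <- function(name) {
    replicate(n_per_node, make_founder(name), simplify = FALSE)
  }
  get_pool <- function(name) {
    if (!is.null(pools[[name]])) return(pools[[name]])
    .stop_if(!(name %in% breeds),
             sprintf("unknown parent reference '%s'", name))
    founder_pool(name)
  }
  gamete <- function(animal) {
    pick <- stats::rbinom(n_loci, 1L, 0.5) + 1L
    idx <- cbind(pick, seq_len(n_loci))
    list(al = animal$al[idx], or = animal$or[idx])
  }
  for (r in seq_len(nrow(scheme))) {
    nd <- scheme$node[r]
    if (is.na(scheme$sire[r]) && is.na(scheme$dam[r])) {
      .stop_if(!(nd %in% breeds),
               sprintf("founder node '%s' must name a breed", nd))
      pools[[nd]] <- founder_pool(nd)
    } else {
      sp <- get_pool(scheme$sire[r])
      dp <- get_pool(scheme$dam[r])
      pools[[nd]] <- replicate(n_per_node, {
        s <- sp[[sample.int(length(sp), 1L)]]
        d <- dp[[sample.int(length(dp), 1L)]]
        gs <- gamete(s); gd <- gamete(d)
        list(al = rbind(gs$al, gd$al), or = rbind(gs$or, gd$or))
      }, simplify = FALSE)
    }
  }

  expected <- pedigree_expected_fraction(scheme, breeds = breeds)$fractions
  nodes <- scheme$node
  rows <- list(); ids <- character(0); grp <- character(0)
  qre <- list(); qex <- list()
  for (nd in nodes) {
    for (a in seq_along(pools[[nd]])) {
      an <- pools[[nd]][[a]]
      ids <- c(ids, sprintf("%s_%03d", nd, a))
      grp <- c(grp, nd)
      rows[[length(rows) + 1L]] <- colSums(an$al)
      qre[[length(qre) + 1L]] <-
        tabulate(an$or, nbins = k) / (2 * n_loci)
      qex[[length(qex) + 1L]] <- expected[nd, ]
    }
  }
  d <- do.call(rbind, rows)
  storage.mode(d) <- "integer"
  map <- attr(freqs, "map")
  map <- if (is.null(map)) {
    data.frame(snp_id = colnames(f), chr = 1L, pos = seq_len(n_loci) * 50000L,
               allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  } else map[seq_len(n_loci), ]
  g <- genotype_matrix(d, map,
                       data.frame(id = ids, group = grp,
                                  stringsAsFactors = FALSE))
  qre <- do.call(rbind, qre); colnames(qre) <- paste0("q_", breeds)
  qex <- do.call(rbind, qex); colnames(qex) <- paste0("eq_", breeds)
  truth <- cbind(data.frame(sample_id = ids, group = grp,
                            stringsAsFactors = FALSE),
                 as.data.frame(qre), as.data.frame(qex))
  rownames(truth) <- NULL
  list(genotypes = g, truth = truth)
}

#' Simulate phased haplotypes with decaying linkage disequilibrium
#'
#' A copy-with-probability-c first-order Markov chain over loci: the allele
#' at locus j+1 copies the allele at locus j with probability `copy_prob`,
#' otherwise it is a fresh Bernoulli(p) draw.  Adjacent-locus correlation is
#' `copy_prob` when allele frequencies are equal, and correlation decays
#' geometrically with lag, giving a monotone LD-decay profile.  Used to
#' exercise the LD module; the admixture estimators assume (and the other
#' generators produce) linkage equilibrium.
#'
#' @param n_haplotypes number of phased haplotypes.
#' @param p per-locus allele-1 frequency (scalar or vector of length
#'   `n_loci`).
#' @param n_loci number of loci.
#' @param copy_prob adjacent-locus copy probability in `[0,1)`.
#' @param seed integer seed.
#' @param spacing_bp base-pair spacing of consecutive loci.
#' @return list with `haplotypes` (haplotypes-by-loci 0/1 matrix), `map`
#'   (SNP map, all on chromosome 1), and `genotypes` (a [genotype_matrix]
#'   formed by pairing consecutive haplotypes).
#' @export
simulate_ld_haplotypes <- function(n_haplotypes, p = 0.5, n_loci = 200L,
                                   copy_prob = 0.8, seed = 1,
                                   spacing_bp = 10000L) {
  .stop_if(n_haplotypes %% 2L != 0L, "n_haplotypes must be even")
  .stop_if(copy_prob < 0 || copy_prob >= 1, "copy_prob must be in [0,1)")
  p <- rep_len(p, n_loci)
  set.seed(seed)
  h <- matrix(0L, n_haplotypes, n_loci)
  h[, 1L] <- stats::rbinom(n_haplotypes, 1L, p[1L])
  for (jl in 2L:n_loci) {
    copy <- stats::runif(n_haplotypes) < copy_prob
    fresh <- stats::rbinom(n_haplotypes, 1L, p[jl])
    h[, jl] <- ifelse(copy, h[, jl - 1L], fresh)
  }
  map <- data.frame(snp_id = paste0("L", seq_len(n_loci)), chr = 1L,
                    pos = seq_len(n_loci) * spacing_bp,
                    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  odd <- seq(1L, n_haplotypes, by = 2L)
  d <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  ids <- sprintf("hind%03d", seq_along(odd))
  g <- genotype_matrix(d, map, data.frame(id = ids, group = "ldpop",
                                          stringsAsFactors = FALSE))
  list(haplotypes = h, map = map, genotypes = g)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Generates purebred reference panels plus an admixed cohort and writes
#' PLINK text (PED/MAP) and binary (BED/BIM/FAM) files, the ground-truth
#' ancestry table (TSV) and the generator configuration (key=value text).
#' Two runs with the same configuration produce byte-identical files.
#'
#' @param config list of generator settings; recognised entries (defaults in
#'   parentheses): `n_snps` (1000), `breed_names` (c("B1","B2")), `fst`
#'   (0.1), `n_per_breed` (25), `n_admixed` (25), `admix_alpha` Dirichlet
#'   concentration for admixed ancestry draws (1), `missing_rate` (0),
#'   `seed` (1).
#' @param out_dir output directory (created if absent).
#' @return manifest data.frame (`file`, `md5`), invisibly also written as
#'   `manifest.tsv`.
#' @export
generate_fixture_bundle <- function(config = list(), out_dir) {
  cfg <- utils::modifyList(list(
    n_snps = 1000L, breed_names = c("B1", "B2"), fst = 0.1,
    n_per_breed = 25L, n_admixed = 25L, admix_alpha = 1,
    missing_rate = 0, seed = 1L), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .stop_if(!dir.exists(out_dir), sprintf("cannot create '%s'", out_dir))
  k <- length(cfg$breed_names)
  seeds <- .child_seeds(cfg$seed, 3L)
  f <- simulate_breed_frequencies(cfg$n_snps, k, cfg$fst, seed = seeds[1],
                                  breed_names = cfg$breed_names)
  q_pure <- diag(k)[rep(seq_len(k), each = cfg$n_per_breed), , drop = FALSE]
  set.seed(seeds[2])
  q_adm <- .rdirichlet(cfg$n_admixed, rep(cfg$admix_alpha, k))
  q <- rbind(q_pure, q_adm)
  labels <- c(rep(cfg$breed_names, each = cfg$n_per_breed),
              rep("admixed", cfg$n_admixed))
  sim <- simulate_admixed_cohort(f, q, missing_rate = cfg$missing_rate,
                                 seed = seeds[3], group_labels = labels)
  prefix <- file.path(out_dir, "fixture")
  write_plink(sim$genotypes, prefix, dialect = "text")
  write_plink(sim$genotypes, prefix, dialect = "binary")
  truth_file <- file.path(out_dir, "truth.tsv")
  utils::write.table(sim$truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg_file <- file.path(out_dir, "generator-config.txt")
  writeLines(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(v) paste(v, collapse = ","), "")),
             cfg_file)
  files <- c(paste0(prefix, c(".ped", ".map", ".bed", ".bim", ".fam")),
             truth_file, cfg_file)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
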