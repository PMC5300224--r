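# Internal helpers shared across the package.

# numerical floor used to keep likelihoods finite at the boundary
.EPS <- 1e-6

.clamp <- function(x, lo = .EPS, hi = 1 - .EPS) {
  pmin(pmax(x, lo), hi)
}

# One Dirichlet draw per row; alpha recycled across rows if a vector.
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# All permutations of 1..n (n small; used for label alignment, n <= 5).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out[[i]] <- block
  }
  do.call(rbind, out)
}

# Exact rational arithmetic on small fractions (pedigree propagation).
.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

.rat <- function(num, den = 1L) {
  stopifnot(den != 0)
  if (num == 0) return(c(num = 0L, den = 1L))
  g <- .gcd(abs(num), abs(den))
  c(num = as.integer(num / g), den = as.integer(den / g))
}

.rat_add <- function(a, b) .rat(a["num"] * b["den"] + b["num"] * a["den"],
                                a["den"] * b["den"])

.rat_halve <- function(a) .rat(a["num"], a["den"] * 2L)

.rat_format <- function(a) {
  if (a["den"] == 1L) as.character(a["num"]) else
    paste0(a["num"], "/", a["den"])
}

# Derive a stream of child seeds from one user seed (kept below 2^31).
.child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
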