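# Shared fixtures (memoised so expensive simulations run once per session)
# and independent oracles used across test files.

.fixtures <- new.env(parent = emptyenv())

# A small F2 population shared by several test files.
small_pop <- function() {
  if (is.null(.fixtures$small_pop)) {
    .fixtures$small_pop <- simulate_population(
      n_snps = 600, n_chromosomes = 6, n_f2 = 240,
      traits = chicken_traits(n_qtl = 60)["BW6"], seed = 4242)
  }
  .fixtures$small_pop
}

# Closed-form BLUP oracle: b = GLS estimate, u = s2a * K Z' V^-1 (y - X b)
# with V = Z K Z' s2a + I s2e. Independent of the MME route.
blup_closed_form <- function(y, X, K, zi, s2a, s2e) {
  n <- length(y)
  Z <- matrix(0, n, nrow(K))
  Z[cbind(seq_len(n), zi)] <- 1
  V <- Z %*% K %*% t(Z) * s2a + diag(s2e, n)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- drop(s2a * K %*% t(Z) %*% Vi %*% (y - X %*% b))
  list(b = drop(b), u = setNames(u, rownames(K)))
}

# Gene-dropping kinship oracle: unique founder alleles dropped down the
# pedigree `reps` times; phi[i,j] = P(IBD of two randomly drawn alleles).
# Returns list(A = 2*phi matrix, se = elementwise Monte-Carlo SE of A).
gene_drop_A <- function(ped, reps, seed = 1) {
  set.seed(seed)
  ped <- ped
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  pat <- matrix(0L, reps, n)
  mat <- matrix(0L, reps, n)
  nxt <- 1L
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s)) {
      pat[, i] <- nxt; nxt <- nxt + 1L
    } else {
      si <- idx[[s]]
      pick <- runif(reps) < 0.5
      pat[, i] <- ifelse(pick, pat[, si], mat[, si])
    }
    if (is.na(d)) {
      mat[, i] <- nxt; nxt <- nxt + 1L
    } else {
      di <- idx[[d]]
      pick <- runif(reps) < 0.5
      mat[, i] <- ifelse(pick, pat[, di], mat[, di])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  SE <- A
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- (pat[, i] == pat[, j]) + (pat[, i] == mat[, j]) +
             (mat[, i] == pat[, j]) + (mat[, i] == mat[, j])
      a <- ibd / 2  # 2 * kinship per replicate
      A[i, j] <- A[j, i] <- mean(a)
      SE[i, j] <- SE[j, i] <- sd(a) / sqrt(reps)
    }
  }
  list(A = A, se = SE)
}

# Hudson FST estimator (ratio of averages) from two vectors of allele
# frequencies and haploid sample sizes.
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# A 15-individual pedigree with founders, two generations and some
# inbreeding (a sire mated to his half-sister), used by A-matrix oracles.
pedigree_15 <- function() {
  data.frame(
    id   = sprintf("i%02d", 1:15),
    sire = c(NA, NA, NA, NA, "i01", "i01", "i03", "i03", "i05", "i05",
             "i07", "i05", "i09", "i09", "i11"),
    dam  = c(NA, NA, NA, NA, "i02", "i04", "i02", "i04", "i06", "i08",
             "i06", "i08", "i10", "i12", "i10"),
    sex = rep(c("M", "F"), length.out = 15),
    generation = c(rep("F0", 4), rep("F1", 8), rep("F2", 3)),
    hatch = 1L,
    stringsAsFactors = FALSE
  )
}
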