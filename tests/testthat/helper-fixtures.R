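# shared fixtures: tiny abundance builders and small simulation specs

tiny_counts <- function(values, sample_ids = NULL, genome_ids = NULL) {
  m <- as.matrix(values)
  if (!is.null(sample_ids)) rownames(m) <- sample_ids
  if (!is.null(genome_ids)) colnames(m) <- genome_ids
  abundance_matrix(m, mode = "counts")
}

tiny_relative <- function(values, ...) {
  m <- tiny_counts(values, ...)
  to_relative(m)
}

# small-but-structured cohort for fast module tests
small_spec <- function(...) {
  simulation_spec(group_sizes = c(YHCG = 12L, HCG = 12L, EDG = 12L, LDG = 12L),
                  n_guild1 = 8L, n_guild2 = 6L, n_background = 30L,
                  depth = 5e4, ...)
}

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

# all 720 permutations of 1..6 (recursive enumeration)
gtools_permutations_6 <- function() {
  perm_rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perm_rec(v[-i]))
    }))
  }
  perm_rec(1:6)
}

# block-correlated Gaussian log-abundance -> multinomial counts; used to
# plant known basis correlation structure for the SparCC tests
basis_counts <- function(n, D, pairs_rho = NULL, seed = 1, depth = 1e5) {
  set.seed(seed)
  z <- matrix(rnorm(n * D), n, D)
  if (!is.null(pairs_rho)) {
    for (k in seq_len(nrow(pairs_rho))) {
      i <- pairs_rho[k, 1]; j <- pairs_rho[k, 2]; r <- pairs_rho[k, 3]
      z[, j] <- r * z[, i] + sqrt(1 - r^2) * z[, j]
    }
  }
  logab <- sweep(z, 2, rnorm(D, 0, 0.5), `+`)
  rel <- exp(logab); rel <- rel / rowSums(rel)
  counts <- t(vapply(seq_len(n),
                     function(s) as.numeric(rmultinom(1, depth, rel[s, ])),
                     numeric(D)))
  dimnames(counts) <- list(sprintf("S%03d", 1:n), sprintf("G%03d", 1:D))
  abundance_matrix(counts, mode = "counts")
}
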