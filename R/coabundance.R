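# SparCC-style compositional correlation with permutation p-values,
# co-abundance network construction, and connected components.
#
# The estimator follows the log-ratio-variance route: per resampling
# iteration, fractions are drawn Dirichlet(counts + 1) per sample,
# t_ij = var over samples of log(x_i/x_j), basis variances are solved from
# the sparse-correlation linear system, and rho is formed from (omega, t).
# Strongly correlated pairs are iteratively excluded from the system; the
# final estimate is the elementwise median over iterations.

# one SparCC pass on a fixed fraction matrix (samples x genomes, rows sum 1)
sparcc_once <- function(frac, exclusion_threshold, exclusion_rounds) {
  L <- log(frac)
  C <- cov(L)                       # genome x genome covariance of logs
  D <- ncol(C)
  v <- diag(C)
  t_mat <- outer(v, v, `+`) - 2 * C # t_ij = var(log x_i - log x_j)
  t_mat[t_mat < 0] <- 0
  diag(t_mat) <- 0

  # linear system: sum_j t_ij = (D-2) omega_i + sum_j omega_j
  M <- matrix(1, D, D) + diag(D - 2, D)
  tsum <- rowSums(t_mat)
  excl <- matrix(FALSE, D, D)
  rho <- NULL
  for (round in seq_len(exclusion_rounds + 1L)) {
    omega <- solve(M, tsum)
    omega[omega < 1e-12] <- 1e-12
    rho <- (outer(omega, omega, `+`) - t_mat) / (2 * sqrt(outer(omega, omega)))
    rho[rho > 1] <- 1; rho[rho < -1] <- -1
    diag(rho) <- 1
    if (round > exclusion_rounds) break
    cand <- abs(rho)
    cand[excl] <- 0
    diag(cand) <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    excl[i, j] <- excl[j, i] <- TRUE
    M[i, i] <- M[i, i] - 1; M[j, j] <- M[j, j] - 1
    M[i, j] <- M[i, j] - 1; M[j, i] <- M[j, i] - 1
    tsum[i] <- tsum[i] - t_mat[i, j]
    tsum[j] <- tsum[j] - t_mat[i, j]
  }
  list(rho = rho, t = t_mat, omega = omega, excluded = excl)
}

dirichlet_fractions <- function(counts) {
  g <- matrix(rgamma(length(counts), shape = counts + 1), nrow(counts))
  g / rowSums(g)
}

#' SparCC compositional correlation
#'
#' Estimates correlations between underlying (basis) abundances from
#' compositional count data. Requires counts mode and at least 4 genomes
#' (the basis-variance system is underdetermined below that). Relative
#' abundances are accepted by scaling to pseudo-counts at `pseudo_depth`
#' with a warning.
#'
#' @param m counts-mode [abundance_matrix()] (samples x genomes).
#' @param inner_iterations Dirichlet resampling iterations (default 20);
#'   the estimate is the elementwise median across iterations.
#' @param exclusion_threshold,exclusion_rounds strong-pair exclusion loop:
#'   per round the largest remaining |rho| above the threshold is removed
#'   from the linear system (default 0.1 / 10 rounds).
#' @param seed optional integer seed.
#' @param pseudo_depth depth used to convert relative input to counts.
#' @return list of class `sparcc_fit`: `rho` (clamped to [-1,1], unit
#'   diagonal), `t` (log-ratio variances), `omega` (basis variances),
#'   `excluded_pairs`, `genome_ids`.
#' @export
sparcc <- function(m, inner_iterations = 20L, exclusion_threshold = 0.1,
                   exclusion_rounds = 10L, seed = NULL, pseudo_depth = 1e5) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (identical(abundance_mode(m), "relative")) {
    warning("relative input scaled to pseudo-counts at depth ", pseudo_depth)
    m <- abundance_matrix(round(unclass_mat(m) * pseudo_depth), mode = "counts")
  }
  D <- ncol(m)
  if (D < 4) stop("SparCC needs >= 4 genomes")
  if (!is.null(seed)) set.seed(as.integer(seed))
  counts <- unclass_mat(m)
  rhos <- array(0, c(D, D, inner_iterations))
  ts <- array(0, c(D, D, inner_iterations))
  oms <- matrix(0, D, inner_iterations)
  excl_any <- matrix(FALSE, D, D)
  for (it in seq_len(inner_iterations)) {
    fit <- sparcc_once(dirichlet_fractions(counts),
                       exclusion_threshold, exclusion_rounds)
    rhos[, , it] <- fit$rho
    ts[, , it] <- fit$t
    oms[, it] <- fit$omega
    excl_any <- excl_any | fit$excluded
  }
  rho <- apply(rhos, c(1, 2), median)
  tm <- apply(ts, c(1, 2), median)
  omega <- apply(oms, 1, median)
  dimnames(rho) <- dimnames(tm) <- list(colnames(m), colnames(m))
  names(omega) <- colnames(m)
  excl_idx <- which(excl_any & upper.tri(excl_any), arr.ind = TRUE)
  structure(list(rho = rho, t = tm, omega = omega,
                 excluded_pairs = data.frame(
                   genome_a = colnames(m)[excl_idx[, 1]],
                   genome_b = colnames(m)[excl_idx[, 2]],
                   stringsAsFactors = FALSE),
                 genome_ids = colnames(m),
                 inner_iterations = inner_iterations),
            class = "sparcc_fit")
}

#' @export
print.sparcc_fit <- function(x, ...) {
  cat(sprintf("<sparcc_fit> %d genomes, %d iterations, %d excluded pairs\n",
              length(x$genome_ids), x$inner_iterations,
              nrow(x$excluded_pairs)))
  invisible(x)
}

#' Permutation p-values for SparCC correlations
#'
#' Each permutation shuffles every genome's counts independently across
#' samples (destroying all cross-genome dependence while preserving
#' marginals), recomputes SparCC, and compares |rho_null| with |rho_obs|
#' elementwise: p_ij = (1 + #{|rho_null| >= |rho_obs|}) / (1 + B).
#' Two-sided by construction.
#'
#' @param m the counts matrix used for `observed`.
#' @param observed a `sparcc_fit`.
#' @param n_permutations number of permutations B >= 1 (default 1000).
#' @param seed integer seed (p-values are deterministic given it).
#' @param inner_iterations iterations per null fit; a reduced count
#'   (default 5) keeps the null affordable.
#' @param exclusion_threshold,exclusion_rounds as in [sparcc()].
#' @return symmetric p-value matrix, unit diagonal.
#' @export
sparcc_pvalues <- function(m, observed, n_permutations = 1000L, seed = NULL,
                           inner_iterations = 5L, exclusion_threshold = 0.1,
                           exclusion_rounds = 10L) {
  stopifnot(inherits(observed, "sparcc_fit"))
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (identical(abundance_mode(m), "relative"))
    m <- abundance_matrix(round(unclass_mat(m) * 1e5), mode = "counts")
  counts <- unclass_mat(m)
  D <- ncol(counts); n <- nrow(counts)
  if (!is.null(seed)) set.seed(as.integer(seed))
  obs <- abs(observed$rho)
  count_ge <- matrix(0L, D, D)
  for (b in seq_len(n_permutations)) {
    perm <- apply(counts, 2, function(col) col[sample.int(n)])
    fit <- sparcc(abundance_matrix(perm, mode = "counts"),
                  inner_iterations = inner_iterations,
                  exclusion_threshold = exclusion_threshold,
                  exclusion_rounds = exclusion_rounds, seed = NULL)
    count_ge <- count_ge + (abs(fit$rho) >= obs)
  }
  p <- (1 + count_ge) / (1 + n_permutations)
  diag(p) <- 1
  dimnames(p) <- dimnames(observed$rho)
  p
}

#' Build a co-abundance network from correlations and p-values
#'
#' Retains all pairs with p <= `edge_p` (default 0.001); edge sign is the
#' sign of rho. When a guild assignment is supplied, within/between-guild
#' positive/negative edge counts are attached.
#'
#' @param rho,p aligned symmetric matrices.
#' @param edge_p retention threshold.
#' @param guilds optional [guild assignment][detect_guilds()] data.frame.
#' @return data.frame of class `edge_list`: genome_a, genome_b, rho, p,
#'   sign; attribute `guild_edge_summary` when guilds given.
#' @export
build_network <- function(rho, p, edge_p = 0.001, guilds = NULL) {
  stopifnot(identical(dim(rho), dim(p)))
  idx <- which(upper.tri(p) & p <= edge_p, arr.ind = TRUE)
  out <- data.frame(genome_a = rownames(rho)[idx[, 1]],
                    genome_b = colnames(rho)[idx[, 2]],
                    rho = rho[idx], p = p[idx],
                    sign = ifelse(rho[idx] >= 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  if (!is.null(guilds)) {
    ga <- setNames(guilds$guild, guilds$genome_id)
    a <- ga[out$genome_a]; b <- ga[out$genome_b]
    within <- !is.na(a) & !is.na(b) & a == b & a != "unassigned"
    between <- !is.na(a) & !is.na(b) & a != b &
      a != "unassigned" & b != "unassigned"
    attr(out, "guild_edge_summary") <- data.frame(
      scope = c("within", "within", "between", "between"),
      sign = c("positive", "negative", "positive", "negative"),
      n = c(sum(within & out$sign == "positive"),
            sum(within & out$sign == "negative"),
            sum(between & out$sign == "positive"),
            sum(between & out$sign == "negative")))
  }
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Connected components of a co-abundance network
#'
#' Union-find over the chosen edge subset; `positive_only` drops negative
#' edges first.
#'
#' @param edges an `edge_list`.
#' @param nodes character vector of all node ids (isolated nodes become
#'   singleton components).
#' @param mode `"all_edges"` or `"positive_only"`.
#' @return named integer vector: component id per node (1-based, ordered
#'   by first appearance).
#' @export
connected_components <- function(edges, nodes,
                                 mode = c("all_edges", "positive_only")) {
  mode <- match.arg(mode)
  if (mode == "positive_only") edges <- edges[edges$sign == "positive", ]
  parent <- seq_along(nodes)
  names(parent) <- nodes
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(edges))) {
    a <- match(edges$genome_a[k], nodes)
    b <- match(edges$genome_b[k], nodes)
    if (is.na(a) || is.na(b)) next
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  comp <- match(roots, unique(roots))
  names(comp) <- nodes
  comp
}
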