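# Nonparametric group statistics: Kruskal-Wallis + Dunn post hoc with BH
# adjustment and compact letter displays, Mann-Whitney, Fisher's exact
# 2x2, age-adjusted partial Spearman, and Benjamini-Hochberg adjustment.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' preserves the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, elementwise >= `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- sum(!is.na(p))
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  o <- order(p[ok], decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[ok][o]))
  out[ok][o] <- adj
  out
}

# midranks with tie bookkeeping
rank_ties <- function(x) {
  r <- rank(x, ties.method = "average")
  tab <- table(x)
  list(rank = r, tie_term = sum(tab^3 - tab))
}

#' Kruskal-Wallis with Dunn post hoc and compact letter display
#'
#' Tie-corrected Kruskal-Wallis across groups; Dunn's two-sided pairwise z
#' tests on mean ranks with tie correction; Benjamini-Hochberg adjustment
#' across the pairs; compact letters via the insert-and-absorb algorithm so
#' that two groups share a letter iff their adjusted p >= alpha.
#'
#' @param values numeric vector.
#' @param groups factor aligned to `values`; every level needs n >= 2.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list of class `group_test`: `H`, `df`, `p` (KW), `pairs`
#'   (data.frame: group_a, group_b, z, p, p_adjusted), `letters` (named
#'   character per group).
#' @export
kruskal_dunn_cld <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  k <- nlevels(groups)
  if (k < 2) stop("need >= 2 groups")
  n_g <- table(groups)
  if (any(n_g < 2)) stop("each group needs n >= 2: ",
                         paste(names(n_g)[n_g < 2], collapse = ", "))
  N <- length(values)
  rt <- rank_ties(values)
  r <- rt$rank
  mean_rank <- tapply(r, groups, mean)
  H <- (12 / (N * (N + 1))) * sum(n_g * (mean_rank - (N + 1) / 2)^2)
  C <- 1 - rt$tie_term / (N^3 - N)
  H <- if (C > 0) H / C else H
  kw_p <- pchisq(H, df = k - 1, lower.tail = FALSE)

  lv <- levels(groups)
  prs <- combn(lv, 2, simplify = FALSE)
  sigma2 <- (N * (N + 1) / 12) - rt$tie_term / (12 * (N - 1))
  pair_df <- do.call(rbind, lapply(prs, function(pr) {
    i <- pr[1]; j <- pr[2]
    z <- (mean_rank[i] - mean_rank[j]) /
      sqrt(sigma2 * (1 / n_g[i] + 1 / n_g[j]))
    data.frame(group_a = i, group_b = j, z = as.numeric(z),
               p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  pair_df$p_adjusted <- bh_adjust(pair_df$p)
  sig <- pair_df$p_adjusted < alpha
  letters_out <- compact_letters(lv, pair_df$group_a[sig], pair_df$group_b[sig])
  structure(list(H = H, df = k - 1, p = kw_p, pairs = pair_df,
                 letters = letters_out, alpha = alpha),
            class = "group_test")
}

# insert-and-absorb compact letter display: groups sharing no letter are
# exactly the significantly different pairs
compact_letters <- function(groups, sig_a, sig_b) {
  sets <- list(groups)
  for (k in seq_along(sig_a)) {
    i <- sig_a[k]; j <- sig_b[k]
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) {
      for (b in seq_along(new_sets)) {
        if (a != b && keep[a] && keep[b] &&
            all(new_sets[[a]] %in% new_sets[[b]]) &&
            (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    sets <- new_sets[keep]
    sets <- sets[vapply(sets, length, integer(1)) > 0]
  }
  # order sets by the position of their first group for stable letters
  first <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first)]
  out <- setNames(rep("", length(groups)), groups)
  for (s in seq_along(sets)) {
    lt <- letters[(s - 1) %% 26 + 1]
    if (s > 26) lt <- paste0(lt, (s - 1) %/% 26)
    for (g in sets[[s]]) out[g] <- paste0(out[g], lt)
  }
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' U counts pairs with x > y plus half the ties. Small samples
#' (min(n, m) <= 8 and a feasible enumeration) use exact enumeration of
#' group assignments (tie-aware); otherwise a tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y nonempty numeric vectors.
#' @return list: `U`, `p`, `method` ("exact" or "normal").
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (!n || !m) stop("both samples must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  small <- min(n, m)
  if (small <= 8 && choose(n + m, small) <= 2e5) {
    # exact: enumerate which pooled positions belong to the smaller sample
    swap <- m < n
    idx_n <- if (swap) m else n
    combos <- combn(n + m, idx_n)
    rsums <- colSums(matrix(r[combos], nrow = idx_n))
    Uall <- rsums - idx_n * (idx_n + 1) / 2
    Uobs <- if (swap) sum(r[n + seq_len(m)]) - m * (m + 1) / 2 else U
    mu <- idx_n * (n + m - idx_n) / 2
    eps <- 1e-9
    lower <- mean(Uall <= Uobs + eps)
    upper <- mean(Uall >= Uobs - eps)
    p <- min(1, 2 * min(lower, upper))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- n * m / 2
  ties <- table(pooled)
  N <- n + m
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p-value by the minimum-likelihood convention: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed the observed table's. A zero margin
#' gives p = 1 by convention (with a warning).
#'
#' @param tab 2x2 matrix of nonnegative integers.
#' @return list: `odds_ratio` (sample OR), `p`.
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must hold nonnegative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- (a * d) / (b * c_)
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) {
    warning("zero margin; p = 1 by convention")
    return(list(odds_ratio = or, p = 1))
  }
  support <- max(0, k - m2):min(k, m1)
  dens <- dhyper(support, m1, m2, k)
  obs <- dhyper(a, m1, m2, k)
  p <- sum(dens[dens <= obs * (1 + 1e-7)])
  list(odds_ratio = or, p = min(1, p))
}

#' Age-adjusted partial Spearman correlation
#'
#' Rank-transforms x, y and the covariate, then computes the first-order
#' partial Pearson correlation of the ranks:
#' rho_p = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)).
#' The p-value uses the t approximation with df = n - 3.
#'
#' @param x,y numeric vectors.
#' @param z covariate to partial out (typically age).
#' @return list: `rho`, `p`, `n` (complete cases used).
#' @export
partial_spearman <- function(x, y, z) {
  keep <- complete.cases(x, y, z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  n <- length(x)
  if (n < 4) stop("need >= 4 complete cases")
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0) stop("constant input")
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  r_xy <- cor(rx, ry); r_xz <- cor(rx, rz); r_yz <- cor(ry, rz)
  denom <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
  rho <- if (denom == 0) 0 else (r_xy - r_xz * r_yz) / denom
  rho <- max(-1, min(1, rho))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 3) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 3)
  }
  list(rho = rho, p = p, n = n)
}
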