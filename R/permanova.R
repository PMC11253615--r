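# Permutational multivariate ANOVA on a distance matrix: single-factor,
# marginal (each term adjusted for the others), and pairwise group
# comparisons with Benjamini-Hochberg adjustment.

# hat matrix of a design (QR-based, rank-aware)
hat_matrix <- function(X) {
  qr_ <- qr(X)
  Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  tcrossprod(Q)
}

# trace(H G) for symmetric G
ss_model <- function(H, G) sum(H * G)

permanova_core <- function(G, X, df_model, n_permutations, seed,
                           tot = sum(diag(G)), permutations = NULL) {
  H <- hat_matrix(X)
  n <- nrow(G)
  ssm <- ss_model(H, G) - sum(G) / n   # subtract intercept SS (grand mean)
  ssr <- tot - sum(G) / n - ssm
  df_resid <- n - qr(X)$rank
  Fobs <- (ssm / df_model) / (ssr / df_resid)
  if (!is.null(permutations)) n_permutations <- nrow(permutations)
  if (!is.null(seed)) set.seed(as.integer(seed))
  count <- 0L
  # inclusive ties, robust to fp noise; a non-finite observed F (perfect
  # fit) is only matched by another perfect fit, and 0/0 permutations
  # count as non-exceedances
  thresh <- if (is.finite(Fobs)) Fobs - 1e-8 * (abs(Fobs) + 1) else Fobs
  for (b in seq_len(n_permutations)) {
    p <- if (is.null(permutations)) sample.int(n) else permutations[b, ]
    Gp <- G[p, p]
    ssm_p <- ss_model(H, Gp) - sum(Gp) / n
    ssr_p <- tot - sum(Gp) / n - ssm_p
    Fp <- (ssm_p / df_model) / (ssr_p / df_resid)
    if (!is.na(Fp) && Fp >= thresh) count <- count + 1L
  }
  list(SS = ssm, SS_resid = ssr, SS_total = tot - sum(G) / n,
       df = df_model, df_resid = df_resid,
       R2 = ssm / (tot - sum(G) / n), F = Fobs,
       p = (1 + count) / (1 + n_permutations))
}

#' Single-factor PERMANOVA
#'
#' Partitions the Gower-centered inner-product decomposition of a distance
#' matrix by a single factor or numeric covariate. The pseudo-F statistic
#' is (SS_model/df_model)/(SS_resid/df_resid); its p-value comes from free
#' permutation of whole samples, with ties counted inclusively.
#'
#' @param d a [distance_matrix()].
#' @param labels factor (>= 2 levels, each with >= 2 samples) or numeric
#'   covariate, aligned to `d`.
#' @param n_permutations number of permutations (default 999; the p-value
#'   floor is 1/(n_permutations + 1)).
#' @param seed optional integer seed for the permutation stream.
#' @param term name used in the report.
#' @param permutations optional matrix of explicit permutations (one row
#'   per permutation of 1..n); overrides `n_permutations`, enabling exact
#'   enumeration.
#' @return one-row data.frame of class `permanova_result`: term, df, SS,
#'   R2, F, p, n_permutations.
#' @export
permanova_single <- function(d, labels, n_permutations = 999L, seed = NULL,
                             term = "term", permutations = NULL) {
  stopifnot(inherits(d, "distance_matrix"))
  n <- nrow(d)
  if (length(labels) != n) stop("labels must align with the distance matrix")
  if (!is.numeric(labels)) {
    labels <- factor(labels)
    tab <- table(labels)
    if (nlevels(labels) < 2) stop("need >= 2 levels")
    if (any(tab < 2)) stop("each level needs >= 2 samples: ",
                           paste(names(tab)[tab < 2], collapse = ", "))
  }
  G <- gower_center(unclass(d))
  X <- stats::model.matrix(~labels)
  df_model <- qr(X)$rank - 1L
  res <- permanova_core(G, X, df_model, n_permutations, seed,
                        permutations = permutations)
  n_used <- if (is.null(permutations)) n_permutations else nrow(permutations)
  out <- data.frame(term = term, df = res$df, SS = res$SS, R2 = res$R2,
                    F = res$F, p = res$p, n_permutations = n_used,
                    stringsAsFactors = FALSE)
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' Marginal PERMANOVA over several terms
#'
#' For each term, the marginal sum of squares is SS(full) - SS(without the
#' term); pseudo-F uses the full model's residual. Rows are freely permuted
#' (adonis2 `by = "margin"` style).
#'
#' @param d a [distance_matrix()].
#' @param data data.frame of term columns aligned to `d`.
#' @param terms character vector of column names to test (default: all).
#' @param n_permutations,seed as in [permanova_single()].
#' @return `permanova_result` data.frame with one row per term.
#' @export
permanova_marginal <- function(d, data, terms = names(data),
                               n_permutations = 999L, seed = NULL) {
  stopifnot(inherits(d, "distance_matrix"), is.data.frame(data))
  n <- nrow(d)
  if (nrow(data) != n) stop("data must align with the distance matrix")
  G <- gower_center(unclass(d))
  tot <- sum(diag(G))
  sst <- tot - sum(G) / n
  full_form <- stats::as.formula(paste("~", paste(terms, collapse = "+")))
  Xf <- stats::model.matrix(full_form, data)
  rank_full <- qr(Xf)$rank
  Hf <- hat_matrix(Xf)
  df_resid <- n - rank_full
  if (df_resid < 1) stop("full design leaves no residual degrees of freedom")
  ss_full <- ss_model(Hf, G) - sum(G) / n
  ssr_full <- sst - ss_full

  rows <- lapply(terms, function(tm) {
    others <- setdiff(terms, tm)
    Xr <- if (length(others)) {
      stats::model.matrix(stats::as.formula(paste("~", paste(others, collapse = "+"))), data)
    } else matrix(1, n, 1)
    rank_red <- qr(Xr)$rank
    df_term <- rank_full - rank_red
    Hr <- hat_matrix(Xr)
    ss_term <- ss_full - (ss_model(Hr, G) - sum(G) / n)
    if (df_term == 0) {
      return(data.frame(term = tm, df = 0L, SS = ss_term, R2 = ss_term / sst,
                        F = NA_real_, p = NA_real_,
                        n_permutations = n_permutations,
                        stringsAsFactors = FALSE))
    }
    Fobs <- (ss_term / df_term) / (ssr_full / df_resid)
    if (!is.null(seed)) set.seed(as.integer(seed))
    count <- 0L
    thresh <- if (is.finite(Fobs)) Fobs - 1e-8 * (abs(Fobs) + 1) else Fobs
    for (b in seq_len(n_permutations)) {
      p <- sample.int(n)
      Gp <- G[p, p]
      gshift <- sum(Gp) / n
      ssf_p <- ss_model(Hf, Gp) - gshift
      sst_p <- sum(diag(Gp)) - gshift
      ss_term_p <- ssf_p - (ss_model(Hr, Gp) - gshift)
      Fp <- (ss_term_p / df_term) / ((sst_p - ssf_p) / df_resid)
      if (!is.na(Fp) && Fp >= thresh) count <- count + 1L
    }
    data.frame(term = tm, df = df_term, SS = ss_term, R2 = ss_term / sst,
               F = Fobs, p = (1 + count) / (1 + n_permutations),
               n_permutations = n_permutations, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' Pairwise PERMANOVA between factor levels
#'
#' Runs [permanova_single()] on the sub-distance-matrix of every pair of
#' levels and adjusts p-values across pairs with Benjamini-Hochberg.
#'
#' @param d a [distance_matrix()].
#' @param group factor aligned to `d`.
#' @param n_permutations,seed as in [permanova_single()].
#' @return `permanova_result` data.frame, one row per pair, with
#'   `p_adjusted`.
#' @export
pairwise_permanova <- function(d, group, n_permutations = 999L, seed = NULL) {
  group <- factor(group)
  lv <- levels(group)
  if (length(lv) < 2) stop("need >= 2 levels")
  pairs <- combn(lv, 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    keep <- which(group %in% pr)
    dsub <- distance_matrix(unclass(d)[keep, keep, drop = FALSE],
                            metric = attr(d, "metric"))
    res <- permanova_single(dsub, droplevels(group[keep]),
                            n_permutations = n_permutations,
                            seed = if (is.null(seed)) NULL else seed + i,
                            term = paste(pr, collapse = " vs "))
    res
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  class(out) <- c("permanova_result", "data.frame")
  out
}
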