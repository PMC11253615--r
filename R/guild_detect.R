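# Guild detection: complete-linkage hierarchical clustering on a signed
# WGCNA-style topological overlap (or directly on 1 - rho), with
# clinically anchored guild labels.

#' Signed topological overlap matrix
#'
#' Signed adjacency a_ij = ((1 + rho_ij)/2)^beta (anti-correlated pairs get
#' near-zero weight), then topological overlap
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij), with
#' unit diagonal.
#'
#' @param rho symmetric correlation matrix in [-1, 1].
#' @param beta soft-threshold power >= 1 (default 6, a common signed-network
#'   choice).
#' @return TOM similarity matrix in [0, 1].
#' @export
signed_tom <- function(rho, beta = 6) {
  if (beta < 1) stop("beta must be >= 1")
  stopifnot(is.matrix(rho), max(abs(rho - t(rho))) < 1e-8)
  a <- ((1 + rho) / 2)^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(rho)
  tom
}

#' Detect guilds from a co-abundance correlation matrix
#'
#' Complete-linkage hierarchical clustering on 1 - TOM (default) or
#' 1 - rho, cut to `n_guilds` clusters. Clusters smaller than
#' `min_guild_size` are relabeled "unassigned". Guild numbering defaults to
#' descending mean abundance (guild1 = most abundant guild) when an
#' abundance matrix is supplied; use [anchor_guild_labels()] to fix
#' numbering by clinical correlation instead.
#'
#' @param rho symmetric correlation matrix with dimnames.
#' @param method `"tom_tree"` (default) or `"corr_tree"`.
#' @param n_guilds number of clusters to cut (default 2).
#' @param min_guild_size minimum retained guild size (default 3).
#' @param beta TOM soft-threshold power.
#' @param abundance optional [abundance_matrix()] used for abundance-based
#'   guild numbering.
#' @return data.frame of class `guild_assignment`: genome_id, guild; the
#'   `hclust` tree and parameters are attached as attributes.
#' @export
detect_guilds <- function(rho, method = c("tom_tree", "corr_tree"),
                          n_guilds = 2L, min_guild_size = 3L, beta = 6,
                          abundance = NULL) {
  method <- match.arg(method)
  ids <- rownames(rho)
  if (is.null(ids)) stop("rho needs dimnames")
  if (length(ids) < 2 * min_guild_size)
    stop("need at least 2 * min_guild_size genomes")
  sim <- if (method == "tom_tree") signed_tom(rho, beta = beta) else rho
  dist_mat <- 1 - sim
  off <- dist_mat[upper.tri(dist_mat)]
  if (max(off) - min(off) < 1e-12) stop("degenerate distance: all pairs equal")
  tree <- hclust(as.dist(dist_mat), method = "complete")
  cl <- cutree(tree, k = n_guilds)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_guild_size])
  guild <- rep("unassigned", length(ids))
  if (length(keep)) {
    # order retained clusters: by mean member abundance if available,
    # else by size then first appearance
    ord_stat <- vapply(keep, function(k) {
      members <- ids[cl == k]
      if (!is.null(abundance)) {
        mean(to_relative(abundance)[, members, drop = FALSE])
      } else {
        length(members) + 1e-9 * (length(ids) - min(which(cl == k)))
      }
    }, numeric(1))
    ranked <- keep[order(-ord_stat)]
    for (g in seq_along(ranked))
      guild[cl == ranked[g]] <- paste0("guild", g)
  }
  out <- data.frame(genome_id = ids, guild = guild, stringsAsFactors = FALSE)
  attr(out, "tree") <- tree
  attr(out, "parameters") <- list(method = method, n_guilds = n_guilds,
                                  min_guild_size = min_guild_size, beta = beta)
  class(out) <- c("guild_assignment", "data.frame")
  out
}

#' Members of one guild
#' @param g a `guild_assignment`.
#' @param guild guild label.
#' @return character vector of genome ids.
#' @export
guild_members <- function(g, guild) g$genome_id[g$guild == guild]

#' Anchor guild numbering to a clinical covariate
#'
#' Relabels guilds so that the guild whose index correlates positively with
#' the covariate (typically eGFR, higher = healthier) is "guild1"
#' (protective) and the negatively correlated one "guild2" (detrimental).
#' Ties are broken by larger absolute correlation. If all correlations are
#' zero or the covariate is constant, the incoming labels are kept with a
#' warning.
#'
#' @param g a `guild_assignment` with >= 2 guilds.
#' @param indices [guild_index()] table for the current labels.
#' @param clinical numeric covariate aligned to the samples of `indices`.
#' @return relabeled `guild_assignment`.
#' @export
anchor_guild_labels <- function(g, indices, clinical) {
  labs <- setdiff(unique(g$guild), "unassigned")
  if (length(labs) < 2) stop("need >= 2 guilds to anchor")
  if (sd(clinical, na.rm = TRUE) == 0 || all(is.na(clinical))) {
    warning("clinical covariate constant; keeping abundance-based labels")
    return(g)
  }
  cors <- vapply(labs, function(lb) {
    suppressWarnings(cor(indices[[paste0(lb, "_index")]], clinical,
                         method = "spearman", use = "pairwise.complete.obs"))
  }, numeric(1))
  if (all(is.na(cors)) || all(abs(cors) < .Machine$double.eps)) {
    warning("all guild-index correlations zero; keeping abundance-based labels")
    return(g)
  }
  # protective first: sort by correlation descending, |cor| breaks ties
  ord <- order(-sign(cors), -abs(cors))
  mapping <- setNames(paste0("guild", seq_along(labs)), labs[ord])
  out <- g
  out$guild <- ifelse(g$guild == "unassigned", "unassigned", mapping[g$guild])
  attr(out, "tree") <- attr(g, "tree")
  attr(out, "parameters") <- c(attr(g, "parameters"),
                               list(anchored = TRUE,
                                    anchor_correlations = cors))
  class(out) <- class(g)
  out
}
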