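# Constrained-ordination screening: per-genome fraction of (Hellinger)
# abundance variance explained by the group constraint, with an inclusive
# selection threshold.

#' Per-genome variance explained by the group constraint
#'
#' RDA with the group indicator matrix as the only constraint: the
#' constrained axes jointly span the design's column space, so the
#' variability of a genome explained by all constrained axes equals its
#' ordinary least-squares R^2 on the group design. Computed as
#' (sum of squared fitted values) / (sum of squared centered values), per
#' genome, after Hellinger transformation and column centering.
#'
#' @param m an [abundance_matrix()]; Hellinger transform is applied unless
#'   `hellinger_transform = FALSE`.
#' @param group factor with >= 2 levels aligned to samples.
#' @param hellinger_transform apply [hellinger()] first (default TRUE).
#' @return named numeric vector of variance_explained in [0, 1] per genome;
#'   constant genomes get 0 with a warning.
#' @export
rda_variance_explained <- function(m, group, hellinger_transform = TRUE) {
  stopifnot(inherits(m, "abundance_matrix"))
  group <- factor(group)
  if (nlevels(group) < 2) stop("group needs >= 2 levels")
  if (length(group) != nrow(m)) stop("group must align with samples")
  x <- if (hellinger_transform) unclass_mat(hellinger(m)) else unclass_mat(m)
  xc <- scale(x, center = TRUE, scale = FALSE)
  H <- hat_matrix(stats::model.matrix(~group))
  fitted <- H %*% xc
  ss_fit <- colSums(fitted^2)
  ss_tot <- colSums(xc^2)
  ve <- numeric(ncol(x))
  const <- ss_tot <= .Machine$double.eps * nrow(x)
  if (any(const))
    warning("constant genome column(s), variance_explained set to 0: ",
            paste(colnames(x)[const], collapse = ", "))
  ve[!const] <- ss_fit[!const] / ss_tot[!const]
  ve <- pmin(pmax(ve, 0), 1)
  names(ve) <- colnames(x)
  ve
}

#' Select signature genomes by explained-variance threshold
#'
#' Genomes with at least `threshold` of their abundance variability
#' explained by the constrained axes are selected (inclusive comparison).
#'
#' @param ve named vector from [rda_variance_explained()].
#' @param threshold selection threshold in (0, 1), default 0.10.
#' @return data.frame (class `selection_result`) sorted by
#'   variance_explained descending: genome_id, variance_explained, selected.
#' @export
select_signature <- function(ve, threshold = 0.10) {
  stopifnot(threshold > 0, threshold < 1)
  out <- data.frame(genome_id = names(ve),
                    variance_explained = as.numeric(ve),
                    selected = as.numeric(ve) >= threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$variance_explained), ]
  rownames(out) <- NULL
  class(out) <- c("selection_result", "data.frame")
  out
}
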