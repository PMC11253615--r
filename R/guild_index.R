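# Per-sample guild index: (total relative abundance of guild members) x
# (Gini-Simpson diversity of the members within the sample).

#' Guild index per sample
#'
#' For each sample j and guild with member set N:
#' T_j = sum_{i in N} A_ij, q_i = A_ij / T_j, and
#' index_j = T_j * (1 - sum q_i^2) under the Gini-Simpson convention
#' (index_j = 0 when T_j = 0 or the guild has a single effective member).
#' High values mean the guild is both abundant and even in the sample.
#'
#' @param m an [abundance_matrix()]; counts are converted to relative so
#'   the index is comparable across sequencing depths.
#' @param g a [guild_assignment][detect_guilds()].
#' @param convention Simpson convention, `"gini"` (default) or
#'   `"inverse"` (uses 1/sum q^2 as the diversity weight).
#' @return data.frame of class `guild_index_table`: sample_id plus one
#'   `<guild>_index` column per guild.
#' @export
guild_index <- function(m, g, convention = c("gini", "inverse")) {
  convention <- match.arg(convention)
  m <- to_relative(m)
  x <- unclass_mat(m)
  labs <- setdiff(sort(unique(g$guild)), "unassigned")
  if (!length(labs)) stop("no guilds in assignment")
  out <- data.frame(sample_id = rownames(x), stringsAsFactors = FALSE)
  for (lb in labs) {
    members <- guild_members(g, lb)
    missing <- setdiff(members, colnames(x))
    if (length(missing) == length(members))
      stop(sprintf("guild '%s' has no members in the abundance matrix: %s",
                   lb, paste(missing, collapse = ", ")))
    if (length(missing))
      warning(sprintf("guild '%s': dropping members absent from matrix: %s",
                      lb, paste(missing, collapse = ", ")))
    sub <- x[, intersect(members, colnames(x)), drop = FALSE]
    total <- rowSums(sub)
    div <- apply(sub, 1, simpson_diversity, convention = convention)
    out[[paste0(lb, "_index")]] <- total * div
  }
  class(out) <- c("guild_index_table", "data.frame")
  out
}
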