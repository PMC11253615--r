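# Guild-level functional comparisons from per-genome annotation tables:
# gene-carrier contrasts (Fisher), copy-number contrasts (Mann-Whitney),
# guild-unique KEGG-module detection, and KO-space ordination.

guild_pair <- function(g) {
  labs <- setdiff(sort(unique(g$guild)), "unassigned")
  if (length(labs) < 2) stop("need >= 2 guilds")
  labs[1:2]
}

#' Gene-carrier contrast between two guilds
#'
#' A genome is a carrier if its copy number of the gene family is >= 1.
#' Builds the guild x carrier 2x2 table and applies
#' [fisher_exact_2x2()].
#'
#' @param ann a [genome_annotation()].
#' @param g a guild assignment.
#' @param gene gene-family name (must be a column of `ann$gene_copies`).
#' @return list: `table` (data.frame gene, guild, carriers, total),
#'   `odds_ratio`, `p`.
#' @export
carrier_contrast <- function(ann, g, gene) {
  if (!gene %in% colnames(ann$gene_copies))
    stop("unknown gene '", gene, "'; valid names: ",
         paste(colnames(ann$gene_copies), collapse = ", "))
  labs <- guild_pair(g)
  counts <- vapply(labs, function(lb) {
    members <- intersect(guild_members(g, lb), rownames(ann$gene_copies))
    c(carriers = sum(ann$gene_copies[members, gene] >= 1),
      total = length(members))
  }, numeric(2))
  tab <- matrix(c(counts["carriers", 1], counts["total", 1] - counts["carriers", 1],
                  counts["carriers", 2], counts["total", 2] - counts["carriers", 2]),
                2, 2, byrow = TRUE,
                dimnames = list(labs, c("carrier", "non_carrier")))
  fit <- fisher_exact_2x2(tab)
  list(table = data.frame(gene = gene, guild = labs,
                          carriers = counts["carriers", ],
                          total = counts["total", ],
                          stringsAsFactors = FALSE),
       odds_ratio = fit$odds_ratio, p = fit$p)
}

#' Copy-number contrast between two guilds
#'
#' Splits per-genome copy numbers of one gene family by guild and runs a
#' two-sided [mann_whitney()] test.
#'
#' @inheritParams carrier_contrast
#' @return list: `copies` (named list of per-guild copy vectors), `U`, `p`.
#' @export
copy_number_contrast <- function(ann, g, gene) {
  if (!gene %in% colnames(ann$gene_copies))
    stop("unknown gene '", gene, "'; valid names: ",
         paste(colnames(ann$gene_copies), collapse = ", "))
  labs <- guild_pair(g)
  copies <- lapply(labs, function(lb) {
    members <- intersect(guild_members(g, lb), rownames(ann$gene_copies))
    ann$gene_copies[members, gene]
  })
  names(copies) <- labs
  mw <- mann_whitney(copies[[1]], copies[[2]])
  list(copies = copies, U = mw$U, p = mw$p, method = mw$method)
}

#' Guild-unique module detection
#'
#' A module (a flat KO list) is present in a guild iff at least one member
#' genome carries at least `completeness` of the module's KO set
#' (per-genome completeness; default 1 = all KOs in one genome). Reports
#' modules unique to each guild.
#'
#' @param ann a [genome_annotation()] with `ko_copies`.
#' @param g a guild assignment.
#' @param catalog named list: module_id -> character vector of KO ids.
#' @param completeness fraction of a module's KOs a single genome must
#'   carry (default 1.0).
#' @return list: `present` (named list of per-guild module id vectors),
#'   `unique` (named list of guild-unique module ids).
#' @export
unique_modules <- function(ann, g, catalog, completeness = 1.0) {
  if (!length(catalog)) stop("empty module catalog")
  if (is.null(ann$ko_copies)) stop("annotation lacks KO copy numbers")
  stopifnot(completeness > 0, completeness <= 1)
  labs <- guild_pair(g)
  ko <- ann$ko_copies
  present <- lapply(labs, function(lb) {
    members <- intersect(guild_members(g, lb), rownames(ko))
    sub <- ko[members, , drop = FALSE] >= 1
    hit <- vapply(catalog, function(kos) {
      kos_here <- intersect(kos, colnames(sub))
      if (!length(kos_here) ||
          length(kos_here) / length(kos) < completeness) return(FALSE)
      frac <- rowSums(sub[, kos_here, drop = FALSE]) / length(kos)
      any(frac >= completeness - 1e-9)
    }, logical(1))
    names(catalog)[hit]
  })
  names(present) <- labs
  uniq <- list(setdiff(present[[1]], present[[2]]),
               setdiff(present[[2]], present[[1]]))
  names(uniq) <- labs
  list(present = present, unique = uniq)
}

#' ARG / VF tallies per guild
#'
#' Reports, per guild, how many genomes carry antibiotic-resistance genes
#' or virulence factors and the totals carried.
#'
#' @param ann a [genome_annotation()].
#' @param g a guild assignment.
#' @return data.frame: guild, n_genomes, arg_genomes, arg_total,
#'   vf_genomes, vf_total, vf_genome_fraction.
#' @export
resistance_virulence_summary <- function(ann, g) {
  labs <- setdiff(sort(unique(g$guild)), "unassigned")
  rows <- lapply(labs, function(lb) {
    members <- intersect(guild_members(g, lb), ann$genome_ids)
    data.frame(guild = lb, n_genomes = length(members),
               arg_genomes = sum(ann$arg_count[members] > 0),
               arg_total = sum(ann$arg_count[members]),
               vf_genomes = sum(ann$vf_count[members] > 0),
               vf_total = sum(ann$vf_count[members]),
               vf_genome_fraction = mean(ann$vf_count[members] > 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' KO-space ordination of guild genomes
#'
#' Euclidean distance on the genome x KO copy-number matrix, PCoA, and a
#' single-factor PERMANOVA with guild as the factor.
#'
#' @param ann a [genome_annotation()] with `ko_copies`.
#' @param g a guild assignment.
#' @param n_permutations,seed PERMANOVA controls.
#' @return list: `ordination` ([pcoa()] result), `permanova`
#'   ([permanova_single()] row), `distance`.
#' @export
ko_ordination <- function(ann, g, n_permutations = 999L, seed = NULL) {
  if (is.null(ann$ko_copies)) stop("annotation lacks KO copy numbers")
  labs <- guild_pair(g)
  members <- unlist(lapply(labs, guild_members, g = g))
  members <- intersect(members, rownames(ann$ko_copies))
  if (length(members) < 3) stop("need >= 3 genomes with KO profiles")
  d <- euclidean_distance(ann$ko_copies[members, , drop = FALSE])
  guild_f <- factor(setNames(g$guild, g$genome_id)[members])
  list(ordination = pcoa(d),
       permanova = permanova_single(d, guild_f,
                                    n_permutations = n_permutations,
                                    seed = seed, term = "guild"),
       distance = d)
}
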