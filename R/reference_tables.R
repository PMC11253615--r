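# Published reference tallies shipped with the package.

#' Published two-guild signature membership tallies
#'
#' Per-taxon genome counts of the published 54-genome microbiome
#' signature: 34 genomes in the protective guild and 20 in the detrimental
#' guild (15 of the latter belong to distinct taxa not individually
#' resolvable from the published tally and are carried as one pooled row).
#'
#' @return data.frame: taxon, guild, n_genomes.
#' @export
published_guild_membership <- function() {
  path <- system.file("extdata", "guild_membership.tsv",
                      package = "guildscope", mustWork = TRUE)
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Published validation-cohort composition
#'
#' Sample counts of the external validation cohort (hemodialysis patients
#' with end-stage renal disease vs healthy controls) used for classifier
#' transfer: the precision-recall baseline is the positive fraction.
#'
#' @return list: `n_case`, `n_control`, `pr_baseline`.
#' @export
published_validation_cohort <- function() {
  n_case <- 223L; n_control <- 69L
  list(n_case = n_case, n_control = n_control,
       pr_baseline = n_case / (n_case + n_control))
}
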