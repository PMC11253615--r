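#' @useDynLib guildscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cov median pchisq pnorm pt quantile rbinom rgamma
#'   rmultinom rnorm runif sd var complete.cases cutree hclust as.dist
#'   setNames dhyper aggregate
#' @importFrom utils read.delim write.table combn head
NULL

# ---- abundance matrix ------------------------------------------------------

#' Construct a genome abundance matrix
#'
#' The central data container of the pipeline: a samples x genomes matrix of
#' nonnegative abundances. `mode = "counts"` holds (estimated) read counts;
#' `mode = "relative"` holds per-sample relative abundances whose rows sum to
#' at most 1 (background mass may be unobserved).
#'
#' @param values numeric matrix, samples as rows, genomes as columns, with
#'   unique dimnames.
#' @param mode `"counts"`, `"relative"`, or `"hellinger"` (square-root
#'   scores whose squared row entries sum to 1).
#' @return an `abundance_matrix` (a numeric matrix with a `mode` attribute).
#' @export
abundance_matrix <- function(values, mode = c("counts", "relative", "hellinger")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("G", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate genome ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop("abundance matrix contains missing values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', genome '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (mode == "relative") {
    rs <- rowSums(values)
    if (any(rs > 1 + 1e-9))
      stop("relative-mode rows must sum to <= 1; offending sample: ",
           rownames(values)[which.max(rs)])
  }
  structure(values, mode = mode, class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d samples x %d genomes, mode = %s\n",
              nrow(x), ncol(x), abundance_mode(x)))
  invisible(x)
}

#' Abundance mode of a matrix
#' @param m an `abundance_matrix`.
#' @return `"counts"` or `"relative"`.
#' @export
abundance_mode <- function(m) attr(m, "mode", exact = TRUE)

# strip class/attrs for plain matrix math
unclass_mat <- function(m) {
  attr(m, "mode") <- NULL
  unclass(m)
}

#' Read an abundance table from TSV
#'
#' Expects a header row and an id first column. By default samples are rows
#' and genomes are columns; set `samples_as_rows = FALSE` for the transposed
#' layout.
#'
#' @param path TSV file path.
#' @param mode `"counts"` or `"relative"`.
#' @param samples_as_rows orientation flag (default TRUE).
#' @return an [abundance_matrix()].
#' @export
read_abundance <- function(path, mode = c("counts", "relative"),
                           samples_as_rows = TRUE) {
  mode <- match.arg(mode)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!samples_as_rows) m <- t(m)
  abundance_matrix(m, mode = mode)
}

#' Write an abundance table to TSV
#' @param m an `abundance_matrix`.
#' @param path output path.
#' @param id_column name for the id column header.
#' @export
write_abundance <- function(m, path, id_column = "sample_id") {
  df <- data.frame(rownames(m), unclass_mat(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundance
#'
#' Divides each sample row by its total. All-zero rows are rejected because
#' they have no defined composition.
#'
#' @param m counts-mode `abundance_matrix`.
#' @return relative-mode `abundance_matrix` with rows summing to 1.
#' @export
to_relative <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (identical(abundance_mode(m), "relative")) return(m)
  if (identical(abundance_mode(m), "hellinger"))
    stop("cannot convert Hellinger scores back to relative abundance")
  rs <- rowSums(m)
  if (any(rs <= 0))
    stop("all-zero sample row(s): ",
         paste(rownames(m)[rs <= 0], collapse = ", "))
  abundance_matrix(unclass_mat(m) / rs, mode = "relative")
}

# ---- sample metadata -------------------------------------------------------

#' Validate sample metadata
#'
#' Metadata is a plain data.frame with columns `sample_id`, `group`
#' (factor-like), `age` (years), and any number of clinical variables
#' (numeric; NA allowed). Clinical missingness propagates as
#' pairwise-complete deletion in downstream correlations.
#'
#' @param meta a data.frame.
#' @return the validated data.frame, `group` coerced to factor.
#' @export
sample_metadata <- function(meta) {
  stopifnot(is.data.frame(meta))
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  meta$group <- factor(meta$group)
  if ("age" %in% names(meta) && any(!is.na(meta$age) & meta$age <= 0))
    stop("age must be positive where present")
  meta
}

#' Read sample metadata from TSV
#' @param path TSV with columns sample_id, group, age, clinical variables.
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  sample_metadata(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE))
}

#' Align an abundance matrix with metadata
#'
#' Restricts both to the intersection of sample ids, in the abundance
#' matrix's order, and reports how many samples were dropped from each side.
#'
#' @param m an `abundance_matrix`.
#' @param meta metadata data.frame.
#' @return list with elements `abundance`, `metadata`, `dropped` (counts).
#' @export
align_samples <- function(m, meta) {
  meta <- sample_metadata(meta)
  keep <- intersect(rownames(m), meta$sample_id)
  if (!length(keep)) stop("no overlapping sample ids between abundance and metadata")
  dropped <- c(abundance = nrow(m) - length(keep),
               metadata = nrow(meta) - length(keep))
  if (any(dropped > 0))
    message(sprintf("align_samples: dropped %d abundance / %d metadata samples",
                    dropped[1], dropped[2]))
  m2 <- abundance_matrix(unclass_mat(m)[keep, , drop = FALSE], mode = abundance_mode(m))
  meta2 <- meta[match(keep, meta$sample_id), , drop = FALSE]
  rownames(meta2) <- NULL
  list(abundance = m2, metadata = meta2, dropped = dropped)
}

# ---- genome annotation -----------------------------------------------------

#' Construct a genome annotation object
#'
#' Per-genome functional annotations: copy numbers of short-chain-fatty-acid
#' terminal genes and tryptophanase, counts of antibiotic-resistance genes
#' (ARG) and virulence factors (VF), and a genome x KO copy-number matrix.
#'
#' @param gene_copies genomes x gene-family integer matrix (rownames are
#'   genome ids).
#' @param arg_count named integer vector of ARG counts per genome.
#' @param vf_count named integer vector of VF counts per genome.
#' @param ko_copies optional genomes x KO integer matrix.
#' @return a `genome_annotation` list.
#' @export
genome_annotation <- function(gene_copies, arg_count = NULL, vf_count = NULL,
                              ko_copies = NULL) {
  stopifnot(is.matrix(gene_copies), !is.null(rownames(gene_copies)))
  if (any(gene_copies < 0)) stop("gene copy numbers must be nonnegative")
  if (anyDuplicated(rownames(gene_copies))) stop("duplicate genome ids")
  ids <- rownames(gene_copies)
  z <- setNames(rep(0L, length(ids)), ids)
  if (is.null(arg_count)) arg_count <- z
  if (is.null(vf_count)) vf_count <- z
  if (any(arg_count < 0) || any(vf_count < 0)) stop("ARG/VF counts must be nonnegative")
  if (!is.null(ko_copies)) {
    stopifnot(is.matrix(ko_copies))
    if (any(ko_copies < 0)) stop("KO copy numbers must be nonnegative")
  }
  structure(list(genome_ids = ids, gene_copies = gene_copies,
                 arg_count = arg_count[ids], vf_count = vf_count[ids],
                 ko_copies = ko_copies),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d genomes, %d gene families%s\n",
              length(x$genome_ids), ncol(x$gene_copies),
              if (is.null(x$ko_copies)) "" else
                sprintf(", %d KOs", ncol(x$ko_copies))))
  invisible(x)
}

# ---- run configuration -----------------------------------------------------

#' Pipeline run configuration
#'
#' Bundles every threshold and tuning parameter used across stages so a run
#' is a pure function of (inputs, config, seed).
#'
#' @param seed master random seed.
#' @param rda_min_variance signature-selection threshold on per-genome
#'   variance explained (inclusive; default 0.10).
#' @param edge_p network edge retention p-value cutoff (default 0.001).
#' @param n_permutations permutations for PERMANOVA and co-abundance
#'   p-values (default 999 and 1000 respectively; this field seeds both,
#'   see `sparcc_permutations`).
#' @param sparcc_permutations permutations for co-abundance p-values.
#' @param sparcc_inner_iterations Dirichlet resampling iterations.
#' @param sparcc_exclusion_threshold,sparcc_exclusion_rounds strong-pair
#'   exclusion loop controls.
#' @param sparcc_null_inner_iterations reduced iteration count used inside
#'   the permutation null (speed).
#' @param n_guilds,min_guild_size,tom_beta guild detection controls.
#' @param guild_method `"tom_tree"` (complete linkage on 1 - TOM) or
#'   `"corr_tree"` (1 - rho).
#' @param rf_n_trees,rf_mtry random forest controls (`rf_mtry = NULL` means
#'   floor(sqrt(p))).
#' @param simpson `"gini"` (1 - sum q^2, default) or `"inverse"`.
#' @param alpha significance level for compact letter displays.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       rda_min_variance = 0.10,
                       edge_p = 0.001,
                       n_permutations = 999L,
                       sparcc_permutations = 1000L,
                       sparcc_inner_iterations = 20L,
                       sparcc_exclusion_threshold = 0.1,
                       sparcc_exclusion_rounds = 10L,
                       sparcc_null_inner_iterations = 5L,
                       n_guilds = 2L,
                       min_guild_size = 3L,
                       tom_beta = 6L,
                       guild_method = c("tom_tree", "corr_tree"),
                       rf_n_trees = 500L,
                       rf_mtry = NULL,
                       simpson = c("gini", "inverse"),
                       alpha = 0.05) {
  stopifnot(rda_min_variance > 0, rda_min_variance < 1,
            edge_p > 0, edge_p < 1, n_permutations >= 1,
            sparcc_permutations >= 1, alpha > 0, alpha < 1)
  cfg <- list(seed = as.integer(seed),
              rda_min_variance = rda_min_variance,
              edge_p = edge_p,
              n_permutations = as.integer(n_permutations),
              sparcc_permutations = as.integer(sparcc_permutations),
              sparcc_inner_iterations = as.integer(sparcc_inner_iterations),
              sparcc_exclusion_threshold = sparcc_exclusion_threshold,
              sparcc_exclusion_rounds = as.integer(sparcc_exclusion_rounds),
              sparcc_null_inner_iterations = as.integer(sparcc_null_inner_iterations),
              n_guilds = as.integer(n_guilds),
              min_guild_size = as.integer(min_guild_size),
              tom_beta = as.integer(tom_beta),
              guild_method = match.arg(guild_method),
              rf_n_trees = as.integer(rf_n_trees),
              rf_mtry = if (is.null(rf_mtry)) NULL else as.integer(rf_mtry),
              simpson = match.arg(simpson),
              alpha = alpha)
  structure(cfg, class = "run_config")
}

#' Write a run manifest
#'
#' Records seed, thresholds and package version next to the outputs so a run
#' can be reproduced.
#'
#' @param config a [run_config()].
#' @param path output JSON path.
#' @export
write_manifest <- function(config, path) {
  manifest <- c(unclass(config),
                list(package = "guildscope",
                     version = as.character(utils::packageVersion("guildscope"))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}
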