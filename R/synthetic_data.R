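# Synthetic cohort generator: two anti-correlated guilds of co-abundant
# genomes embedded in a background community, with group-severity effects,
# coupled clinical covariates, and guild-biased gene carriage.

#' Specification for a synthetic guild-structured cohort
#'
#' Defaults emulate the cohort structure the pipeline targets: four groups
#' of 45/46/57/59 samples spanning young/old healthy controls (YHCG, HCG)
#' and early/late disease (EDG, LDG), a protective guild of 34 genomes and
#' a detrimental guild of 20 genomes embedded in a background community,
#' and clinical covariates (eGFR, UACR, ALB) linearly coupled to the two
#' latent guild factors.
#'
#' @param group_sizes named integer vector of group sizes in severity order.
#' @param n_guild1,n_guild2 planted guild sizes.
#' @param n_background number of background genomes (scalable; the study
#'   scale is ~1500, the default keeps simulations desk-sized).
#' @param severity_effect per-group shift applied to the latent guild
#'   factors: guild-1 factor decreases and guild-2 factor increases
#'   monotonically with severity when positive. 0 gives a null cohort.
#'   The default (2) plants a deliberately unambiguous disease effect so
#'   that recovery failures downstream indicate implementation defects
#'   rather than an underpowered world.
#' @param between_guild_corr correlation of the two latent factors, in
#'   (-1, 0].
#' @param noise_sd residual sd of genome log-abundance around its loading
#'   on the latent factor (controls within-guild correlation; at unit
#'   loading the implied pairwise correlation is 1/(1+noise_sd^2)).
#' @param background_sd sd of independent background log-abundance noise.
#' @param depth multinomial reads per sample for count mode.
#' @param clinical_coupling multiplier on the clinical-covariate couplings
#'   (0 disables them).
#' @param carrier_rates list of per-gene-family carrier probabilities,
#'   each a numeric vector c(guild1, guild2, background). Defaults carry
#'   the butyrate terminal gene `but` at 14/34 vs 2/20 and tryptophanase
#'   `tnaA` at 0 vs 2/20.
#' @param n_ko number of KO columns in the simulated annotation.
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 (default)
#'   draws plain multinomial counts.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(group_sizes = c(YHCG = 45L, HCG = 46L, EDG = 57L, LDG = 59L),
                            n_guild1 = 34L, n_guild2 = 20L,
                            n_background = 200L,
                            severity_effect = 2,
                            between_guild_corr = -0.6,
                            noise_sd = 0.65,
                            background_sd = 1,
                            depth = 1e6,
                            clinical_coupling = 1,
                            carrier_rates = NULL,
                            n_ko = 300L,
                            overdispersion = 0) {
  stopifnot(all(group_sizes > 0), length(group_sizes) >= 2,
            n_guild1 >= 2, n_guild2 >= 2, n_background >= 0,
            between_guild_corr > -1, between_guild_corr <= 0,
            noise_sd > 0, depth >= 1000, overdispersion >= 0)
  if (is.null(names(group_sizes)))
    names(group_sizes) <- paste0("grp", seq_along(group_sizes))
  default_rates <- list(
    but  = c(14 / 34, 2 / 20, 0.15),
    buk  = c(0, 0, 0.05),
    atoA = c(0, 0, 0.05),
    atoD = c(0, 0, 0.05),
    `4Hbt` = c(8 / 34, 2 / 20, 0.10),
    fdtl = c(0.5, 0.3, 0.25),
    pct  = c(23 / 34, 4 / 20, 0.20),
    pst  = c(0.3, 0.2, 0.15),
    tnaA = c(0, 2 / 20, 0.10))
  if (!is.null(carrier_rates)) {
    for (g in names(carrier_rates)) default_rates[[g]] <- carrier_rates[[g]]
  }
  bad <- vapply(default_rates, function(r) any(r < 0 | r > 1), logical(1))
  if (any(bad)) stop("carrier rates must lie in [0,1]: ",
                     paste(names(default_rates)[bad], collapse = ", "))
  structure(list(group_sizes = as.integer(group_sizes),
                 group_names = names(group_sizes),
                 n_guild1 = as.integer(n_guild1),
                 n_guild2 = as.integer(n_guild2),
                 n_background = as.integer(n_background),
                 severity_effect = severity_effect,
                 between_guild_corr = between_guild_corr,
                 noise_sd = noise_sd,
                 background_sd = background_sd,
                 depth = depth,
                 clinical_coupling = clinical_coupling,
                 carrier_rates = default_rates,
                 n_ko = as.integer(n_ko),
                 overdispersion = overdispersion),
            class = "simulation_spec")
}

# group-level latent means: guild-1 factor decreases, guild-2 increases
# linearly with severity rank
latent_group_means <- function(spec) {
  k <- length(spec$group_sizes)
  shift <- spec$severity_effect * seq(1, -1, length.out = k)
  list(g1 = shift, g2 = -shift)
}

#' Simulate a guild-structured cohort
#'
#' Generative model: two per-sample latent factors (g1, g2) are drawn
#' jointly Gaussian with correlation `between_guild_corr` and group-mean
#' shifts proportional to `severity_effect` (g1 decreasing, g2 increasing
#' with severity). Each guild genome's log-abundance is
#' `baseline + loading * factor + N(0, noise_sd)` with loadings drawn
#' Uniform(0.5, 1.5); background genomes get independent log-normal noise.
#' Rows are closed to composition and multinomial counts drawn at `depth`.
#' Clinical covariates are linear in (g1, g2) plus noise; gene carriage is
#' Bernoulli at per-guild rates.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @return list with `abundance` (counts-mode [abundance_matrix()]),
#'   `metadata` (data.frame), `annotation` ([genome_annotation()]), and
#'   `truth` (list: `guild` named vector over genomes, `factors` per-sample
#'   latent values, `signal_genomes`).
#' @export
simulate_community <- function(spec = simulation_spec(), seed = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(as.integer(seed))
  n <- sum(spec$group_sizes)
  k <- length(spec$group_sizes)
  group <- factor(rep(spec$group_names, spec$group_sizes),
                  levels = spec$group_names)
  sample_ids <- sprintf("S%03d", seq_len(n))

  # latent factors: bivariate normal, group-shifted means
  r <- spec$between_guild_corr
  sig <- matrix(c(1, r, r, 1), 2)
  if (min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("implied latent covariance is not positive definite")
  ch <- chol(sig)
  z <- matrix(rnorm(2 * n), n, 2) %*% ch
  mu <- latent_group_means(spec)
  g1 <- z[, 1] + mu$g1[as.integer(group)]
  g2 <- z[, 2] + mu$g2[as.integer(group)]

  p1 <- spec$n_guild1; p2 <- spec$n_guild2; pb <- spec$n_background
  genome_ids <- c(sprintf("guild1_%02d", seq_len(p1)),
                  sprintf("guild2_%02d", seq_len(p2)),
                  if (pb > 0) sprintf("bg_%03d", seq_len(pb)))
  truth_guild <- setNames(rep(c("guild1", "guild2", "background"),
                              c(p1, p2, pb)), genome_ids)

  base <- rnorm(p1 + p2 + pb, 0, 0.5)
  load1 <- runif(p1, 0.5, 1.5)
  load2 <- runif(p2, 0.5, 1.5)
  logab <- matrix(0, n, p1 + p2 + pb, dimnames = list(sample_ids, genome_ids))
  logab[, seq_len(p1)] <- outer(g1, load1) +
    matrix(rnorm(n * p1, 0, spec$noise_sd), n, p1)
  logab[, p1 + seq_len(p2)] <- outer(g2, load2) +
    matrix(rnorm(n * p2, 0, spec$noise_sd), n, p2)
  if (pb > 0)
    logab[, p1 + p2 + seq_len(pb)] <-
      matrix(rnorm(n * pb, 0, spec$background_sd), n, pb)
  logab <- sweep(logab, 2, base, `+`)
  rel <- exp(logab)
  rel <- rel / rowSums(rel)

  counts <- matrix(0, n, ncol(rel), dimnames = dimnames(rel))
  for (j in seq_len(n)) {
    pr <- rel[j, ]
    if (spec$overdispersion > 0) {
      gam <- rgamma(length(pr), shape = pr / spec$overdispersion)
      pr <- gam / sum(gam)
    }
    counts[j, ] <- rmultinom(1, size = spec$depth, prob = pr)
  }

  cc <- spec$clinical_coupling
  egfr <- pmax(5, 90 + cc * (15 * g1 - 10 * g2) + rnorm(n, 0, 15))
  uacr <- pmax(0, 300 + cc * (-80 * g1 + 120 * g2) + rnorm(n, 0, 150))
  alb <- 42 + cc * (2 * g1 - 2 * g2) + rnorm(n, 0, 3)
  age_mu <- c(35, rep(55, k - 1))[seq_len(k)]
  age <- round(pmax(20, rnorm(n, age_mu[as.integer(group)], 6)))
  metadata <- sample_metadata(data.frame(
    sample_id = sample_ids, group = group, age = age,
    eGFR = egfr, UACR = uacr, ALB = alb,
    stringsAsFactors = FALSE))

  annotation <- simulate_annotation(spec, truth_guild)

  list(abundance = abundance_matrix(counts, mode = "counts"),
       metadata = metadata,
       annotation = annotation,
       truth = list(guild = truth_guild,
                    factors = data.frame(sample_id = sample_ids,
                                         g1 = g1, g2 = g2),
                    signal_genomes = genome_ids[seq_len(p1 + p2)]))
}

# carrier draws + copy numbers + KO profiles, guild-biased
simulate_annotation <- function(spec, truth_guild) {
  ids <- names(truth_guild)
  gidx <- match(truth_guild, c("guild1", "guild2", "background"))
  genes <- names(spec$carrier_rates)
  gene_copies <- matrix(0L, length(ids), length(genes),
                        dimnames = list(ids, genes))
  for (g in genes) {
    rate <- spec$carrier_rates[[g]][gidx]
    carrier <- rbinom(length(ids), 1, rate)
    copies <- carrier * (1L + stats::rpois(length(ids), 0.5))
    # guild-1 but carriers hold elevated copy numbers
    if (g == "but") copies <- copies + carrier * as.integer(gidx == 1)
    gene_copies[, g] <- as.integer(copies)
  }
  arg_rate <- c(1 / 34, 4 / 20, 0.08)[gidx]
  arg_carrier <- rbinom(length(ids), 1, arg_rate)
  arg_count <- as.integer(arg_carrier * (1L + stats::rpois(length(ids),
                                                           c(0, 1, 0.3)[gidx])))
  vf_rate <- c(0.735, 0.95, 0.5)[gidx]
  vf_carrier <- rbinom(length(ids), 1, vf_rate)
  vf_count <- as.integer(vf_carrier * (1L + stats::rpois(length(ids),
                                                         c(1.5, 15, 2)[gidx])))
  # KO profile: one block enriched per guild plus a shared block
  n_ko <- spec$n_ko
  b <- n_ko %/% 3
  ko_rate <- matrix(0.3, 3, n_ko)       # background row
  ko_rate[1, ] <- c(rep(0.8, b), rep(0.1, b), rep(0.5, n_ko - 2 * b))
  ko_rate[2, ] <- c(rep(0.1, b), rep(0.8, b), rep(0.5, n_ko - 2 * b))
  ko <- matrix(rbinom(length(ids) * n_ko, 1, ko_rate[gidx, ]),
               length(ids), n_ko,
               dimnames = list(ids, sprintf("K%05d", seq_len(n_ko))))
  ko <- ko * (1L + matrix(stats::rpois(length(ko), 0.3), nrow(ko)))
  genome_annotation(gene_copies,
                    arg_count = setNames(arg_count, ids),
                    vf_count = setNames(vf_count, ids),
                    ko_copies = ko)
}

#' Simulate a null cohort
#'
#' Same machinery as [simulate_community()] with `severity_effect = 0` and
#' `clinical_coupling = 0`: group labels and clinical variables carry no
#' signal about the microbiome.
#'
#' @param spec a [simulation_spec()]; severity/coupling are overridden.
#' @param seed integer seed.
#' @return list with `abundance` and `metadata`.
#' @export
simulate_null <- function(spec = simulation_spec(), seed = 1L) {
  spec$severity_effect <- 0
  spec$clinical_coupling <- 0
  sim <- simulate_community(spec, seed = seed)
  list(abundance = sim$abundance, metadata = sim$metadata)
}
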