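mk_annotation <- function(n1 = 6, n2 = 5, seed = 157) {
  set.seed(seed)
  ids <- c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2)))
  gc <- matrix(0L, length(ids), 3,
               dimnames = list(ids, c("but", "tnaA", "pct")))
  gc[1:4, "but"] <- 2L          # guild1-biased carriage
  gc[n1 + 1, "but"] <- 1L
  gc[n1 + (1:2), "tnaA"] <- 1L  # guild2-only
  ko <- matrix(0L, length(ids), 6,
               dimnames = list(ids, paste0("K", 1:6)))
  ko[1:n1, 1:3] <- 1L           # guild1 block
  ko[n1 + (1:n2), 4:6] <- 1L    # guild2 block
  g <- data.frame(genome_id = ids,
                  guild = rep(c("guild1", "guild2"), c(n1, n2)),
                  stringsAsFactors = FALSE)
  class(g) <- c("guild_assignment", "data.frame")
  list(ann = genome_annotation(gc, ko_copies = ko), g = g)
}

test_that("carrier_contrast builds the right table and delegates to Fisher", {
  fx <- mk_annotation()
  res <- carrier_contrast(fx$ann, fx$g, "but")
  expect_equal(res$table$carriers, c(4, 1))
  expect_equal(res$table$total, c(6, 5))
  ref <- fisher_exact_2x2(matrix(c(4, 2, 1, 4), 2, byrow = TRUE))
  expect_equal(res$p, ref$p, tolerance = 1e-12)

  # margins equal guild sizes
  expect_equal(res$table$total,
               unname(table(fx$g$guild)[c("guild1", "guild2")]),
               ignore_attr = TRUE)

  res0 <- suppressWarnings(carrier_contrast(fx$ann, fx$g, "pct"))
  expect_equal(res0$p, 1)    # no carriers anywhere

  expect_error(carrier_contrast(fx$ann, fx$g, "nope"), "but.*tnaA.*pct")
})

test_that("copy_number_contrast runs exact Mann-Whitney per guild", {
  fx <- mk_annotation()
  same <- copy_number_contrast(fx$ann, fx$g, "pct")
  expect_equal(same$p, 1)    # all zeros on both sides

  # 5 vs 5 full separation reproduces the enumeration p
  ids <- c(paste0("a", 1:5), paste0("b", 1:5))
  gc <- matrix(c(rep(2L, 5), rep(0L, 5)), ncol = 1,
               dimnames = list(ids, "but"))
  g <- data.frame(genome_id = ids, guild = rep(c("guild1", "guild2"), each = 5),
                  stringsAsFactors = FALSE)
  class(g) <- c("guild_assignment", "data.frame")
  res <- copy_number_contrast(genome_annotation(gc), g, "but")
  expect_equal(res$p, 2 / choose(10, 5), tolerance = 1e-12)
})

test_that("unique_modules honors per-genome completeness and matches a scan oracle", {
  fx <- mk_annotation()
  catalog <- list(M1 = c("K1", "K2"), M2 = c("K4"), M3 = c("K1", "K4"),
                  M4 = c("K2", "K3"))
  um <- unique_modules(fx$ann, fx$g, catalog)
  expect_true("M2" %in% um$unique$guild2)
  expect_true(all(c("M1", "M4") %in% um$unique$guild1))
  # M3 spans both blocks: no single genome carries both KOs
  expect_false("M3" %in% c(um$present$guild1, um$present$guild2))
  # antisymmetry
  expect_length(intersect(um$unique$guild1, um$unique$guild2), 0)

  # random catalogs vs brute-force per-module scan
  set.seed(163)
  for (r in 1:5) {
    cat_r <- lapply(1:6, function(i) sample(paste0("K", 1:6), sample(1:3, 1)))
    names(cat_r) <- paste0("R", 1:6)
    um_r <- unique_modules(fx$ann, fx$g, cat_r)
    for (lb in c("guild1", "guild2")) {
      members <- fx$g$genome_id[fx$g$guild == lb]
      oracle <- names(cat_r)[vapply(cat_r, function(kos) {
        any(vapply(members, function(gm)
          all(fx$ann$ko_copies[gm, kos] >= 1), logical(1)))
      }, logical(1))]
      expect_setequal(um_r$present[[lb]], oracle)
    }
  }
  expect_error(unique_modules(fx$ann, fx$g, list()), "empty")
})

test_that("ko_ordination separates disjoint KO guilds", {
  fx <- mk_annotation()
  res <- ko_ordination(fx$ann, fx$g, n_permutations = 199, seed = 2)
  expect_gt(res$permanova$R2, 0.8)
  expect_lte(res$permanova$p, 0.05)

  # duplicated genome has zero KO distance to its twin
  ann2 <- fx$ann
  ko2 <- rbind(ann2$ko_copies, a_dup = ann2$ko_copies["a1", ])
  gc2 <- rbind(ann2$gene_copies, a_dup = ann2$gene_copies["a1", ])
  ann_d <- genome_annotation(gc2, ko_copies = ko2)
  g_d <- rbind(as.data.frame(fx$g),
               data.frame(genome_id = "a_dup", guild = "guild1"))
  class(g_d) <- c("guild_assignment", "data.frame")
  res_d <- ko_ordination(ann_d, g_d, n_permutations = 19, seed = 1)
  expect_equal(res_d$distance["a1", "a_dup"], 0)
})

test_that("ARG/VF summary tallies per guild", {
  fx <- mk_annotation()
  ann <- fx$ann
  ann$arg_count[] <- 0L; ann$arg_count["b1"] <- 3L
  ann$vf_count[] <- c(rep(1L, 6), rep(2L, 5))
  s <- resistance_virulence_summary(ann, fx$g)
  expect_equal(s$arg_total[s$guild == "guild2"], 3)
  expect_equal(s$vf_genome_fraction, c(1, 1))
  expect_equal(s$n_genomes, c(6, 5))
})
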