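test_that("sparcc recovers planted structure and the null stays flat", {
  # null: independent basis variables
  m0 <- basis_counts(300, 20, seed = 61)
  fit0 <- sparcc(m0, inner_iterations = 10, seed = 1)
  off0 <- fit0$rho[upper.tri(fit0$rho)]
  expect_lt(mean(abs(off0)), 0.1)
  expect_true(all(diag(fit0$rho) == 1))
  expect_true(all(abs(fit0$rho) <= 1))
  expect_equal(max(abs(fit0$rho - t(fit0$rho))), 0, tolerance = 1e-12)

  # planted basis correlation
  m1 <- basis_counts(400, 20, pairs_rho = cbind(1, 2, 0.8), seed = 62)
  fit1 <- sparcc(m1, inner_iterations = 10, seed = 1)
  expect_equal(fit1$rho[1, 2], 0.8, tolerance = 0.2)

  # duplicated genome approaches perfect correlation
  x <- unclass(m0)
  x <- cbind(x, dup = x[, 1])
  fit2 <- sparcc(abundance_matrix(x, mode = "counts"),
                 inner_iterations = 5, seed = 1)
  expect_gte(fit2$rho[1, ncol(x)], 0.99)

  expect_error(sparcc(tiny_counts(matrix(1:6, 2, 3))), ">= 4 genomes")
})

test_that("sparcc is invariant to per-sample depth rescaling", {
  m <- basis_counts(300, 15, pairs_rho = cbind(1, 2, 0.7), seed = 67)
  fit_a <- sparcc(m, inner_iterations = 10, seed = 4)
  scaled <- abundance_matrix(unclass(m) * 3L, mode = "counts")
  fit_b <- sparcc(scaled, inner_iterations = 10, seed = 4)
  expect_lt(max(abs(fit_a$rho - fit_b$rho)), 0.05)
})

test_that("permutation p-values are calibrated, floored, and deterministic", {
  m <- basis_counts(100, 12, pairs_rho = cbind(1, 2, 0.9), seed = 71)
  fit <- sparcc(m, inner_iterations = 5, seed = 1)
  p <- sparcc_pvalues(m, fit, n_permutations = 99, seed = 2,
                      inner_iterations = 3)
  expect_equal(p[1, 2], 1 / 100, tolerance = 1e-12)   # planted pair at floor
  expect_equal(max(abs(p - t(p))), 0, tolerance = 1e-12)

  p2 <- sparcc_pvalues(m, fit, n_permutations = 99, seed = 2,
                       inner_iterations = 3)
  expect_identical(p, p2)

  expect_error(sparcc_pvalues(m, fit, n_permutations = 0), ">= 1")

  # null p-values approximately uniform
  mn <- basis_counts(100, 12, seed = 73)
  fitn <- sparcc(mn, inner_iterations = 5, seed = 1)
  pn <- sparcc_pvalues(mn, fitn, n_permutations = 99, seed = 3,
                       inner_iterations = 3)
  pv <- pn[upper.tri(pn)]
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.2)
})

test_that("network thresholding and guild edge summary behave", {
  rho <- matrix(c(1, 0.9, -0.8, 0.9, 1, 0.1, -0.8, 0.1, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p_all1 <- matrix(1, 3, 3, dimnames = dimnames(rho))
  expect_equal(nrow(build_network(rho, p_all1)), 0)

  p <- p_all1
  p["a", "b"] <- p["b", "a"] <- 0.0005
  p["a", "c"] <- p["c", "a"] <- 0.001
  net <- build_network(rho, p)
  expect_equal(nrow(net), 2)
  expect_setequal(net$sign, c("positive", "negative"))

  g <- data.frame(genome_id = c("a", "b", "c"),
                  guild = c("guild1", "guild1", "guild2"))
  class(g) <- c("guild_assignment", "data.frame")
  net2 <- build_network(rho, p, guilds = g)
  es <- attr(net2, "guild_edge_summary")
  expect_equal(es$n[es$scope == "within" & es$sign == "positive"], 1)
  expect_equal(es$n[es$scope == "between" & es$sign == "negative"], 1)
})

test_that("connected components match a BFS oracle", {
  nodes <- paste0("n", 1:5)
  empty <- data.frame(genome_a = character(), genome_b = character(),
                      sign = character(), stringsAsFactors = FALSE)
  expect_equal(length(unique(connected_components(empty, nodes))), 5)

  path <- data.frame(genome_a = c("n1", "n2"), genome_b = c("n2", "n3"),
                     sign = c("positive", "negative"),
                     stringsAsFactors = FALSE)
  comp <- connected_components(path, nodes)
  expect_equal(length(unique(comp[c("n1", "n2", "n3")])), 1)
  expect_equal(length(unique(comp)), 3)
  comp_pos <- connected_components(path, nodes, mode = "positive_only")
  expect_equal(length(unique(comp_pos)), 4)

  # random graphs vs BFS
  set.seed(79)
  for (rep in 1:5) {
    nn <- paste0("v", 1:12)
    ne <- 8
    ed <- data.frame(genome_a = sample(nn, ne, TRUE),
                     genome_b = sample(nn, ne, TRUE),
                     sign = "positive", stringsAsFactors = FALSE)
    ed <- ed[ed$genome_a != ed$genome_b, ]
    comp <- connected_components(ed, nn)
    # BFS oracle
    adj <- setNames(vector("list", length(nn)), nn)
    for (k in seq_len(nrow(ed))) {
      adj[[ed$genome_a[k]]] <- c(adj[[ed$genome_a[k]]], ed$genome_b[k])
      adj[[ed$genome_b[k]]] <- c(adj[[ed$genome_b[k]]], ed$genome_a[k])
    }
    seen <- setNames(rep(0L, length(nn)), nn)
    cid <- 0L
    for (s in nn) {
      if (seen[s]) next
      cid <- cid + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (seen[v]) next
        seen[v] <- cid
        queue <- c(queue, adj[[v]])
      }
    }
    same_ours <- outer(comp, comp, `==`)
    same_bfs <- outer(seen, seen, `==`)
    expect_identical(same_ours, same_bfs)
  }
})
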