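test_that("single-factor PERMANOVA matches vegan and its invariants", {
  skip_if_not_installed("vegan")
  set.seed(19)
  m <- tiny_relative(matrix(rpois(120, 30) + 1, 12, 10))
  grp <- factor(rep(c("a", "b", "c"), each = 4))
  d <- bray_curtis(m)
  res <- permanova_single(d, grp, n_permutations = 99, seed = 1)

  fit <- vegan::adonis2(as.dist(unclass(d)) ~ grp, permutations = 99)
  expect_equal(res$F, fit$F[1], tolerance = 1e-10)
  expect_equal(res$R2, fit$R2[1], tolerance = 1e-10)

  # R2(term) + R2(residual) = 1
  expect_equal(res$SS / res$R2, res$SS + (res$SS / res$R2 - res$SS),
               tolerance = 1e-10)
  expect_gte(res$p, 1 / 100)
})

test_that("perfect separation gives R2 = 1 at the p floor", {
  pts <- rbind(matrix(0, 4, 2), matrix(5, 4, 2)) +
    matrix(rep(c(0, 0.001, 0.002, 0.003), 2), 8, 2)  # duplicated-ish points
  pts <- rbind(matrix(c(0, 0), 4, 2, byrow = TRUE),
               matrix(c(5, 5), 4, 2, byrow = TRUE))
  rownames(pts) <- paste0("s", 1:8)
  d <- euclidean_distance(pts)
  grp <- factor(rep(c("x", "y"), each = 4))
  res <- permanova_single(d, grp, n_permutations = 199, seed = 2)
  expect_equal(res$R2, 1, tolerance = 1e-10)
  # attainable floor: only relabelings preserving the two point clouds
  # tie the observed F, i.e. 2 * (4!)^2 / 8! of permutations
  expect_lte(res$p, 0.06)
})

test_that("pseudo-F on Euclidean distances equals the classical trace F", {
  set.seed(23)
  x <- matrix(rnorm(15 * 4), 15, 4)
  rownames(x) <- paste0("s", 1:15)
  grp <- factor(rep(c("a", "b", "c"), each = 5))
  d <- euclidean_distance(x)
  res <- permanova_single(d, grp, n_permutations = 9, seed = 1)

  # oracle: direct sums of squares from coordinates
  xc <- scale(x, scale = FALSE)
  H <- with(list(X = model.matrix(~grp)),
            X %*% solve(crossprod(X)) %*% t(X))
  fitted <- H %*% xc
  ss_m <- sum(fitted^2)
  ss_t <- sum(xc^2)
  F_or <- (ss_m / 2) / ((ss_t - ss_m) / 12)
  expect_equal(res$F, F_or, tolerance = 1e-8)
})

test_that("permutation p agrees with exhaustive enumeration at n = 6", {
  set.seed(29)
  x <- matrix(rnorm(12), 6, 2)
  rownames(x) <- paste0("s", 1:6)
  grp <- factor(rep(c("a", "b"), each = 3))
  d <- euclidean_distance(x)

  perms <- gtools_permutations_6()
  res <- permanova_single(d, grp, permutations = perms)
  # exact enumeration oracle: F recomputed from scratch per relabeling
  G <- local({
    a <- -0.5 * unclass(d)^2
    sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  })
  X <- model.matrix(~grp)
  Hx <- X %*% solve(crossprod(X)) %*% t(X)
  f_of <- function(p) {
    Gp <- G[p, p]
    ssm <- sum(Hx * Gp)
    sst <- sum(diag(Gp))
    (ssm / 1) / ((sst - ssm) / 4)
  }
  Fobs <- f_of(1:6)
  Fall <- apply(perms, 1, f_of)
  p_exact <- (1 + sum(Fall >= Fobs)) / (1 + nrow(perms))
  expect_equal(res$p, p_exact, tolerance = 2 / nrow(perms))
  expect_equal(res$F, Fobs, tolerance = 1e-10)
})

test_that("marginal PERMANOVA reduces, zeroes duplicates, and separates terms", {
  set.seed(31)
  m <- tiny_relative(matrix(rpois(160, 25) + 1, 16, 10))
  grp <- factor(rep(c("a", "b", "c", "d"), each = 4))
  d <- bray_curtis(m)

  # one term only equals the single-factor result
  marg1 <- permanova_marginal(d, data.frame(group = grp), terms = "group",
                              n_permutations = 49, seed = 5)
  single <- permanova_single(d, grp, n_permutations = 49, seed = 5)
  expect_equal(marg1$F, single$F, tolerance = 1e-10)
  expect_equal(marg1$p, single$p)

  # a duplicated term has zero marginal SS
  dup <- data.frame(g1 = grp, g2 = grp)
  marg2 <- permanova_marginal(d, dup, n_permutations = 19, seed = 1)
  expect_true(all(abs(marg2$SS) < 1e-10))

  # planted group effect vs pure-noise age
  sim <- simulate_community(small_spec(severity_effect = 2), seed = 41)
  rel <- to_relative(sim$abundance)
  dd <- bray_curtis(rel)
  noise_age <- rnorm(nrow(rel))
  marg3 <- permanova_marginal(dd, data.frame(age = noise_age,
                                             group = sim$metadata$group),
                              n_permutations = 99, seed = 2)
  expect_lt(marg3$p[marg3$term == "group"], 0.05)
  expect_gt(marg3$p[marg3$term == "age"], 0.05)
})

test_that("pairwise PERMANOVA enumerates pairs with BH adjustment", {
  set.seed(37)
  m <- tiny_relative(matrix(rpois(128, 25) + 1, 16, 8))
  d <- bray_curtis(m)
  grp2 <- factor(rep(c("a", "b"), each = 8))
  pw2 <- pairwise_permanova(d, grp2, n_permutations = 49, seed = 3)
  expect_equal(nrow(pw2), 1)
  expect_equal(pw2$p_adjusted, pw2$p)

  grp4 <- factor(rep(c("a", "b", "c", "d"), each = 4))
  pw4 <- pairwise_permanova(d, grp4, n_permutations = 49, seed = 3)
  expect_equal(nrow(pw4), 6)
  o <- order(pw4$p)
  expect_true(all(diff(pw4$p_adjusted[o]) >= -1e-12))
})
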