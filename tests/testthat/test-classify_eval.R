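test_that("roc_auc equals the Mann-Whitney U statistic and its properties", {
  y <- c(0, 0, 1, 1, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9, 0.95), y)$auroc, 1)
  expect_equal(roc_auc(rep(0.4, 5), y)$auroc, 0.5)

  set.seed(131)
  for (i in 1:10) {
    s <- sample(seq(0, 1, by = 0.1), 30, TRUE)   # heavy ties
    lab <- rbinom(30, 1, 0.5)
    if (length(unique(lab)) < 2) next
    auc <- roc_auc(s, lab)$auroc
    # U-statistic oracle with half-weight ties
    pos <- s[lab == 1]; neg <- s[lab == 0]
    u <- sum(outer(pos, neg, `>`)) + 0.5 * sum(outer(pos, neg, `==`))
    expect_equal(auc, u / (length(pos) * length(neg)), tolerance = 1e-12)
    # complement and monotone-transform invariance
    expect_equal(roc_auc(1 - s, lab)$auroc, 1 - auc, tolerance = 1e-12)
    expect_equal(roc_auc(qlogis(pmin(pmax(s, 1e-3), 1 - 1e-3)), lab)$auroc,
                 auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "2 classes")
})

test_that("pr_auc uses step-wise average precision with the exact baseline", {
  y <- c(0, 0, 1, 1)
  pr <- pr_auc(c(0.1, 0.2, 0.7, 0.9), y)
  expect_equal(pr$auprc, 1)
  expect_equal(pr$pr_baseline, 0.5)

  # hand-computed small case: scores rank one negative above a positive
  s <- c(0.9, 0.8, 0.7, 0.6)
  y2 <- c(1, 0, 1, 0)
  pr2 <- pr_auc(s, y2)
  # thresholds: .9 -> P=1,R=.5 ; .8 -> P=.5,R=.5 ; .7 -> P=2/3,R=1 ; .6 -> .5,1
  expect_equal(pr2$auprc, 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)

  # random scores concentrate near the baseline
  set.seed(137)
  devs <- replicate(20, {
    yy <- rep(c(1, 0), c(30, 10))
    pr_auc(runif(40), yy)$auprc
  })
  expect_lt(abs(mean(devs) - 0.75), 0.05)
  expect_error(pr_auc(runif(4), rep(0, 4)), "2 classes")
})

test_that("LOOCV forest separates a planted effect and stays null on noise", {
  sim <- simulate_community(small_spec(severity_effect = 2), seed = 139)
  rel <- to_relative(sim$abundance)
  sig <- sim$truth$signal_genomes
  msig <- abundance_matrix(unclass(rel)[, sig], mode = "relative")
  case <- factor(ifelse(sim$metadata$group %in% c("YHCG", "HCG"),
                        "control", "case"), levels = c("control", "case"))
  sc <- rf_loocv_scores(msig, case, n_trees = 150, seed = 7)
  expect_true(all(sc >= 0 & sc <= 1))
  auc <- roc_auc(sc, case)$auroc
  expect_gt(auc, 0.8)

  # determinism
  sc2 <- rf_loocv_scores(msig, case, n_trees = 150, seed = 7)
  expect_identical(sc, sc2)

  # shuffled labels: no signal
  set.seed(11)
  aucs_null <- vapply(1:3, function(s) {
    set.seed(500 + s)
    shuf <- sample(case)
    roc_auc(rf_loocv_scores(msig, shuf, n_trees = 100, seed = s), shuf)$auroc
  }, numeric(1))
  expect_lt(max(abs(aucs_null - 0.5)), 0.15)

  expect_error(rf_loocv_scores(
    abundance_matrix(unclass(rel)[1:9, sig], mode = "relative"),
    case[1:9], n_trees = 10), ">= 10")
  expect_error(rf_loocv_scores(msig, rep("case", nrow(msig))), "2 classes")
})

test_that("transfer_classifier generalizes, zero-fills, and is optimistic on train", {
  sim <- simulate_community(small_spec(severity_effect = 2), seed = 149)
  rel <- to_relative(sim$abundance)
  sig <- sim$truth$signal_genomes
  msig <- abundance_matrix(unclass(rel)[, sig], mode = "relative")
  case <- factor(ifelse(sim$metadata$group %in% c("YHCG", "HCG"),
                        "control", "case"), levels = c("control", "case"))

  # resubstitution beats LOOCV
  loocv_auc <- roc_auc(rf_loocv_scores(msig, case, n_trees = 100, seed = 3),
                       case)$auroc
  resub <- transfer_classifier(msig, case, msig, case, n_trees = 100, seed = 3)
  expect_gte(resub$auroc + 1e-9, loocv_auc)

  # external cohort from the same spec, new seed
  ext <- simulate_community(small_spec(severity_effect = 2), seed = 151)
  rel_e <- to_relative(ext$abundance)
  m_e <- abundance_matrix(unclass(rel_e)[, sig], mode = "relative")
  case_e <- factor(ifelse(ext$metadata$group %in% c("YHCG", "HCG"),
                          "control", "case"), levels = c("control", "case"))
  ev <- transfer_classifier(msig, case, m_e, case_e, n_trees = 150, seed = 3)
  expect_gt(ev$auroc, 0.8)
  expect_equal(ev$pr_baseline, mean(case_e == "case"))

  # missing signature genomes are zero-filled with a warning
  m_part <- abundance_matrix(unclass(rel_e)[, sig[1:8]], mode = "relative")
  expect_warning(ev2 <- transfer_classifier(msig, case, m_part, case_e,
                                            n_trees = 50, seed = 3),
                 "zero-filling")
  expect_s3_class(ev2, "eval_curves")
})
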