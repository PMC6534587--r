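test_that("ROC sweeps produce the expected curves on degenerate inputs", {
  # identical groups: the staircase hugs the diagonal, AUC 0.5
  x <- c(1, 2, 3, 4)
  roc <- roc_points(x, x)
  expect_equal(roc$fpr, roc$tpr)
  expect_equal(auc_trapezoid(roc), 0.5)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[nrow(roc)], 1)

  # full separation passes through (0, 1)
  sep <- roc_points(c(3, 4), c(1, 2))
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))
  expect_equal(auc_trapezoid(sep), 1)
  expect_equal(auc_trapezoid(sep), mann_whitney_auc(c(3, 4), c(1, 2)))

  expect_error(roc_points(numeric(0), 1:3), "non-empty")
})

test_that("trapezoidal AUC equals the tie-corrected Mann-Whitney statistic", {
  set.seed(20)
  for (i in 1:1000) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    pos <- sample(0:20, n1, replace = TRUE)  # heavy ties on purpose
    neg <- sample(0:20, n2, replace = TRUE)
    roc <- roc_points(pos, neg)
    u_auc <- mann_whitney_auc(pos, neg)
    # fixed direction convention: the sweep reports max(AUC, 1 - AUC)
    expect_equal(auc_trapezoid(roc), max(u_auc, 1 - u_auc))
  }
})

test_that("label swap symmetry holds under the value-direction convention", {
  set.seed(21)
  pos <- rnorm(40, 55, 8); neg <- rnorm(35, 32, 4)
  expect_equal(mann_whitney_auc(pos, neg) + mann_whitney_auc(neg, pos), 1)
  # the automatic direction makes both orderings report the same area
  expect_equal(auc_trapezoid(roc_points(pos, neg)),
               auc_trapezoid(roc_points(neg, pos)))
})

test_that("ROC sweep agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(22)
  pos <- round(rnorm(60, 50, 7)); neg <- round(rnorm(50, 35, 5))
  ours <- auc_trapezoid(roc_points(pos, neg))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 60), rep(0, 50)), predictor = c(pos, neg),
    quiet = TRUE
  )))
  expect_equal(ours, ref)
})

test_that("Youden cutoff lands between separated groups and flags degeneracy", {
  roc <- roc_points(c(20, 21), c(10, 11))
  yc <- youden_cutoff(roc)
  expect_gt(yc$cutoff, 11); expect_lte(yc$cutoff, 20)
  expect_equal(yc$youden, 1)
  expect_equal(yc$sensitivity, 100); expect_equal(yc$specificity, 100)
  expect_false(yc$degenerate)

  same <- youden_cutoff(roc_points(c(5, 6, 7), c(5, 6, 7)))
  expect_true(same$degenerate)
  expect_equal(same$youden, 0)
})

test_that("Youden cutoff approximates the Gaussian density-intersection oracle", {
  # calibrated Control vs LGD classes (stage total SDs)
  mu1 <- 32.5; s1 <- sqrt(3.2^2 + 2.43^2)
  mu2 <- 54.6; s2 <- sqrt(7.5^2 + 3.79^2)
  # oracle: grid search of the Youden index on the closed-form Gaussian ROC
  grid <- seq(mu1, mu2, by = 0.01)
  j <- (1 - pnorm(grid, mu2, s2)) - (1 - pnorm(grid, mu1, s1))
  oracle <- grid[which.max(j)]
  set.seed(23)
  pos <- round(rnorm(20000, mu2, s2)); neg <- round(rnorm(20000, mu1, s1))
  yc <- youden_cutoff(roc_points(pos, neg))
  expect_lt(abs(yc$cutoff - oracle), 2)
  expect_lt(abs(oracle - 40), 2)  # the oracle itself sits near G = 40
})

test_that("gaussian_auc_oracle evaluates the closed form", {
  expect_equal(gaussian_auc_oracle(50, 5, 50, 7), 0.5)
  # Control/LGD totals from the published group and variation tables
  expect_equal(gaussian_auc_oracle(32.5, 4.02, 54.6, 8.40),
               pnorm(22.1 / sqrt(4.02^2 + 8.40^2)))
  expect_equal(round(gaussian_auc_oracle(32.5, 4.02, 54.6, 8.40), 3), 0.991)
  expect_equal(gaussian_auc_oracle(10, 0, 60, 0), 1)  # separated point masses
  expect_error(gaussian_auc_oracle(10, 0, 10, 0), "undefined")
  expect_error(gaussian_auc_oracle(10, -1, 20, 1), ">= 0")
})

test_that("stage_comparison reproduces an exhaustive small-case enumeration", {
  groups <- list(Control = c(30, 31, 33), LGD = c(50, 52, 58))
  res <- stage_comparison(groups, list(
    list(label = "LGD vs Control", positive = "LGD", negative = "Control")
  ))
  expect_equal(res$auc, 1)
  expect_equal(res$sensitivity, 100)
  expect_equal(res$specificity, 100)
  expect_gt(res$cutoff, 33); expect_lte(res$cutoff, 50)
  expect_equal(res$n_pos, 3); expect_equal(res$n_neg, 3)

  # group vs itself: AUC 0.5, degenerate cutoff
  self <- stage_comparison(list(A = c(1, 2, 3), B = c(1, 2, 3)),
                           list(list(label = "A vs B", positive = "A", negative = "B")))
  expect_equal(self$auc, 0.5)
  expect_true(self$degenerate)

  # pooled positives take the union of the listed stages
  groups3 <- list(Control = c(30, 31), LGD = c(50, 51), Cancer = c(49, 52))
  pooled <- stage_comparison(groups3, list(
    list(label = "LGD, Ca vs Control", positive = c("LGD", "Cancer"),
         negative = "Control")
  ))
  expect_equal(pooled$n_pos, 4)
  expect_equal(pooled$auc,
               mann_whitney_auc(c(50, 51, 49, 52), c(30, 31)))

  expect_error(stage_comparison(groups, list(
    list(label = "bad", positive = "HGD_CIS", negative = "Control")
  )), "unknown stage")
})

test_that("published animal table arithmetic matches the quoted aggregates", {
  tab <- roc_reference("rat")
  expect_equal(nrow(tab), 11)
  expect_equal(nrow(roc_reference("human")), 6)
  s <- roc_reference_summary()
  vals <- setNames(s$value, s$quantity)
  expect_equal(unname(vals["mean_sensitivity_control_vs_lesion"]), 94)
  expect_equal(unname(vals["mean_specificity_control_vs_lesion"]), 97.5)
  expect_equal(unname(vals["mean_cutoff_control_vs_lesion"]), 38.6)
  expect_equal(round(unname(vals["mean_cutoff_lgd_vs_higher"]), 1), 50.8)
})
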