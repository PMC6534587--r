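test_that("sample_sd implements the N-1 formula", {
  expect_equal(sample_sd(c(7, 7, 7)), 0)
  expect_equal(sample_sd(c(2, 4)), sqrt(2))  # sqrt(((2-3)^2+(4-3)^2)/1)
  expect_error(sample_sd(5), "at least 2")
  expect_error(sample_sd(c(3, NA)), "at least 2")
  # brute-force evaluation of the formula on random inputs
  set.seed(1)
  for (i in 1:5) {
    x <- runif(17, 0, 255)
    brute <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
    expect_equal(sample_sd(x), brute)
  }
})

test_that("per-sample summaries match brute-force order statistics", {
  s <- summarize_sample(make_profile(c(5, 5, 5, 5)), sample_id = "a")
  expect_equal(s$mean, 5); expect_equal(s$sd, 0)
  expect_equal(s$median, 5); expect_equal(s$range, 0)

  s2 <- summarize_sample(make_profile(c(1, 2, 3, 4)))
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$sd, sqrt(sum((1:4 - 2.5)^2) / 3))
  expect_equal(s2$median, 2.5)  # midpoint of the two central order stats
  expect_equal(s2$min, 1); expect_equal(s2$max, 4); expect_equal(s2$range, 3)

  expect_equal(summarize_sample(make_profile(c(2, 9, NA, 4)))$n_pixels, 3)
  expect_error(summarize_sample(make_profile(c(1, NA, NA))), "at least 2")
  # sd field agrees with sample_sd to machine precision
  set.seed(2); x <- round(runif(50, 0, 255))
  expect_identical(summarize_sample(make_profile(x))$sd, sample_sd(x))
})

test_that("group summaries pool pixels and bound member ranges", {
  p1 <- make_profile(c(10, 20, 30, 40), "LGD", "a")
  # single sample: group stats equal sample stats
  g1 <- summarize_group(list(p1))
  s1 <- summarize_sample(p1)
  expect_equal(g1[c("mean", "sd", "median", "min", "max", "range")],
               s1[c("mean", "sd", "median", "min", "max", "range")])

  p2 <- make_profile(c(15, 25, 35, 60), "LGD", "b")
  g <- summarize_group(list(p1, p2), "LGD")
  pooled <- c(10, 20, 30, 40, 15, 25, 35, 60)
  expect_equal(g$mean, mean(pooled))
  expect_equal(g$min, 10); expect_equal(g$max, 60)
  expect_equal(g$median, median(pooled))
  expect_equal(g$n_samples, 2)
  # group range covers every member's range
  expect_gte(g$range, s1$range)
  expect_gte(g$range, summarize_sample(p2)$range)
})

test_that("group mean is a consistent estimator of the stage mean", {
  p <- rat_stage_presets()$stages$LGD
  set.seed(77)
  seeds <- sample.int(2^31 - 2, 11)
  profs <- lapply(seeds, function(s) simulated_profile(p, s))
  g <- summarize_group(profs, "LGD")
  se <- sqrt(p$between_sd^2 / 11 + p$within_sd^2 / (11 * 200))
  expect_lt(abs(g$mean - p$mean_g), 3 * se)
})

test_that("scattering histogram conserves counts with right-open bins", {
  tab <- scatter_distribution(list(Control = rep(42, 100)), bin_width = 1)
  occ <- tab[tab$count > 0, ]
  expect_equal(nrow(occ), 1)
  expect_equal(occ$bin_lo, 42); expect_equal(occ$count, 100)

  set.seed(3)
  stages <- list(A = round(runif(500, 0, 255)), B = round(runif(301, 0, 255)))
  tab2 <- scatter_distribution(stages, bin_width = 5)
  sums <- tapply(tab2$count, tab2$stage_label, sum)
  expect_equal(as.vector(sums[c("A", "B")]), c(500, 301))
  expect_error(scatter_distribution(stages, bin_width = 0), "bin_width")
  # boundary value 255 lands in the final bin
  top <- scatter_distribution(list(x = c(255, 255)), bin_width = 1)
  expect_equal(top$count[top$bin_lo == 255], 2)
})

test_that("Control pixels concentrate in the 25-35 band relative to lesions", {
  cfg <- rat_stage_presets()
  set.seed(2718)
  pix <- lapply(cfg$stages[c("Control", "LGD", "HGD_CIS", "Cancer")], function(p) {
    pooled_stage_pixels(p, p$n_animals, sample.int(2^31 - 2, p$n_animals))
  })
  in_band <- vapply(pix, function(v) mean(v >= 25 & v <= 35), numeric(1))
  expect_gt(in_band[["Control"]], 0.6)
  expect_true(all(in_band[["Control"]] > in_band[c("LGD", "HGD_CIS", "Cancer")]))
})

test_that("pairwise concordance matches the direct Pearson formula", {
  base <- make_profile(30 + 0.1 * (0:99))
  expect_equal(group_concordance(list(base, base))$mean_pcc, 1)
  anti <- make_profile(80 - base$values)
  expect_equal(group_concordance(list(base, anti))$mean_pcc, -1)

  set.seed(4)
  a <- 30 + 0.03 * (0:199) + rnorm(200, 0, 0.5)
  b <- 35 + 0.03 * (0:199) + rnorm(200, 0, 0.5)
  res <- group_concordance(list(make_profile(a), make_profile(b)))
  # brute-force covariance formula
  brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$mean_pcc, brute)
  expect_gt(res$mean_pcc, 0.7)
  expect_equal(nrow(res$pairs), 1)
  expect_lt(res$pairs$p, 0.01)

  # unequal lengths are aligned by even-index resampling before correlating
  long <- make_profile(30 + 0.5 * (0:199))
  short <- make_profile(30 + 2 * (0:49))
  expect_gt(group_concordance(list(long, short))$mean_pcc, 0.999)
  expect_error(group_concordance(list(base)), "at least 2")
  expect_error(group_concordance(list(make_profile(1:2), make_profile(1:2))),
               "length >= 3")
})
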