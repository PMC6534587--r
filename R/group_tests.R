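#' One-way (non-repeated measures) ANOVA across stage groups
#'
#' Classical one-way fixed-effects ANOVA on the per-group value lists,
#' computed with [stats::oneway.test()] under equal variances (the textbook
#' F test).
#'
#' @param groups list (optionally named) of numeric vectors, >= 2 groups
#'   with >= 2 values each.
#' @return list with `statistic` (F), `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("anova_oneway needs at least 2 groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) stop("each group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(
    statistic = unname(ht$statistic),
    p = unname(ht$p.value),
    df_between = unname(ht$parameter[1]),
    df_within = unname(ht$parameter[2])
  )
}

# Null distribution of the maximum |Dunnett t| for given group sizes:
# group means drawn N(0, 1/n_j), pooled variance as chi-square(df)/df.
dunnett_null_tmax <- function(sizes, reference_index, n_mc, seed) {
  g <- length(sizes)
  df <- sum(sizes) - g
  set.seed(as.integer(seed))
  z <- matrix(rnorm(n_mc * g), n_mc, g)
  z <- sweep(z, 2L, sqrt(1 / sizes), `*`)
  s2 <- rchisq(n_mc, df) / df
  others <- setdiff(seq_len(g), reference_index)
  tmax <- rep(0, n_mc)
  for (j in others) {
    tj <- abs(z[, j] - z[, reference_index]) /
      sqrt(s2 * (1 / sizes[j] + 1 / sizes[reference_index]))
    tmax <- pmax(tmax, tj)
  }
  tmax
}

#' Monte-Carlo critical value for Dunnett's many-to-one test
#'
#' Two-sided critical value of `max_j |t_j|` under the global null for the
#' balanced-correlation structure induced by a shared reference group,
#' estimated by Monte-Carlo simulation of the joint null distribution.
#'
#' @param sizes integer vector of group sizes (including the reference).
#' @param reference_index index of the reference group in `sizes`.
#' @param alpha familywise error rate (default 0.05).
#' @param n_mc Monte-Carlo replicates (>= 1e4; default 1e5).
#' @param seed integer seed.
#' @return the critical value (scalar).
#' @export
dunnett_critical <- function(sizes, reference_index = 1L, alpha = 0.05,
                             n_mc = 1e5, seed = 1L) {
  if (n_mc < 1e4) stop("n_mc must be >= 1e4 for a stable critical value")
  tmax <- dunnett_null_tmax(as.numeric(sizes), reference_index, n_mc, seed)
  unname(quantile(tmax, 1 - alpha))
}

#' Dunnett-style many-to-one comparisons against a reference group
#'
#' Compares every group to the reference group with the Dunnett t statistic
#' (pooled error variance across all groups), adjusting for multiplicity by
#' the joint null distribution of the maximum absolute statistic, estimated
#' by seeded Monte-Carlo sampling. With a single comparison (k = 1) the
#' adjusted p reduces to the ordinary two-sample pooled t-test p.
#'
#' @param groups named list of numeric vectors (per-animal mean G-values;
#'   pixels within an animal are pseudo-replicates and should be averaged
#'   first).
#' @param reference_index index of the reference (e.g. Control) group.
#' @param alpha familywise error rate for the significance flag.
#' @param n_mc Monte-Carlo replicates for the null distribution (>= 1e4).
#' @param seed integer seed (the result is reproducible under a fixed seed).
#' @return a [tibble::tibble()] with one row per non-reference group:
#'   `comparison_label`, `statistic`, `p_adjusted`, `significant`;
#'   attributes `critical_value`, `df`, `alpha`.
#' @export
dunnett_many_to_one <- function(groups, reference_index = 1L, alpha = 0.05,
                                n_mc = 1e5, seed = 1L) {
  g <- length(groups)
  if (g < 2L) stop("dunnett_many_to_one needs at least 2 groups")
  if (reference_index < 1L || reference_index > g) {
    stop("reference index out of range")
  }
  if (n_mc < 1e4) stop("n_mc must be >= 1e4")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) stop("each group needs at least 2 values")
  labs <- names(groups) %||% paste0("group", seq_len(g))
  means <- vapply(groups, mean, numeric(1))
  df <- sum(sizes) - g
  s2 <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) / df

  others <- setdiff(seq_len(g), reference_index)
  tstat <- (means[others] - means[reference_index]) /
    sqrt(s2 * (1 / sizes[others] + 1 / sizes[reference_index]))

  tmax <- dunnett_null_tmax(as.numeric(sizes), reference_index, n_mc, seed)
  p_adj <- vapply(tstat, function(t) mean(tmax >= abs(t)), numeric(1))
  crit <- unname(quantile(tmax, 1 - alpha))

  out <- tibble::tibble(
    comparison_label = paste(labs[others], "vs", labs[reference_index]),
    statistic = unname(tstat),
    p_adjusted = unname(p_adj),
    significant = unname(p_adj < alpha)
  )
  attr(out, "critical_value") <- crit
  attr(out, "df") <- df
  attr(out, "alpha") <- alpha
  out
}
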