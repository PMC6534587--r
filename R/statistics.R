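#' Sample standard deviation of G-values
#'
#' The variation statistic used to grade scattering:
#' \deqn{S = \sqrt{\frac{1}{N-1} \sum_{i=1}^{N} (x_i - \bar{x})^2}}
#' i.e. the N-1 (sample) denominator. `NA` values (masked pixels) are
#' dropped first.
#'
#' @param values numeric G-values; at least 2 non-missing.
#' @return the sample SD (G-value units).
#' @export
sample_sd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("sample_sd needs at least 2 values")
  sd(values)
}

profile_values <- function(x) {
  if (inherits(x, "measurement_profile")) x$values else as.numeric(x)
}

#' Per-sample intensity summary
#'
#' One row of the per-animal statistics table: pixel count, mean, sample SD,
#' median (midpoint of the two central order statistics for even n), min,
#' max and range of the unmasked G-values of one measurement profile.
#'
#' @param profile a [measurement_profile()] or numeric vector.
#' @param sample_id,stage_label metadata overrides (taken from the profile
#'   when available).
#' @return a one-row [tibble::tibble()].
#' @export
summarize_sample <- function(profile, sample_id = NULL, stage_label = NULL) {
  vals <- profile_values(profile)
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2L) stop("summarize_sample needs at least 2 unmasked values")
  if (inherits(profile, "measurement_profile")) {
    sample_id <- sample_id %||% profile$sample_id
    stage_label <- stage_label %||% profile$stage_label
  }
  tibble::tibble(
    sample_id = sample_id %||% NA_character_,
    stage_label = stage_label %||% NA_character_,
    n_pixels = length(vals),
    mean = mean(vals),
    sd = sd(vals),
    median = median(vals),
    min = min(vals),
    max = max(vals),
    range = max(vals) - min(vals)
  )
}

#' Per-group (stage) intensity summary
#'
#' Pools all unmasked pixels of a stage's profiles and computes the group
#' statistics (mean, SD, median, min, max, range) over the pooled pixels,
#' plus the mean pairwise Pearson correlation between the profiles (see
#' [group_concordance()]). Pooling over pixels (rather than averaging
#' per-animal summaries) is used because the published group extremes span
#' pixel-level values.
#'
#' @param profiles list of [measurement_profile()]s (or numeric vectors)
#'   belonging to one stage.
#' @param stage_label stage name for the output row.
#' @return a one-row [tibble::tibble()] with columns `stage_label`,
#'   `n_samples`, `mean`, `sd`, `median`, `min`, `max`, `range`,
#'   `mean_pcc`, `pcc_low`, `pcc_high`.
#' @export
summarize_group <- function(profiles, stage_label = NA_character_) {
  if (!length(profiles)) stop("summarize_group needs at least 1 sample")
  if (inherits(profiles, "measurement_profile")) profiles <- list(profiles)
  pooled <- unlist(lapply(profiles, profile_values))
  pooled <- pooled[!is.na(pooled)]
  if (is.na(stage_label) && inherits(profiles[[1]], "measurement_profile")) {
    stage_label <- profiles[[1]]$stage_label
  }
  pcc <- if (length(profiles) >= 2L) {
    group_concordance(profiles)
  } else {
    list(mean_pcc = NA_real_, pcc_low = NA_real_, pcc_high = NA_real_)
  }
  tibble::tibble(
    stage_label = stage_label,
    n_samples = length(profiles),
    mean = mean(pooled),
    sd = sd(pooled),
    median = median(pooled),
    min = min(pooled),
    max = max(pooled),
    range = max(pooled) - min(pooled),
    mean_pcc = pcc$mean_pcc,
    pcc_low = pcc$pcc_low,
    pcc_high = pcc$pcc_high
  )
}

#' Pixel-distribution (scattering) table across stages
#'
#' Histograms the pooled unmasked G-values of each stage over `[0, 255]`
#' with right-open bins `[lo, lo + bin_width)`; the final bin also includes
#' 255 so counts are conserved. The widening of these distributions with
#' tumor progression is the "scattering" readout.
#'
#' @param profiles_by_stage named list: stage label -> list of profiles (or
#'   a numeric vector of pooled pixels).
#' @param bin_width bin width in G-values (> 0); default 1, the native
#'   8-bit quantization.
#' @return a [tibble::tibble()] with columns `stage_label`, `bin_lo`,
#'   `bin_hi`, `count`; bin edges attached as attribute `bin_edges`.
#' @export
scatter_distribution <- function(profiles_by_stage, bin_width = 1) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  edges <- seq(0, 256, by = bin_width)
  if (edges[length(edges)] < 256) edges <- c(edges, 256)
  rows <- lapply(names(profiles_by_stage), function(lab) {
    x <- profiles_by_stage[[lab]]
    if (!is.numeric(x)) x <- unlist(lapply(x, profile_values))
    x <- x[!is.na(x)]
    idx <- findInterval(x, edges, rightmost.closed = TRUE)
    counts <- tabulate(idx, nbins = length(edges) - 1L)
    tibble::tibble(
      stage_label = lab,
      bin_lo = edges[-length(edges)],
      bin_hi = edges[-1],
      count = counts
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "bin_edges") <- edges
  out
}

#' Pairwise Pearson concordance between profiles of a group
#'
#' Measures how uniformly tumor progression advanced within a group:
#' every unordered pair of apex-to-root profiles is aligned on normalized
#' position (profiles longer than the shortest are resampled by even index
#' selection) and correlated. Per-pair p-values come from the standard
#' t transform of r ([stats::cor.test()]); they are reported, not used for
#' gating.
#'
#' @param profiles list of at least 2 profiles (or numeric vectors), each
#'   of length >= 3.
#' @return list with `mean_pcc`, `pcc_low`, `pcc_high` (min/max pairwise r)
#'   and `pairs`, a tibble of per-pair r and p.
#' @export
group_concordance <- function(profiles) {
  if (length(profiles) < 2L) stop("group_concordance needs at least 2 profiles")
  vals <- lapply(profiles, profile_values)
  lens <- vapply(vals, length, integer(1))
  if (any(lens < 3L)) stop("profiles must have length >= 3")
  m <- min(lens)
  aligned <- lapply(vals, function(v) {
    if (length(v) == m) v else v[round(seq(1, length(v), length.out = m))]
  })
  combos <- utils::combn(length(aligned), 2L)
  rows <- apply(combos, 2L, function(ij) {
    a <- aligned[[ij[1]]]; b <- aligned[[ij[2]]]
    ok <- !is.na(a) & !is.na(b)
    ct <- cor.test(a[ok], b[ok])
    c(i = ij[1], j = ij[2], r = unname(ct$estimate), p = ct$p.value)
  })
  pairs <- tibble::as_tibble(t(rows))
  list(
    mean_pcc = mean(pairs$r),
    pcc_low = min(pairs$r),
    pcc_high = max(pairs$r),
    pairs = pairs
  )
}
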