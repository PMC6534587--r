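#' ROC curve points for a lesion-vs-reference comparison
#'
#' Sweeps the decision threshold over all distinct observed G-values and
#' returns the (FPR, TPR) staircase from (0,0) to (1,1). The calling
#' direction (lesion when value >= threshold, or <= threshold) is chosen
#' automatically so the resulting AUC is >= 0.5, and recorded in the
#' output's `direction` attribute (`"gte"` / `"lte"`).
#'
#' @param lesion_values G-values of the positive (lesion) class.
#' @param reference_values G-values of the negative (reference) class.
#' @return a [tibble::tibble()] with columns `threshold`, `fpr`, `tpr`,
#'   ordered from (0,0) to (1,1); attributes `direction`, `mean_pos`,
#'   `mean_neg`, `n_pos`, `n_neg`.
#' @export
roc_points <- function(lesion_values, reference_values) {
  lesion_values <- lesion_values[!is.na(lesion_values)]
  reference_values <- reference_values[!is.na(reference_values)]
  if (!length(lesion_values) || !length(reference_values)) {
    stop("both groups must be non-empty")
  }
  # pick the calling direction from the rank statistic so AUC >= 0.5
  r <- rank(c(lesion_values, reference_values))
  n1 <- length(lesion_values); n2 <- length(reference_values)
  u_auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  direction <- if (u_auc >= 0.5) "gte" else "lte"
  uniq <- sort(unique(c(lesion_values, reference_values)))
  if (direction == "gte") {
    thr <- c(Inf, rev(uniq))
    tpr <- vapply(thr, function(t) mean(lesion_values >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(reference_values >= t), numeric(1))
  } else {
    thr <- c(-Inf, uniq)
    tpr <- vapply(thr, function(t) mean(lesion_values <= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(reference_values <= t), numeric(1))
  }
  out <- tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)
  attr(out, "direction") <- direction
  attr(out, "mean_pos") <- mean(lesion_values)
  attr(out, "mean_neg") <- mean(reference_values)
  attr(out, "n_pos") <- length(lesion_values)
  attr(out, "n_neg") <- length(reference_values)
  out
}

#' Trapezoidal area under an ROC curve
#'
#' On the threshold-sweep staircase of [roc_points()], the trapezoidal area
#' equals the tie-corrected Mann-Whitney statistic `U / (n1 n2)`.
#'
#' @param roc output of [roc_points()] (or any data frame with monotone
#'   `fpr`, `tpr` columns from (0,0) to (1,1)).
#' @return the AUC (dimensionless, in `[0, 1]`).
#' @export
auc_trapezoid <- function(roc) {
  fpr <- roc$fpr; tpr <- roc$tpr
  n <- length(fpr)
  sum(diff(fpr) * (tpr[-1] + tpr[-n]) / 2)
}

#' Youden-index cutoff from an ROC sweep
#'
#' Selects the threshold maximizing Youden's J = TPR - FPR. Ties are broken
#' toward the threshold nearest the midpoint of the two group means. The
#' reported G-value cutoff is the midpoint between the selected threshold
#' and the adjacent distinct observed value (the usual reported operating
#' point between two observable intensities). When no threshold separates
#' the groups at all (max J ~ 0) the result is flagged `degenerate`.
#'
#' @param roc output of [roc_points()].
#' @return list with `cutoff` (reported G-value), `threshold` (observed
#'   value attaining max J), `youden`, `sensitivity` and `specificity`
#'   (percent, at the cutoff), `direction`, `degenerate`.
#' @export
youden_cutoff <- function(roc) {
  j <- roc$tpr - roc$fpr
  best <- max(j)
  cand <- which(j > best - 1e-12)
  cand <- cand[is.finite(roc$threshold[cand])]
  if (!length(cand)) cand <- which.max(j)
  mid <- (attr(roc, "mean_pos") + attr(roc, "mean_neg")) / 2
  pick <- cand[which.min(abs(roc$threshold[cand] - mid))]
  thr <- roc$threshold[pick]
  # midpoint with the adjacent distinct value on the non-calling side
  obs <- sort(unique(roc$threshold[is.finite(roc$threshold)]))
  i <- match(thr, obs)
  cutoff <- if (attr(roc, "direction") == "gte") {
    if (!is.na(i) && i > 1L) (obs[i - 1L] + thr) / 2 else thr
  } else {
    if (!is.na(i) && i < length(obs)) (obs[i + 1L] + thr) / 2 else thr
  }
  list(
    cutoff = cutoff,
    threshold = thr,
    youden = best,
    sensitivity = 100 * roc$tpr[pick],
    specificity = 100 * (1 - roc$fpr[pick]),
    direction = attr(roc, "direction"),
    degenerate = best < 1e-9
  )
}

#' Mann-Whitney p-value for an AUC (normal approximation)
#' @noRd
auc_p_value <- function(auc, pos, neg) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  n1 <- length(pos); n2 <- length(neg); n <- n1 + n2
  u <- auc * n1 * n2
  ties <- table(c(pos, neg))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- (n1 * n2 / 12) * (n + 1 - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  2 * pnorm(-abs(z))
}

#' ROC comparisons between stage groups
#'
#' Runs the full cutoff-threshold analysis for a list of stage comparisons
#' (e.g. Control vs each lesion stage, LGD vs higher grades). Pooled
#' comparisons take the union of the listed stages; by convention the class
#' listed first in each comparison is the positive class, and sensitivity
#' is its true-positive rate at the Youden cutoff.
#'
#' @param groups named list: stage label -> vector of G-values (pooled
#'   pixels, or per-animal means).
#' @param comparisons list of comparison specs, each a list with `label`,
#'   `positive` (character vector of stage labels) and `negative`; defaults
#'   to [default_stage_comparisons()].
#' @return a [tibble::tibble()] with one row per comparison: `comparison`,
#'   `cutoff`, `auc`, `p`, `sensitivity`, `specificity`, `n_pos`, `n_neg`,
#'   `direction`, `degenerate`.
#' @export
stage_comparison <- function(groups, comparisons = default_stage_comparisons()) {
  labs <- names(groups)
  rows <- lapply(comparisons, function(cmp) {
    unknown <- setdiff(c(cmp$positive, cmp$negative), labs)
    if (length(unknown)) {
      stop("unknown stage label in comparison spec: ", paste(unknown, collapse = ", "))
    }
    pos <- unlist(groups[cmp$positive], use.names = FALSE)
    neg <- unlist(groups[cmp$negative], use.names = FALSE)
    roc <- roc_points(pos, neg)
    auc <- auc_trapezoid(roc)
    yc <- youden_cutoff(roc)
    tibble::tibble(
      comparison = cmp$label,
      cutoff = yc$cutoff,
      auc = auc,
      p = auc_p_value(auc, pos, neg),
      sensitivity = yc$sensitivity,
      specificity = yc$specificity,
      n_pos = length(pos),
      n_neg = length(neg),
      direction = yc$direction,
      degenerate = yc$degenerate
    )
  })
  do.call(rbind, rows)
}

#' The eleven animal-model stage comparisons
#'
#' The standard comparison grid for the four-stage rat model, from
#' control-vs-lesion discrimination through between-lesion grading. The
#' first-listed class of each row is treated as positive.
#'
#' @return list of comparison specs for [stage_comparison()].
#' @export
default_stage_comparisons <- function() {
  cmp <- function(label, positive, negative) {
    list(label = label, positive = positive, negative = negative)
  }
  list(
    cmp("Control vs LGD, HGD/CIS, Ca", "Control", c("LGD", "HGD_CIS", "Cancer")),
    cmp("Control vs LGD", "Control", "LGD"),
    cmp("Control vs HGD", "Control", "HGD_CIS"),
    cmp("Control vs Ca", "Control", "Cancer"),
    cmp("LGD vs HGD", "LGD", "HGD_CIS"),
    cmp("LGD vs Ca", "LGD", "Cancer"),
    cmp("HGD vs Ca", "HGD_CIS", "Cancer"),
    cmp("Control, LGD vs HGD, Ca", c("Control", "LGD"), c("HGD_CIS", "Cancer")),
    cmp("Control, LGD, HGD vs Ca", c("Control", "LGD", "HGD_CIS"), "Cancer"),
    cmp("LGD vs HGD, Ca", "LGD", c("HGD_CIS", "Cancer")),
    cmp("LGD, HGD vs Ca", c("LGD", "HGD_CIS"), "Cancer")
  )
}

#' Closed-form AUC for two Gaussian classes
#'
#' For classes `N(mu1, sd1^2)` and `N(mu2, sd2^2)` the ROC area is exactly
#' `Phi(|mu2 - mu1| / sqrt(sd1^2 + sd2^2))`. Used as the analytic oracle
#' for AUCs measured on the Gaussian synthetic cohorts.
#'
#' @param mu1,sd1 mean and SD of the first class.
#' @param mu2,sd2 mean and SD of the second class.
#' @return the AUC (dimensionless).
#' @export
gaussian_auc_oracle <- function(mu1, sd1, mu2, sd2) {
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0")
  s <- sqrt(sd1^2 + sd2^2)
  if (s == 0) {
    if (mu1 == mu2) stop("both SDs zero with equal means: AUC undefined")
    return(1)
  }
  pnorm(abs(mu2 - mu1) / s)
}

#' Published cutoff-threshold table
#'
#' The printed ROC reference table for the animal model (11 comparisons)
#' or the human application (6 comparisons), shipped with the package:
#' cutoff G-value, AUC, p label, sensitivity and specificity percent.
#'
#' @param model `"rat"` or `"human"`.
#' @return a [tibble::tibble()].
#' @export
roc_reference <- function(model = c("rat", "human")) {
  model <- match.arg(model)
  path <- system.file("extdata", paste0("table2_reference_", model, ".csv"),
                      package = "fiquant")
  tibble::as_tibble(read.csv(path, check.names = TRUE, stringsAsFactors = FALSE))
}

#' Summary arithmetic on the published animal ROC table
#'
#' Recomputes the headline aggregates quoted for the animal comparisons:
#' mean sensitivity and specificity over the four control-vs-lesion rows,
#' their mean cutoff, and the mean cutoff of the LGD-vs-higher-grade rows
#' (5, 6 and 10).
#'
#' @return a [tibble::tibble()] with columns `quantity` and `value`.
#' @export
roc_reference_summary <- function() {
  tab <- roc_reference("rat")
  r14 <- tab[tab$row %in% 1:4, ]
  r5610 <- tab[tab$row %in% c(5, 6, 10), ]
  tibble::tibble(
    quantity = c(
      "mean_sensitivity_control_vs_lesion",
      "mean_specificity_control_vs_lesion",
      "mean_cutoff_control_vs_lesion",
      "mean_cutoff_lgd_vs_higher"
    ),
    value = c(
      mean(r14$sensitivity),
      mean(r14$specificity),
      mean(r14$cutoff),
      mean(r5610$cutoff)
    )
  )
}
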