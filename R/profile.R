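#' Measurement line specification
#'
#' The apex-to-root measurement line: `start` is the tongue apex (A),
#' `end` the tongue root (R), both as 0-based `(x, y)` pixel coordinates
#' with origin top-left. `n_points` samples are taken evenly along the
#' segment (200 for the rat model, 50 for the human sites).
#'
#' @param start,end numeric length-2 vectors `c(x, y)`.
#' @param n_points number of samples along the line (>= 2).
#' @return an object of class `line_spec`.
#' @export
line_spec <- function(start, end, n_points) {
  stopifnot(length(start) == 2L, length(end) == 2L)
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be >= 2")
  if (all(start == end)) stop("line start and end must differ")
  structure(
    list(start = as.numeric(start), end = as.numeric(end), n_points = n_points),
    class = "line_spec"
  )
}

#' Measurement profile container
#'
#' Ordered G-values sampled along the apex-to-root line, with positions in
#' pixel distance from the apex. Masked samples are `NA` and excluded from
#' downstream statistics.
#'
#' @param values numeric G-values (NA = masked).
#' @param positions strictly increasing pixel distances from the apex.
#' @param stage_label,sample_id optional metadata.
#' @return an object of class `measurement_profile`.
#' @export
measurement_profile <- function(values, positions, stage_label = NA_character_,
                                sample_id = NA_character_) {
  stopifnot(length(values) == length(positions))
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  structure(
    list(values = as.numeric(values), positions = as.numeric(positions),
         stage_label = stage_label, sample_id = sample_id),
    class = "measurement_profile"
  )
}

#' @export
length.measurement_profile <- function(x) length(x$values)

#' @export
print.measurement_profile <- function(x, ...) {
  cat(sprintf(
    "<measurement_profile> %s/%s: %d points (%d masked), mean G %.1f\n",
    x$stage_label, x$sample_id, length(x$values), sum(is.na(x$values)),
    mean(x$values, na.rm = TRUE)
  ))
  invisible(x)
}

#' Sample the measurement-line profile from an image
#'
#' Takes `n_points` evenly spaced samples along the A-to-R segment. The
#' default `"nearest"` method looks up the nearest pixel: G-values are
#' 8-bit categories, and interpolation would fabricate non-observable
#' intensities. Bilinear interpolation is available for sub-pixel lines.
#' Masked pixels are recorded as `NA`.
#'
#' @param image a [gvalue_image()].
#' @param line a [line_spec()]; endpoints must lie inside the image.
#' @param method `"nearest"` (default) or `"bilinear"`.
#' @param stage_label,sample_id metadata carried into the profile.
#' @return a [measurement_profile()].
#' @export
extract_line_profile <- function(image, line, method = c("nearest", "bilinear"),
                                 stage_label = NA_character_,
                                 sample_id = NA_character_) {
  stopifnot(inherits(image, "gvalue_image"), inherits(line, "line_spec"))
  method <- match.arg(method)
  w <- ncol(image$pixels); h <- nrow(image$pixels)
  pts <- rbind(line$start, line$end)
  if (any(pts[, 1] < 0 | pts[, 1] > w - 1 | pts[, 2] < 0 | pts[, 2] > h - 1)) {
    stop("measurement line exits image bounds")
  }
  t <- seq(0, 1, length.out = line$n_points)
  xs <- line$start[1] + t * (line$end[1] - line$start[1])
  ys <- line$start[2] + t * (line$end[2] - line$start[2])
  if (method == "nearest") {
    xi <- round(xs); yi <- round(ys)
    vals <- image$pixels[cbind(yi + 1, xi + 1)]
    masked <- image$mask[cbind(yi + 1, xi + 1)]
  } else {
    x0 <- pmin(floor(xs), w - 2); y0 <- pmin(floor(ys), h - 2)
    fx <- xs - x0; fy <- ys - y0
    p <- image$pixels
    vals <- (1 - fx) * (1 - fy) * p[cbind(y0 + 1, x0 + 1)] +
      fx * (1 - fy) * p[cbind(y0 + 1, x0 + 2)] +
      (1 - fx) * fy * p[cbind(y0 + 2, x0 + 1)] +
      fx * fy * p[cbind(y0 + 2, x0 + 2)]
    m <- image$mask
    masked <- m[cbind(y0 + 1, x0 + 1)] | m[cbind(y0 + 1, x0 + 2)] |
      m[cbind(y0 + 2, x0 + 1)] | m[cbind(y0 + 2, x0 + 2)]
  }
  vals[masked] <- NA_real_
  if (all(is.na(vals))) stop("all points on the measurement line are masked")
  len <- sqrt(sum((line$end - line$start)^2))
  measurement_profile(vals, t * len, stage_label, sample_id)
}

#' Height matrix for surface plots
#'
#' Returns the G-value grid for 3D surface plotting, optionally smoothed
#' with a square box filter. Masked cells are set to `NA`. With smoothing,
#' the filter is normalized by the full window area (zero padding), so a
#' single-pixel spike of mass 1 spreads to 1/w^2 per covered cell.
#'
#' @param image a [gvalue_image()].
#' @param smooth box window width in pixels (odd; 0 or 1 = no smoothing).
#' @return numeric matrix of heights (`NA` where masked).
#' @export
surface_matrix <- function(image, smooth = 0L) {
  stopifnot(inherits(image, "gvalue_image"))
  smooth <- as.integer(smooth)
  out <- image$pixels
  if (smooth > 1L) {
    if (smooth %% 2L == 0L) stop("smoothing window must be odd")
    half <- smooth %/% 2L
    h <- nrow(out); w <- ncol(out)
    padded <- matrix(0, h + 2 * half, w + 2 * half)
    padded[half + seq_len(h), half + seq_len(w)] <- image$pixels
    acc <- matrix(0, h, w)
    for (dy in -half:half) {
      for (dx in -half:half) {
        acc <- acc + padded[half + seq_len(h) + dy, half + seq_len(w) + dx]
      }
    }
    out <- acc / smooth^2
  }
  out[image$mask] <- NA_real_
  out
}
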