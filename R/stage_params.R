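#' Stage generator parameters
#'
#' Bundle of generator parameters for one histological stage of the tongue
#' carcinogenesis model. The parameters are phrased in terms of what a
#' measurement line through a sample of that stage *looks like*:
#'
#' * `mean_g` is the expected mean G-value along the measurement line of a
#'   typical animal of the stage (stage population mean).
#' * `between_sd` is the SD of per-animal line means around `mean_g`.
#' * `within_sd` is the total sample SD of G-values along one animal's
#'   measurement line -- the quantity the sample-standard-deviation analysis
#'   reports. It subsumes the axial gradient, dark-spot depressions and
#'   per-pixel noise; the generator decomposes it internally (see
#'   [generate_animal_field()]).
#' * `axial_slope` / `slope_sd` give the mean and between-animal SD of the
#'   apex-to-root linear intensity gradient (G-value per pixel).
#' * `spot_rate` is the expected number of dark spots per 100 pixels of
#'   line, each a top-hat depression `spot_depth` G-values deep and
#'   `spot_width` pixels wide.
#'
#' @param stage_label one of `"Control"`, `"LGD"`, `"HGD_CIS"`, `"Cancer"`.
#' @param mean_g stage mean G-value, in `[0, 255]`.
#' @param between_sd SD of per-animal mean G-values (>= 0).
#' @param within_sd total within-line sample SD (>= 0).
#' @param axial_slope mean apex-to-root gradient, G-value per pixel.
#' @param slope_sd between-animal SD of the gradient (>= 0).
#' @param spot_rate expected dark spots per 100 px of line (>= 0).
#' @param spot_depth G-values subtracted inside a spot (>= 0).
#' @param spot_width spot width in pixels (>= 1).
#' @param n_animals number of animals (samples) in the stage cohort (>= 1).
#'
#' @return an object of class `stage_params`.
#' @export
stage_params <- function(stage_label,
                         mean_g,
                         between_sd,
                         within_sd,
                         axial_slope = 0,
                         slope_sd = 0,
                         spot_rate = 0,
                         spot_depth = 0,
                         spot_width = 3,
                         n_animals = 1) {
  stage_label <- match.arg(stage_label, stage_levels())
  stopifnot(is.numeric(mean_g), length(mean_g) == 1L)
  if (mean_g < 0 || mean_g > 255) {
    stop("mean_g must lie in [0, 255], got ", mean_g)
  }
  if (between_sd < 0) stop("between_sd must be >= 0")
  if (within_sd < 0) stop("within_sd must be >= 0")
  if (slope_sd < 0) stop("slope_sd must be >= 0")
  if (spot_rate < 0) stop("spot_rate must be >= 0")
  if (spot_depth < 0) stop("spot_depth must be >= 0")
  if (spot_width < 1) stop("spot_width must be >= 1 pixel")
  if (n_animals < 1) stop("n_animals must be >= 1")
  if (stage_label == "Control" && spot_rate > 0) {
    stop("Control presets must have spot_rate = 0 (normal mucosa shows no dark spots)")
  }
  if (stage_label == "Control" && axial_slope < 0) {
    stop("Control axial_slope must be >= 0 (control slopes are all positive)")
  }
  structure(
    list(
      stage_label = stage_label,
      mean_g = as.numeric(mean_g),
      between_sd = as.numeric(between_sd),
      within_sd = as.numeric(within_sd),
      axial_slope = as.numeric(axial_slope),
      slope_sd = as.numeric(slope_sd),
      spot_rate = as.numeric(spot_rate),
      spot_depth = as.numeric(spot_depth),
      spot_width = as.integer(spot_width),
      n_animals = as.integer(n_animals)
    ),
    class = "stage_params"
  )
}

#' @export
print.stage_params <- function(x, ...) {
  cat(sprintf(
    "<stage_params> %s: mean %.1f (between-SD %.2f, within-SD %.2f), slope %+.3f (SD %.3f), spots %.1f/100px depth %.1f width %d, n = %d\n",
    x$stage_label, x$mean_g, x$between_sd, x$within_sd,
    x$axial_slope, x$slope_sd, x$spot_rate, x$spot_depth,
    x$spot_width, x$n_animals
  ))
  invisible(x)
}

stage_levels <- function() c("Control", "LGD", "HGD_CIS", "Cancer")

#' Decompose the total within-line SD into its pixel-noise component
#'
#' The published within-sample SD is measured on the raw line profile, so it
#' already contains the variance contributed by the axial gradient and the
#' dark spots. Given a line of `n_points` pixels, the generator therefore
#' draws per-pixel Gaussian noise with
#' `noise_sd^2 = within_sd^2 - E[a^2] * var(x) - p(1-p) * depth^2`,
#' where `a` is the (random) axial slope, `x` the line positions, and
#' `p = spot_rate * spot_width / 100` the expected fraction of line pixels
#' inside a spot. Errors if the stated components already exceed the target
#' total (an infeasible calibration).
#'
#' @param params a [stage_params()] object.
#' @param n_points number of pixels on the measurement line.
#' @return the pixel-noise SD (G-value units).
#' @export
pixel_noise_sd <- function(params, n_points) {
  stopifnot(inherits(params, "stage_params"), n_points >= 2)
  x <- seq_len(n_points) - 1
  slope_var <- (params$axial_slope^2 + params$slope_sd^2) * var(x)
  p <- min(params$spot_rate * params$spot_width / 100, 1)
  spot_var <- p * (1 - p) * params$spot_depth^2
  noise_var <- params$within_sd^2 - slope_var - spot_var
  if (noise_var < 0) {
    stop(sprintf(
      "infeasible calibration for %s: gradient + spot variance (%.2f) exceeds within_sd^2 (%.2f)",
      params$stage_label, slope_var + spot_var, params$within_sd^2
    ))
  }
  sqrt(noise_var)
}

#' Read a cohort configuration file
#'
#' A cohort config is a YAML file with keys `model` (free label), `n_points`
#' (measurement-line length in pixels), `height` (image height in pixels)
#' and `stages`, a map of stage label to [stage_params()] fields.
#'
#' @param path path to a YAML cohort configuration.
#' @return a list with elements `model`, `n_points`, `height` and `stages`
#'   (named list of `stage_params`).
#' @export
read_stage_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$stages) || length(raw$stages) == 0) {
    stop("no stages configured")
  }
  stages <- lapply(names(raw$stages), function(lab) {
    do.call(stage_params, c(list(stage_label = lab), raw$stages[[lab]]))
  })
  names(stages) <- names(raw$stages)
  list(
    model = raw$model %||% "unnamed",
    n_points = as.integer(raw$n_points %||% 200L),
    height = as.integer(raw$height %||% 64L),
    stages = stages
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrated stage presets for the rat carcinogenesis cohort
#'
#' Presets for the four-stage rat tongue model (Control, LGD, HGD/CIS,
#' Cancer): stage means and between-animal SDs from the published group
#' table, within-line SDs from the published sample-SD table, axial slopes
#' from the inclination-line analysis, and spot parameters chosen so pooled
#' pixel ranges approximate the published per-group ranges. Cohort sizes are
#' 10/11/15/14 animals on 200-pixel measurement lines.
#'
#' @return cohort config list (same shape as [read_stage_config()]).
#' @export
rat_stage_presets <- function() {
  read_stage_config(system.file("extdata", "rat_cohort.yaml", package = "fiquant"))
}

#' Calibrated presets for the four human tongue measurement sites
#'
#' One 50-pixel measurement line per site (Normal/control, LGD, HGD/CIS,
#' Cancer) from a single patient; site means from the clinical application
#' and within-line SDs from the human sample-SD row. With a single site per
#' stage there is no between-site replication, so `between_sd = 0` and no
#' axial gradient is imposed.
#'
#' @return cohort config list (same shape as [read_stage_config()]).
#' @export
human_site_presets <- function() {
  read_stage_config(system.file("extdata", "human_sites.yaml", package = "fiquant"))
}
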